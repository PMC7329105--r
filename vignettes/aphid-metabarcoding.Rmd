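---
title: "Molecular diet analysis of aphidophagous predators with aphidiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular diet analysis of aphidophagous predators with aphidiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidiet)
```

## The problem

Ladybirds (*Coccinella septempunctata*, *Harmonia axyridis*) and other
aphidophagous predators consume aphids whose remains can be identified
from gut-content DNA by amplicon sequencing of a short fragment of the
mitochondrial COI barcode. Doing this well requires four linked pieces
of methodology, each of which this package implements as a testable
module:

1. **Primer evaluation** (`gc_content()`, `molecular_weight()`,
   `melting_temperature()`, `align_binding()`, `binding_penalty()`,
   `pair_coverage()`): group-specific degenerate primers must amplify
   the prey (aphids) while excluding the predator itself, otherwise
   predator DNA swamps the sequencing library.
2. **Marker resolution** (`pairwise_identity()`,
   `classify_resolvability()`, `optimize_threshold()`,
   `similarity_summary()`): a ~308 bp amplicon resolves some aphid
   genera to species and others not; the species-assignment identity
   threshold has to be derived from a labelled reference library.
3. **Read pipeline** (`quality_trim()`, `merge_pairs()`,
   `demultiplex()`, `dereplicate()`, `abundance_filter()`,
   `screen_chimeras()`, `cluster_centroids()`, `assign_taxon()`,
   `run_pipeline()`): paired-end MID-tagged reads become per-individual
   prey detections through a fixed sequence of filters.
4. **Composition statistics** (`recovery_rates()`,
   `composition_matrix()`, `hellinger()`, `permanova()`,
   `dispersion_test()`, `nmds()`): detection tables become recovery
   rates and multivariate comparisons of diet composition.

A fifth module (`simulate_library()`, `simulate_gut_samples()`,
`simulate_null_composition()`) generates all inputs with known ground
truth, so the whole chain is exercised end-to-end without any
sequencing data or downloads.

## Primer binding model

Degenerate primers are IUPAC strings; a position like W (A/T)
represents a synthesised mixture. Physical properties treat a
degenerate position as the mean over its possibilities, which makes GC
content and molecular weight exactly linear: the value of a degenerate
primer equals the mean over its concrete expansions (a tested
invariant). Molecular weight uses per-base monophosphate masses
(A 313.21, C 289.18, G 329.21, T 304.20 g/mol) minus 61.96 g/mol for
the missing 5' phosphate. Note that reported weights can land exactly
on a `.05` tie at the customary 0.1 g/mol reporting precision; the
functions therefore return unrounded values and leave reporting
rounding (`digits = 1`) to the caller. Melting temperature offers the
Wallace rule (2(A+T) + 4(G+C), degenerate positions fractional) and a
nearest-neighbour model (unified thermodynamic parameters, 50 mM
monovalent salt, 0.5 µM oligo, expansions averaged); different
calculators differ by several °C, so Tm is reported with its method
and never used as a decision criterion.

Amplification success is predicted by a position-weighted mismatch
penalty. The scoring table is deliberately simple and fully
overridable via `mismatch_scheme()`:

* transitions cost 15 points, transversions 30 — transversion
  mispairs destabilise extension more;
* positions 1–6 from the 3' end carry weights 5, 4, 3, 2, 1.5, 1.2
  (1 beyond) — polymerase extension is most sensitive to 3' mispairs;
* adjacent mismatches are each multiplied by 1.5; gaps (optional
  gapped mode) cost a flat 40;
* a template fails when the total exceeds 120.

With these defaults a single 3'-terminal transversion (30 × 5 = 150)
abolishes amplification, a single terminal transition (75) does not,
and four or fewer internal mismatches (≤ 120) pass. The calibration
reflects qualitative primer-design practice rather than measured
thermodynamics; consumers needing a different regime override the
scheme. A primer pair covers a template only if **both** primers pass,
so group coverage can never exceed either single-primer coverage
(tested). Reverse primers are evaluated on the reverse complement of
the template, and strand symmetry is asserted against a
forward-on-reverse-complement oracle.

## Identity, resolvability and the threshold search

Percent identity between barcodes is defined as matches over alignment
columns within the mutually covered region: equal-length sequences are
compared columnwise without gaps; otherwise a global alignment with
free end gaps is used, internal gaps count as mismatches, end gaps are
ignored, and ambiguity codes match compatibly. This is the common
barcoding convention; tools differ here, which is why the package
documents one convention and applies it uniformly to both the
resolution analysis and pipeline assignment.

A query resolves to **species** when every other record matching at or
above the threshold belongs to the query's own species, to **genus**
when matches stay within its genus, and is **unresolved** when matches
span genera or none exist. `optimize_threshold()` starts from a
permissive value (90%) and scans all observed pairwise identities plus
midpoints, scoring lexicographically: first minimise retained
cross-species matches, then maximise species-level classifications,
returning the smallest optimal candidate. Candidates are restricted to
observed values and midpoints to avoid arbitrary grids; the search is
verified against an independently coded exhaustive oracle in the test
suite. Two congeneric species sharing a barcode can never be separated
— the corresponding genus stays genus-level at every threshold, which
is exactly the behaviour expected for taxonomically difficult aphid
genera such as *Aphis*.

Records covering fewer than 296 bases of the amplicon are excluded
(`filter_by_coverage()`, boundary inclusive: exactly 296 is kept), and
assignment additionally requires at least 296 aligned bases.

## Pipeline stage semantics

The pipeline reimplements the semantics of the usual third-party tools
(adapter clipping, sliding-window trimming, overlap merging, oligo
demultiplexing, denoising, centroid clustering) in simplified,
documented form; bit-equivalence with any external binary is a
non-goal — the thresholds, not the binaries, define the analysis.

* **Quality trimming** clips leading/trailing bases below Phred 3,
  cuts at the first 4-base window with mean quality below 20 (keeping
  bases before the window start), and discards reads shorter than
  250 bases.
* **Merging** reverse-complements the second read, scores every
  overlap of at least 10 bases by mismatch fraction, accepts the best
  (longest on ties) if at most 25% mismatched, and takes the
  higher-quality base at conflicts.
* **Demultiplexing** assigns a read if and only if exactly one
  sample's forward/reverse MID tag pair matches with at most one
  mismatch per tag; ambiguous reads are never arbitrarily assigned but
  go to the unassigned pool with a reason code. Tags and primers are
  then stripped.
* **Abundance filtering** keeps uniques with at least `min_size`
  reads within their sample (default 10; "fewer than 10" removed, so
  exactly 10 is kept). `tag_jump_threshold()` raises this per pool to
  one more than the largest detection observed where none is possible
  (negative controls, alien spike-ins) — a defensible, monotone
  realization of abundance-based tag-jump mitigation.
* **Chimera screening** flags a unique that can be split at one
  crossover into prefix and suffix matching two distinct more-abundant
  uniques (each parent at least twice the child's size); the most
  abundant unique can never be flagged. Together with dereplication
  and the abundance filter this approximates denoising; each stage can
  be disabled by its parameters.
* **Clustering** is greedy single-pass at 99% identity over
  size-sorted input (ties broken lexicographically for
  reproducibility): join the first centroid within the radius, else
  found one. The membership invariant is tested against a brute-force
  oracle.
* **Assignment** requires ≥ 98.36% identity over ≥ 296 aligned bases;
  species if all matches are conspecific, genus if they span species
  of one genus, unassigned otherwise. Predator-assigned and unassigned
  reads are tallied separately from the prey detection matrix, so an
  individual with only predator reads appears as a legitimate all-zero
  row ("negative for aphids").

The pipeline is deterministic given the input order — there is no
random step — and every stage logs reads in/out/discarded; the test
suite asserts exact conservation and stage chaining.

## Composition statistics

Detection matrices aggregate to composition units (landscape ×
sampling round × predator species by default); cells are the
proportion of the unit's individuals in which a taxon was detected, so
rows sum to 1 (or 0 for empty units, which are retained and flagged).
The Hellinger transform (square root of row proportions) makes
Euclidean distances appropriate for relative data with many zeros.

`permanova()` implements the one-factor pseudo-F from the among/within
partition of squared distances with label permutations restricted
within strata (sampling rounds), so temporal structure cannot
masquerade as a diet difference. The p-value includes the observed
ordering: `p = (1 + #{F* ≥ F}) / (1 + n_perm)` — the standard
conservative convention. The statistic is cross-checked against
`vegan::adonis2` and against an exhaustive within-stratum enumeration
on small inputs; type-I error under a simulated null is checked at
about 0.05 (500 simulations × 99 permutations). `dispersion_test()`
embeds objects by principal coordinates (negative-eigenvalue axes
handled by the standard imaginary-part correction, distances clamped
at zero), measures distances to group centroids, and permutes labels
around a one-way F; its geometry is cross-checked against
`vegan::betadisper`. `nmds()` wraps `vegan::metaMDS` (Kruskal stress-1,
monotone regression, default 20 random starts) because a bespoke NMDS
would duplicate a mature implementation; stress is start-dependent, so
it is reported but never used as an acceptance quantity.

Mixed-model inference on recovery rates (GLMMs with nested random
effects) is deliberately out of scope: the package computes the exact
count and rate tables such models consume (`recovery_rates()`,
`prey_frequency()`, `trap_type_share()`), and any standard
mixed-model package can take it from there.

## What the simulators emulate — and what they do not

`simulate_library()` builds genus roots separated by disjoint mutation
blocks (guaranteeing cross-genus identity below 90%), species at a
congeneric pairwise divergence drawn from 1–8% (identities spanning
both sides of the 98.36% assignment threshold), and conspecific
replicates at 0.2% pairwise divergence (~99.8% intra-specific
identity, matching what curated aphid COI libraries show). Divergence
is substitution-only by design: identity thresholds sit near
boundaries, and indel conventions would confound exact expectations;
sequences with indels are still handled (free-end-gap alignment) but
are not generated.

`simulate_gut_samples()` emits tagged paired-end reads (300 bp, tag +
primer + barcode + primer + tag templates), with ~90% of each gut
sample's reads drawn from predator sequences — the dominance regime
that makes prey detection hard in practice — plus linear per-cycle
quality decay with Gaussian jitter (the simplest profile that
exercises the window trimmer), uniform substitution errors,
single-crossover chimeras, and cross-sample tag-jumps, all recorded in
a ground-truth object. Tags are generated with pairwise Hamming
distance ≥ 3 so the one-mismatch demultiplexer cannot collide.

Not emulated: instrument-specific error spectra, quality-correlated
errors, PCR stochasticity beyond fixed read counts, indels, and
non-overlapping read pairs (a ~308 bp amplicon on 2 × 300 chemistry
always overlaps). Passing the round-trip tests therefore demonstrates
the correctness of the pipeline's logic under its stated model, not
robustness to every artefact of real sequencing runs.

Problem sizes used by the test-suite simulations — libraries of up to
~50 sequences, read sets of a few thousand — were chosen as the
smallest scales at which every property (threshold search vs
exhaustive oracle, full-chain recovery, tag-jump removal, clustering
invariant, permutation-test calibration) is genuinely exercised.

## Numerical and degenerate-input choices

* Boundary semantics are inclusive keeps throughout: size ≥ 10
  retained, coverage ≥ 296 retained.
* Binding-site scans break penalty ties toward the most 3'-proximal
  site on the template; sort ties in dereplication/clustering break
  lexicographically.
* Empty taxon groups yield `NA` coverage rather than division by
  zero; zero-total recovery strata are marked not-estimable; empty
  impossible-detection sets return the baseline threshold with a
  warning; all-equal distance matrices give a degenerate NMDS with
  stress 0.
* All stochastic procedures take an explicit seed and are
  byte-reproducible; p-values always include the observed permutation.

## Known limitations

* The mismatch-penalty table is a calibrated heuristic, not a
  thermodynamic model; coverage percentages depend on it and should be
  read comparatively (pair A vs pair B over one library), not as
  absolute amplification probabilities.
* Greedy clustering is input-order dependent by construction (as is
  the tool it mirrors); the package fixes the order deterministically.
* `assign_taxon()` searches a local library only; centroids absent
  from the library simply stay unassigned — there is no remote
  fallback search.
* The chimera screen models exact two-parent single crossovers; mosaic
  chimeras with mismatches near the breakpoint can escape it (they are
  then usually caught by the abundance filter).
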