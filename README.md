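# aphidiet

Molecular diet analysis of aphidophagous predators (ladybirds such as
*Coccinella septempunctata* and *Harmonia axyridis*) from gut-content
DNA, built around a short (~308 bp) COI barcode amplicon. The package
implements the complete analysis chain as tested, reusable R
functions:

* **In-silico primer evaluation** — degenerate (IUPAC) primer
  properties (GC%, molecular weight, Tm) and amplification prediction
  from position-weighted mismatch penalties: a template fails when its
  penalty `Σ s(b_p, b_t) · w(d3')` (transition/transversion score
  times a weight growing toward the primer 3' end, adjacent mismatches
  inflated) exceeds a threshold (default 120). Per-group coverage of a
  primer pair over a reference library requires both primers to pass.
* **Amplicon taxon resolution** — pairwise identity (matches /
  alignment columns over the mutually covered region), resolvability
  classification (species / genus / unresolved by the
  exclusive-species rule), and a lexicographic threshold search
  (minimise retained cross-species matches, then maximise
  species-level records) starting from 90% identity.
* **Reads-to-diet pipeline** — sliding-window quality trimming
  (4 bases, mean Q ≥ 20, edge Q ≥ 3, min length 250), overlap merging,
  MID-tag demultiplexing (exactly one sample within 1 mismatch per
  tag), dereplication, per-sample minimum-abundance filtering
  (default ≥ 10; tag-jump mitigation raises it to 1 + the largest
  detection seen in negative controls), two-parent chimera screening,
  greedy 99% centroid clustering, and taxonomic assignment at
  ≥ 98.36% identity over ≥ 296 bases.
* **Composition statistics** — DNA recovery rates, composition
  matrices (proportions per landscape × sampling round), Hellinger
  transform, Euclidean distances, one-factor PERMANOVA with
  permutations restricted within strata (`p = (1 + #{F* ≥ F}) /
  (1 + n_perm)`), multivariate dispersion (PCoA distances to group
  centroids), and NMDS (k = 2, Kruskal stress-1 via vegan).
* **Simulators** — seed-deterministic reference libraries
  (intra-specific identity ≈ 99.8%, congeneric identities spanning the
  98.36% threshold, cross-genus < 90%), predator-dominated (~90%)
  MID-tagged paired-end gut read sets with injected chimeras and
  tag-jumps plus full ground truth, and null/shifted composition
  matrices for calibrating the permutation tests.

See the vignette (`vignettes/aphid-metabarcoding.Rmd`) for the models,
parameter rationale and limitations.

## Worked example

```r
library(aphidiet)

fw <- degenerate_primer("Aph344.MF", "GGAACAGGWACAGGATGAACWA", "forward")
rv <- degenerate_primer("Aph149.MR", "AATCARAATARATGTTGATA",   "reverse")
gc_content(fw, digits = 1)        # 45.5  (% ; W counts 0 towards GC)
molecular_weight(rv, digits = 1)  # 6172.1 (g/mol; R averaged over A/G)

# simulate a labelled library and two gut samples plus a negative control
sim  <- simulate_library(n_genera = 3, species_per_genus = 2, seqs_per_species = 2,
                         congeneric_divergence = c(0.03, 0.06),
                         predator_species = 2, seed = 7)
guts <- simulate_gut_samples(sim, compositions = list(
          S1 = c("G1 s1" = 30, "G2 s2" = 30), S2 = c("G3 s1" = 30),
          NEG = numeric(0)),
        forward = fw, reverse = rv,
        error_rate = 0, chimera_rate = 0, tagjump_rate = 0.002, seed = 7)

res <- run_pipeline(guts$r1, guts$r2, guts$scheme, sim$library, min_size = 10)
res$detections
#>     G1 s1 G2 s2 G3 s1
#> S1     30    30     0
#> S2      0     0    30
#> NEG     0     0     0
res$log
#>                          stage n_in n_out n_discarded
#> 1                 quality_trim  900   900           0
#> 2                  merge_pairs  900   900           0
#> 3                  demultiplex  900   900           0
#> 4 abundance_and_chimera_filter  900   899           1
```

Each gut individual recovers exactly its simulated prey (read counts
are the simulated per-taxon depths); the negative control stays empty —
the one discarded read is a tag-jumped read removed by the abundance
filter. Downstream:

```r
recovery_rates(c(hand = 167, trap = 19), c(hand = 330, trap = 289))$rates
#>   stratum positives total rate estimable
#> 1    hand       167   330 50.6      TRUE
#> 2    trap        19   289  6.6      TRUE

x  <- simulate_null_composition(16, 6, groups = 2, shift = 2, seed = 5)
pm <- permanova(euclidean_distances(hellinger(x$matrix)), x$groups,
                n_perm = 999, seed = 1)
sprintf("PERMANOVA F = %.2f, p = %.3f", pm$F, pm$p)
#> "PERMANOVA F = 76.90, p = 0.001"
```

The rate table reads as percentages of individuals positive for aphid
DNA per sampling stratum; the PERMANOVA detects the simulated
between-group composition shift at the smallest attainable p for 999
permutations.

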