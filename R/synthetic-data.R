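# Seed-deterministic simulators: barcode reference libraries, MID-tagged
# paired-end gut-content read sets with known ground truth, and null/shift
# composition matrices for calibrating the permutation tests.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

mutate_at <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

#' Simulate a labelled barcode reference library
#'
#' Builds one root sequence per genus (genera separated by disjoint
#' mutation blocks so every cross-genus identity sits below
#' `100 * (1 - cross_genus_divergence)`), derives species within a genus
#' by congeneric-divergence substitutions, and conspecific replicates by
#' intra-species substitutions. The divergence model is substitution-only,
#' keeping identities exactly interpretable against assignment thresholds.
#' Optionally appends predator (off-target) species as additional distant
#' genera. Deterministic given the seed.
#'
#' @param n_genera Aphid genera.
#' @param species_per_genus Species per genus.
#' @param seqs_per_species Conspecific replicate sequences per species.
#' @param amplicon_length Sequence length in bases.
#' @param intra_species_divergence Expected pairwise substitutions/site
#'   between conspecific replicates (0.002 emulates ~99.8% intra-specific
#'   identity).
#' @param congeneric_divergence Length-2 range of pairwise
#'   substitutions/site between congeneric species.
#' @param cross_genus_divergence Minimum pairwise substitutions/site
#'   between genera.
#' @param predator_species Number of off-target predator species appended
#'   (group `"coccinellid"`, one replicate each unless
#'   `predator_seqs_per_species` says otherwise).
#' @param predator_seqs_per_species Replicates per predator species.
#' @param seed Random seed.
#' @return A list of class `library_sim`: `library` (a
#'   [reference_library()]) and `taxonomy` (ground-truth data frame).
#' @export
simulate_library <- function(n_genera = 6L, species_per_genus = 3L,
                             seqs_per_species = 3L, amplicon_length = 308L,
                             intra_species_divergence = 0.002,
                             congeneric_divergence = c(0.01, 0.08),
                             cross_genus_divergence = 0.10,
                             predator_species = 2L,
                             predator_seqs_per_species = 2L,
                             seed = 1L) {
  stopifnot(length(congeneric_divergence) == 2L)
  if (!(intra_species_divergence < congeneric_divergence[1L] &&
        congeneric_divergence[2L] < cross_genus_divergence)) {
    stop("divergences must be ordered intra < congeneric < cross-genus",
         call. = FALSE)
  }
  L <- as.integer(amplicon_length)
  n_roots <- n_genera + predator_species
  block <- ceiling(cross_genus_divergence * L / 2)
  if (n_roots * block > L) stop("too many genera for the requested cross-genus divergence", call. = FALSE)

  set.seed(seed)
  ancestor <- iupac_chars(random_dna(L))
  block_pos <- split(sample(L, n_roots * block), rep(seq_len(n_roots), each = block))

  ids <- genus <- species <- group <- seqs <- character(0)
  add <- function(id, g, sp, grp, sq) {
    ids <<- c(ids, id); genus <<- c(genus, g); species <<- c(species, sp)
    group <<- c(group, grp); seqs <<- c(seqs, sq)
  }
  make_genus <- function(root_id, g_name, grp, n_species, n_reps) {
    root <- mutate_at(ancestor, block_pos[[root_id]])
    for (s in seq_len(n_species)) {
      d <- stats::runif(1, congeneric_divergence[1L] / 2, congeneric_divergence[2L] / 2)
      sp_root <- mutate_at(root, sample(L, round(d * L)))
      for (r in seq_len(n_reps)) {
        # halved: divergence parameters are pairwise, replicates diverge
        # independently from the species root
        n_mut <- stats::rbinom(1L, L, intra_species_divergence / 2)
        rep_seq <- mutate_at(sp_root, sample(L, n_mut))
        add(sprintf("%s_s%d_r%d", g_name, s, r), g_name, sprintf("s%d", s),
            grp, paste(rep_seq, collapse = ""))
      }
    }
  }
  for (g in seq_len(n_genera)) {
    make_genus(g, sprintf("G%d", g), "aphid", species_per_genus, seqs_per_species)
  }
  for (p in seq_len(predator_species)) {
    make_genus(n_genera + p, sprintf("P%d", p), "coccinellid", 1L,
               predator_seqs_per_species)
  }
  lib <- reference_library(id = ids, genus = genus, species = species,
                           sequence = seqs, group = group)
  structure(list(library = lib,
                 taxonomy = data.frame(id = ids, genus = genus,
                                       species = species, group = group,
                                       stringsAsFactors = FALSE)),
            class = "library_sim")
}

# tags with pairwise Hamming distance >= min_dist so one tag mismatch can
# never make two samples collide
make_tags <- function(n, length = 8L, min_dist = 3L) {
  tags <- character(0)
  while (length(tags) < n) {
    cand <- random_dna(length)
    ok <- all(vapply(tags, function(t) n_mismatches(t, cand) >= min_dist,
                     logical(1)))
    if (ok) tags <- c(tags, cand)
  }
  tags
}

phred_profile <- function(len, q_start, q_slope, q_sd) {
  q <- q_start - q_slope * (seq_len(len) - 1L) + stats::rnorm(len, 0, q_sd)
  as.integer(pmin(40L, pmax(2L, round(q))))
}

apply_errors <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hits <- which(stats::runif(length(chars)) < rate)
  if (length(hits)) chars <- mutate_at(chars, hits)
  chars
}

#' Simulate MID-tagged paired-end gut-content read sets
#'
#' Every read is a tagged amplicon fragment: forward tag + a concrete
#' expansion of the forward primer + the source barcode + reverse
#' complement of reverse primer + reverse complement of the reverse tag.
#' Paired 5' and 3' reads of fixed length are cut from this template with
#' per-cycle linear quality decay (Gaussian jitter) and uniform
#' substitution errors. Predator reads dominate each gut sample at the
#' requested fraction; single-crossover chimeras and cross-sample
#' tag-jumps are injected at their respective per-read rates and recorded
#' in the ground truth. Samples with an empty composition act as negative
#' controls and receive only tag-jumped reads.
#'
#' @param library A [simulate_library()] result or [reference_library()].
#' @param compositions Named list: sample id to named numeric vector of
#'   aphid read counts per taxon (`"genus species"` keys); empty vector
#'   for negative controls.
#' @param forward,reverse `degenerate_primer` objects.
#' @param predator_read_fraction Fraction of a gut sample's reads drawn
#'   from predator (off-target) sequences.
#' @param error_rate Per-base substitution error rate applied to each
#'   read.
#' @param q_start,q_slope,q_sd Quality profile: mean Phred at cycle 1,
#'   linear decline per cycle, Gaussian jitter SD.
#' @param chimera_rate Per-read probability of replacing the amplicon by
#'   a single-crossover chimera of two sampled amplicons.
#' @param tagjump_rate Per-read probability of re-labelling the read with
#'   another sample's tag pair.
#' @param read_length Read length in bases.
#' @param tag_length MID tag length.
#' @param seed Random seed.
#' @return A list of class `gut_sim`: `r1`, `r2` (lists of
#'   [fastq_read()]), `scheme` (a [tag_scheme()]), `truth`
#'   (`composition`, `tag_jumps`, `chimeras`), `amplicon_library` (the
#'   aphid amplicon reference used).
#' @export
simulate_gut_samples <- function(library, compositions, forward, reverse,
                                 predator_read_fraction = 0.9,
                                 error_rate = 0.001,
                                 q_start = 38, q_slope = 0.02, q_sd = 1.5,
                                 chimera_rate = 0.005, tagjump_rate = 0.002,
                                 read_length = 300L, tag_length = 8L,
                                 seed = 1L) {
  if (inherits(library, "library_sim")) library <- library$library
  taxa_keys <- species_key(library)
  known <- unique(stats::na.omit(taxa_keys[library$group == "aphid"]))
  for (comp in compositions) {
    if (length(comp) && !all(names(comp) %in% known)) {
      stop("composition references unknown taxon: ",
           paste(setdiff(names(comp), known), collapse = ", "), call. = FALSE)
    }
  }
  predators <- which(library$group != "aphid")
  if (length(predators) == 0L && predator_read_fraction > 0) {
    stop("library has no predator (off-target) records", call. = FALSE)
  }

  set.seed(seed)
  sample_ids <- names(compositions)
  tags <- data.frame(sample = sample_ids,
                     forward_tag = make_tags(length(sample_ids), tag_length),
                     reverse_tag = make_tags(length(sample_ids), tag_length),
                     stringsAsFactors = FALSE)
  scheme <- tag_scheme(tags, forward, reverse)
  fwd_expansions <- expand_degenerate(forward)
  rev_expansions <- expand_degenerate(reverse)

  r1 <- list(); r2 <- list()
  jumps <- NULL; chims <- NULL
  read_no <- 0L

  pick_amplicon <- function(key) {
    if (key == ".predator") {
      idx <- sample(predators, 1L)
    } else {
      idx <- which(!is.na(taxa_keys) & taxa_keys == key)
      idx <- if (length(idx) > 1L) sample(idx, 1L) else idx
    }
    library$sequence[idx]
  }

  for (s in sample_ids) {
    comp <- compositions[[s]]
    comp <- comp[comp > 0]
    n_aphid <- sum(comp)
    n_pred <- if (n_aphid > 0 && predator_read_fraction > 0) {
      round(n_aphid * predator_read_fraction / (1 - predator_read_fraction))
    } else 0L
    sources <- c(rep(names(comp), times = comp), rep(".predator", n_pred))
    for (src in sources) {
      read_no <- read_no + 1L
      amplicon <- pick_amplicon(src)
      is_chim <- stats::runif(1) < chimera_rate
      if (is_chim && length(sources) > 1L) {
        other <- pick_amplicon(sample(sources, 1L))
        cut <- sample(seq_len(min(nchar(amplicon), nchar(other)) - 1L), 1L)
        amplicon <- paste0(substr(amplicon, 1L, cut),
                           substr(other, cut + 1L, nchar(other)))
        chims <- rbind(chims, data.frame(sample = s, read = read_no, cut = cut))
      }
      sink <- s
      if (stats::runif(1) < tagjump_rate && length(sample_ids) > 1L) {
        sink <- sample(setdiff(sample_ids, s), 1L)
        jumps <- rbind(jumps, data.frame(source = s, sink = sink,
                                         taxon = src, read = read_no,
                                         stringsAsFactors = FALSE))
      }
      k <- match(sink, tags$sample)
      template <- paste0(tags$forward_tag[k], sample(fwd_expansions, 1L),
                         amplicon,
                         reverse_complement(sample(rev_expansions, 1L)),
                         reverse_complement(tags$reverse_tag[k]))
      tchars <- iupac_chars(template)
      id <- sprintf("read%06d", read_no)
      len1 <- min(read_length, length(tchars))
      b1 <- apply_errors(tchars[seq_len(len1)], error_rate)
      r1[[length(r1) + 1L]] <- fastq_read(
        id, paste(b1, collapse = ""), phred_profile(len1, q_start, q_slope, q_sd))
      rchars <- iupac_chars(reverse_complement(template))
      b2 <- apply_errors(rchars[seq_len(len1)], error_rate)
      r2[[length(r2) + 1L]] <- fastq_read(
        id, paste(b2, collapse = ""), phred_profile(len1, q_start, q_slope, q_sd))
    }
  }

  amplicon_library <- library[library$group == "aphid", , drop = FALSE]
  structure(list(r1 = r1, r2 = r2, scheme = scheme,
                 truth = list(composition = compositions,
                              tag_jumps = jumps, chimeras = chims),
                 amplicon_library = amplicon_library),
            class = "gut_sim")
}

#' Simulate composition matrices under a null or group-shift model
#'
#' Rows are multinomial proportions drawn either from one shared taxon
#' profile (null: groups differ only by sampling noise) or from
#' group-specific profiles tilted by `shift` (alternative), for type-I
#' error and power checks of the permutation tests.
#'
#' @param n_units Number of rows (at least 4).
#' @param n_taxa Number of taxa.
#' @param groups Group labels of length `n_units` (or a number of groups
#'   to assign in round-robin).
#' @param shift Log-scale tilt of the second and later groups' profiles;
#'   0 gives the null.
#' @param depth Multinomial draw size per row.
#' @param seed Random seed.
#' @return A list: `matrix` (rows sum to 1), `groups`.
#' @export
simulate_null_composition <- function(n_units, n_taxa, groups = 2L,
                                      shift = 0, depth = 50L, seed = 1L) {
  stopifnot(n_units >= 4L, n_taxa >= 2L)
  if (length(groups) == 1L) {
    groups <- rep(paste0("g", seq_len(groups)), length.out = n_units)
  }
  stopifnot(length(groups) == n_units)
  set.seed(seed)
  base <- stats::rgamma(n_taxa, 1)
  base <- base / sum(base)
  tilt <- rep(c(1, -1), length.out = n_taxa)
  glev <- unique(groups)
  probs <- lapply(seq_along(glev), function(i) {
    p <- base * exp(shift * tilt * (i - 1L))
    p / sum(p)
  })
  names(probs) <- glev
  mat <- t(vapply(seq_len(n_units), function(i) {
    counts <- stats::rmultinom(1L, depth, probs[[groups[i]]])[, 1L]
    counts / sum(counts)
  }, numeric(n_taxa)))
  colnames(mat) <- paste0("taxon", seq_len(n_taxa))
  rownames(mat) <- paste0("unit", seq_len(n_units))
  list(matrix = mat, groups = groups)
}
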