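# Taxon-resolution analysis of a short barcode amplicon against a
# labelled reference library.

#' Extract the inter-primer amplicon region from a template
#'
#' Locates the binding site of the forward primer on the template and of
#' the reverse primer on its reverse complement (each by minimum-penalty
#' ungapped scan) and returns the region between the two sites, excluding
#' the primer footprints. A record whose sites cannot be located under the
#' penalty ceiling, or whose sites overlap, is flagged unextractable.
#'
#' @param template Template nucleotide sequence (or a single-row
#'   [reference_library()] record).
#' @param forward,reverse `degenerate_primer` objects.
#' @param scheme A [mismatch_scheme()]; its fail threshold is the default
#'   penalty ceiling for accepting a located site.
#' @param max_penalty Penalty ceiling for site acceptance.
#' @return A list of class `amplicon_extraction`: `extractable`,
#'   `sequence` (the insert, `NA` if unextractable), `length`,
#'   `fwd_site`/`rev_site` (1-based template coordinates of the primer
#'   footprints).
#' @export
extract_amplicon <- function(template, forward, reverse,
                             scheme = mismatch_scheme(),
                             max_penalty = scheme$fail_threshold) {
  if (is.data.frame(template)) template <- template$sequence[1L]
  template <- toupper(template)
  L <- nchar(template)
  failed <- structure(list(extractable = FALSE, sequence = NA_character_,
                           length = 0L, fwd_site = NULL, rev_site = NULL),
                      class = "amplicon_extraction")
  if (L < nchar(forward$sequence) + nchar(reverse$sequence)) return(failed)

  fa <- align_binding(forward, template, scheme = scheme)
  fp <- binding_penalty(fa, scheme)
  ra <- align_binding(reverse, template, scheme = scheme)
  rp <- binding_penalty(ra, scheme)
  if (fp$total_penalty > max_penalty || rp$total_penalty > max_penalty) return(failed)

  nf <- nchar(forward$sequence)
  nr <- nchar(reverse$sequence)
  f_start <- fa$site_start
  f_end <- f_start + nf - 1L
  # reverse site was located on the reverse complement; map back
  r_start <- L - (ra$site_start + nr - 1L) + 1L
  r_end <- L - ra$site_start + 1L
  if (f_end >= r_start) return(failed)
  insert <- substr(template, f_end + 1L, r_start - 1L)
  structure(list(extractable = TRUE, sequence = insert, length = nchar(insert),
                 fwd_site = c(start = f_start, end = f_end),
                 rev_site = c(start = r_start, end = r_end)),
            class = "amplicon_extraction")
}

#' Drop records covering too little of the amplicon region
#'
#' Records covering less than `min_bases` of the amplicon are excluded;
#' a record covering exactly `min_bases` is retained.
#'
#' @param library A [reference_library()].
#' @param min_bases Minimum amplicon coverage in bases.
#' @param coverage Optional per-record coverage; defaults to the sequence
#'   length.
#' @return The filtered library, with the removed record ids in attribute
#'   `"removed"`.
#' @export
filter_by_coverage <- function(library, min_bases = 296, coverage = NULL) {
  if (is.null(coverage)) coverage <- nchar(library$sequence)
  stopifnot(length(coverage) == nrow(library))
  keep <- coverage >= min_bases
  out <- library[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- library$id[!keep]
  out
}

identity_stats <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    ac <- iupac_chars(a); bc <- iupac_chars(b)
    ok <- ac == bc
    amb <- !ok & (!(ac %in% c("A", "C", "G", "T")) | !(bc %in% c("A", "C", "G", "T")))
    if (any(amb)) ok[amb] <- iupac_compatible(ac[amb], bc[amb])
    return(list(identity = 100 * sum(ok) / length(ok), columns = length(ok)))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  pa <- iupac_chars(gsub("-", "x", as.character(Biostrings::alignedPattern(aln))))
  pb <- iupac_chars(gsub("-", "x", as.character(Biostrings::alignedSubject(aln))))
  gap <- pa == "X" | pb == "X"
  ok <- !gap & iupac_compatible(ifelse(gap, "N", pa), ifelse(gap, "N", pb))
  list(identity = 100 * sum(ok) / length(ok), columns = length(ok))
}

#' Percent identity between two barcode sequences
#'
#' For equal-length sequences the comparison is columnwise and ungapped.
#' Otherwise a global alignment with free end gaps is computed and
#' identity is `100 * matches / alignment columns` within the mutually
#' covered region: internal gaps count as mismatches, end gaps outside
#' the covered region are ignored. An ambiguity code matches any
#' compatible base. Symmetric in its arguments.
#'
#' @param a,b Nucleotide sequences.
#' @return Percent identity, with the number of covered alignment columns
#'   in attribute `"columns"`.
#' @export
pairwise_identity <- function(a, b) {
  st <- identity_stats(a, b)
  structure(st$identity, columns = st$columns)
}

# dense pairwise identity matrix over library records
identity_matrix <- function(library) {
  n <- nrow(library)
  m <- matrix(100, n, n, dimnames = list(library$id, library$id))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- as.numeric(pairwise_identity(library$sequence[i],
                                                         library$sequence[j]))
    }
  }
  m
}

species_key <- function(library) {
  ifelse(is.na(library$species), NA_character_,
         paste(library$genus, library$species))
}

classify_one <- function(i, library, idm, threshold) {
  hits <- which(idm[i, ] >= threshold)
  hits <- setdiff(hits, i)
  n_matches <- length(hits)
  keys <- species_key(library)
  if (n_matches == 0L) {
    cls <- "unresolved"
  } else if (any(library$genus[hits] != library$genus[i])) {
    cls <- "unresolved"
  } else if (!is.na(keys[i]) && !anyNA(keys[hits]) && all(keys[hits] == keys[i])) {
    cls <- "species-level"
  } else {
    cls <- "genus-level"
  }
  structure(cls, n_matches = n_matches)
}

#' Classify a record's achievable taxonomic resolution
#'
#' The query is matched against every other library record at the given
#' identity threshold. If all matches originate from the query's own
#' species exclusively, it is identifiable to species level; if the
#' matches stay within its genus but involve other species, to genus
#' level; if they span genera, or no record matches, the query is
#' unresolved.
#'
#' @param query Record id or row index of the query within `library`.
#' @param library A [reference_library()].
#' @param threshold Identity threshold in percent.
#' @return `"species-level"`, `"genus-level"` or `"unresolved"`, with the
#'   match count in attribute `"n_matches"`.
#' @export
classify_resolvability <- function(query, library, threshold = 98.36) {
  i <- if (is.character(query)) match(query, library$id) else as.integer(query)
  if (is.na(i) || i < 1L || i > nrow(library)) stop("query not in library", call. = FALSE)
  classify_one(i, library, identity_matrix(library), threshold)
}

#' Per-genus species-level resolvability report
#'
#' Classifies every record at the threshold and summarises per genus. A
#' genus is resolvable to species level if none of its records classify
#' genus-level and none match across genera; records without any match
#' are uninformative and do not block resolvability.
#'
#' @inheritParams classify_resolvability
#' @return A list of class `resolution_report`: `per_genus` data frame
#'   (`genus`, `n_species`, `n_sequences`, `resolvable`), `threshold`,
#'   `n_genera_resolvable`, `species_covered`, and the per-record
#'   classifications in `record_class`.
#' @export
resolution_report <- function(library, threshold = 98.36) {
  idm <- identity_matrix(library)
  cls <- vapply(seq_len(nrow(library)), function(i) {
    as.character(classify_one(i, library, idm, threshold))
  }, "")
  nm <- vapply(seq_len(nrow(library)), function(i) {
    attr(classify_one(i, library, idm, threshold), "n_matches")
  }, 1L)
  genera <- sort(unique(library$genus))
  per_genus <- do.call(rbind, lapply(genera, function(g) {
    in_g <- library$genus == g
    data.frame(genus = g,
               n_species = length(unique(stats::na.omit(library$species[in_g]))),
               n_sequences = sum(in_g),
               resolvable = !any(cls[in_g] == "genus-level") &&
                 !any(cls[in_g] == "unresolved" & nm[in_g] > 0L),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_genus = per_genus, threshold = threshold,
                 n_genera_resolvable = sum(per_genus$resolvable),
                 species_covered = length(unique(stats::na.omit(
                   species_key(library)[library$genus %in% per_genus$genus[per_genus$resolvable]]))),
                 record_class = stats::setNames(cls, library$id)),
            class = "resolution_report")
}

#' Optimise the species-assignment identity threshold
#'
#' Scans candidate thresholds (the distinct observed pairwise identities
#' at or above `start`, plus midpoints between consecutive values) and
#' scores each lexicographically: first minimise the number of retained
#' deviating matches (record pairs at or above the threshold whose species
#' labels differ), then maximise the number of records classified
#' species-level. Returns the smallest candidate achieving the optimum,
#' mirroring the practice of raising a permissive starting threshold until
#' cross-species matches are excluded as often as possible.
#'
#' @param library A [reference_library()] with at least two species.
#' @param start Lowest threshold considered, percent.
#' @return A list of class `threshold_search`: `threshold`, and `trace`, a
#'   data frame with one row per candidate (`threshold`,
#'   `deviating_matches`, `n_species_level`).
#' @export
optimize_threshold <- function(library, start = 90) {
  if (length(unique(stats::na.omit(species_key(library)))) < 2L) {
    stop("library must contain at least two species", call. = FALSE)
  }
  idm <- identity_matrix(library)
  n <- nrow(library)
  vals <- sort(unique(idm[upper.tri(idm)]))
  vals <- vals[vals >= start]
  cand <- sort(unique(c(start, vals, (utils::head(vals, -1L) + utils::tail(vals, -1L)) / 2)))
  keys <- species_key(library)
  trace <- do.call(rbind, lapply(cand, function(t) {
    retained <- which(upper.tri(idm) & idm >= t, arr.ind = TRUE)
    dev <- sum(!is.na(keys[retained[, 1L]]) & !is.na(keys[retained[, 2L]]) &
                 keys[retained[, 1L]] != keys[retained[, 2L]])
    nsp <- sum(vapply(seq_len(n), function(i) {
      as.character(classify_one(i, library, idm, t)) == "species-level"
    }, logical(1)))
    data.frame(threshold = t, deviating_matches = dev, n_species_level = nsp)
  }))
  best_dev <- min(trace$deviating_matches)
  at_dev <- trace[trace$deviating_matches == best_dev, , drop = FALSE]
  best_nsp <- max(at_dev$n_species_level)
  opt <- min(at_dev$threshold[at_dev$n_species_level == best_nsp])
  structure(list(threshold = opt, trace = trace), class = "threshold_search")
}

pooled_mean_sd <- function(values) {
  if (length(values) == 0L) return(list(mean = NA_real_, sd = NA_real_, n_pairs = 0L))
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n_pairs = length(values))
}

#' Intra-specific and within-genus similarity summary
#'
#' Intra-specific similarity pools the pairwise identities of all
#' conspecific pairs over species represented by two or more sequences.
#' Within-genus similarity pools the pairwise identities among records
#' identified to genus only, over genera holding more than two such
#' records. Species represented by a single sequence contribute nothing.
#'
#' @param library A [reference_library()].
#' @return A list of class `similarity_summary` with elements
#'   `intraspecific` and `within_genus`, each `list(mean, sd, n_pairs)`
#'   in percent (`NA` mean when no group is eligible).
#' @export
similarity_summary <- function(library) {
  idm <- identity_matrix(library)
  keys <- species_key(library)

  intra <- c()
  for (k in unique(stats::na.omit(keys))) {
    idx <- which(!is.na(keys) & keys == k)
    if (length(idx) >= 2L) {
      sub <- idm[idx, idx]
      intra <- c(intra, sub[upper.tri(sub)])
    }
  }

  within <- c()
  for (g in unique(library$genus)) {
    idx <- which(library$genus == g & is.na(library$species))
    if (length(idx) > 2L) {
      sub <- idm[idx, idx]
      within <- c(within, sub[upper.tri(sub)])
    }
  }

  structure(list(intraspecific = pooled_mean_sd(intra),
                 within_genus = pooled_mean_sd(within)),
            class = "similarity_summary")
}
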