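# Reads-to-diet metabarcoding pipeline: quality control, pair merging,
# tag demultiplexing, abundance/chimera filtering, centroid clustering
# and identity-threshold taxonomic assignment.

#' Construct a FASTQ read
#'
#' Reads are held as plain lists so that per-base quality manipulation
#' stays cheap; [read_fastq()]/[write_fastq()] convert from and to disk
#' FASTQ (Phred+33).
#'
#' @param id Read identifier.
#' @param bases ACGTN string.
#' @param qualities Integer Phred scores, one per base.
#' @return A list of class `fastq_read`.
#' @export
fastq_read <- function(id, bases, qualities) {
  bases <- toupper(bases)
  if (nchar(bases) != length(qualities)) {
    stop("bases and qualities differ in length", call. = FALSE)
  }
  if (any(qualities < 0)) stop("Phred scores must be >= 0", call. = FALSE)
  structure(list(id = id, bases = bases, qualities = as.integer(qualities)),
            class = "fastq_read")
}

#' Read a FASTQ file into a list of reads
#'
#' @param path FASTQ file (Phred+33).
#' @return List of [fastq_read()] objects.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- Biostrings::PhredQuality(S4Vectors::mcols(seqs)$qualities)
  qlist <- methods::as(quals, "IntegerList")
  lapply(seq_along(seqs), function(i) {
    fastq_read(names(seqs)[i], as.character(seqs[[i]]), as.integer(qlist[[i]]))
  })
}

#' Write a list of reads to FASTQ (Phred+33)
#'
#' @param reads List of [fastq_read()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$id), r$bases, "+",
                 intToUtf8(r$qualities + 33L)), con)
  }
  invisible(path)
}

subset_read <- function(read, from, to) {
  if (to < from) {
    return(fastq_read(read$id, "", integer(0)))
  }
  fastq_read(read$id, substr(read$bases, from, to), read$qualities[from:to])
}

#' Default quality-trimming parameters
#'
#' Defaults mirror a standard amplicon QC recipe: clip leading/trailing
#' bases below Phred 3, cut at the first 4-base window whose mean quality
#' drops below 20, and discard reads shorter than 250 bases afterwards.
#'
#' @param window Sliding-window width in bases.
#' @param min_mean_q Minimum mean window quality.
#' @param edge_q Leading/trailing bases below this Phred score are clipped.
#' @param min_length Reads shorter than this after trimming are discarded.
#' @param adapter_seqs Adapter sequences searched by [clip_adapters()].
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(window = 4L, min_mean_q = 20, edge_q = 3,
                        min_length = 250L, adapter_seqs = character(0)) {
  stopifnot(window >= 1L, min_length >= 1L)
  structure(list(window = as.integer(window), min_mean_q = min_mean_q,
                 edge_q = edge_q, min_length = as.integer(min_length),
                 adapter_seqs = toupper(adapter_seqs)),
            class = "trim_params")
}

n_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Clip 3' adapter read-through
#'
#' Scans the read for the earliest position where its suffix matches a
#' prefix of an adapter over at least `min_overlap` bases, tolerating at
#' most `max_mismatch` mismatches and a mismatch fraction of at most
#' `mismatch_rate` (so short chance matches at the read end do not
#' trigger clipping), and truncates the read there.
#'
#' @param read A [fastq_read()].
#' @param params A [trim_params()] supplying `adapter_seqs`.
#' @param min_overlap Minimum adapter match length.
#' @param max_mismatch Mismatches tolerated within the match.
#' @param mismatch_rate Maximum mismatch fraction within the match.
#' @return The (possibly truncated) read.
#' @export
clip_adapters <- function(read, params = trim_params(), min_overlap = 12L,
                          max_mismatch = 2L, mismatch_rate = 0.125) {
  n <- nchar(read$bases)
  for (adapter in params$adapter_seqs) {
    na <- nchar(adapter)
    for (p in seq_len(n)) {
      len <- min(n - p + 1L, na)
      if (len < min_overlap) break
      mism <- n_mismatches(substr(read$bases, p, p + len - 1L),
                           substr(adapter, 1L, len))
      if (mism <= max_mismatch && mism <= len * mismatch_rate) {
        read <- subset_read(read, 1L, p - 1L)
        n <- nchar(read$bases)
        break
      }
    }
  }
  read
}

#' Sliding-window quality trimming
#'
#' Removes leading and trailing bases below the edge quality, then scans
#' 5' to 3' with a sliding window and cuts the read at the start of the
#' first window whose mean quality falls below the minimum. Reads shorter
#' than the minimum length afterwards are discarded (`NULL`).
#'
#' @param read A [fastq_read()].
#' @param params A [trim_params()].
#' @return The trimmed read, or `NULL` if discarded.
#' @export
quality_trim <- function(read, params = trim_params()) {
  q <- read$qualities
  keep <- which(q >= params$edge_q)
  if (length(keep) == 0L) return(NULL)
  read <- subset_read(read, min(keep), max(keep))
  q <- read$qualities
  n <- length(q)
  if (n >= params$window) {
    means <- stats::filter(q, rep(1 / params$window, params$window),
                           sides = 1)
    # means[i] is the mean of the window ending at i
    bad_end <- which(!is.na(means) & means < params$min_mean_q)
    if (length(bad_end) > 0L) {
      cut_at <- bad_end[1L] - params$window  # keep bases before the window start
      read <- subset_read(read, 1L, cut_at)
    }
  }
  if (nchar(read$bases) < params$min_length) return(NULL)
  read
}

reverse_complement_read <- function(read) {
  fastq_read(read$id, reverse_complement(read$bases), rev(read$qualities))
}

#' Merge a read pair over its best ungapped overlap
#'
#' The second read is reverse complemented, then every overlap length of
#' at least `min_overlap` is scored by its mismatch fraction; the overlap
#' with the lowest fraction wins (longer overlap on ties) and is accepted
#' if the fraction does not exceed `max_mismatch_frac`. At conflicting
#' overlap positions the consensus takes the base with the higher Phred
#' score.
#'
#' @param r1,r2 [fastq_read()] objects (r2 as sequenced, i.e. it is
#'   reverse complemented internally).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the
#'   overlap.
#' @return The merged [fastq_read()], or `NULL` when no acceptable
#'   overlap exists.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.25) {
  rc2 <- reverse_complement_read(r2)
  x <- utf8ToInt(r1$bases)
  y <- utf8ToInt(rc2$bases)
  n1 <- length(x)
  n2 <- length(y)
  if (min(n1, n2) < min_overlap) return(NULL)
  best_len <- 0L
  best_frac <- Inf
  for (len in seq.int(min(n1, n2), min_overlap)) {
    mism <- sum(x[(n1 - len + 1L):n1] != y[seq_len(len)])
    frac <- mism / len
    if (frac < best_frac) {  # ties keep the longer (earlier) overlap
      best_frac <- frac
      best_len <- len
    }
  }
  if (best_len < min_overlap || best_frac > max_mismatch_frac) return(NULL)
  ov1 <- (n1 - best_len + 1L):n1
  ov2 <- seq_len(best_len)
  take2 <- rc2$qualities[ov2] > r1$qualities[ov1]
  ov_bases <- ifelse(take2,
                     strsplit(rc2$bases, "")[[1]][ov2],
                     strsplit(r1$bases, "")[[1]][ov1])
  ov_qual <- pmax(r1$qualities[ov1], rc2$qualities[ov2])
  fastq_read(r1$id,
             paste0(substr(r1$bases, 1L, n1 - best_len),
                    paste(ov_bases, collapse = ""),
                    substr(rc2$bases, best_len + 1L, n2)),
             c(r1$qualities[seq_len(n1 - best_len)], ov_qual,
               rc2$qualities[seq.int(best_len + 1L, length.out = n2 - best_len)]))
}

#' Define a MID-tag demultiplexing scheme
#'
#' @param samples Data frame with columns `sample`, `forward_tag`,
#'   `reverse_tag`. Tag pairs must be unique across samples.
#' @param forward_primer,reverse_primer The amplification primers
#'   (stripped together with the tags).
#' @param max_mismatch_per_tag Mismatches tolerated in each tag.
#' @return A list of class `tag_scheme`.
#' @export
tag_scheme <- function(samples, forward_primer, reverse_primer,
                       max_mismatch_per_tag = 1L) {
  stopifnot(all(c("sample", "forward_tag", "reverse_tag") %in% names(samples)))
  samples$forward_tag <- toupper(samples$forward_tag)
  samples$reverse_tag <- toupper(samples$reverse_tag)
  if (any(!nzchar(samples$forward_tag)) || any(!nzchar(samples$reverse_tag))) {
    stop("tags must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(paste(samples$forward_tag, samples$reverse_tag))) {
    stop("duplicate tag pair in scheme", call. = FALSE)
  }
  if (anyDuplicated(samples$sample)) stop("duplicate sample id in scheme", call. = FALSE)
  structure(list(samples = samples,
                 forward_primer = primer_seq(forward_primer),
                 reverse_primer = primer_seq(reverse_primer),
                 max_mismatch_per_tag = as.integer(max_mismatch_per_tag)),
            class = "tag_scheme")
}

#' Read a tab-delimited tag scheme
#'
#' Expects columns `sample`, `forward_tag`, `reverse_tag`.
#'
#' @param path TSV file.
#' @inheritParams tag_scheme
#' @return A [tag_scheme()].
#' @export
read_tag_scheme <- function(path, forward_primer, reverse_primer,
                            max_mismatch_per_tag = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tag_scheme(tab, forward_primer, reverse_primer, max_mismatch_per_tag)
}

# mismatches between two strings of equal length, degenerate codes in
# `pattern` matching compatibly
tag_mismatches <- function(observed, pattern) {
  if (!grepl("[^ACGT]", pattern)) return(n_mismatches(observed, pattern))
  sum(!iupac_compatible(iupac_chars(pattern), iupac_chars(observed)))
}

#' Demultiplex merged reads by MID tag pairs
#'
#' A merged amplicon read carries the forward tag + forward primer at its
#' 5' end and the reverse complement of reverse primer + reverse tag at
#' its 3' end. A read is assigned to a sample if and only if exactly one
#' sample's tag pair matches both ends with at most the allowed mismatches
#' per tag; tags and primers are then stripped. Reads matching no sample
#' or more than one go to the unassigned pool with reason `"no_match"` or
#' `"ambiguous"`.
#'
#' @param reads List of merged [fastq_read()] objects.
#' @param scheme A [tag_scheme()].
#' @return A list with `samples` (named list of read lists),
#'   `unassigned` (list of reads, each with an `unassigned_reason`
#'   attribute), and `counts` (data frame of per-sample read counts).
#' @export
demultiplex <- function(reads, scheme) {
  tab <- scheme$samples
  mm <- scheme$max_mismatch_per_tag
  np_f <- nchar(scheme$forward_primer)
  np_r <- nchar(scheme$reverse_primer)
  rc_rtags <- vapply(tab$reverse_tag, reverse_complement, "")
  out <- stats::setNames(vector("list", nrow(tab)), tab$sample)
  for (s in names(out)) out[[s]] <- list()
  unassigned <- list()

  for (read in reads) {
    n <- nchar(read$bases)
    hits <- integer(0)
    for (k in seq_len(nrow(tab))) {
      lf <- nchar(tab$forward_tag[k])
      lr <- nchar(tab$reverse_tag[k])
      if (n < lf + np_f + np_r + lr) next
      if (tag_mismatches(substr(read$bases, 1L, lf), tab$forward_tag[k]) > mm) next
      if (tag_mismatches(substr(read$bases, n - lr + 1L, n), rc_rtags[k]) > mm) next
      hits <- c(hits, k)
    }
    if (length(hits) == 1L) {
      k <- hits
      lf <- nchar(tab$forward_tag[k])
      lr <- nchar(tab$reverse_tag[k])
      stripped <- subset_read(read, lf + np_f + 1L, n - lr - np_r)
      out[[tab$sample[k]]] <- c(out[[tab$sample[k]]], list(stripped))
    } else {
      attr(read, "unassigned_reason") <- if (length(hits) == 0L) "no_match" else "ambiguous"
      unassigned <- c(unassigned, list(read))
    }
  }
  counts <- data.frame(sample = tab$sample,
                       n_reads = vapply(out, length, 1L),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(samples = out, unassigned = unassigned, counts = counts)
}

#' Collapse identical sequences into unique amplicons
#'
#' @param sequences Character vector of read sequences (or a list of
#'   [fastq_read()] objects).
#' @param sample Optional sample id recorded on the output.
#' @return Data frame of class `unique_amplicons` with columns `sequence`
#'   and `size`, sorted by decreasing size (ties broken lexicographically
#'   by sequence for reproducibility).
#' @export
dereplicate <- function(sequences, sample = NA_character_) {
  if (is.list(sequences)) {
    sequences <- vapply(sequences, function(r) r$bases, "")
  }
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), size = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$size, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out$sample <- sample
  class(out) <- c("unique_amplicons", "data.frame")
  out
}

#' Remove low-abundance unique amplicons
#'
#' Uniques appearing fewer than `min_size` times within their sample are
#' removed; a unique of exactly `min_size` reads is retained.
#'
#' @param uniques A [dereplicate()] data frame.
#' @param min_size Minimum per-sample read count.
#' @return The filtered data frame.
#' @export
abundance_filter <- function(uniques, min_size = 10L) {
  stopifnot(min_size >= 1L)
  out <- uniques[uniques$size >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag-jump mitigation threshold from impossible detections
#'
#' Detections that cannot be genuine (sequences appearing in negative
#' controls, or taxa impossible for a sample) gauge the leakage of reads
#' between samples caused by tag jumping. The per-pool minimum-abundance
#' threshold is raised to one more than the largest impossible detection,
#' never dropping below `base`.
#'
#' @param impossible Data frame of impossible detections with a `size`
#'   column and optionally a `pool` column.
#' @param base Baseline minimum abundance.
#' @return Named numeric vector of per-pool thresholds (a single unnamed
#'   value when no `pool` column is present). Returns `base` with a
#'   warning when no impossible detections are supplied.
#' @export
tag_jump_threshold <- function(impossible, base = 10L) {
  if (is.null(impossible) || nrow(impossible) == 0L) {
    warning("no impossible detections supplied; returning the baseline threshold")
    return(base)
  }
  if (!"pool" %in% names(impossible)) {
    return(max(base, 1L + max(impossible$size)))
  }
  vapply(split(impossible$size, impossible$pool),
         function(sz) max(base, 1L + max(sz)), numeric(1))
}

longest_common_prefix <- function(x, y) {
  n <- min(length(x), length(y))
  d <- which(x[seq_len(n)] != y[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Flag two-parent chimeras among unique amplicons
#'
#' A unique is flagged as chimeric if it can be split at a single
#' crossover point into a left segment identical to one more abundant
#' unique and a right segment identical to another, each candidate parent
#' carrying at least twice the child's read count. The most abundant
#' unique can never be flagged.
#'
#' @param uniques A [dereplicate()] data frame (size-sorted).
#' @param min_parent_ratio Minimum parent/child abundance ratio.
#' @return The uniques with flagged chimeras removed; removed rows are
#'   attached as attribute `"chimeras"`.
#' @export
screen_chimeras <- function(uniques, min_parent_ratio = 2) {
  n <- nrow(uniques)
  if (n < 3L) {
    attr(uniques, "chimeras") <- uniques[0, , drop = FALSE]
    return(uniques)
  }
  chars <- lapply(uniques$sequence, function(s) utf8ToInt(s))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    len <- length(chars[[i]])
    parents <- which(uniques$size >= min_parent_ratio * uniques$size[i])
    parents <- parents[parents != i]
    if (length(parents) < 2L) next
    lcp <- vapply(parents, function(p) {
      longest_common_prefix(chars[[i]], chars[[p]])
    }, 1L)
    lcs <- vapply(parents, function(p) {
      longest_common_prefix(rev(chars[[i]]), rev(chars[[p]]))
    }, 1L)
    # crossover at k needs a parent matching positions 1..k and another
    # matching k+1..len; neither parent may equal the child outright
    lcp <- pmin(lcp, len - 1L)
    lcs <- pmin(lcs, len - 1L)
    for (a in seq_along(parents)) {
      others <- setdiff(seq_along(parents), a)
      if (lcp[a] >= 1L && any(lcp[a] + lcs[others] >= len)) {
        flagged[i] <- TRUE
        break
      }
    }
  }
  out <- uniques[!flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chimeras") <- uniques[flagged, , drop = FALSE]
  out
}

#' Greedy centroid clustering at a fixed identity radius
#'
#' Uniques are visited in decreasing abundance (ties broken
#' lexicographically); each joins the first existing centroid it matches
#' at or above the identity threshold, otherwise it founds a new centroid.
#'
#' @param uniques A [dereplicate()] data frame.
#' @param identity Identity threshold in percent.
#' @return Data frame of class `centroids`: `centroid` (sequence),
#'   `n_members`, `total_reads`, `sample`; the member-to-centroid map is
#'   attached as attribute `"members"`.
#' @export
cluster_centroids <- function(uniques, identity = 99) {
  uniques <- uniques[order(-uniques$size, uniques$sequence), , drop = FALSE]
  cent_seq <- character(0)
  assignment <- integer(nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    assigned <- 0L
    for (k in seq_along(cent_seq)) {
      if (as.numeric(pairwise_identity(uniques$sequence[i], cent_seq[k])) >= identity) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      cent_seq <- c(cent_seq, uniques$sequence[i])
      assigned <- length(cent_seq)
    }
    assignment[i] <- assigned
  }
  out <- data.frame(
    centroid = cent_seq,
    n_members = as.integer(tabulate(assignment, length(cent_seq))),
    total_reads = vapply(seq_along(cent_seq), function(k) {
      sum(uniques$size[assignment == k])
    }, numeric(1)),
    sample = if ("sample" %in% names(uniques)) uniques$sample[1L] else NA_character_,
    stringsAsFactors = FALSE)
  attr(out, "members") <- data.frame(sequence = uniques$sequence,
                                     size = uniques$size,
                                     centroid = assignment,
                                     stringsAsFactors = FALSE)
  class(out) <- c("centroids", "data.frame")
  out
}

#' Assign a centroid to a taxon by library identity search
#'
#' Matches are library records reaching at least `min_identity` percent
#' identity over at least `min_len` aligned bases. A species is assigned
#' when all matches are conspecific; a genus when the matches span several
#' species of one genus; otherwise the centroid stays unassigned (no
#' match, or matches across genera).
#'
#' @param centroid Centroid sequence (or one row of a
#'   [cluster_centroids()] result).
#' @param library A [reference_library()] holding amplicon-region
#'   sequences.
#' @param min_identity Identity threshold, percent.
#' @param min_len Minimum aligned length, bases.
#' @return A one-row data frame: `rank` (`"species"`, `"genus"` or
#'   `"unassigned"`), `taxon`, `group`, `best_identity`, `aligned_length`.
#' @export
assign_taxon <- function(centroid, library, min_identity = 98.36, min_len = 296L) {
  if (is.data.frame(centroid)) centroid <- centroid$centroid[1L]
  stats_list <- lapply(library$sequence, function(ref) identity_stats(centroid, ref))
  ident <- vapply(stats_list, `[[`, numeric(1), "identity")
  cols <- vapply(stats_list, `[[`, numeric(1), "columns")
  hit <- ident >= min_identity & cols >= min_len
  best <- if (any(hit)) max(ident[hit]) else if (length(ident)) max(ident) else NA_real_
  best_len <- if (any(hit)) max(cols[hit & ident == max(ident[hit])]) else NA_real_
  if (!any(hit)) {
    return(data.frame(rank = "unassigned", taxon = NA_character_,
                      group = NA_character_, best_identity = best,
                      aligned_length = NA_real_, stringsAsFactors = FALSE))
  }
  keys <- species_key(library)[hit]
  genera <- library$genus[hit]
  groups <- library$group[hit]
  if (length(unique(genera)) > 1L) {
    rank <- "unassigned"; taxon <- NA_character_; group <- NA_character_
  } else if (!anyNA(keys) && length(unique(keys)) == 1L) {
    rank <- "species"; taxon <- keys[1L]; group <- groups[1L]
  } else {
    rank <- "genus"; taxon <- paste(genera[1L], "spp."); group <- groups[1L]
  }
  data.frame(rank = rank, taxon = taxon, group = group, best_identity = best,
             aligned_length = best_len, stringsAsFactors = FALSE)
}

#' Build the per-individual detection matrix
#'
#' @param assignments Data frame with one row per centroid: `sample`,
#'   `rank`, `taxon`, `group`, `reads`.
#' @param target_group Group counted as diet detections (columns of the
#'   matrix); centroids of other groups and unassigned centroids are
#'   tallied separately.
#' @param samples Optional vector of sample ids fixing the row set (so
#'   individuals with no detections keep an all-zero row).
#' @return An integer matrix (rows = individuals, columns = detected
#'   taxa, cells = summed reads) of class `detection_matrix`, with
#'   per-sample `"offtarget_reads"` and `"unassigned_reads"` attributes.
#' @export
build_detection_matrix <- function(assignments, target_group = "aphid",
                                   samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(assignments$sample))
  is_target <- !is.na(assignments$group) & assignments$group == target_group &
    assignments$rank != "unassigned"
  taxa <- sort(unique(assignments$taxon[is_target]))
  mat <- matrix(0L, length(samples), max(length(taxa), 0L),
                dimnames = list(samples, taxa))
  tgt <- assignments[is_target, , drop = FALSE]
  for (r in seq_len(nrow(tgt))) {
    mat[tgt$sample[r], tgt$taxon[r]] <- mat[tgt$sample[r], tgt$taxon[r]] +
      as.integer(tgt$reads[r])
  }
  tally <- function(rows) {
    vapply(samples, function(s) {
      as.integer(sum(assignments$reads[rows & assignments$sample == s]))
    }, integer(1))
  }
  attr(mat, "offtarget_reads") <- tally(!is_target & assignments$rank != "unassigned")
  attr(mat, "unassigned_reads") <- tally(assignments$rank == "unassigned")
  class(mat) <- c("detection_matrix", class(mat))
  mat
}

#' Run the full reads-to-diet pipeline
#'
#' Chains quality trimming, pair merging, demultiplexing, dereplication,
#' per-pool minimum-abundance filtering, chimera screening, centroid
#' clustering and taxonomic assignment, keeping a per-stage
#' read-conservation log.
#'
#' @param r1,r2 Lists of [fastq_read()] objects (paired, same order).
#' @param scheme A [tag_scheme()].
#' @param library A [reference_library()] of amplicon-region sequences.
#' @param trim A [trim_params()].
#' @param min_size Minimum per-sample unique-amplicon abundance (scalar,
#'   e.g. from [tag_jump_threshold()]).
#' @param cluster_identity Centroid clustering identity, percent.
#' @param min_identity,min_len Taxonomic assignment thresholds.
#' @param target_group Group reported in the detection matrix.
#' @return A list of class `pipeline_result`: `detections` (the
#'   [build_detection_matrix()] output), `assignments`, `centroids` (per
#'   sample), `log` (per-stage read accounting), `unassigned_reads`.
#' @export
run_pipeline <- function(r1, r2, scheme, library, trim = trim_params(),
                         min_size = 10L, cluster_identity = 99,
                         min_identity = 98.36, min_len = 296L,
                         target_group = "aphid") {
  stopifnot(length(r1) == length(r2))
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out,
                                           n_discarded = n_in - n_out,
                                           stringsAsFactors = FALSE)
  }

  n0 <- length(r1)
  t1 <- lapply(r1, function(r) quality_trim(clip_adapters(r, trim), trim))
  t2 <- lapply(r2, function(r) quality_trim(clip_adapters(r, trim), trim))
  keep <- !vapply(t1, is.null, logical(1)) & !vapply(t2, is.null, logical(1))
  note("quality_trim", n0, sum(keep))

  merged <- list()
  for (i in which(keep)) {
    m <- merge_pairs(t1[[i]], t2[[i]])
    if (!is.null(m)) merged <- c(merged, list(m))
  }
  note("merge_pairs", sum(keep), length(merged))

  dmx <- demultiplex(merged, scheme)
  note("demultiplex", length(merged), sum(dmx$counts$n_reads))

  assignments <- NULL
  centroids <- list()
  n_derep_in <- sum(dmx$counts$n_reads)
  n_after_abund <- 0L
  for (s in names(dmx$samples)) {
    reads_s <- dmx$samples[[s]]
    if (length(reads_s) == 0L) next
    uni <- dereplicate(reads_s, sample = s)
    uni <- abundance_filter(uni, min_size = min_size)
    uni <- screen_chimeras(uni)
    n_after_abund <- n_after_abund + sum(uni$size)
    if (nrow(uni) == 0L) next
    cent <- cluster_centroids(uni, identity = cluster_identity)
    centroids[[s]] <- cent
    asg <- do.call(rbind, lapply(seq_len(nrow(cent)), function(k) {
      assign_taxon(cent$centroid[k], library,
                   min_identity = min_identity, min_len = min_len)
    }))
    asg$sample <- s
    asg$reads <- cent$total_reads
    assignments <- rbind(assignments, asg)
  }
  note("abundance_and_chimera_filter", n_derep_in, n_after_abund)

  if (is.null(assignments)) {
    assignments <- data.frame(rank = character(0), taxon = character(0),
                              group = character(0), best_identity = numeric(0),
                              aligned_length = numeric(0), sample = character(0),
                              reads = numeric(0), stringsAsFactors = FALSE)
  }
  detections <- build_detection_matrix(assignments, target_group = target_group,
                                       samples = scheme$samples$sample)
  structure(list(detections = detections, assignments = assignments,
                 centroids = centroids, log = do.call(rbind, log),
                 unassigned_reads = dmx$unassigned),
            class = "pipeline_result")
}
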