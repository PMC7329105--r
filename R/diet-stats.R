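# Downstream composition statistics: recovery rates, Hellinger-transformed
# Euclidean distances, stratified-permutation PERMANOVA, multivariate
# dispersion and NMDS.

#' Per-stratum DNA recovery rates
#'
#' The recovery rate of a stratum (e.g. a sampling method or predator
#' species) is the percentage of its individuals in which prey DNA was
#' detected. Ratios between all pairs of estimable strata are reported
#' alongside.
#'
#' @param positives,totals Named integer vectors (same names): prey-DNA
#'   positive individuals and individuals analysed per stratum.
#' @return A list of class `recovery_rates`: `rates` data frame
#'   (`stratum`, `positives`, `total`, `rate` in percent to 0.1,
#'   `estimable`), and `ratios`, a named vector of pairwise rate ratios.
#' @examples
#' recovery_rates(c(hand = 167, trap = 19), c(hand = 330, trap = 289))
#' @export
recovery_rates <- function(positives, totals) {
  stopifnot(length(positives) == length(totals),
            identical(names(positives), names(totals)))
  if (any(positives > totals)) stop("positives exceed totals", call. = FALSE)
  if (any(positives < 0 | totals < 0)) stop("counts must be >= 0", call. = FALSE)
  estimable <- totals > 0
  rate <- ifelse(estimable, round(100 * positives / totals, 1), NA_real_)
  rates <- data.frame(stratum = names(positives), positives = positives,
                      total = totals, rate = rate, estimable = estimable,
                      row.names = NULL, stringsAsFactors = FALSE)
  ratios <- c()
  est <- which(estimable & positives > 0)
  if (length(est) >= 2L) {
    for (i in est) for (j in est) {
      if (i != j) {
        ratios[paste0(names(positives)[i], "/", names(positives)[j])] <-
          (positives[i] / totals[i]) / (positives[j] / totals[j])
      }
    }
  }
  structure(list(rates = rates, ratios = ratios), class = "recovery_rates")
}

#' Species share in one trap type from marginal totals
#'
#' Given the total catch of a species across two trap types, the number
#' of individuals caught per trap type, and the species' percentage share
#' in one of them, returns its share in the other (the remaining
#' individuals divided by that trap type's catch).
#'
#' @param species_total Total individuals of the species over both trap
#'   types.
#' @param n_focal Individuals (all species) caught in the focal trap type.
#' @param n_other Individuals caught in the other trap type.
#' @param other_share_pct The species' share in the other trap type,
#'   percent.
#' @return The species' share in the focal trap type, percent to 0.1.
#' @examples
#' trap_type_share(854, 720, 320, 67.5) # 88.6
#' @export
trap_type_share <- function(species_total, n_focal, n_other, other_share_pct) {
  stopifnot(n_focal > 0, n_other >= 0, other_share_pct >= 0, other_share_pct <= 100)
  in_other <- n_other * other_share_pct / 100
  in_focal <- species_total - in_other
  if (in_focal < 0 || in_focal > n_focal) {
    stop("marginals are inconsistent", call. = FALSE)
  }
  round(100 * in_focal / n_focal, 1)
}

#' Per-taxon detection frequency among prey-positive individuals
#'
#' For a per-individual detection table, computes for each prey taxon the
#' percentage of prey-positive individuals in which it was detected,
#' overall and within groups (e.g. predator species).
#'
#' @param detections A [build_detection_matrix()] matrix, or any
#'   individuals-by-taxa matrix of counts.
#' @param group Optional factor of length `nrow(detections)` (e.g.
#'   predator species) for within-group frequencies.
#' @return A data frame with `taxon`, `group` (`"all"` plus each group
#'   level), `n_positive` (positive individuals in the group), `n_detected`
#'   and `frequency` (percent to 0.1).
#' @export
prey_frequency <- function(detections, group = NULL) {
  detections <- unclass(detections)
  pos <- rowSums(detections) > 0
  groups <- list(all = rep(TRUE, nrow(detections)))
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(detections))
    for (g in sort(unique(as.character(group)))) groups[[g]] <- group == g
  }
  out <- NULL
  for (g in names(groups)) {
    idx <- groups[[g]] & pos
    npos <- sum(idx)
    det <- if (npos > 0) colSums(detections[idx, , drop = FALSE] > 0) else
      rep(0L, ncol(detections))
    out <- rbind(out, data.frame(
      taxon = colnames(detections), group = g, n_positive = npos,
      n_detected = as.integer(det),
      frequency = if (npos > 0) round(100 * det / npos, 1) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE))
  }
  out
}

#' Aggregate detections into a composition matrix
#'
#' Detections are aggregated over the individuals of each unit (e.g.
#' landscape x sampling round x predator species): a taxon's cell is the
#' number of individuals of the unit in which it was detected, converted
#' to within-unit proportions. Units without any detection keep an
#' all-zero row.
#'
#' @param detections A [build_detection_matrix()] matrix (individuals x
#'   taxa).
#' @param metadata Data frame with one row per individual (matched to
#'   `rownames(detections)` through its `sample` column) carrying the
#'   unit-defining columns.
#' @param unit_cols Metadata columns that define a unit.
#' @return A numeric matrix (units x taxa, rows summing to 1 or 0) of
#'   class `composition_matrix` with the unit metadata in attribute
#'   `"units"`. Individuals without metadata are dropped with a message.
#' @export
composition_matrix <- function(detections, metadata,
                               unit_cols = c("landscape", "round", "species")) {
  stopifnot("sample" %in% names(metadata), all(unit_cols %in% names(metadata)))
  idx <- match(rownames(detections), metadata$sample)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " individual(s) without metadata excluded")
  }
  keep <- !is.na(idx)
  det <- unclass(detections)[keep, , drop = FALSE]
  meta <- metadata[idx[keep], unit_cols, drop = FALSE]
  unit <- interaction(meta, drop = TRUE, sep = ":")
  units <- levels(unit)
  mat <- matrix(0, length(units), ncol(det), dimnames = list(units, colnames(det)))
  for (u in units) {
    mat[u, ] <- colSums(det[unit == u, , drop = FALSE] > 0)
  }
  rs <- rowSums(mat)
  nz <- rs > 0
  mat[nz, ] <- mat[nz, , drop = FALSE] / rs[nz]
  units_meta <- meta[match(units, as.character(unit)), , drop = FALSE]
  rownames(units_meta) <- units
  attr(mat, "units") <- units_meta
  attr(mat, "zero_rows") <- units[!nz]
  class(mat) <- c("composition_matrix", class(mat))
  mat
}

#' Hellinger transform
#'
#' Each cell becomes the square root of its within-row proportion, making
#' Euclidean distances appropriate for relative-abundance data with many
#' zeros. Zero rows stay zero; the squares of a transformed nonzero row
#' sum to 1.
#'
#' @param x Non-negative numeric matrix.
#' @return The transformed matrix.
#' @export
hellinger <- function(x) {
  x <- unclass(x)
  if (any(x < 0)) stop("cells must be non-negative", call. = FALSE)
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  sqrt(x / rs)
}

#' Euclidean distances between rows
#'
#' @param x Numeric matrix.
#' @return A [stats::dist] object.
#' @export
euclidean_distances <- function(x) {
  stats::dist(unclass(x), method = "euclidean")
}

# among/within decomposition of squared distances for one grouping factor
permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(groups))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

permute_within_strata <- function(n, strata) {
  perm <- seq_len(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) > 1L) perm[idx] <- sample(idx)
  }
  perm
}

#' One-factor PERMANOVA with permutations restricted within strata
#'
#' Partitions the squared inter-object distances into among- and
#' within-group sums of squares (the one-factor `adonis` form) and tests
#' the pseudo-F statistic by permuting group labels; when strata are
#' supplied, labels are shuffled only within each stratum so that
#' between-stratum differences cannot masquerade as group effects. The
#' p-value includes the observed ordering:
#' `p = (1 + number of permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param d A [stats::dist] object or square distance matrix.
#' @param groups Group labels, one per object (at least 2 levels).
#' @param strata Optional stratum labels restricting the permutations.
#' @param n_perm Number of permutations.
#' @param seed Random seed (the procedure is reproducible given the seed).
#' @return A list of class `permanova_result`: `F`, `p`, `n_perm`,
#'   `strata` flag, and the permuted statistics in `F_perm`.
#' @export
permanova <- function(d, groups, strata = NULL, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2L) stop("need at least two groups", call. = FALSE)
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)
  for (s in unique(strata)) {
    if (length(unique(groups[strata == s])) < 2L) {
      warning("stratum '", s, "' holds a single group level; it contributes no permutation freedom")
    }
  }
  d2 <- dm^2
  f_obs <- permanova_F(d2, groups)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    permanova_F(d2, groups[permute_within_strata(n, strata)])
  }, numeric(1))
  structure(list(F = f_obs,
                 p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = as.integer(n_perm),
                 strata = !all(strata == strata[1L]),
                 F_perm = f_perm),
            class = "permanova_result")
}

# principal-coordinate embedding with the usual negative-eigenvalue
# correction: distances to centroids combine positive- and
# negative-axis contributions as sqrt(max(0, d+^2 - d-^2))
centroid_distances <- function(dm, groups) {
  n <- nrow(dm)
  d2 <- dm^2
  G <- -0.5 * scale(t(scale(t(d2), scale = FALSE)), scale = FALSE)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  axes <- vecs %*% diag(sqrt(abs(vals)), nrow = length(vals))
  pos <- vals > 0
  dist_to <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(axes[idx, , drop = FALSE])
    dif <- sweep(axes[idx, , drop = FALSE], 2, cen)
    dpos <- rowSums(dif[, pos, drop = FALSE]^2)
    dneg <- rowSums(dif[, !pos, drop = FALSE]^2)
    dist_to[idx] <- sqrt(pmax(0, dpos - dneg))
  }
  dist_to
}

#' Multivariate dispersion test
#'
#' Embeds the objects by principal-coordinate analysis (negative
#' eigenvalues handled by the standard imaginary-part correction),
#' measures each object's distance to its group centroid, and compares
#' group mean dispersions with a one-way F statistic whose null
#' distribution is obtained by permuting group labels. Groups of size 1
#' are excluded with a warning.
#'
#' @inheritParams permanova
#' @return A list of class `dispersion_result`: `F`, `p`, `n_perm`,
#'   `distances` (per-object distance to group centroid).
#' @export
dispersion_test <- function(d, groups, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    warning("excluding group(s) of size 1: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes >= 2L]
    dm <- dm[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L) stop("need at least two groups", call. = FALSE)
  z <- centroid_distances(dm, groups)
  f_stat <- function(z, g) {
    fit <- stats::oneway.test(z ~ factor(g), var.equal = TRUE)
    unname(fit$statistic)
  }
  f_obs <- f_stat(z, groups)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) f_stat(z, sample(groups)),
                   numeric(1))
  structure(list(F = f_obs,
                 p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = as.integer(n_perm), distances = z),
            class = "dispersion_result")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimisation with monotone regression (via
#' `vegan::metaMDS` on the supplied distances), taking the best of
#' `n_starts` random starts. Coordinates are centred.
#'
#' @param d A [stats::dist] object or square distance matrix.
#' @param k Embedding dimension.
#' @param n_starts Number of random starts.
#' @param seed Random seed.
#' @return A list of class `nmds_result`: `coordinates` (n x k, centred),
#'   `stress` (Kruskal stress-1), `converged`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1L) stop("need at least k + 1 objects", call. = FALSE)
  if (max(d) == 0) {
    coords <- matrix(0, n, k)
    return(structure(list(coordinates = coords, stress = 0, converged = TRUE,
                          degenerate = TRUE), class = "nmds_result"))
  }
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  coords <- scale(fit$points, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  structure(list(coordinates = coords, stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$stress < 1e-3,
                 degenerate = FALSE),
            class = "nmds_result")
}
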