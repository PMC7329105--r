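# Recovery rates, composition matrices, Hellinger/Euclidean geometry and
# the permutation tests.

test_that("recovery rates reproduce stratum percentages and ratios", {
  rr <- recovery_rates(c(hand = 167, trap = 19), c(hand = 330, trap = 289))
  expect_equal(rr$rates$rate, c(50.6, 6.6))
  expect_gt(rr$ratios[["hand/trap"]], 7.5)   # "almost eight times higher"
  expect_lt(rr$ratios[["hand/trap"]], 8)

  z <- recovery_rates(c(a = 0, b = 5), c(a = 40, b = 10))
  expect_equal(z$rates$rate, c(0, 50))
  n0 <- recovery_rates(c(a = 0, b = 1), c(a = 0, b = 2))
  expect_true(is.na(n0$rates$rate[1]) && !n0$rates$estimable[1])
  expect_error(recovery_rates(c(a = 5), c(a = 4)), "exceed")
})

test_that("trap-type shares follow from the printed marginals", {
  expect_equal(trap_type_share(854, 720, 320, 67.5), 88.6)
  # a 50/50 split with equal trap catches stays 50/50
  expect_equal(trap_type_share(100, 100, 100, 50), 50)
  expect_error(trap_type_share(500, 100, 100, 10), "inconsistent")
})

test_that("prey frequencies count detections among positive individuals", {
  m <- matrix(c(1, 0, 0,
                1, 2, 0,
                0, 0, 0,
                0, 5, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("i", 1:4), c("tA", "tB", "tC")))
  pf <- prey_frequency(m, group = c("H", "C", "H", "C"))
  all <- pf[pf$group == "all", ]
  expect_identical(all$n_positive, rep(3L, 3))
  expect_equal(all$frequency[all$taxon == "tA"], round(100 * 2 / 3, 1))
  expect_equal(pf$frequency[pf$group == "C" & pf$taxon == "tB"], 100)
})

test_that("composition rows are within-unit proportions over detected individuals", {
  det <- matrix(c(1, 0,
                  0, 1,
                  1, 0,
                  0, 0), 4, 2, byrow = TRUE,
                dimnames = list(paste0("i", 1:4), c("tA", "tB")))
  meta <- data.frame(sample = paste0("i", 1:4),
                     landscape = c("L1", "L1", "L2", "L2"),
                     round = 1, species = "H")
  cm <- composition_matrix(det, meta)
  expect_equal(unname(cm["L1.1.H" == rownames(cm) | grepl("^L1", rownames(cm)), ,
                         drop = FALSE][1, ]), c(0.5, 0.5))
  rs <- rowSums(cm)
  expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))

  set.seed(1)
  for (i in 1:5) {
    n <- 12
    det2 <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                   dimnames = list(paste0("s", 1:n), paste0("t", 1:3)))
    meta2 <- data.frame(sample = paste0("s", 1:n),
                        landscape = sample(c("L1", "L2"), n, TRUE),
                        round = sample(1:2, n, TRUE), species = "H")
    rs2 <- rowSums(composition_matrix(det2, meta2))
    expect_true(all(abs(rs2 - 1) < 1e-12 | rs2 == 0))
  }
})

test_that("the Hellinger transform matches its algebraic definition", {
  expect_equal(hellinger(matrix(c(1, 1, 2), 1)), matrix(sqrt(c(.25, .25, .5)), 1))
  one_hot <- matrix(c(0, 1, 0), 1)
  expect_equal(hellinger(one_hot), one_hot)
  set.seed(2)
  m <- matrix(rpois(60, 3), 10, 6)
  m[3, ] <- 0
  h <- hellinger(m)
  expect_true(all(h[3, ] == 0))
  expect_equal(unname(rowSums(h[-3, ]^2)), rep(1, 9))
  # zero cells stay zero (support preservation)
  expect_true(all((m == 0) == (h == 0)))
  # agrees with the standard community-ecology implementation
  expect_equal(unname(h[-3, ]),
               unname(as.matrix(vegan::decostand(m[-3, ], "hellinger"))),
               ignore_attr = TRUE)
  expect_error(hellinger(matrix(-1)), "non-negative")
})

test_that("Euclidean distances are metric and match the 3-4-5 triangle", {
  d <- euclidean_distances(rbind(c(0, 0), c(3, 4), c(0, 0)))
  dm <- as.matrix(d)
  expect_equal(dm[1, 2], 5)
  expect_equal(dm[1, 3], 0)
  expect_equal(dm, t(dm))
})

test_that("PERMANOVA pseudo-F agrees with vegan and separation drives p to its floor", {
  set.seed(3)
  x <- simulate_null_composition(16, 6, groups = 2, shift = 0, seed = 9)
  d <- euclidean_distances(hellinger(x$matrix))
  mine <- permanova(d, x$groups, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = x$groups), permutations = 99)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)

  # strong mean shift: smallest attainable p
  y <- simulate_null_composition(16, 6, groups = 2, shift = 4, seed = 10)
  d2 <- euclidean_distances(hellinger(y$matrix))
  ps <- permanova(d2, y$groups, n_perm = 199, seed = 1)
  expect_equal(ps$p, 1 / 200)
})

test_that("stratified PERMANOVA agrees with the exhaustive-permutation oracle", {
  set.seed(4)
  m <- matrix(runif(6 * 3), 6, 3)
  groups <- c("a", "b", "a", "b", "a", "b")
  strata <- c("s1", "s1", "s1", "s2", "s2", "s2")
  d <- euclidean_distances(m)
  dm2 <- as.matrix(d)^2

  # independent F oracle from the sum-of-squares definition
  oracle_F <- function(g) {
    n <- 6
    ss_tot <- sum(dm2[upper.tri(dm2)]) / n
    ss_w <- 0
    for (lev in unique(g)) {
      i <- which(g == lev)
      ss_w <- ss_w + sum(dm2[i, i][upper.tri(dm2[i, i])]) / length(i)
    }
    ((ss_tot - ss_w) / 1) / (ss_w / (n - 2))
  }

  res <- permanova(d, groups, strata = strata, n_perm = 999, seed = 2)
  expect_equal(res$F, oracle_F(groups))

  # enumerate every within-stratum relabelling (strata keep their own
  # group composition: 2 vs 1 "a" labels here)
  perms1 <- combn(3, sum(groups[1:3] == "a"))
  perms2 <- combn(3, sum(groups[4:6] == "a"))
  f_all <- c()
  for (i in seq_len(ncol(perms1))) for (j in seq_len(ncol(perms2))) {
    g <- rep("b", 6)
    g[perms1[, i]] <- "a"
    g[3 + perms2[, j, drop = TRUE]] <- "a"
    f_all <- c(f_all, oracle_F(g))
  }
  p_exact <- mean(f_all >= res$F - 1e-12)
  expect_lt(abs(res$p - p_exact), 0.05)
})

test_that("dispersion differences are detected and match betadisper geometry", {
  set.seed(5)
  base <- matrix(rnorm(60 * 4, sd = 1), 60, 4)
  base[31:60, ] <- base[31:60, ] * 2        # second group's spread doubled
  groups <- rep(c("tight", "wide"), each = 30)
  d <- euclidean_distances(base)
  res <- dispersion_test(d, groups, n_perm = 99, seed = 3)
  bd <- vegan::betadisper(d, groups, type = "centroid")
  expect_equal(sort(res$distances), sort(unname(bd$distances)), tolerance = 1e-8)
  expect_equal(res$F, unname(stats::anova(bd)$`F value`[1]), tolerance = 1e-8)
  expect_true(all(res$distances >= 0))
  expect_lte(res$p, 0.05)

  # equal spread: no signal over repeated draws
  rejections <- 0
  for (i in 1:10) {
    set.seed(100 + i)
    x0 <- matrix(rnorm(24 * 3), 24, 3)
    r0 <- dispersion_test(euclidean_distances(x0), rep(c("a", "b"), each = 12),
                          n_perm = 99, seed = i)
    rejections <- rejections + (r0$p <= 0.05)
  }
  expect_lte(rejections, 3)
})

test_that("NMDS embeds planar configurations with near-zero stress", {
  set.seed(6)
  pts <- matrix(rnorm(20), 10, 2)
  d <- euclidean_distances(pts)
  # vegan flags the (expected) near-zero stress of a perfect embedding
  fit <- suppressWarnings(nmds(d, k = 2, n_starts = 5, seed = 1))
  expect_lt(fit$stress, 0.01)
  # recovered inter-point ranks match the input ranks
  drec <- stats::dist(fit$coordinates)
  expect_gt(stats::cor(as.vector(d), as.vector(drec), method = "spearman"), 0.99)
  expect_equal(unname(colMeans(fit$coordinates)), c(0, 0))
  # reproducible given the seed
  fit2 <- suppressWarnings(nmds(d, k = 2, n_starts = 5, seed = 1))
  expect_identical(fit$stress, fit2$stress)
})
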