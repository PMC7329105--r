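# Stage-by-stage behaviour of the reads-to-diet pipeline.

test_that("sliding-window quality trimming follows the windowed cut rule", {
  good <- make_read(rand_seq(300), q = 30)
  expect_identical(quality_trim(good), good)

  # window 101-104 (mean Q15) is the first failing window: the read is cut
  # to 100 bases and then discarded as too short
  q <- c(rep(30, 100), 20, 20, 10, 10, rep(30, 196))
  r <- fastq_read("r", rand_seq(300), q)
  expect_null(quality_trim(r))
  expect_identical(nchar(quality_trim(r, trim_params(min_length = 50))$bases), 100L)

  # a single leading Q2 base is clipped, the rest retained
  r2 <- fastq_read("r", rand_seq(260), c(2, rep(30, 259)))
  expect_identical(nchar(quality_trim(r2)$bases), 259L)
})

test_that("adapter read-through is clipped with mismatch tolerance", {
  adapter <- "AGATCGGAAGAGC"
  p <- trim_params(adapter_seqs = adapter)
  set.seed(1)
  insert <- rand_seq(80)
  r <- make_read(paste0(insert, adapter))
  expect_identical(clip_adapters(r, p)$bases, insert)

  clean <- make_read(insert)
  expect_identical(clip_adapters(clean, p)$bases, insert)

  noisy <- make_read(paste0(insert, mutate_seq(adapter, 1)))
  expect_identical(clip_adapters(noisy, p, max_mismatch = 2)$bases, insert)
})

test_that("pair merging takes the best overlap and the higher-quality base", {
  set.seed(2)
  full <- rand_seq(500)
  r1 <- make_read(substr(full, 1, 300), q = 35, id = "p")
  r2 <- fastq_read("p", reverse_complement(substr(full, 201, 500)), rep(35, 300))
  m <- merge_pairs(r1, r2)
  expect_identical(nchar(m$bases), 500L)  # 300 + 300 - 100
  expect_identical(m$bases, full)

  # conflicting base: consensus takes Q40 over Q10
  chars <- strsplit(substr(full, 1, 300), "")[[1]]
  chars[250] <- setdiff(BASES, chars[250])[1]
  q1 <- rep(35, 300); q1[250] <- 10
  r1c <- fastq_read("p", paste(chars, collapse = ""), q1)
  q2 <- rep(35, 300); q2[300 - (250 - 201)] <- 40
  r2c <- fastq_read("p", reverse_complement(substr(full, 201, 500)), q2)
  mc <- merge_pairs(r1c, r2c)
  expect_identical(substr(mc$bases, 250, 250), substr(full, 250, 250))
  expect_identical(mc$qualities[250], 40L)

  # unrelated reads do not merge
  expect_null(merge_pairs(make_read(rand_seq(200)), make_read(rand_seq(200))))
})

demo_scheme <- function() {
  tag_scheme(data.frame(sample = c("S1", "S2", "S3"),
                        forward_tag = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                        reverse_tag = c("TTTTTTTT", "AAAACCCC", "GGGGTTTT"),
                        stringsAsFactors = FALSE),
             fwd_primer(), rev_primer())
}

tagged_read <- function(ftag, rtag, insert) {
  make_read(paste0(ftag, FWD20, insert, reverse_complement(REV20),
                   reverse_complement(rtag)))
}

test_that("demultiplexing allows one tag mismatch and strips tags and primers", {
  set.seed(3)
  sch <- demo_scheme()
  insert <- rand_seq(120)

  d <- demultiplex(list(tagged_read("GGGGGGGG", "GGGGTTTT", insert)), sch)
  expect_length(d$samples$S3, 1L)
  expect_identical(d$samples$S3[[1]]$bases, insert)

  d1 <- demultiplex(list(tagged_read("GGGGGGGT", "GGGGTTTT", insert)), sch)
  expect_length(d1$samples$S3, 1L)

  d2 <- demultiplex(list(tagged_read("GGGGGGTT", "GGGGTTTT", insert)), sch)
  expect_length(d2$samples$S3, 0L)
  expect_identical(attr(d2$unassigned[[1]], "unassigned_reason"), "no_match")

  # a read one mismatch away from two samples' tag pairs is ambiguous
  amb <- tag_scheme(data.frame(sample = c("A", "B"),
                               forward_tag = c("AAAAAAAA", "AAAAAAAC"),
                               reverse_tag = c("TTTTTTTT", "TTTTTTTT")),
                    fwd_primer(), rev_primer())
  da <- demultiplex(list(tagged_read("AAAAAAAA", "TTTTTTTT", insert)), amb)
  expect_identical(attr(da$unassigned[[1]], "unassigned_reason"), "ambiguous")

  expect_error(tag_scheme(data.frame(sample = c("A", "B"),
                                     forward_tag = c("AAAA", "AAAA"),
                                     reverse_tag = c("TTTT", "TTTT")),
                          fwd_primer(), rev_primer()),
               "duplicate tag pair")
})

test_that("dereplication conserves read counts and sorts by abundance", {
  x <- rand_seq(50); y <- rand_seq(50)
  uni <- dereplicate(c(rep(x, 5), rep(y, 3)))
  expect_identical(uni$sequence, c(x, y))
  expect_identical(uni$size, c(5L, 3L))

  all_distinct <- dereplicate(replicate(7, rand_seq(30)))
  expect_true(all(all_distinct$size == 1L))

  set.seed(4)
  for (i in 1:5) {
    pool <- sample(replicate(4, rand_seq(20)), 60, replace = TRUE)
    expect_identical(sum(dereplicate(pool)$size), 60L)
  }
})

test_that("abundance filtering removes uniques below the per-sample minimum", {
  uni <- data.frame(sequence = c("A", "C", "G"), size = c(10L, 9L, 97L))
  expect_identical(abundance_filter(uni, 10)$size, c(10L, 97L))
  expect_identical(abundance_filter(uni, 97)$size, 97L)
})

test_that("tag-jump thresholds raise the minimum above the largest impossible detection", {
  imp <- data.frame(size = c(3L, 12L, 7L), pool = c("pool1", "pool1", "pool2"))
  thr <- tag_jump_threshold(imp, base = 10)
  expect_identical(thr[["pool1"]], 13)
  expect_identical(thr[["pool2"]], 10)
  expect_warning(t0 <- tag_jump_threshold(data.frame(size = integer(0))), "baseline")
  expect_identical(t0, 10L)
  # monotone in the largest impossible size
  thr2 <- tag_jump_threshold(data.frame(size = c(3L, 25L, 7L)), base = 10)
  expect_identical(thr2, 26)
})

test_that("chimera screening flags single-crossover children of abundant parents", {
  set.seed(5)
  a <- rand_seq(200); b <- mutate_seq(a, 30)
  child <- paste0(substr(a, 1, 100), substr(b, 101, 200))
  uni <- dereplicate(c(rep(a, 100), rep(b, 100), rep(child, 10)))
  screened <- screen_chimeras(uni)
  expect_setequal(screened$sequence, c(a, b))
  expect_identical(attr(screened, "chimeras")$sequence, child)

  # an unrelated unique with no compatible parents is retained
  lone <- rand_seq(200)
  uni2 <- dereplicate(c(rep(a, 100), rep(b, 100), rep(lone, 5)))
  expect_true(lone %in% screen_chimeras(uni2)$sequence)

  # the most abundant sequence can never be flagged
  uni3 <- dereplicate(c(rep(child, 200), rep(a, 50), rep(b, 50)))
  expect_true(child %in% screen_chimeras(uni3)$sequence)
})

test_that("greedy centroid clustering respects the identity radius", {
  set.seed(6)
  a <- rand_seq(200)
  b <- mutate_seq(a, 1)     # 99.5% to a
  c_ <- mutate_seq(a, 20)   # 90% to a
  cl <- cluster_centroids(dereplicate(c(rep(a, 10), rep(b, 5), rep(c_, 3))),
                          identity = 99)
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$centroid[1], a)
  expect_identical(cl$total_reads, c(15, 3))

  one <- cluster_centroids(dereplicate(rep(a, 20)), identity = 99)
  expect_identical(nrow(one), 1L)

  uni <- dereplicate(c(rep(a, 5), rep(b, 4), rep(c_, 3)))
  expect_identical(nrow(cluster_centroids(uni, identity = 100)), nrow(uni))
})

test_that("clustering membership matches the brute-force invariant on small sets", {
  set.seed(7)
  for (i in 1:3) {
    root <- rand_seq(150)
    seqs <- c(replicate(8, mutate_seq(root, sample(0:2, 1))),
              replicate(8, mutate_seq(root, sample(15:30, 1))))
    uni <- dereplicate(sample(seqs, 60, replace = TRUE))
    cl <- cluster_centroids(uni, identity = 99)
    members <- attr(cl, "members")
    for (r in seq_len(nrow(members))) {
      own <- members$centroid[r]
      # member is within the radius of its centroid
      expect_gte(oracle_identity(members$sequence[r], cl$centroid[own]), 99)
      # and not within the radius of any earlier centroid
      if (own > 1L) {
        for (k in seq_len(own - 1L)) {
          expect_lt(oracle_identity(members$sequence[r], cl$centroid[k]), 99)
        }
      }
    }
  }
})

test_that("taxon assignment applies identity and aligned-length thresholds", {
  set.seed(8)
  sim <- simulate_library(n_genera = 3, species_per_genus = 2,
                          seqs_per_species = 2,
                          congeneric_divergence = c(0.03, 0.06),
                          predator_species = 1, seed = 31)
  lib <- sim$library
  q <- lib$sequence[lib$id == "G1_s1_r1"]
  asg <- assign_taxon(q, lib)
  expect_identical(asg$rank, "species")
  expect_identical(asg$taxon, "G1 s1")
  expect_identical(asg$group, "aphid")
  expect_equal(asg$best_identity, 100)

  # a centroid equidistant to two congeneric species resolves to genus
  s1 <- lib$sequence[lib$id == "G1_s1_r1"]
  s2 <- lib$sequence[lib$id == "G1_s2_r1"]
  half <- paste0(substr(s1, 1, 154), substr(s2, 155, 308))
  asg2 <- assign_taxon(half, lib, min_identity = 95)
  expect_identical(asg2$rank, "genus")
  expect_identical(asg2$taxon, "G1 spp.")

  # best identity below the threshold leaves the centroid unassigned
  far <- mutate_seq(q, 20)  # ~93.5%
  expect_identical(assign_taxon(far, lib)$rank, "unassigned")
  # long enough identity but too short an alignment also fails
  expect_identical(assign_taxon(substr(q, 1, 200), lib)$rank, "unassigned")
})

test_that("detection matrices sum reads per taxon and conserve totals", {
  asg <- data.frame(
    rank = c("species", "species", "species", "genus", "unassigned"),
    taxon = c("G1 s1", "G1 s1", "G2 s1", "G3 spp.", NA),
    group = c("aphid", "aphid", "aphid", "aphid", NA),
    best_identity = c(100, 99, 100, 99, 80),
    aligned_length = c(308, 308, 308, 308, NA),
    sample = c("I1", "I1", "I2", "I2", "I3"),
    reads = c(40, 10, 25, 5, 100),
    stringsAsFactors = FALSE)
  dm <- build_detection_matrix(asg, samples = c("I1", "I2", "I3"))
  expect_identical(dm["I1", "G1 s1"], 50L)
  expect_identical(sum(dm["I3", ]), 0L)  # predator-only individual
  expect_identical(sum(dm) + sum(attr(dm, "unassigned_reads")),
                   as.integer(sum(asg$reads)))
})

test_that("the pipeline is deterministic and conserves reads at every stage", {
  sim <- simulate_library(n_genera = 2, species_per_genus = 2,
                          seqs_per_species = 2,
                          congeneric_divergence = c(0.03, 0.06),
                          predator_species = 1, seed = 41)
  fw <- degenerate_primer("Aph344.MF", "GGAACAGGWACAGGATGAACWA", "forward")
  rv <- degenerate_primer("Aph149.MR", "AATCARAATARATGTTGATA", "reverse")
  comps <- list(S1 = c("G1 s1" = 20, "G2 s2" = 15), S2 = c("G2 s1" = 25))
  g <- simulate_gut_samples(sim, comps, fw, rv, predator_read_fraction = 0.5,
                            error_rate = 0.002, chimera_rate = 0.01,
                            tagjump_rate = 0.01, seed = 5)
  res1 <- run_pipeline(g$r1, g$r2, g$scheme, sim$library, min_size = 5)
  res2 <- run_pipeline(g$r1, g$r2, g$scheme, sim$library, min_size = 5)
  expect_identical(res1$detections, res2$detections)
  expect_identical(res1$assignments, res2$assignments)

  log <- res1$log
  expect_true(all(log$n_in == log$n_out + log$n_discarded))
  # stages chain: each stage consumes exactly what the previous emitted
  expect_identical(log$n_in[-1], log$n_out[-nrow(log)])
  # ground truth without errors at the detection level: both gut samples
  # recover their true taxa
  expect_true(all(res1$detections["S1", c("G1 s1", "G2 s2")] > 0))
  expect_true(res1$detections["S2", "G2 s1"] > 0)
})
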