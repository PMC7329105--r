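# Shared fixture builders. All fixtures are constructed in code so the
# suite needs no data files.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# mutate `seq` at `k` distinct random positions (always to a different base)
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  for (p in sample(length(chars), k)) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

make_read <- function(bases, q = 35, id = "r") {
  fastq_read(id, bases, rep(q, nchar(bases)))
}

# simple independent identity oracle for equal-length concrete sequences
oracle_identity <- function(a, b) {
  100 * sum(utf8ToInt(a) == utf8ToInt(b)) / nchar(a)
}

# concrete primer pair + template builder used across primer/amplicon tests
FWD20 <- "ACGTACGGTACCGATGGATC"
REV20 <- "TGCATGCCAGTCAAGGCTAG"          # written 5'->3' on the amplicon's minus strand
fwd_primer <- function() degenerate_primer("fwd20", FWD20, "forward")
rev_primer <- function() degenerate_primer("rev20", REV20, "reverse")

# template = pad5 + forward site + insert + reverse-complement of reverse
# primer + pad3 (so both primers bind perfectly)
make_template <- function(insert, pad5 = "", pad3 = "") {
  paste0(pad5, FWD20, insert, reverse_complement(REV20), pad3)
}

# exhaustive, independently-coded threshold-search oracle:
# identity matrix by direct base comparison, candidates = observed values
# >= start plus midpoints, lexicographic (min deviating, max species-level)
oracle_optimize_threshold <- function(library, start = 90) {
  n <- nrow(library)
  idm <- matrix(100, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idm[i, j] <- idm[j, i] <- oracle_identity(library$sequence[i], library$sequence[j])
  }
  key <- paste(library$genus, library$species)
  key[is.na(library$species)] <- NA
  vals <- sort(unique(idm[upper.tri(idm)]))
  vals <- vals[vals >= start]
  cand <- sort(unique(c(start, vals, (head(vals, -1) + tail(vals, -1)) / 2)))
  score <- function(t) {
    dev <- 0
    nsp <- 0
    for (i in seq_len(n)) {
      hits <- setdiff(which(idm[i, ] >= t), i)
      dev_i <- sum(!is.na(key[i]) & !is.na(key[hits]) & key[hits] != key[i])
      dev <- dev + dev_i
      if (length(hits) > 0 && !is.na(key[i]) && !anyNA(key[hits]) &&
          all(key[hits] == key[i])) {
        nsp <- nsp + 1
      }
    }
    c(dev = dev / 2, nsp = nsp)  # pair-level deviating count
  }
  sc <- vapply(cand, score, numeric(2))
  best_dev <- min(sc["dev", ])
  ok <- sc["dev", ] == best_dev
  best_nsp <- max(sc["nsp", ok])
  min(cand[ok & sc["nsp", ] == best_nsp])
}
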