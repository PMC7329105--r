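# IUPAC nucleotide code tables shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

iupac_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

check_iupac <- function(x, what = "sequence") {
  chars <- iupac_chars(x)
  if (length(chars) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- which(!(chars %in% names(IUPAC_SETS)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC code '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(chars)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented by their IUPAC rules (R to Y, W to W,
#' B to V, and so on), so degenerate primers can be evaluated on either
#' strand.
#'
#' @param x A character string over the IUPAC nucleotide alphabet.
#' @return A character string of the same length.
#' @examples
#' reverse_complement("ACWGT")
#' @export
reverse_complement <- function(x) {
  chars <- check_iupac(x)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# precomputed code-by-code compatibility (possibility sets intersect)
IUPAC_COMPAT <- local({
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- any(IUPAC_SETS[[a]] %in% IUPAC_SETS[[b]])
  }
  m
})

# TRUE where the possibility sets of the two codes intersect
iupac_compatible <- function(a_chars, b_chars) {
  unname(IUPAC_COMPAT[cbind(a_chars, b_chars)])
}
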