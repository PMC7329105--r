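#' Construct a degenerate primer
#'
#' A primer is an oligonucleotide written 5' to 3' over the IUPAC alphabet;
#' ambiguity codes (W = A/T, R = A/G, ...) denote a mixture of concrete
#' oligos synthesised together. The degeneracy of the primer is the product
#' of per-position possibility counts.
#'
#' @param name Primer label.
#' @param sequence IUPAC nucleotide string, 5' to 3'.
#' @param direction `"forward"` or `"reverse"`.
#' @return An object of class `degenerate_primer` with fields `name`,
#'   `sequence`, `direction` and `degeneracy`.
#' @examples
#' degenerate_primer("Aph344F", "GGAACAGGWACAGGATGAAC", "forward")
#' @export
degenerate_primer <- function(name, sequence, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  chars <- check_iupac(sequence, what = sprintf("primer '%s'", name))
  structure(
    list(name = name,
         sequence = paste(chars, collapse = ""),
         direction = direction,
         degeneracy = prod(vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), 1L))),
    class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s)\n  5'-%s-3'  length %d, degeneracy %d\n",
              x$name, x$direction, x$sequence, nchar(x$sequence), x$degeneracy))
  invisible(x)
}

primer_seq <- function(primer) {
  if (inherits(primer, "degenerate_primer")) primer$sequence else {
    check_iupac(primer, "primer")
    toupper(primer)
  }
}

#' Expand a degenerate primer into its concrete sequences
#'
#' @param primer A `degenerate_primer` or IUPAC string.
#' @return Character vector of all concrete ACGT sequences the degenerate
#'   pattern represents; its length equals the primer degeneracy.
#' @examples
#' expand_degenerate("ACWT")
#' @export
expand_degenerate <- function(primer) {
  chars <- iupac_chars(primer_seq(primer))
  sets <- lapply(chars, function(ch) IUPAC_SETS[[ch]])
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = ""))
}

#' GC content of a (possibly degenerate) primer
#'
#' Each position contributes the fraction of its possibility set that is G
#' or C, so a W contributes 0 and an R contributes 0.5. Equivalent to the
#' mean GC content over all concrete expansions.
#'
#' @inheritParams expand_degenerate
#' @param digits If non-`NULL`, round half-up to this many decimals for
#'   reporting.
#' @return GC content in percent.
#' @examples
#' gc_content("GGAACAGGWACAGGATGAAC") # 50
#' @export
gc_content <- function(primer, digits = NULL) {
  chars <- iupac_chars(primer_seq(primer))
  frac <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    sum(set %in% c("G", "C")) / length(set)
  }, numeric(1))
  maybe_round(100 * sum(frac) / length(frac), digits)
}

maybe_round <- function(x, digits) {
  if (is.null(digits)) x else round(x, digits)
}

# monophosphate residue masses, g/mol
NT_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
MW_END_CORRECTION <- 61.96

#' Molecular weight of a (possibly degenerate) primer
#'
#' Sum of per-base monophosphate masses (A 313.21, C 289.18, G 329.21,
#' T 304.20 g/mol) minus 61.96 g/mol for the 5' end. A degenerate position
#' contributes the mean mass over its possibilities, i.e. the expected mass
#' of the synthesised oligo mixture.
#'
#' @inheritParams gc_content
#' @return Molecular weight in g/mol (unrounded unless `digits` is set;
#'   conventionally reported to 0.1).
#' @examples
#' molecular_weight("GGAACAGGWACAGGATGAAC", digits = 1) # 6228.6
#' @export
molecular_weight <- function(primer, digits = NULL) {
  chars <- iupac_chars(primer_seq(primer))
  masses <- vapply(chars, function(ch) mean(NT_MASS[IUPAC_SETS[[ch]]]), numeric(1))
  maybe_round(sum(masses) - MW_END_CORRECTION, digits)
}

# SantaLucia (1998) unified nearest-neighbour parameters
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
           GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

tm_wallace_one <- function(chars) {
  at <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    sum(set %in% c("A", "T")) / length(set)
  }, numeric(1))
  2 * sum(at) + 4 * sum(1 - at)
}

tm_nn_one <- function(seq, Na = 0.05, conc = 5e-7) {
  chars <- iupac_chars(seq)
  n <- length(chars)
  pairs <- paste0(chars[-n], chars[-1L])
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  for (end in chars[c(1L, n)]) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  dh * 1000 / (ds + 1.987 * log(conc / 4)) - 273.15 + 16.6 * log10(Na)
}

#' Melting temperature of a primer
#'
#' Two methods are offered: the Wallace rule `2(A+T) + 4(G+C)` with
#' degenerate positions contributing fractionally, and a nearest-neighbour
#' model (unified thermodynamic parameters, 50 mM monovalent salt, 0.5 uM
#' oligo) averaged over the concrete expansions of a degenerate primer.
#'
#' @inheritParams expand_degenerate
#' @param method `"wallace"` or `"nearest_neighbour"`.
#' @return Temperature in degrees Celsius, with the method recorded in the
#'   `"method"` attribute.
#' @examples
#' melting_temperature("ACGT") # 12
#' @export
melting_temperature <- function(primer, method = c("wallace", "nearest_neighbour")) {
  method <- match.arg(method)
  seq <- primer_seq(primer)
  tm <- switch(method,
    wallace = tm_wallace_one(iupac_chars(seq)),
    nearest_neighbour = mean(vapply(expand_degenerate(seq), tm_nn_one, numeric(1))))
  structure(tm, method = method)
}

#' Position-weighted mismatch scoring scheme for primer binding
#'
#' Penalty points accumulate per mismatch between primer and template:
#' transitions (A/G, C/T) cost `transition`, transversions `transversion`,
#' each multiplied by a position weight that grows toward the primer 3'
#' end (where polymerase extension is most sensitive to mispairing). Two
#' mismatches at adjacent positions are each inflated by
#' `adjacent_multiplier`; in gapped mode every indel column adds
#' `gap_penalty`. A template is predicted to amplify while the total stays
#' at or below `fail_threshold`. A degenerate primer position matches any
#' of its possibilities at zero cost and is otherwise scored by its
#' cheapest possibility.
#'
#' With the defaults a single transversion at the 3'-terminal position
#' (30 x 5 = 150) is predicted to abolish amplification, a single terminal
#' transition (15 x 5 = 75) is not, and it takes five or more internal
#' mismatches to cross the threshold.
#'
#' @param transition,transversion Base penalties per mismatch type.
#' @param position_weights Multipliers for positions 1, 2, ... counted from
#'   the 3' end; positions beyond the vector get weight 1.
#' @param adjacent_multiplier Factor applied to each member of an adjacent
#'   mismatch pair.
#' @param gap_penalty Points per indel column (gapped mode only).
#' @param fail_threshold Predicted amplification fails when the total
#'   penalty exceeds this value.
#' @return An object of class `mismatch_scheme`.
#' @export
mismatch_scheme <- function(transition = 15, transversion = 30,
                            position_weights = c(5, 4, 3, 2, 1.5, 1.2),
                            adjacent_multiplier = 1.5,
                            gap_penalty = 40, fail_threshold = 120) {
  stopifnot(transition >= 0, transversion >= 0, all(position_weights > 0),
            adjacent_multiplier >= 1, gap_penalty >= 0, fail_threshold > 0)
  structure(list(transition = transition, transversion = transversion,
                 position_weights = position_weights,
                 adjacent_multiplier = adjacent_multiplier,
                 gap_penalty = gap_penalty, fail_threshold = fail_threshold),
            class = "mismatch_scheme")
}

position_weight <- function(scheme, pos3) {
  w <- scheme$position_weights
  ifelse(pos3 <= length(w), w[pmin(pos3, length(w))], 1)
}

PURINES <- c("A", "G")

# cheapest mismatch class between a primer IUPAC code and a concrete base
mismatch_base_score <- function(scheme, primer_char, template_char) {
  poss <- IUPAC_SETS[[primer_char]]
  tset <- IUPAC_SETS[[template_char]]
  if (any(poss %in% tset)) return(0)
  classes <- vapply(poss, function(p) {
    any((p %in% PURINES) == (tset %in% PURINES))
  }, logical(1))
  if (any(classes)) scheme$transition else scheme$transversion
}

#' Score primer-template mismatch events at a binding site
#'
#' Aligns a primer against a template without gaps, either at a supplied
#' binding-site start or at the minimum-penalty site found by scanning all
#' ungapped offsets (ties broken in favour of the most 3'-proximal site on
#' the template). Reverse primers are evaluated against the reverse
#' complement of the template, so both strands are handled by the same
#' forward logic.
#'
#' @param primer A `degenerate_primer` (or IUPAC string, treated as
#'   forward).
#' @param template Concrete template sequence, 5' to 3'.
#' @param site Optional 1-based start of the binding site on the evaluated
#'   strand; `NULL` scans for the minimum-penalty site.
#' @param scheme A [mismatch_scheme()] used to rank candidate sites.
#' @return A list of class `binding_alignment`: `events` (data frame with
#'   `pos3` = distance from the primer 3' end, 1 = terminal, `primer_base`,
#'   `template_base`, `type`), `site_start`, `strand`.
#' @export
align_binding <- function(primer, template, site = NULL, scheme = mismatch_scheme()) {
  direction <- if (inherits(primer, "degenerate_primer")) primer$direction else "forward"
  pseq <- primer_seq(primer)
  template <- toupper(template)
  strand <- "+"
  if (direction == "reverse") {
    template <- reverse_complement(template)
    strand <- "-"
  }
  np <- nchar(pseq)
  nt <- nchar(template)
  if (nt < np) stop("template shorter than primer", call. = FALSE)
  pchars <- iupac_chars(pseq)
  tchars <- iupac_chars(template)

  events_at <- function(start) {
    idx <- start:(start + np - 1L)
    mism <- which(!iupac_compatible(pchars, tchars[idx]))
    data.frame(pos3 = np - mism + 1L,
               primer_base = pchars[mism],
               template_base = tchars[idx][mism],
               type = rep("mismatch", length(mism)),
               stringsAsFactors = FALSE)
  }

  if (is.null(site)) {
    starts <- seq_len(nt - np + 1L)
    penalties <- vapply(starts, function(s) {
      binding_penalty(events_at(s), scheme, primer = pchars)$total_penalty
    }, numeric(1))
    # most 3'-proximal site on the template among ties
    site <- max(starts[penalties == min(penalties)])
  } else if (site < 1L || site + np - 1L > nt) {
    stop("binding site out of template range", call. = FALSE)
  }

  structure(list(events = events_at(site), site_start = site, strand = strand,
                 primer_length = np),
            class = "binding_alignment")
}

#' Total binding penalty and amplification prediction
#'
#' Sums position-weighted mismatch penalties over the events of a binding
#' alignment: each mismatch costs its base score (transition or
#' transversion, the cheapest possibility for a degenerate primer base)
#' times the weight of its distance from the 3' end; members of adjacent
#' mismatch pairs are additionally multiplied by the scheme's adjacent
#' multiplier; gap events add the flat gap penalty. Amplification is
#' predicted while the total does not exceed the scheme's fail threshold.
#'
#' @param events A `binding_alignment`, or its `events` data frame.
#' @param scheme A [mismatch_scheme()].
#' @param primer Optional primer (used only to label the evaluation).
#' @return A list of class `binding_evaluation`: `total_penalty`,
#'   `mismatch_positions`, `amplification_predicted`.
#' @export
binding_penalty <- function(events, scheme = mismatch_scheme(), primer = NULL) {
  if (inherits(events, "binding_alignment")) events <- events$events
  if (nrow(events) == 0L) {
    total <- 0
  } else {
    is_mis <- events$type == "mismatch"
    base <- numeric(nrow(events))
    base[!is_mis] <- scheme$gap_penalty
    if (any(is_mis)) {
      score <- mapply(mismatch_base_score,
                      primer_char = events$primer_base[is_mis],
                      template_char = events$template_base[is_mis],
                      MoreArgs = list(scheme = scheme), USE.NAMES = FALSE)
      base[is_mis] <- score * position_weight(scheme, events$pos3[is_mis])
    }
    adj <- rep(1, nrow(events))
    mpos <- events$pos3[is_mis]
    adjacent <- (mpos + 1L) %in% mpos | (mpos - 1L) %in% mpos
    adj[is_mis][adjacent] <- scheme$adjacent_multiplier
    total <- sum(base * adj)
  }
  name <- if (inherits(primer, "degenerate_primer")) primer$name else NA_character_
  structure(list(primer = name,
                 total_penalty = total,
                 mismatch_positions = events,
                 amplification_predicted = total <= scheme$fail_threshold),
            class = "binding_evaluation")
}

#' Predicted amplification coverage of a primer pair over a library
#'
#' Evaluates both primers of a pair against every record of a labelled
#' reference library (forward primer on the given strand, reverse primer
#' on the reverse complement, binding sites located by minimum-penalty
#' scan) and reports, per taxon group, the percentage of templates for
#' which BOTH primers are predicted to amplify.
#'
#' @param forward,reverse `degenerate_primer` objects.
#' @param library A reference library data frame (see
#'   [reference_library()]) with a `group` column.
#' @param scheme A [mismatch_scheme()].
#' @return A data frame with one row per group: `group`, `n_templates`,
#'   `n_predicted_amplified`, `coverage` (percent; `NA` for an empty
#'   group). The per-template verdicts are attached as attribute
#'   `"per_template"`.
#' @export
pair_coverage <- function(forward, reverse, library, scheme = mismatch_scheme()) {
  stopifnot(inherits(forward, "degenerate_primer"),
            inherits(reverse, "degenerate_primer"))
  verdict <- vapply(library$sequence, function(tmpl) {
    f <- binding_penalty(align_binding(forward, tmpl, scheme = scheme), scheme)
    if (!f$amplification_predicted) return(FALSE)
    r <- binding_penalty(align_binding(reverse, tmpl, scheme = scheme), scheme)
    r$amplification_predicted
  }, logical(1), USE.NAMES = FALSE)
  groups <- unique(library$group)
  out <- data.frame(
    group = groups,
    n_templates = vapply(groups, function(g) sum(library$group == g), 1L),
    n_predicted_amplified = vapply(groups, function(g) sum(verdict[library$group == g]), 1L),
    stringsAsFactors = FALSE)
  out$coverage <- ifelse(out$n_templates > 0L,
                         100 * out$n_predicted_amplified / out$n_templates, NA_real_)
  attr(out, "per_template") <- data.frame(id = library$id, amplified = verdict,
                                          stringsAsFactors = FALSE)
  out
}
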