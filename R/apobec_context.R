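# Extended sequence context of APOBEC mutations: YTCA/RTCA classification of
# mutated TCA motifs (position -2 pyrimidine vs purine separates APOBEC3A-like
# from APOBEC3B-like mutagenesis), enrichment against local background
# context, and position-by-base frequency matrices for logo plots.

# Forward-strand window around positions, as a matrix of single bases;
# columns named by offset. Positions too close to the ends are rejected.
.window_bases <- function(bases, pos, flank) {
  L <- length(bases)
  if (any(pos <= flank | pos > L - flank)) {
    stop("positions within ", flank, " bases of the reference ends cannot ",
         "be context-resolved")
  }
  offs <- -flank:flank
  m <- vapply(offs, function(o) bases[pos + o], character(length(pos)))
  if (length(pos) == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- as.character(offs)
  m
}

#' Classify mutated TCA motifs by the -2 base (YTCA vs RTCA)
#'
#' Restricts to cytosine mutations (pyrimidine-strand normalized) whose
#' -1/0/+1 context is TCA, and labels each by the base two positions 5' of
#' the mutated cytosine: pyrimidine (Y) or purine (R). Mutations whose
#' pyrimidine-strand reference is not a cytosine in TCA context are excluded
#' and counted.
#'
#' @param mutations data.frame with `pos`, `ref`, `alt`.
#' @param reference character scalar genome.
#' @return list: `labels` (per retained mutation: "YTCA"/"RTCA"), `tally`
#'   (named counts), `n_c_mutations` (all C>N after strand normalization),
#'   `n_excluded` (input mutations not classifiable).
#' @export
classify_minus2 <- function(mutations, reference) {
  b <- .ref_bases(reference)
  is_c <- mutations$ref == "C"
  is_g <- mutations$ref == "G"
  keep <- is_c | is_g
  m <- mutations[keep, , drop = FALSE]
  w <- .window_bases(b, m$pos, 2)
  # pyrimidine-strand 4-mer (-2,-1,0,+1): reverse-complement for G reference
  fwd <- m$ref == "C"
  minus2 <- ifelse(fwd, w[, "-2"], unname(COMPLEMENT[w[, "2"]]))
  minus1 <- ifelse(fwd, w[, "-1"], unname(COMPLEMENT[w[, "1"]]))
  plus1 <- ifelse(fwd, w[, "1"], unname(COMPLEMENT[w[, "-1"]]))
  in_tca <- minus1 == "T" & plus1 == "A"
  labels <- ifelse(minus2 %in% PYRIMIDINES, "YTCA", "RTCA")[in_tca]
  tally <- c(YTCA = sum(labels == "YTCA"), RTCA = sum(labels == "RTCA"))
  list(labels = labels, tally = tally,
       n_c_mutations = nrow(m),
       n_excluded = nrow(mutations) - sum(in_tca))
}

#' Background context counts around mutations
#'
#' Counts cytosines (both strands) and YTCA/RTCA motif occurrences within
#' `flank` bases of each mutation, the local background against which motif
#' enrichment is scored.
#'
#' @param mutations data.frame with `pos`.
#' @param reference character scalar genome.
#' @param flank window half-width in bases (default 20).
#' @return named counts: `C`, `TCA`, `YTCA`, `RTCA`.
#' @export
context_background <- function(mutations, reference, flank = 20) {
  b <- .ref_bases(reference)
  L <- length(b)
  idx <- unique(unlist(lapply(mutations$pos, function(p) {
    max(3, p - flank):min(L - 2, p + flank)
  })))
  ctx_c <- sum(b[idx] %in% c("C", "G"))
  fwd_tca <- b[idx] == "C" & b[idx - 1] == "T" & b[idx + 1] == "A"
  # reverse-strand TCA at a forward G: forward bases are T,G,A with the
  # pyrimidine-strand -2 base complementary to the forward +2 base
  rev_tca <- b[idx] == "G" & b[idx - 1] == "T" & b[idx + 1] == "A"
  fwd_y <- fwd_tca & b[idx - 2] %in% PYRIMIDINES
  rev_y <- rev_tca & b[idx + 2] %in% PURINES
  c(C = ctx_c,
    TCA = sum(fwd_tca) + sum(rev_tca),
    YTCA = sum(fwd_y) + sum(rev_y),
    RTCA = sum(fwd_tca & !b[idx - 2] %in% PYRIMIDINES) +
      sum(rev_tca & !b[idx + 2] %in% PURINES))
}

#' YTCA/RTCA enrichment scores and Fisher tests
#'
#' Enrichment follows the P-MACD convention:
#' `E(YTCA) = (mut_YTCA x ctx_C) / (mut_C x ctx_YTCA)` with the background
#' taken from the local windows, and symmetrically for RTCA. The Fisher test
#' compares the YTCA:RTCA split among mutations with the split among
#' background motif occurrences, one-sided in each direction.
#'
#' @param tally result of [classify_minus2()].
#' @param background result of [context_background()] (all counts > 0).
#' @return list: `enrichment` (named YTCA/RTCA scores), `fisher_ytca`
#'   (p, alternative = mutations enriched for YTCA), `fisher_rtca`, `table`.
#' @export
context_enrichment <- function(tally, background) {
  if (any(background[c("C", "YTCA", "RTCA")] == 0)) {
    stop("background context counts must be positive")
  }
  mut_y <- tally$tally[["YTCA"]]
  mut_r <- tally$tally[["RTCA"]]
  mut_c <- tally$n_c_mutations
  enr <- c(
    YTCA = (mut_y * background[["C"]]) / (mut_c * background[["YTCA"]]),
    RTCA = (mut_r * background[["C"]]) / (mut_c * background[["RTCA"]]))
  tab <- matrix(c(mut_y, mut_r, background[["YTCA"]], background[["RTCA"]]),
                nrow = 2,
                dimnames = list(c("mutations", "background"),
                                c("YTCA", "RTCA")))
  f_y <- stats::fisher.test(t(tab), alternative = "greater")
  f_r <- stats::fisher.test(t(tab), alternative = "less")
  list(enrichment = enr,
       fisher_ytca = f_y$p.value,
       fisher_rtca = f_r$p.value,
       table = tab)
}

#' Extended-context base-frequency matrix around mutated cytosines
#'
#' Per-position base frequencies on the pyrimidine strand in a window of
#' `flank` bases around each mutated C (G-reference mutations are
#' reverse-complemented). Rows (positions) sum to 1; suitable for sequence
#' logos.
#'
#' @param mutations data.frame with `pos`, `ref`.
#' @param reference character scalar genome.
#' @param flank window half-width (default 2).
#' @return matrix (2*flank+1) x 4, rows named by offset, columns A/C/G/T.
#' @export
extended_spectrum <- function(mutations, reference, flank = 2) {
  keep <- mutations$ref %in% c("C", "G")
  m <- mutations[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no cytosine-reference mutations to profile")
  b <- .ref_bases(reference)
  w <- .window_bases(b, m$pos, flank)
  fwd <- m$ref == "C"
  offs <- -flank:flank
  freq <- t(vapply(offs, function(o) {
    col <- ifelse(fwd, w[, as.character(o)],
                  unname(COMPLEMENT[w[, as.character(-o)]]))
    tab <- table(factor(col, levels = BASES))
    as.numeric(tab) / length(col)
  }, numeric(4)))
  dimnames(freq) <- list(as.character(offs), BASES)
  freq
}
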