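# 96-channel spectra, EM signature attribution with the two-round pruning and
# per-individual permission rules, APOBEC-positivity calls, WES scaling, and
# the small-vs-large intestine branch-proportion test.

#' Build a 96-channel spectrum from mutations
#'
#' Looks up the trinucleotide context of each substitution in the reference,
#' reverse-complements purine-reference mutations onto the pyrimidine strand
#' and tallies the 96 channels. Counts conserve the number of input mutations.
#'
#' @param mutations data.frame with columns `pos`, `ref`, `alt` (single-base
#'   substitutions, 1-based positions on the reference).
#' @param reference character scalar genome.
#' @return named numeric vector of 96 channel counts.
#' @export
build_spectrum <- function(mutations, reference) {
  ch <- sbs_channels()
  spectrum <- stats::setNames(rep(0, 96), ch$channel)
  if (nrow(mutations) == 0) return(spectrum)
  ctx <- trinucleotide_at(reference, mutations$pos)
  genome_ref <- substr(ctx, 2, 2)
  bad <- genome_ref != mutations$ref
  if (any(bad)) {
    stop("ref allele mismatch with reference at positions: ",
         paste(utils::head(mutations$pos[bad], 10), collapse = ", "))
  }
  oriented <- pyrimidine_orient(ctx, mutations$ref, mutations$alt)
  tab <- table(factor(oriented$channel, levels = ch$channel))
  spectrum + as.numeric(tab)
}

#' Attribute a spectrum to reference signatures by expectation maximization
#'
#' Multinomial-mixture EM: the spectrum is modelled as a mixture of the
#' catalog columns; the E step distributes each channel's count over
#' signatures proportionally to `pi_s * f_s(channel)`, the M step renormalizes.
#' Initialization is uniform, so the fit is deterministic. The log-likelihood
#' is non-decreasing by construction and iteration stops on a relative change
#' below `tol` or after `max_iter` iterations.
#'
#' @param spectrum named 96 vector of counts (total > 0).
#' @param catalog 96 x S matrix of signature probability vectors.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `counts` (expected mutations per signature),
#'   `proportions`, `reconstruction` (fitted 96 vector scaled to the spectrum
#'   total), `cosine` (reconstruction vs spectrum), `loglik` (trace),
#'   `iterations`.
#' @export
em_attribute <- function(spectrum, catalog, tol = 1e-8, max_iter = 1e4) {
  stopifnot(ncol(catalog) >= 1)
  if (sum(spectrum) <= 0) stop("spectrum total must be positive")
  catalog <- sweep(catalog, 2, colSums(catalog), "/")
  dup <- duplicated(t(round(catalog, 12)))
  if (any(dup)) {
    warning("catalog contains identical signature columns; their exposures ",
            "are not separately identifiable")
  }
  S <- ncol(catalog)
  x <- as.numeric(spectrum)
  pi <- rep(1 / S, S)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    mix <- as.numeric(catalog %*% pi)          # 96 fitted probabilities
    keep <- x > 0
    ll_now <- sum(x[keep] * log(mix[keep]))
    ll <- c(ll, ll_now)
    # E step: expected share of each channel's count per signature
    resp <- sweep(catalog, 2, pi, "*") / ifelse(mix > 0, mix, 1)
    pi_new <- as.numeric(t(resp) %*% x)
    pi_new <- pi_new / sum(pi_new)
    # require both the log-likelihood and the mixing weights to settle: the
    # likelihood flattens long before boundary components finish draining
    if (it > 1 &&
        abs(ll[it] - ll[it - 1]) <
          tol * (abs(ll[it - 1]) + .Machine$double.eps) &&
        max(abs(pi_new - pi)) < 1e-9) {
      pi <- pi_new
      break
    }
    pi <- pi_new
  }
  recon_p <- as.numeric(catalog %*% pi)
  counts <- pi * sum(x)
  names(counts) <- names(pi) <- colnames(catalog)
  list(counts = counts,
       proportions = pi,
       reconstruction = stats::setNames(recon_p * sum(x), rownames(catalog)),
       cosine = cosine(recon_p, x),
       loglik = ll,
       iterations = length(ll))
}

#' Two-round EM attribution with 10% pruning
#'
#' Runs EM on the full permitted catalog, drops signatures contributing
#' <= `prune` of the spectrum, and refits on the survivors to reduce
#' overfitting. The reconstruction is checked against the spectrum at a
#' cosine-similarity floor; failures are flagged but exposures are still
#' returned. If pruning removes everything, the round-1 exposures are
#' returned with a flag.
#'
#' @param spectrum named 96 vector of counts.
#' @param catalog 96 x S matrix.
#' @param prune round-1 contribution at or below which a signature is dropped.
#' @param min_cosine reconstruction check threshold.
#' @inheritParams em_attribute
#' @return as [em_attribute()], plus `kept` (signatures in round 2),
#'   `flag` (`NA`, `"low_reconstruction"` or `"empty_after_prune"`).
#' @export
two_round_prune <- function(spectrum, catalog, prune = 0.10,
                            min_cosine = 0.8, tol = 1e-8, max_iter = 1e4) {
  round1 <- em_attribute(spectrum, catalog, tol = tol, max_iter = max_iter)
  keep <- names(round1$proportions)[round1$proportions > prune]
  flag <- NA_character_
  if (length(keep) == 0) {
    fit <- round1
    fit$kept <- colnames(catalog)
    fit$flag <- "empty_after_prune"
    return(fit)
  }
  fit <- em_attribute(spectrum, catalog[, keep, drop = FALSE],
                      tol = tol, max_iter = max_iter)
  full <- stats::setNames(rep(0, ncol(catalog)), colnames(catalog))
  full[keep] <- fit$counts
  fit$counts <- full
  prop <- full / sum(full)
  fit$proportions <- prop
  if (fit$cosine <= min_cosine) flag <- "low_reconstruction"
  fit$kept <- keep
  fit$flag <- flag
  fit
}

#' Per-individual permitted signature sets and final branch exposures
#'
#' A signature is permitted for an individual if it reaches at least
#' `min_share` of the mutations on at least one branch carrying more than
#' `min_branch` assigned mutations. Branch spectra are then refit by EM
#' restricted to the permitted set, and per-branch signatures reported are
#' those exceeding `min_share` after refitting. When no branch exceeds
#' `min_branch` mutations, only the ubiquitous set (`SBS1`, `SBS5`, `SBS18`,
#' intersected with the catalog) is permitted and the result is flagged.
#'
#' @param branch_spectra matrix branches x 96 of counts (rows named by
#'   branch).
#' @param catalog 96 x S matrix.
#' @param min_share contribution threshold (default 0.05).
#' @param min_branch branch length above which a branch can license a
#'   signature (default 200 mutations).
#' @param ubiquitous fallback signature set.
#' @return list: `permitted` (character), `flag`, `exposures` (branch x S
#'   count matrix after the restricted refit), `proportions`,
#'   `branch_signatures` (list of reported signatures per branch).
#' @export
permitted_signatures <- function(branch_spectra, catalog, min_share = 0.05,
                                 min_branch = 200,
                                 ubiquitous = c("SBS1", "SBS5", "SBS18")) {
  stopifnot(ncol(branch_spectra) == 96)
  totals <- rowSums(branch_spectra)
  fits <- lapply(seq_len(nrow(branch_spectra)), function(i) {
    if (totals[i] == 0) return(NULL)
    two_round_prune(branch_spectra[i, ], catalog)
  })
  flag <- NA_character_
  qualifying <- totals > min_branch
  if (!any(qualifying)) {
    permitted <- intersect(ubiquitous, colnames(catalog))
    flag <- "no_branch_over_min_length"
  } else {
    share <- vapply(fits, function(f) {
      if (is.null(f)) rep(0, ncol(catalog)) else f$proportions
    }, numeric(ncol(catalog)))
    share <- t(share)  # branches x S
    colnames(share) <- colnames(catalog)
    permitted <- colnames(catalog)[
      apply(share[qualifying, , drop = FALSE] >= min_share, 2, any)]
    if (length(permitted) == 0) {
      permitted <- intersect(ubiquitous, colnames(catalog))
      flag <- "no_signature_licensed"
    }
  }
  sub <- catalog[, permitted, drop = FALSE]
  exposures <- matrix(0, nrow(branch_spectra), length(permitted),
                      dimnames = list(rownames(branch_spectra), permitted))
  for (i in seq_len(nrow(branch_spectra))) {
    if (totals[i] == 0) next
    exposures[i, ] <- em_attribute(branch_spectra[i, ], sub)$counts
  }
  proportions <- exposures / ifelse(totals > 0, totals, 1)
  branch_signatures <- apply(proportions, 1, function(p) {
    names(p)[p > min_share]
  }, simplify = FALSE)
  list(permitted = permitted, flag = flag, exposures = exposures,
       proportions = proportions, branch_signatures = branch_signatures)
}

#' APOBEC positivity of an exposure vector
#'
#' A crypt or branch is APOBEC-positive when SBS2 and SBS13 together account
#' for at least 5% of its mutation burden.
#'
#' @param proportions named proportion vector (sums to 1).
#' @param threshold combined SBS2 + SBS13 share (default 0.05).
#' @return logical.
#' @export
apobec_positive <- function(proportions, threshold = 0.05) {
  share <- sum(proportions[intersect(c("SBS2", "SBS13"), names(proportions))])
  share >= threshold
}

#' Scale an exome APOBEC mutation count to a genome equivalent
#'
#' Exomes cover ~2% of the genome, so whole-exome counts are multiplied by 50
#' for comparison with whole-genome burdens.
#'
#' @param apobec_count_exome non-negative count(s).
#' @return scaled count(s).
#' @export
scale_wes <- function(apobec_count_exome) {
  stopifnot(all(apobec_count_exome >= 0))
  apobec_count_exome * 50
}

#' Chi-squared test on a 2x2 APOBEC-positive branch table
#'
#' Compares the proportion of signature-positive phylogenetic branches
#' between two tissues (rows = tissue, columns = positive/negative) with a
#' continuity-corrected chi-squared test.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return list: `statistic`, `p_value`, `proportions` (per row),
#'   `ratio` (row1/row2 positive-proportion ratio), `warning` flag when an
#'   expected cell is below 1.
#' @export
branch_proportion_test <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)),
            all(table >= 0), all(table == round(table)))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  warn <- any(expected < 1)
  if (warn) warning("expected cell count below 1; chi-squared approximation ",
                    "is unreliable")
  fit <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  props <- table[, 1] / rowSums(table)
  list(statistic = unname(fit$statistic),
       p_value = fit$p.value,
       proportions = props,
       ratio = unname(props[1] / props[2]),
       warning = warn)
}
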