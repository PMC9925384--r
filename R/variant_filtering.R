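# Post-calling filter chain: read-metric predicate, exact binomial germline
# classification with Benjamini-Hochberg correction, and beta-binomial
# overdispersion (rho) artifact filtering.

#' Read-metric filter
#'
#' A substitution passes when the median alignment score of its supporting
#' reads is at least 140 and fewer than half of those reads are clipped.
#' Indels must additionally carry a caller quality score of at least 300 at
#' positions covered by at least 15 reads. Variants with missing metrics are
#' flagged unevaluable and excluded.
#'
#' @param metrics data.frame with `variant_id`, `median_alignment_score`,
#'   `clipped_fraction`, and for indels `pindel_quality`,
#'   `min_supporting_depth`.
#' @param variant_class character vector ("SBS" or "ID") aligned with
#'   `metrics` rows, or a single value recycled.
#' @return data.frame: `variant_id`, `stage = "read_metrics"`, `verdict`
#'   ("pass"/"fail"/"unevaluable").
#' @export
read_metric_filter <- function(metrics, variant_class = "SBS") {
  n <- nrow(metrics)
  variant_class <- rep_len(variant_class, n)
  as_ok <- metrics$median_alignment_score >= 140
  clip_ok <- metrics$clipped_fraction < 0.5
  verdict <- ifelse(as_ok & clip_ok, "pass", "fail")
  is_id <- variant_class == "ID"
  if (any(is_id)) {
    id_ok <- metrics$pindel_quality >= 300 &
      metrics$min_supporting_depth >= 15
    verdict[is_id] <- ifelse(verdict[is_id] == "pass" & id_ok[is_id],
                             "pass", "fail")
    verdict[is_id][is.na(id_ok[is_id])] <- NA
  }
  verdict[is.na(as_ok) | is.na(clip_ok) | is.na(verdict)] <- "unevaluable"
  data.frame(variant_id = metrics$variant_id, stage = "read_metrics",
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Exact binomial germline filter
#'
#' Aggregates alt and total depth across all of a patient's samples at each
#' site and applies a one-sided exact binomial test of the global VAF against
#' the germline expectation (success probability 0.5, or 0.95 on male sex
#' chromosomes), alternative "less". P values are Benjamini-Hochberg adjusted
#' across all of the patient's variants; sites with q < 1e-5 reject the
#' germline null and are classified somatic.
#'
#' @param alt,depth integer matrices (variants x samples) for one patient.
#' @param p0 germline success probability per variant (scalar or vector);
#'   0.5 for autosomes, 0.95 for male sex chromosomes.
#' @param q_cutoff somatic classification threshold on the adjusted p value.
#' @return data.frame: `variant_id`, `p`, `q`, `classification`
#'   ("somatic"/"germline"/"unevaluable").
#' @export
germline_binomial_filter <- function(alt, depth, p0 = 0.5,
                                     q_cutoff = 1e-5) {
  stopifnot(all(dim(alt) == dim(depth)))
  agg_alt <- rowSums(alt)
  agg_depth <- rowSums(depth)
  p0 <- rep_len(p0, nrow(alt))
  p <- stats::pbinom(agg_alt, agg_depth, p0)
  p[agg_depth == 0] <- NA
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  classification <- ifelse(is.na(p), "unevaluable",
                           ifelse(q < q_cutoff, "somatic", "germline"))
  data.frame(variant_id = rownames(alt) %||% seq_len(nrow(alt)),
             p = p, q = q, classification = classification,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default rho search grid
#'
#' 64 log-spaced points on [1e-6, 0.89], mirroring the Shearwater-style
#' implementation of the overdispersion filter.
#' @return numeric vector of length 64.
#' @export
rho_grid <- function() exp(seq(log(1e-6), log(0.89), length.out = 64))

# Beta-binomial log-likelihood of one rho for matrices of counts: the mean is
# fixed at each variant's pooled VAF; rows are variants.
.bb_loglik_rows <- function(alt, depth, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  A <- matrix(a, nrow(alt), ncol(alt))
  B <- matrix(b, nrow(alt), ncol(alt))
  ll <- lchoose(depth, alt) + lbeta(alt + A, depth - alt + B) - lbeta(A, B)
  rowSums(ll)
}

#' Beta-binomial overdispersion (rho) maximum-likelihood estimate
#'
#' Maximizes the beta-binomial log-likelihood over rho on a log-spaced grid
#' with the mean fixed at the pooled VAF across samples. Systematic artifacts
#' recur at similar low VAFs across samples (small rho); genuine somatic
#' variants are near 0.5 in some samples and absent in others (large rho).
#'
#' @param alt_vector,depth_vector per-sample alt and total read counts at one
#'   site (>= 2 samples with depth > 0).
#' @param grid rho search grid.
#' @return rho at the grid argmax. When the pooled VAF is 0 or 1 the
#'   likelihood is flat in rho; the lower grid boundary is returned with
#'   attribute `degenerate = TRUE`.
#' @export
rho_mle <- function(alt_vector, depth_vector, grid = rho_grid()) {
  stopifnot(length(alt_vector) == length(depth_vector))
  if (sum(depth_vector > 0) < 2) stop("need >= 2 samples with depth > 0")
  mu <- sum(alt_vector) / sum(depth_vector)
  if (mu <= 0 || mu >= 1) {
    out <- grid[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  alt <- matrix(alt_vector, nrow = 1)
  depth <- matrix(depth_vector, nrow = 1)
  ll <- vapply(grid, function(r) .bb_loglik_rows(alt, depth, mu, r),
               numeric(1))
  grid[which.max(ll)]
}

#' Vectorized rho estimation over a variant matrix
#'
#' @param alt,depth matrices (variants x samples).
#' @param grid rho search grid.
#' @return numeric vector of rho estimates (NA where the pooled VAF is 0
#'   or 1).
#' @export
rho_mle_matrix <- function(alt, depth, grid = rho_grid()) {
  mu <- rowSums(alt) / pmax(rowSums(depth), 1)
  est <- rep(NA_real_, nrow(alt))
  ok <- mu > 0 & mu < 1 & rowSums(depth > 0) >= 2
  if (!any(ok)) return(est)
  a <- alt[ok, , drop = FALSE]
  d <- depth[ok, , drop = FALSE]
  m <- mu[ok]
  best_ll <- rep(-Inf, nrow(a))
  best_rho <- rep(grid[1], nrow(a))
  for (r in grid) {
    ll <- .bb_loglik_rows(a, d, m, r)
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]
    best_rho[upd] <- r
  }
  est[ok] <- best_rho
  est
}

#' Run the full filter chain on one patient's variants
#'
#' Applies read-metric, germline-binomial and rho filtering in order and
#' reports per-stage attrition. Output contains only variants passing every
#' stage (classified somatic); unevaluable variants are conservatively
#' excluded.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `variant_class`.
#' @param alt,depth count matrices (rownames = variant_id).
#' @param metrics read-metric table (see [read_metric_filter()]).
#' @param male logical; when TRUE, sex-chromosome sites (chrom "chrX"/"chrY")
#'   use germline success probability 0.95.
#' @param rho_cutoff variants with estimated rho below this are artifacts.
#' @param q_cutoff germline-test somatic threshold.
#' @return list: `somatic` (variant table of passing sites), `decisions`
#'   (per-variant per-stage table), `audit` (stage, n_in, n_out).
#' @export
run_filter_chain <- function(variants, alt, depth, metrics, male = FALSE,
                             rho_cutoff = 0.1, q_cutoff = 1e-5) {
  stopifnot(nrow(alt) == nrow(variants))
  if (nrow(variants) > 0) {
    stopifnot(identical(rownames(alt), variants$variant_id))
  }
  n0 <- nrow(variants)
  audit <- data.frame(stage = character(0), n_in = integer(0),
                      n_out = integer(0))
  decisions <- list()
  if (n0 == 0) {
    return(list(somatic = variants, decisions = data.frame(),
                audit = data.frame(stage = c("read_metrics", "germline",
                                             "rho"),
                                   n_in = 0L, n_out = 0L)))
  }

  m <- metrics[match(variants$variant_id, metrics$variant_id), ]
  rm_dec <- read_metric_filter(m, variants$variant_class)
  keep1 <- rm_dec$verdict == "pass"
  audit <- rbind(audit, data.frame(stage = "read_metrics", n_in = n0,
                                   n_out = sum(keep1)))
  decisions$read_metrics <- rm_dec

  v1 <- variants[keep1, , drop = FALSE]
  a1 <- alt[keep1, , drop = FALSE]
  d1 <- depth[keep1, , drop = FALSE]
  p0 <- ifelse(male & v1$chrom %in% c("chrX", "chrY"), 0.95, 0.5)
  g_dec <- germline_binomial_filter(a1, d1, p0 = p0, q_cutoff = q_cutoff)
  keep2 <- g_dec$classification == "somatic"
  audit <- rbind(audit, data.frame(stage = "germline", n_in = nrow(v1),
                                   n_out = sum(keep2)))
  decisions$germline <- g_dec

  v2 <- v1[keep2, , drop = FALSE]
  a2 <- a1[keep2, , drop = FALSE]
  d2 <- d1[keep2, , drop = FALSE]
  rho <- rho_mle_matrix(a2, d2)
  keep3 <- !is.na(rho) & rho >= rho_cutoff
  audit <- rbind(audit, data.frame(stage = "rho", n_in = nrow(v2),
                                   n_out = sum(keep3)))
  decisions$rho <- data.frame(variant_id = v2$variant_id, rho = rho,
                              verdict = ifelse(keep3, "pass", "fail"),
                              stringsAsFactors = FALSE)

  list(somatic = v2[keep3, , drop = FALSE],
       decisions = decisions,
       audit = audit)
}

#' Run the filter chain over a whole synthetic cohort
#'
#' @param cohort a `crypt_cohort`.
#' @inheritParams run_filter_chain
#' @return named list (per patient) of [run_filter_chain()] results.
#' @export
run_filter_chain_cohort <- function(cohort, rho_cutoff = 0.1,
                                    q_cutoff = 1e-5) {
  male <- isTRUE(cohort$config$male_x_germline)
  lapply(cohort$patients, function(p) {
    v <- p$variants
    v$chrom <- cohort$truth$chrom[match(v$variant_id,
                                        cohort$truth$variant_id)]
    run_filter_chain(v, p$alt, p$depth, p$metrics, male = male,
                     rho_cutoff = rho_cutoff, q_cutoff = q_cutoff)
  })
}
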