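# Sensitivity-corrected mutation burdens and mixed-effects regression of
# burden on age, region and disease status.

#' Closed-form detection sensitivity
#'
#' Probability of observing at least `min_alt_reads` mutant reads at a clonal
#' site when depth is Poisson(`mean_depth`) and each read carries the variant
#' with probability `vaf`: sum over d of Pois(d; lambda) [1 - BinomCDF(t-1; d,
#' vaf)].
#'
#' @param vaf per-read success probability (median sample VAF).
#' @param mean_depth Poisson mean depth.
#' @param min_alt_reads detection threshold (4 for SBS, 5 for indels).
#' @return probability in (0, 1].
#' @export
sensitivity_closed_form <- function(vaf, mean_depth, min_alt_reads = 4) {
  stopifnot(vaf > 0, vaf <= 1, mean_depth > 0)
  dmax <- stats::qpois(1 - 1e-13, mean_depth)
  d <- 0:dmax
  sum(stats::dpois(d, mean_depth) *
        (1 - stats::pbinom(min_alt_reads - 1, d, vaf)))
}

#' Monte-Carlo detection sensitivity
#'
#' Simulates read sampling at a clonal site: each run draws a depth from
#' Poisson(`mean_depth`) and counts Bernoulli(`median_vaf`) successes; the
#' sensitivity is the fraction of runs with at least `min_alt_reads`
#' successes. The closed form of [sensitivity_closed_form()] is returned
#' alongside for verification.
#'
#' @param median_vaf median VAF of the sample's passing somatic variants.
#' @param mean_depth mean sequencing depth of the sample.
#' @param min_alt_reads minimum mutant reads for a call (4 SBS / 5 ID).
#' @param n_sims simulation count (default 1e5).
#' @param seed integer seed.
#' @return list: `sensitivity` (MC estimate), `se` (MC standard error),
#'   `closed_form`, `n_sims`.
#' @export
estimate_sensitivity <- function(median_vaf, mean_depth, min_alt_reads = 4,
                                 n_sims = 1e5, seed = 1) {
  if (median_vaf <= 0) stop("vaf must be positive: no detectable signal")
  stopifnot(median_vaf <= 1, mean_depth > 0,
            min_alt_reads %in% c(4, 5))
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  depth <- stats::rpois(n_sims, mean_depth)
  alt <- stats::rbinom(n_sims, depth, median_vaf)
  hits <- alt >= min_alt_reads
  est <- mean(hits)
  list(sensitivity = est,
       se = sqrt(est * (1 - est) / n_sims),
       closed_form = sensitivity_closed_form(median_vaf, mean_depth,
                                             min_alt_reads),
       n_sims = n_sims)
}

#' Sensitivity-adjusted burden
#'
#' @param raw_count observed passing mutation count.
#' @param sensitivity detection sensitivity in (0, 1].
#' @return adjusted count = raw / sensitivity.
#' @export
adjust_burden <- function(raw_count, sensitivity) {
  if (any(sensitivity <= 0)) stop("sensitivity must be positive")
  raw_count / sensitivity
}

#' Quality-control exclusions for burden and dynamics modelling
#'
#' Burden mode drops samples with coverage below `min_coverage` and any
#' explicitly listed samples or patients (for example chemotherapy-exposed
#' donors). Dynamics mode additionally drops celiac patients and children,
#' whose crypts may violate the constant-rate, fixed-size assumptions of the
#' stem-cell model.
#'
#' @param metadata per-sample table with `sample_id`, `patient`, `age_years`,
#'   `celiac`, `chemotherapy`, `mean_coverage`.
#' @param mode "burden" or "dynamics".
#' @param min_coverage coverage floor (default 15).
#' @param exclude_samples,exclude_patients explicit exclusion lists.
#' @param adult_age age at or above which a patient counts as adult.
#' @return list: `included` (metadata subset), `audit` (reason table).
#' @export
apply_qc_exclusions <- function(metadata, mode = c("burden", "dynamics"),
                                min_coverage = 15,
                                exclude_samples = character(0),
                                exclude_patients = character(0),
                                adult_age = 18) {
  mode <- match.arg(mode)
  reason <- rep(NA_character_, nrow(metadata))
  reason[metadata$mean_coverage < min_coverage] <- "low_coverage"
  reason[metadata$sample_id %in% exclude_samples] <- "listed_sample"
  reason[metadata$patient %in% exclude_patients] <- "listed_patient"
  if (mode == "dynamics") {
    reason[metadata$celiac == 1 & is.na(reason)] <- "celiac"
    reason[metadata$age_years < adult_age & is.na(reason)] <- "child"
    if ("chemotherapy" %in% names(metadata)) {
      reason[metadata$chemotherapy == 1 & is.na(reason)] <- "chemotherapy"
    }
  }
  keep <- is.na(reason)
  list(included = metadata[keep, , drop = FALSE],
       audit = data.frame(sample_id = metadata$sample_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE))
}

#' Fit a linear mixed-effects burden model
#'
#' Regresses sensitivity-adjusted burden on age with region-specific slopes
#' and, when requested and identifiable, a celiac-by-age effect, with a
#' random age slope per patient to absorb within-patient correlation
#' (REML, `nlme::lme`). On singular or non-convergent fits the model degrades
#' to a random intercept and finally to a fixed-effects-only `lm`, flagged in
#' the output. Wald 95% confidence intervals use the normal approximation.
#'
#' @param burdens data.frame with `adjusted_count`, `age_years`, `region`,
#'   `celiac` (0/1) and `patient`.
#' @param celiac_term include an age:celiac fixed effect when both classes
#'   are present.
#' @return list of class `burden_lmm`: `fit`, `slopes` (term, estimate,
#'   se, lower, upper), `random_structure`
#'   ("age_slope"/"intercept"/"fixed_only"), `n_obs`, `logLik`.
#' @export
fit_burden_lmm <- function(burdens, celiac_term = TRUE) {
  stopifnot(all(c("adjusted_count", "age_years", "region", "celiac",
                  "patient") %in% names(burdens)))
  b <- burdens
  b$region <- factor(b$region)
  use_celiac <- celiac_term && length(unique(b$celiac)) > 1
  age_term <- if (nlevels(b$region) > 1) "age_years:region" else "age_years"
  fixed <- stats::as.formula(paste(
    "adjusted_count ~ 0 +", age_term,
    if (use_celiac) "+ age_years:celiac" else ""))
  structure_used <- "age_slope"
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 0 + age_years | patient, data = b,
              method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    structure_used <- "intercept"
    fit <- tryCatch(
      nlme::lme(fixed, random = ~ 1 | patient, data = b, method = "REML",
                control = nlme::lmeControl(opt = "optim",
                                           returnObject = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    structure_used <- "fixed_only"
    fit <- stats::lm(fixed, data = b)
    ct <- summary(fit)$coefficients
    est <- ct[, 1]; se <- ct[, 2]
  } else {
    ct <- summary(fit)$tTable
    est <- ct[, "Value"]; se <- ct[, "Std.Error"]
  }
  z <- stats::qnorm(0.975)
  slopes <- data.frame(term = rownames(ct), estimate = est, se = se,
                       lower = est - z * se, upper = est + z * se,
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- list(fit = fit, slopes = slopes,
              random_structure = structure_used,
              n_obs = nrow(b),
              logLik = as.numeric(stats::logLik(fit)))
  class(out) <- "burden_lmm"
  out
}

#' Likelihood-ratio comparison of nested burden models
#'
#' Refits both specifications by maximum likelihood and runs a likelihood
#' ratio test, as in model comparisons of region or disease terms.
#'
#' @param burdens data as for [fit_burden_lmm()].
#' @param full,reduced two-sided fixed-effect formulas (reduced nested in
#'   full).
#' @return anova table.
#' @export
compare_burden_models <- function(burdens, full, reduced) {
  b <- burdens
  b$region <- factor(b$region)
  f1 <- nlme::lme(full, random = ~ 1 | patient, data = b, method = "ML",
                  control = nlme::lmeControl(opt = "optim",
                                             returnObject = TRUE))
  f0 <- nlme::lme(reduced, random = ~ 1 | patient, data = b, method = "ML",
                  control = nlme::lmeControl(opt = "optim",
                                             returnObject = TRUE))
  stats::anova(f0, f1)
}

#' Simulate per-crypt burdens from the mixed-effects generative model
#'
#' Used for parameter-recovery checks: per-patient age slopes are drawn
#' around the region slope, an optional celiac-by-age effect is added, and
#' observation noise is Gaussian.
#'
#' @param n_patients patients (ages spread over `age_range`).
#' @param crypts_per_patient crypts per patient.
#' @param slopes named per-region slopes (mutations/year).
#' @param celiac_effect additional mutations/year in celiac patients.
#' @param n_celiac number of celiac patients.
#' @param sd_patient_slope between-patient SD of the age slope.
#' @param sd_resid residual SD of a crypt's burden.
#' @param age_range patient age range.
#' @param seed integer seed.
#' @return data.frame suitable for [fit_burden_lmm()].
#' @export
simulate_burden_cohort <- function(n_patients = 20, crypts_per_patient = 6,
                                   slopes = c(duodenum = 51, jejunum = 50,
                                              ileum = 42),
                                   celiac_effect = 0, n_celiac = 0,
                                   sd_patient_slope = 3, sd_resid = 60,
                                   age_range = c(20, 80), seed = 1) {
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  regions <- names(slopes)
  out <- lapply(seq_len(n_patients), function(i) {
    age <- stats::runif(1, age_range[1], age_range[2])
    region <- regions[(i - 1) %% length(regions) + 1]
    celiac <- as.integer(i <= n_celiac)
    slope_i <- slopes[[region]] + celiac * celiac_effect +
      stats::rnorm(1, 0, sd_patient_slope)
    data.frame(
      patient = sprintf("PT%02d", i),
      sample_id = sprintf("PT%02d_c%02d", i, seq_len(crypts_per_patient)),
      age_years = age, region = region, celiac = celiac,
      adjusted_count = pmax(slope_i * age +
                              stats::rnorm(crypts_per_patient, 0, sd_resid),
                            0),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
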