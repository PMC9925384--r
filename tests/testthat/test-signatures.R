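test_that("spectra are strand-normalized and conserve counts", {
  # forward G>A in a TGA context is the reverse-complement T[C>T]A channel;
  # forward A>G in a CAT context is the reverse-complement A[T>C]G channel
  ref <- paste0("AAAA", "TGA", "AA", "CAT", "AAAA")
  muts <- data.frame(pos = c(6, 11), ref = c("G", "A"), alt = c("A", "G"))
  spec <- build_spectrum(muts, ref)
  expect_equal(sum(spec), 2)
  expect_equal(unname(spec["T[C>T]A"]), 1)
  expect_equal(unname(spec["A[T>C]G"]), 1)

  empty <- build_spectrum(muts[0, ], ref)
  expect_identical(sum(empty), 0)
  expect_length(empty, 96)

  bad <- data.frame(pos = 6, ref = "C", alt = "T")
  expect_error(build_spectrum(bad, ref), "mismatch")
})

test_that("sampled catalog mutations reproduce their signature spectrum", {
  coh <- apobec_cohort()  # SBS2-only mixture
  truth <- coh$truth[coh$truth$label == "somatic" &
                       coh$truth$variant_class == "SBS", ]
  spec <- build_spectrum(truth[, c("pos", "ref", "alt")], coh$reference)
  expect_equal(sum(spec), nrow(truth))
  expect_gte(cosine(spec, sbs_catalog()[, "SBS2"]), 0.95)
})

test_that("cosine similarity is exact, symmetric and bounded", {
  v <- c(1, 2, 3)
  expect_equal(cosine(v, v), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  cat_m <- sbs_catalog()
  a <- cat_m[, "SBS2"]; b <- cat_m[, "SBS13"]
  brute <- sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))
  expect_equal(cosine(a, b), brute, tolerance = 1e-15)
  expect_equal(cosine(a, b), cosine(b, a))
  expect_error(cosine(a, rep(0, 96)), "zero")
})

test_that("EM attribution resolves pure and mixed spectra", {
  cat_m <- sbs_catalog()
  pure <- 500 * cat_m[, "SBS1"]
  fit <- em_attribute(pure, cat_m)
  # EM drains boundary components sublinearly; the vertex is approached to
  # numerical working accuracy rather than machine accuracy
  expect_gte(fit$proportions[["SBS1"]], 1 - 1e-3)
  expect_gt(fit$cosine, 1 - 1e-9)
  expect_equal(sum(fit$counts), 500)
  expect_true(all(diff(fit$loglik) >= -1e-9))

  set.seed(8)
  mix <- as.numeric(rmultinom(1, 5000, 0.6 * cat_m[, "SBS5"] +
                                0.4 * cat_m[, "SBS18"]))
  names(mix) <- rownames(cat_m)
  fit2 <- em_attribute(mix, cat_m[, c("SBS5", "SBS18")])
  expect_lt(abs(fit2$proportions[["SBS5"]] - 0.6), 0.03)
  expect_lt(abs(fit2$proportions[["SBS18"]] - 0.4), 0.03)
  expect_equal(sum(fit2$counts), 5000)
})

test_that("identical catalog entries split exposures with a warning", {
  cat_m <- sbs_catalog()[, c("SBS1", "SBS1", "SBS5")]
  colnames(cat_m) <- c("SBS1a", "SBS1b", "SBS5")
  spec <- 300 * sbs_catalog()[, "SBS1"]
  expect_warning(fit <- em_attribute(spec, cat_m), "identical")
  expect_equal(sum(fit$counts), 300)
  expect_gte(fit$counts[["SBS1a"]] + fit$counts[["SBS1b"]], 300 * (1 - 1e-3))
})

test_that("two-round pruning drops minor signatures and keeps fit quality", {
  cat_m <- sbs_catalog()
  set.seed(9)
  mix <- as.numeric(rmultinom(1, 1e4, 0.85 * cat_m[, "SBS5"] +
                                0.10 * cat_m[, "SBS1"] +
                                0.05 * cat_m[, "SBS18"]))
  names(mix) <- rownames(cat_m)
  fit <- two_round_prune(mix, cat_m)
  expect_false("SBS18" %in% fit$kept)
  expect_gt(fit$cosine, 0.8)
  expect_equal(sum(fit$counts), 1e4)

  # pure APOBEC burst reconstructs well
  burst <- as.numeric(rmultinom(1, 3000, 0.5 * cat_m[, "SBS2"] +
                                  0.5 * cat_m[, "SBS13"]))
  names(burst) <- rownames(cat_m)
  fit_b <- two_round_prune(burst, cat_m)
  expect_gt(fit_b$cosine, 0.8)
  expect_setequal(fit_b$kept, c("SBS2", "SBS13"))
})

test_that("per-individual permission follows the 5%/200-mutation ladder", {
  cat_m <- sbs_catalog()[, c("SBS1", "SBS2", "SBS5", "SBS13", "SBS88")]
  mk <- function(total, shares) {
    v <- rep(0, 96)
    for (s in names(shares)) v <- v + shares[[s]] * cat_m[, s]
    total * v
  }
  spectra <- rbind(
    long_sbs88 = mk(1200, list(SBS88 = 0.52, SBS5 = 0.48)),
    short_sbs2 = mk(150, list(SBS2 = 0.30, SBS5 = 0.70)),
    clock = mk(800, list(SBS1 = 0.40, SBS5 = 0.60)))
  res <- permitted_signatures(spectra, cat_m)
  expect_true("SBS88" %in% res$permitted)       # 52% on a 1200-long branch
  expect_false("SBS2" %in% res$permitted)       # only on a 150-long branch
  expect_true(all(c("SBS1", "SBS5") %in% res$permitted))
  expect_equal(unname(rowSums(res$exposures)), unname(rowSums(spectra)),
               tolerance = 1e-6)
  expect_true("SBS88" %in% res$branch_signatures$long_sbs88)

  # a signature below 5% everywhere is never permitted
  spectra2 <- rbind(b1 = mk(1000, list(SBS13 = 0.049, SBS5 = 0.951)),
                    b2 = mk(900, list(SBS5 = 1)))
  res2 <- permitted_signatures(spectra2, cat_m)
  expect_false("SBS13" %in% res2$permitted)

  # no branch above 200 mutations: ubiquitous fallback, flagged
  spectra3 <- rbind(b1 = mk(150, list(SBS2 = 0.5, SBS5 = 0.5)))
  res3 <- permitted_signatures(spectra3, cat_m)
  expect_identical(res3$flag, "no_branch_over_min_length")
  expect_setequal(res3$permitted, c("SBS1", "SBS5"))
})

test_that("APOBEC positivity applies the combined 5% rule", {
  expect_true(apobec_positive(c(SBS2 = 0.03, SBS13 = 0.03, SBS5 = 0.94)))
  expect_false(apobec_positive(c(SBS2 = 0.02, SBS13 = 0.029, SBS5 = 0.951)))
  expect_false(apobec_positive(c(SBS2 = 0, SBS13 = 0, SBS5 = 1)))
  expect_true(apobec_positive(c(SBS2 = 0.05, SBS13 = 0, SBS5 = 0.95)))
})

test_that("WES counts scale by 50 to genome equivalents", {
  expect_equal(scale_wes(12), 600)
  expect_equal(scale_wes(0), 0)
  expect_error(scale_wes(-1))
})

test_that("the small-vs-large branch table reproduces the printed test", {
  tab <- matrix(c(68, 349, 6, 1069), nrow = 2, byrow = TRUE,
                dimnames = list(c("small", "large"),
                                c("positive", "negative")))
  res <- branch_proportion_test(tab)
  expect_lt(abs(log10(res$p_value) - log10(1.6e-35)), 0.1)
  expect_equal(round(100 * res$proportions[["small"]], 1), 16.3)
  expect_gt(res$ratio, 25)
  expect_lt(res$ratio, 32)

  sym <- branch_proportion_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
})
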