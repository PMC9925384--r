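test_that("read-metric thresholds are applied at the quoted boundaries", {
  m <- data.frame(variant_id = c("a", "b", "c", "d", "e"),
                  median_alignment_score = c(140, 139, 200, 150, NA),
                  clipped_fraction = c(0.49, 0.0, 0.5, 0.1, 0.1),
                  pindel_quality = c(NA, NA, NA, 300, NA),
                  min_supporting_depth = c(NA, NA, NA, 15, NA))
  dec <- read_metric_filter(m, c("SBS", "SBS", "SBS", "ID", "SBS"))
  expect_identical(dec$verdict,
                   c("pass", "fail", "fail", "pass", "unevaluable"))
  # indel boundaries: quality 299 or depth 14 fail
  m_id <- data.frame(variant_id = c("f", "g"),
                     median_alignment_score = c(200, 200),
                     clipped_fraction = c(0.1, 0.1),
                     pindel_quality = c(299, 300),
                     min_supporting_depth = c(15, 14))
  expect_identical(read_metric_filter(m_id, "ID")$verdict, c("fail", "fail"))
})

test_that("germline binomial test matches closed-form tail probabilities", {
  alt <- matrix(c(0, 50, 95), ncol = 1)
  depth <- matrix(c(100, 100, 100), ncol = 1)
  rownames(alt) <- rownames(depth) <- c("v1", "v2", "v3")
  dec <- germline_binomial_filter(alt, depth, p0 = c(0.5, 0.5, 0.95))
  expect_equal(dec$p[1], 0.5^100, tolerance = 1e-12)
  expect_equal(dec$p[2], pbinom(50, 100, 0.5), tolerance = 1e-12)
  expect_equal(dec$p[3], pbinom(95, 100, 0.95), tolerance = 1e-12)
  expect_identical(dec$classification, c("somatic", "germline", "germline"))
  # zero aggregate depth is unevaluable
  dec0 <- germline_binomial_filter(matrix(0, 1, 2), matrix(0, 1, 2))
  expect_identical(dec0$classification, "unevaluable")
})

test_that("germline classification depends only on aggregate counts", {
  set.seed(5)
  alt_a <- matrix(c(10, 2, 0, 8, 5, 0), nrow = 2)
  depth_a <- matrix(c(20, 20, 10, 15, 20, 8), nrow = 2)
  # same aggregates split differently across samples
  alt_b <- cbind(rowSums(alt_a), 0, 0)
  depth_b <- cbind(rowSums(depth_a), 0, 0)
  pa <- germline_binomial_filter(alt_a, depth_a)$p
  pb <- germline_binomial_filter(alt_b, depth_b)$p
  expect_equal(pa, pb)
  # and is invariant to sample order
  perm <- c(3, 1, 2)
  pc <- germline_binomial_filter(alt_a[, perm], depth_a[, perm])$p
  expect_equal(pa, pc)
})

test_that("BH-adjusted q is a monotone non-decreasing transform of p", {
  set.seed(6)
  alt <- matrix(rbinom(200, 25, runif(200, 0.05, 0.6)), ncol = 4)
  depth <- matrix(25, 50, 4)
  dec <- germline_binomial_filter(alt, depth)
  ord <- order(dec$p)
  expect_true(all(diff(dec$q[ord]) >= -1e-12))
  expect_true(all(dec$q >= dec$p - 1e-12))
})

test_that("rho MLE matches a numerical-integration oracle", {
  # clonal in one crypt, absent in nine: overdispersed, passes
  alt1 <- c(12, rep(0, 9)); d1 <- rep(25, 10)
  r1 <- rho_mle(alt1, d1)
  expect_gte(r1, 0.1)
  expect_equal(r1, rho_oracle(alt1, d1))
  # shared low VAF across ten crypts: artifact-like, small rho; near the
  # lower boundary the likelihood is flat so only the classification (not
  # the exact grid argmax) is compared with the oracle
  alt2 <- rep(1, 10); d2 <- rep(25, 10)
  r2 <- rho_mle(alt2, d2)
  expect_lt(r2, 0.1)
  expect_lt(rho_oracle(alt2, d2), 0.1)
  # no between-sample variance: lower grid boundary
  expect_equal(as.numeric(rho_mle(c(5, 5), c(10, 10))), rho_grid()[1])
  # pooled VAF 0: degenerate, boundary with flag
  r0 <- rho_mle(c(0, 0), c(10, 10))
  expect_true(isTRUE(attr(r0, "degenerate")))
  # matrix route agrees with the scalar route
  rm <- rho_mle_matrix(rbind(alt1, alt2), rbind(d1, d2))
  expect_equal(unname(rm), c(as.numeric(r1), as.numeric(r2)))
})

test_that("filter chain output is a subset with consistent attrition", {
  coh <- small_cohort()
  res <- run_filter_chain_cohort(coh)
  for (pid in names(res)) {
    r <- res[[pid]]
    v <- coh$patients[[pid]]$variants
    expect_true(all(r$somatic$variant_id %in% v$variant_id))
    expect_identical(r$audit$n_in[1], nrow(v))
    expect_identical(r$audit$n_in[-1], r$audit$n_out[-3])
    expect_identical(nrow(r$somatic), r$audit$n_out[3])
  }
})

test_that("filter chain recovers truth labels on a labelled cohort", {
  coh <- small_cohort()
  res <- run_filter_chain_cohort(coh)
  perf <- chain_performance(coh, res)
  expect_true(all(perf[, "germline_recall"] >= 0.99))
  expect_true(all(perf[, "somatic_retention"] >= 0.95))
  expect_true(all(perf[, "artifact_removal"] >= 0.90))
  # systematic (non-mapping) artifacts are removed by the rho stage itself
  pid <- names(coh$patients)[1]
  truth <- coh$truth[coh$truth$patient == pid, ]
  sys_art <- truth$variant_id[truth$label == "artifact" &
                                truth$artifact_type == "systematic"]
  rho_dec <- res[[pid]]$decisions$rho
  tested <- rho_dec[rho_dec$variant_id %in% sys_art, ]
  expect_gte(mean(tested$verdict == "fail"), 0.90)
})

test_that("empty input yields empty output and zero-row audit", {
  v <- data.frame(variant_id = character(0), chrom = character(0),
                  variant_class = character(0))
  a <- matrix(integer(0), 0, 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  m <- data.frame(variant_id = character(0))
  r <- run_filter_chain(v, a, a, m)
  expect_identical(nrow(r$somatic), 0L)
  expect_true(all(r$audit$n_in == 0L))
})

test_that("germline/somatic classification approaches 100% at high depth", {
  cfg <- simulation_config(seed = 61, genome_length = 5e5, n_patients = 1,
                           crypts_per_patient = 6, mean_depth = 500,
                           germline_het_count = 400, artifact_count = 50,
                           mapping_artifact_count = 0,
                           age_range = c(50, 50))
  coh <- generate_cohort(cfg)
  res <- run_filter_chain_cohort(coh)
  perf <- chain_performance(coh, res)
  expect_true(all(perf[, "germline_recall"] == 1))
  # truncal somatic mutations (carried by every crypt) are inherently
  # indistinguishable from germline; separability concerns the rest
  pid <- names(coh$patients)[1]
  p <- coh$patients[[pid]]
  truth <- coh$truth[coh$truth$patient == pid, ]
  n_crypts <- ncol(p$alt)
  carriers <- vapply(truth$branch_id, function(b) {
    if (is.na(b)) 0L else length(p$tree$leafsets[[b]])
  }, integer(1))
  subclonal <- truth$variant_id[truth$label == "somatic" &
                                  truth$variant_class == "SBS" &
                                  carriers < n_crypts]
  expect_gte(mean(subclonal %in% res[[pid]]$somatic$variant_id), 0.999)
})
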