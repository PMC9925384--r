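test_that("reference generation is deterministic, uniform and guarded", {
  r1 <- generate_reference(1e4, seed = 1)
  r2 <- generate_reference(1e4, seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(r1, generate_reference(1e4, seed = 2)))

  big <- generate_reference(1e6, seed = 3)
  freqs <- table(strsplit(big, "")[[1]]) / 1e6
  expect_true(all(abs(freqs - 0.25) < 0.01))

  expect_error(generate_reference(3, seed = 1), "1e4")
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(genome_length = 100), "genome_length")
  expect_error(simulation_config(signature_mix = c(SBS1 = 0.5, SBS5 = 0.4)),
               "sum to 1")
  expect_error(simulation_config(
    signature_mix = c(NOTASIG = 1)), "absent from catalog")
  expect_error(simulation_config(mean_depth = 0), "mean_depth")
  expect_error(simulation_config(apobec_episode_prob = 1.2), "probabilities")
})

test_that("cohort generation is bit-reproducible for a fixed seed", {
  cfg <- simulation_config(seed = 11, genome_length = 5e4, n_patients = 1,
                           crypts_per_patient = 3, germline_het_count = 50,
                           artifact_count = 10, mapping_artifact_count = 2,
                           age_range = c(30, 30))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$patients[[1]]$alt, c2$patients[[1]]$alt)
  expect_identical(c1$patients[[1]]$depth, c2$patients[[1]]$depth)
})

test_that("switching APOBEC episodes off removes all SBS2/SBS13 truth", {
  cfg <- simulation_config(seed = 12, genome_length = 5e4, n_patients = 1,
                           crypts_per_patient = 4, apobec_episode_prob = 0,
                           germline_het_count = 10, artifact_count = 5,
                           mapping_artifact_count = 0, age_range = c(40, 40))
  c0 <- generate_cohort(cfg)
  expect_false(any(c0$truth$signature %in% c("SBS2", "SBS13")))
  expect_true(all(is.na(c0$truth$kataegis_id)))
  # and with episodes on, bursts do appear as SBS2/SBS13 with kataegis ids
  cfg_on <- simulation_config(seed = 12, genome_length = 3e5, n_patients = 1,
                              crypts_per_patient = 4,
                              apobec_episode_prob = 1,
                              germline_het_count = 10, artifact_count = 5,
                              mapping_artifact_count = 0,
                              age_range = c(40, 40))
  c_on <- generate_cohort(cfg_on)
  expect_true(any(c_on$truth$signature %in% c("SBS2", "SBS13")))
  expect_true(any(!is.na(c_on$truth$kataegis_id)))
})

test_that("germline heterozygotes are observed in essentially every crypt", {
  coh <- small_cohort()
  p <- coh$patients[[1]]
  truth <- coh$truth[coh$truth$patient == names(coh$patients)[1], ]
  germ <- truth$variant_id[truth$label == "germline"]
  alt <- p$alt[germ, ]
  # P(alt = 0) per cell is exp(-depth * vaf) ~ 3.7e-6 at depth 25
  expect_gt(mean(alt > 0), 0.999)
  # every germline site is seen in at least half the crypts
  expect_true(all(rowSums(alt > 0) >= ncol(alt) / 2))
})

test_that("somatic VAFs are clonal in carriers and absent elsewhere", {
  coh <- small_cohort()
  pid <- names(coh$patients)[1]
  p <- coh$patients[[pid]]
  truth <- coh$truth[coh$truth$patient == pid, ]
  som <- truth[truth$label == "somatic", ]
  vt <- p$vaf_true[som$variant_id, ]
  expect_true(all(vt %in% c(0, 0.5)))
  carriers <- vapply(som$branch_id,
                     function(b) length(p$tree$leafsets[[b]]), integer(1))
  expect_equal(unname(rowSums(vt > 0)), as.numeric(carriers))
})

test_that("single-crypt burden follows Poisson(rate x age)", {
  cfg <- simulation_config(seed = 21, genome_length = 1e6, n_patients = 1,
                           crypts_per_patient = 1, germline_het_count = 0,
                           artifact_count = 0, mapping_artifact_count = 0,
                           apobec_episode_prob = 0,
                           id_rate_per_year = c(duodenum = 0, jejunum = 0,
                                                ileum = 0),
                           age_range = c(60, 60))
  coh <- generate_cohort(cfg)
  n <- sum(coh$truth$label == "somatic")
  lambda <- 51 * 60
  band <- qpois(c(0.005, 0.995), lambda)
  expect_gte(n, band[1])
  expect_lte(n, band[2])
})

test_that("observed germline VAF converges to 0.5 at high depth", {
  cfg <- simulation_config(seed = 31, genome_length = 1e5, n_patients = 1,
                           crypts_per_patient = 2, mean_depth = 1000,
                           germline_het_count = 1e4, artifact_count = 0,
                           mapping_artifact_count = 0,
                           apobec_episode_prob = 0,
                           sbs_rate_per_year = c(duodenum = 0, jejunum = 0,
                                                 ileum = 0),
                           id_rate_per_year = c(duodenum = 0, jejunum = 0,
                                                ileum = 0),
                           age_range = c(50, 50))
  coh <- generate_cohort(cfg)
  p <- coh$patients[[1]]
  vaf <- p$alt / p$depth
  expect_lt(abs(mean(vaf) - 0.5), 0.01)
})

test_that("truth conserves mutation counts across branches and labels", {
  coh <- small_cohort()
  truth <- coh$truth
  n_som <- sum(truth$label == "somatic")
  expect_identical(n_som, nrow(truth) - sum(truth$label == "germline") -
                     sum(truth$label == "artifact"))
  expect_false(any(duplicated(truth$variant_id)))
  # per patient, branch-wise somatic sums add up to the somatic total
  for (pid in names(coh$patients)) {
    t_p <- truth[truth$patient == pid & truth$label == "somatic", ]
    expect_identical(sum(table(t_p$branch_id)), nrow(t_p))
  }
})

test_that("fixtures round-trip bit-identically and conserve rows", {
  cfg <- simulation_config(seed = 41, genome_length = 5e4, n_patients = 1,
                           crypts_per_patient = 3, germline_het_count = 30,
                           artifact_count = 10, mapping_artifact_count = 2,
                           age_range = c(35, 35))
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_fixture(coh, dir)
  back <- read_fixture(dir)
  expect_identical(back$reference, coh$reference)
  pid <- names(coh$patients)[1]
  expect_identical(back$patients[[pid]]$alt[rownames(coh$patients[[pid]]$alt),
                                            colnames(coh$patients[[pid]]$alt)],
                   coh$patients[[pid]]$alt)
  expect_identical(nrow(back$truth), nrow(coh$truth))

  skip_if_not_installed("vcfR")
  vcf <- vcfR::read.vcfR(file.path(dir, "sites.vcf"), verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  expect_equal(nrow(fix), nrow(coh$truth))
  m <- match(fix[, "ID"], coh$truth$variant_id)
  expect_identical(as.integer(fix[, "POS"]), coh$truth$pos[m])
  expect_identical(unname(fix[, "REF"]), coh$truth$ref[m])
  expect_identical(unname(fix[, "ALT"]), coh$truth$alt[m])
})

test_that("an empty cohort writes valid headers with zero data rows", {
  cfg <- simulation_config(seed = 51, genome_length = 1e4, n_patients = 1,
                           crypts_per_patient = 2, germline_het_count = 0,
                           artifact_count = 0, mapping_artifact_count = 0,
                           apobec_episode_prob = 0,
                           sbs_rate_per_year = c(duodenum = 0, jejunum = 0,
                                                 ileum = 0),
                           id_rate_per_year = c(duodenum = 0, jejunum = 0,
                                                ileum = 0),
                           age_range = c(30, 30))
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh$truth), 0L)
  dir <- withr::local_tempdir()
  write_fixture(coh, dir)
  back <- read_fixture(dir)
  expect_identical(nrow(back$counts), 0L)
  expect_identical(nrow(back$truth), 0L)
  expect_identical(nrow(back$metadata), 2L)
})
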