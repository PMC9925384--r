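#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 5 patients x 8 crypts at mean depth
# 25, region-specific substitution rates (51/50/42 per year), a clock-like
# SBS1/SBS5/SBS18 background, episodic APOBEC bursts with kataegis on 16.3%
# of branches, germline heterozygotes and shared low-VAF artifacts. Writes
# the fixture files every later step consumes.

library(cryptomes)

out_dir <- "results/cohort"
cfg <- simulation_config(seed = 20260920)
cohort <- generate_cohort(cfg)
paths <- write_fixture(cohort, out_dir)
saveRDS(cohort, file.path(out_dir, "cohort.rds"))  # convenience for 02-05

truth <- cohort$truth
message(sprintf("cohort: %d patients, %d crypts, %d variants (%d somatic, %d germline, %d artifact)",
                length(cohort$patients), nrow(cohort$metadata), nrow(truth),
                sum(truth$label == "somatic"),
                sum(truth$label == "germline"),
                sum(truth$label == "artifact")))
message(sprintf("APOBEC burst mutations: %d on %d branches; kataegis clusters: %d",
                sum(truth$signature %in% c("SBS2", "SBS13"), na.rm = TRUE),
                length(unique(truth$branch_id[
                  truth$signature %in% c("SBS2", "SBS13")])),
                length(unique(na.omit(truth$kataegis_id)))))
message("fixtures: ", paste(basename(paths), collapse = ", "))
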