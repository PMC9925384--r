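#!/usr/bin/env Rscript
# Run the post-calling filter chain (read metrics -> exact binomial germline
# test with BH correction -> beta-binomial rho filter) on every patient and
# score it against the simulation truth.

library(cryptomes)

cohort <- readRDS("results/cohort/cohort.rds")
flt <- run_filter_chain_cohort(cohort)

audit <- do.call(rbind, lapply(names(flt), function(pid) {
  cbind(patient = pid, flt[[pid]]$audit)
}))
write.table(audit, "results/filter_audit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

perf <- do.call(rbind, lapply(names(flt), function(pid) {
  truth <- cohort$truth[cohort$truth$patient == pid, ]
  passed <- flt[[pid]]$somatic$variant_id
  gdec <- flt[[pid]]$decisions$germline
  germ <- truth$variant_id[truth$label == "germline"]
  som <- truth$variant_id[truth$label == "somatic" &
                            truth$variant_class == "SBS"]
  art <- truth$variant_id[truth$label == "artifact"]
  data.frame(patient = pid,
             germline_recall =
               mean(germ %in% gdec$variant_id[gdec$classification ==
                                                "germline"]),
             somatic_retention = mean(som %in% passed),
             artifact_removal = 1 - mean(art %in% passed))
}))
write.table(perf, "results/filter_performance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
passing <- do.call(rbind, lapply(names(flt), function(pid) {
  flt[[pid]]$somatic
}))
write.table(passing, "results/passing_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("per-stage attrition (pooled):")
print(aggregate(cbind(n_in, n_out) ~ stage, audit, sum))
message(sprintf("germline recall %.2f%%, somatic retention %.2f%%, artifact removal %.2f%%",
                100 * mean(perf$germline_recall),
                100 * mean(perf$somatic_retention),
                100 * mean(perf$artifact_removal)))
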