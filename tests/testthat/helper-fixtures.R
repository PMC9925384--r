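# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small two-patient cohort used across filter/phylogeny/signature tests.
small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(simulation_config(
      seed = 101, genome_length = 1e6, n_patients = 2,
      crypts_per_patient = 8, germline_het_count = 300,
      artifact_count = 100, mapping_artifact_count = 20,
      age_range = c(40, 60)))
  })
}

# One-patient SBS2-only cohort for context/spectrum tests.
apobec_cohort <- function() {
  cached("apobec_cohort", function() {
    generate_cohort(simulation_config(
      seed = 55, genome_length = 2e5, n_patients = 1,
      crypts_per_patient = 2, signature_mix = c(SBS2 = 1),
      sbs_rate_per_year = c(duodenum = 25, jejunum = 25, ileum = 25),
      id_rate_per_year = c(duodenum = 0, jejunum = 0, ileum = 0),
      apobec_episode_prob = 0, germline_het_count = 20,
      artifact_count = 5, mapping_artifact_count = 0,
      age_range = c(40, 40)))
  })
}

# Brute-force negative-binomial lower-tail sum in log space.
nb_brute <- function(r, k, p) {
  j <- 0:k
  sum(exp(lchoose(j + r - 1, j) + j * log1p(-p) + r * log(p)))
}

# Independent beta-binomial rho oracle: likelihood by numerical integration
# of Binomial(alt; depth, q) against Beta(q; a, b), maximized on the grid.
rho_oracle <- function(alt, depth, grid = rho_grid()) {
  mu <- sum(alt) / sum(depth)
  ll <- vapply(grid, function(rho) {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    sum(vapply(seq_along(alt), function(i) {
      f <- function(q) stats::dbinom(alt[i], depth[i], q) *
        stats::dbeta(q, a, b)
      log(stats::integrate(f, 0, 1, rel.tol = 1e-10)$value)
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(ll)]
}

# Truth-based filter-chain performance for one patient of a cohort.
chain_performance <- function(cohort, results) {
  t(vapply(names(cohort$patients), function(pid) {
    truth <- cohort$truth[cohort$truth$patient == pid, ]
    res <- results[[pid]]
    passed <- res$somatic$variant_id
    germ <- truth$variant_id[truth$label == "germline"]
    gdec <- res$decisions$germline
    som <- truth$variant_id[truth$label == "somatic" &
                              truth$variant_class == "SBS"]
    art <- truth$variant_id[truth$label == "artifact"]
    c(germline_recall =
        mean(germ %in% gdec$variant_id[gdec$classification == "germline"]),
      somatic_retention = mean(som %in% passed),
      artifact_removal = 1 - mean(art %in% passed))
  }, numeric(3)))
}

# Map an assignment back to truth: fraction of somatic SBS variants assigned
# to the branch whose crypt set equals their true branch's crypt set.
assignment_accuracy <- function(cohort, pid, tree, assignment) {
  p <- cohort$patients[[pid]]
  truth <- cohort$truth[cohort$truth$patient == pid, ]
  som <- assignment$assignment$variant_id
  br <- tree_branches(tree)
  branch_key <- apply(br$membership, 1, function(r) {
    paste(sort(colnames(br$membership)[r == 1]), collapse = ",")
  })
  truth_key <- vapply(truth$branch_id[match(som, truth$variant_id)],
                      function(b) paste(sort(p$tree$leafsets[[b]]),
                                        collapse = ","), character(1))
  assigned_key <- branch_key[match(assignment$assignment$branch,
                                   names(branch_key))]
  mean(assigned_key == truth_key, na.rm = TRUE)
}
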