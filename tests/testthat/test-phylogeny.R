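test_that("a shared pair plus private mutations yields the caterpillar", {
  g <- rbind(c(1, 1, 0), c(1, 1, 0),  # shared by A, B
             c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(g) <- c("A", "B", "C")
  tree <- build_tree(g)
  expect_identical(sort(tree$tip.label), c("A", "B", "C"))
  ab <- ape::getMRCA(tree, c("A", "B"))
  expect_false(ape::getMRCA(tree, c("A", "C")) == ab)
  # the AB clade branch carries its 2 supporting mutations
  br <- tree_branches(tree)
  ab_row <- which(apply(br$membership, 1, function(r) {
    all(r == (colnames(br$membership) %in% c("A", "B")))
  }))
  expect_length(ab_row, 1)
})

test_that("all-private genotypes give a star topology", {
  g <- diag(4)
  colnames(g) <- letters[1:4]
  tree <- build_tree(g)
  expect_identical(tree$Nnode, 1L)
  # no variants at all also yields the star tree
  g0 <- matrix(0L, 0, 4, dimnames = list(NULL, letters[1:4]))
  expect_identical(build_tree(g0)$Nnode, 1L)
})

test_that("noise-free synthetic genotypes recover the true topology", {
  coh <- small_cohort()
  for (pid in names(coh$patients)) {
    p <- coh$patients[[pid]]
    truth <- coh$truth[coh$truth$patient == pid, ]
    som <- truth$variant_id[truth$label == "somatic" &
                              truth$variant_class == "SBS"]
    g <- (p$vaf_true[som, ] > 0.25) * 1L
    tree <- build_tree(g)
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(tree),
                                               ape::unroot(p$tree$phylo))), 0)
    skip_if_not_installed("phangorn")
    expect_identical(as.numeric(phangorn::RF.dist(tree, p$tree$phylo)), 0)
  }
})

test_that("ML assignment matches a brute-force likelihood oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  alt <- rbind(v1 = c(12, 13, 0), v2 = c(12, 0, 0))
  depth <- rbind(v1 = c(25, 26, 25), v2 = c(25, 25, 25))
  colnames(alt) <- colnames(depth) <- c("A", "B", "C")
  res <- assign_mutations(tree, alt, depth)
  br <- tree_branches(tree)
  # oracle: enumerate every branch, compute the product likelihood directly
  pick <- vapply(rownames(alt), function(v) {
    ll <- vapply(seq_len(nrow(br$membership)), function(b) {
      carriers <- br$membership[b, ] == 1
      sum(dbinom(alt[v, ], depth[v, ],
                 ifelse(carriers, 0.5, 1e-3), log = TRUE))
    }, numeric(1))
    br$labels[which.max(ll)]
  }, character(1))
  expect_identical(res$assignment$branch, unname(pick))
  # v1 sits on the A,B clade branch; v2 on A's terminal branch
  ab_label <- br$labels[which(apply(br$membership, 1, function(r) {
    all(r == (colnames(br$membership) %in% c("A", "B")))
  }))]
  expect_identical(res$assignment$branch, c(ab_label, "A"))
})

test_that("assignment conserves counts and ignores variant order", {
  coh <- small_cohort()
  pid <- names(coh$patients)[2]
  p <- coh$patients[[pid]]
  truth <- coh$truth[coh$truth$patient == pid, ]
  som <- truth$variant_id[truth$label == "somatic" &
                            truth$variant_class == "SBS"]
  som <- som[seq_len(min(2000, length(som)))]
  tree <- p$tree$phylo
  res <- assign_mutations(tree, p$alt[som, ], p$depth[som, ])
  expect_equal(sum(res$branch_counts), length(som))
  perm <- sample(length(som))
  res2 <- assign_mutations(tree, p$alt[som[perm], ], p$depth[som[perm], ])
  m <- match(res$assignment$variant_id, res2$assignment$variant_id)
  expect_identical(res$assignment$branch, res2$assignment$branch[m])
})

test_that("mutations map to their true branches at depth 25", {
  coh <- small_cohort()
  accs <- vapply(names(coh$patients), function(pid) {
    p <- coh$patients[[pid]]
    truth <- coh$truth[coh$truth$patient == pid, ]
    som <- truth$variant_id[truth$label == "somatic" &
                              truth$variant_class == "SBS"]
    res <- assign_mutations(p$tree$phylo, p$alt[som, ], p$depth[som, ])
    assignment_accuracy(coh, pid, p$tree$phylo, res)
  }, numeric(1))
  expect_true(all(accs >= 0.99))
})

test_that("SBS1-clock timing is exact arithmetic with monotone node ages", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  bt <- time_branches(tree, c(root = 30, node5 = 15, A = 10, B = 12, C = 20),
                      sbs1_rate = 1.5)
  expect_equal(bt$age_upper[bt$branch == "root"], 20)
  expect_equal(bt$age_lower[bt$branch == "root"], 0)
  expect_equal(bt$age_upper[bt$branch == "node5"], 30)
  expect_equal(bt$age_upper[bt$branch == "A"], 30 + 10 / 1.5)
  expect_true(all(bt$age_lower <= bt$age_upper + 1e-12))
  expect_error(time_branches(tree, c(root = 30), 0), "positive")
})

test_that("fission times are recovered within the Poisson clock band", {
  cfg <- simulation_config(seed = 71, genome_length = 1e6, n_patients = 1,
                           crypts_per_patient = 2,
                           signature_mix = c(SBS1 = 1),
                           fission_age_range = c(25, 25),
                           apobec_episode_prob = 0, germline_het_count = 0,
                           artifact_count = 0, mapping_artifact_count = 0,
                           id_rate_per_year = c(duodenum = 0, jejunum = 0,
                                                ileum = 0),
                           age_range = c(50, 50))
  coh <- generate_cohort(cfg)
  p <- coh$patients[[1]]
  truth <- coh$truth[coh$truth$label == "somatic", ]
  tree <- p$tree$phylo
  res <- assign_mutations(tree, p$alt[truth$variant_id, ],
                          p$depth[truth$variant_id, ])
  rate <- 51
  bt <- time_branches(tree, res$branch_counts, sbs1_rate = rate)
  est <- bt$age_upper[bt$branch == "root"]
  band <- qpois(c(0.005, 0.995), rate * 25) / rate
  expect_gte(est, band[1])
  expect_lte(est, band[2])
})
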