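# Crypt phylogenies: genotype-based greedy perfect-phylogeny construction,
# maximum-likelihood mutation-to-branch assignment, and SBS1-clock branch
# timing.

#' Binary genotype matrix from read counts
#'
#' A crypt carries a variant when its VAF is at least `vaf_threshold` with at
#' least `min_alt` supporting reads; at depth ~25 this separates clonal
#' heterozygous (VAF ~0.5) from absent.
#'
#' @param alt,depth count matrices (variants x crypts).
#' @param vaf_threshold,min_alt genotype thresholds.
#' @return integer 0/1 matrix.
#' @export
genotype_matrix <- function(alt, depth, vaf_threshold = 0.25, min_alt = 3) {
  vaf <- alt / pmax(depth, 1)
  g <- (vaf >= vaf_threshold & alt >= min_alt) * 1L
  dimnames(g) <- dimnames(alt)
  g
}

#' Build a crypt phylogeny by greedy perfect-phylogeny construction
#'
#' Variants are grouped by their crypt-sharing pattern; patterns are accepted
#' in decreasing order of support (mutation count, ties broken
#' lexicographically) whenever they are compatible (nested or disjoint) with
#' every pattern already accepted. The accepted laminar family, plus the full
#' crypt set and all singletons, defines a rooted tree whose branch lengths
#' are the supporting mutation counts. With no shared variants the result is
#' a star tree. Deterministic given the input.
#'
#' @param genotypes 0/1 matrix (variants x crypts, colnames = crypt ids).
#' @return `ape::phylo` rooted tree; edge lengths are assigned mutation
#'   counts.
#' @export
build_tree <- function(genotypes) {
  crypts <- colnames(genotypes)
  stopifnot(!is.null(crypts), ncol(genotypes) >= 2)
  n <- length(crypts)
  if (nrow(genotypes) > 0) {
    keys <- apply(genotypes > 0, 1, function(r) paste(which(r),
                                                      collapse = ","))
    keys <- keys[keys != ""]
    support <- sort(table(keys), decreasing = TRUE)
    ord <- order(-as.numeric(support), names(support))
    patterns <- lapply(names(support)[ord],
                       function(k) as.integer(strsplit(k, ",")[[1]]))
    supp <- as.numeric(support)[ord]
  } else {
    patterns <- list(); supp <- numeric(0)
  }
  accepted <- list(); acc_supp <- numeric(0)
  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0 || i == length(a) || i == length(b)
  }
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    if (length(p) %in% c(1L, n)) {
      accepted <- c(accepted, list(p)); acc_supp <- c(acc_supp, supp[i])
      next
    }
    if (all(vapply(accepted, compatible, logical(1), b = p))) {
      accepted <- c(accepted, list(p)); acc_supp <- c(acc_supp, supp[i])
    }
  }
  # ensure the full set and every singleton are present
  fam <- accepted; fam_supp <- acc_supp
  have <- vapply(fam, function(p) paste(sort(p), collapse = ","),
                 character(1))
  for (p in c(list(seq_len(n)), as.list(seq_len(n)))) {
    key <- paste(sort(p), collapse = ",")
    if (!key %in% have) {
      fam <- c(fam, list(p)); fam_supp <- c(fam_supp, 0)
      have <- c(have, key)
    }
  }
  sizes <- lengths(fam)
  newick_of <- function(set, candidates) {
    members <- candidates[vapply(candidates, function(j) {
      length(fam[[j]]) < length(set) && all(fam[[j]] %in% set)
    }, logical(1))]
    # maximal proper subsets of `set` within the family
    maximal <- members[vapply(members, function(j) {
      !any(vapply(members, function(k) {
        k != j && length(fam[[j]]) < length(fam[[k]]) &&
          all(fam[[j]] %in% fam[[k]])
      }, logical(1)))
    }, logical(1))]
    subs <- vapply(maximal, function(j) {
      inner <- newick_of(fam[[j]], setdiff(members, j))
      sprintf("%s:%g", inner, fam_supp[j])
    }, character(1))
    if (length(set) == 1) return(crypts[set])
    paste0("(", paste(subs, collapse = ","), ")")
  }
  root_idx <- which(sizes == n)[1]
  txt <- paste0(newick_of(fam[[root_idx]],
                          setdiff(seq_along(fam), root_idx)), ";")
  ape::read.tree(text = txt)
}

#' Enumerate assignable branches of a rooted crypt tree
#'
#' Branches are the tree's edges plus a virtual truncal branch subtending all
#' crypts (mutations shared by every crypt). Branch labels are the child tip
#' label for terminal edges, `"node<N>"` for internal edges and `"root"` for
#' the truncal branch.
#'
#' @param tree `ape::phylo`.
#' @return list: `labels`, `membership` (branches x crypts 0/1 matrix),
#'   `edge_index` (row of `tree$edge`, NA for the truncal branch).
#' @export
tree_branches <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  desc <- .tips_under(tree)
  labels <- c("root", vapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= n) tips[child] else paste0("node", child)
  }, character(1)))
  membership <- rbind(rep(1L, n),
                      t(vapply(seq_len(nrow(tree$edge)), function(e) {
                        as.integer(tips %in% desc[[tree$edge[e, 2]]])
                      }, integer(n))))
  dimnames(membership) <- list(labels, tips)
  list(labels = labels, membership = membership,
       edge_index = c(NA_integer_, seq_len(nrow(tree$edge))))
}

# tip labels under every node (tips and internal), by postorder accumulation
.tips_under <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  desc <- vector("list", n + m)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; c <- edges[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

#' Assign mutations to tree branches by maximum likelihood
#'
#' For each variant the likelihood of every branch is the product over crypts
#' of Binomial(alt; depth, v), with v the clone VAF in crypts descending from
#' the branch and a small error rate elsewhere. Each variant goes to the
#' argmax branch; ties break toward the branch subtending the most crypts
#' (rootward). Variants with zero depth everywhere land in an explicit
#' unassigned bin.
#'
#' @param tree `ape::phylo` whose tips are the count-matrix columns.
#' @param alt,depth count matrices (variants x crypts).
#' @param clone_vaf expected VAF in carrier crypts: a scalar (default 0.5) or
#'   per-crypt vector (for example each crypt's median somatic VAF).
#' @param error_rate miscall floor in non-carrier crypts.
#' @return list: `assignment` (data.frame variant_id, branch),
#'   `branch_counts` (named vector over branches incl. "unassigned"),
#'   `branches` ([tree_branches()] result).
#' @export
assign_mutations <- function(tree, alt, depth, clone_vaf = 0.5,
                             error_rate = 1e-3) {
  br <- tree_branches(tree)
  tips <- tree$tip.label
  stopifnot(all(tips %in% colnames(alt)))
  alt <- alt[, tips, drop = FALSE]
  depth <- depth[, tips, drop = FALSE]
  vaf <- rep_len(clone_vaf, length(tips))
  V <- nrow(alt)
  ll1 <- stats::dbinom(alt, depth,
                       matrix(vaf, V, length(tips), byrow = TRUE),
                       log = TRUE)
  ll0 <- stats::dbinom(alt, depth, error_rate, log = TRUE)
  base <- rowSums(ll0)
  delta <- ll1 - ll0
  scores <- base + delta %*% t(br$membership)   # variants x branches
  # branches ordered by decreasing clade size so which.max ties go rootward
  ord <- order(-rowSums(br$membership))
  pick <- ord[apply(scores[, ord, drop = FALSE], 1, which.max)]
  branch <- br$labels[pick]
  branch[rowSums(depth) == 0] <- "unassigned"
  counts <- table(factor(branch, levels = c(br$labels, "unassigned")))
  list(assignment = data.frame(
         variant_id = rownames(alt) %||% seq_len(V),
         branch = branch, stringsAsFactors = FALSE),
       branch_counts = stats::setNames(as.numeric(counts), names(counts)),
       branches = br)
}

#' Time tree nodes with the SBS1 clock
#'
#' Node age = cumulative root-to-node SBS1 burden divided by the individual's
#' SBS1 rate; each branch's fission-event interval is [parent node age, child
#' node age]. The root node carries the truncal ("root" branch) burden, with
#' 0 as its lower bound.
#'
#' @param tree `ape::phylo`.
#' @param sbs1_burden named numeric vector of per-branch SBS1 burdens, named
#'   as in [tree_branches()] labels (missing branches count 0).
#' @param sbs1_rate SBS1 mutations/year for the individual (> 0).
#' @return data.frame: `branch`, `age_lower`, `age_upper` (years), where the
#'   branch's fission event happened inside the interval; plus node ages as
#'   attribute `node_ages`.
#' @export
time_branches <- function(tree, sbs1_burden, sbs1_rate) {
  if (sbs1_rate <= 0) stop("sbs1_rate must be positive")
  br <- tree_branches(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  node_age <- rep(NA_real_, n + tree$Nnode)
  root_burden <- if ("root" %in% names(sbs1_burden)) {
    sbs1_burden[["root"]]
  } else 0
  node_age[root] <- root_burden / sbs1_rate
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  labels_by_child <- function(child) {
    if (child <= n) tree$tip.label[child] else paste0("node", child)
  }
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    lab <- labels_by_child(ch)
    burden <- if (lab %in% names(sbs1_burden)) sbs1_burden[[lab]] else 0
    node_age[ch] <- node_age[p] + burden / sbs1_rate
  }
  out <- data.frame(
    branch = br$labels,
    age_lower = c(0, node_age[tree$edge[, 1]]),
    age_upper = c(node_age[root], node_age[tree$edge[, 2]]),
    stringsAsFactors = FALSE)
  attr(out, "node_ages") <- node_age
  out
}
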