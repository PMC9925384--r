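# Synthetic crypt cohorts: truth + observed read counts with the statistical
# structure the downstream analysis assumes. Crypts are clonal (somatic VAF
# 0.5 in carriers), patients carry random binary fission trees, mutations
# accrue per year from a signature mixture, APOBEC bursts hit a subset of
# branches and contain kataegis clusters, germline heterozygotes sit at VAF
# 0.5 in all crypts, and systematic artifacts recur across samples at low VAF
# with small overdispersion. Reads are observed through Poisson depth and
# binomial allele sampling.

#' Simulation configuration for a synthetic crypt cohort
#'
#' Defaults define the study conditions emulated throughout the package:
#' per-year substitution rates of 51/50/42 (duodenum/jejunum/ileum), mean
#' sequencing depth 25, a clock-dominated SBS1/SBS5/SBS18 signature mixture,
#' episodic APOBEC bursts on 16.3% of branches, and early-life crypt fission.
#'
#' @param seed integer seed driving all randomness.
#' @param genome_length synthetic genome length in bases (>= 1e4).
#' @param n_patients,crypts_per_patient cohort dimensions.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param sbs_rate_per_year named per-region SBS rates (mutations/year).
#' @param id_rate_per_year named per-region indel rates (mutations/year).
#' @param signature_mix named weights over catalog signatures, summing to 1.
#' @param apobec_episode_prob per-branch probability of an APOBEC burst.
#' @param apobec_burst_size mutations per burst.
#' @param kataegis_per_burst kataegis clusters per burst.
#' @param kataegis_cluster_size,kataegis_span mutations per cluster and
#'   maximum cluster span in bases (span <= 10 kb).
#' @param germline_het_count germline heterozygous variants per patient.
#' @param artifact_count shared low-VAF artifact sites (cohort-wide).
#' @param artifact_vaf,artifact_rho mean VAF and beta overdispersion of
#'   artifact sites across samples.
#' @param mapping_artifact_count artifact sites carrying failing read metrics.
#' @param fission_age_range years between which crypt-fission ages are drawn
#'   uniformly.
#' @param age_range patient ages are spread evenly across this range.
#' @param n_celiac number of patients flagged with celiac disease.
#' @param celiac_sbs1_per_year additional SBS1 mutations/year in celiac
#'   patients.
#' @param male_x_germline when TRUE, patients are male and a twentieth of
#'   germline variants sit on the X chromosome at expected VAF 0.95.
#' @param catalog signature catalog used to draw mutation channels.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(seed = 1,
                              genome_length = 5e6,
                              n_patients = 5,
                              crypts_per_patient = 8,
                              mean_depth = 25,
                              sbs_rate_per_year = c(duodenum = 51,
                                                    jejunum = 50,
                                                    ileum = 42),
                              id_rate_per_year = c(duodenum = 3.7,
                                                   jejunum = 2.6,
                                                   ileum = 2.3),
                              signature_mix = c(SBS1 = 0.30, SBS5 = 0.58,
                                                SBS18 = 0.12),
                              apobec_episode_prob = 0.163,
                              apobec_burst_size = 300,
                              kataegis_per_burst = 1,
                              kataegis_cluster_size = 6,
                              kataegis_span = 2000,
                              germline_het_count = 1000,
                              artifact_count = 200,
                              artifact_vaf = 0.03,
                              artifact_rho = 0.02,
                              mapping_artifact_count = 50,
                              fission_age_range = c(1, 10),
                              age_range = c(30, 70),
                              n_celiac = 0,
                              celiac_sbs1_per_year = 4.8,
                              male_x_germline = FALSE,
                              catalog = sbs_catalog()) {
  if (genome_length < 1e4) stop("genome_length must be >= 1e4")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (abs(sum(signature_mix) - 1) > 1e-9) {
    stop("signature_mix weights must sum to 1")
  }
  probs <- c(apobec_episode_prob, artifact_vaf, artifact_rho)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  missing_sigs <- setdiff(names(signature_mix), colnames(catalog))
  if (length(missing_sigs)) {
    stop("signature_mix names absent from catalog: ",
         paste(missing_sigs, collapse = ", "))
  }
  if (!all(c("SBS2", "SBS13") %in% colnames(catalog)) &&
      apobec_episode_prob > 0) {
    stop("catalog must contain SBS2 and SBS13 when APOBEC episodes are on")
  }
  if (kataegis_span > 1e4) stop("kataegis_span must be <= 10 kb")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# Random binary fission tree: one founder lineage at age 0, crypts - 1
# fission events at ages uniform in fission_age_range, each splitting a
# uniformly chosen extant lineage. Returns a branch table and an ape phylo.
.simulate_fission_tree <- function(n_crypts, age, fission_age_range,
                                   sample_ids) {
  lo <- max(0, min(fission_age_range))
  hi <- min(age, max(fission_age_range))
  branches <- data.frame(branch_id = 1L, parent = 0L, t_start = 0,
                         t_end = NA_real_)
  children <- list()
  active <- 1L
  if (n_crypts > 1) {
    times <- sort(stats::runif(n_crypts - 1, lo, hi))
    for (t in times) {
      split_id <- if (length(active) == 1) active else sample(active, 1)
      branches$t_end[split_id] <- t
      kids <- nrow(branches) + 1:2
      branches <- rbind(branches, data.frame(
        branch_id = kids, parent = split_id, t_start = t,
        t_end = NA_real_))
      children[[split_id]] <- kids
      active <- c(setdiff(active, split_id), kids)
    }
  }
  branches$t_end[is.na(branches$t_end)] <- age
  branches$duration <- branches$t_end - branches$t_start
  is_leaf <- !(branches$branch_id %in% branches$parent)
  branches$is_leaf <- is_leaf
  branches$sample_id <- NA_character_
  branches$sample_id[is_leaf] <- sample_ids
  # leaves (sample ids) under every branch
  leaves_under <- function(id) {
    if (branches$is_leaf[id]) return(branches$sample_id[id])
    unlist(lapply(children[[id]], leaves_under))
  }
  leafsets <- lapply(branches$branch_id, leaves_under)
  branches$n_desc <- lengths(leafsets)
  newick_of <- function(id) {
    len <- branches$duration[id]
    if (branches$is_leaf[id]) {
      sprintf("%s:%f", branches$sample_id[id], len)
    } else {
      sprintf("(%s,%s):%f", newick_of(children[[id]][1]),
              newick_of(children[[id]][2]), len)
    }
  }
  txt <- newick_of(1L)
  if (n_crypts == 1) txt <- paste0("(", txt, ")")  # single-tip newick
  phylo <- ape::read.tree(text = paste0(txt, ";"))
  list(branches = branches, leafsets = leafsets, children = children,
       phylo = phylo)
}

# Sample n unused positions whose pyrimidine context matches `context`.
# `used` is an environment holding a logical vector over the genome.
.sample_context_positions <- function(ctx_index, context, n, used) {
  if (n == 0) return(integer(0))
  pool <- ctx_index$pools[[context]]
  if (is.null(pool)) stop("context ", context, " absent from reference")
  free <- pool[!used$mask[pool]]
  if (length(free) < n) {
    stop("context pool exhausted for ", context,
         "; increase genome_length")
  }
  pos <- if (length(free) == 1) free else sample(free, n)
  used$mask[pos] <- TRUE
  pos
}

# ref/alt on the forward strand for a pyrimidine-strand channel at positions
.forward_alleles <- function(ctx_index, pos, pyr_alt) {
  ref <- ctx_index$bases[pos]
  alt <- ifelse(ref %in% PYRIMIDINES, pyr_alt, unname(COMPLEMENT[pyr_alt]))
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Generate a synthetic crypt cohort
#'
#' Simulates, per patient, a random fission tree, per-branch mutation counts
#' from Poisson(rate x branch years) with channels from the signature
#' mixture, context-matched genome positions, optional APOBEC bursts with
#' kataegis clusters, germline heterozygotes and shared low-VAF artifacts,
#' then observes every variant through Poisson(mean_depth) depths and
#' binomial allele counts. All output is deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param reference character scalar genome; generated from the config seed
#'   when NULL.
#' @return object of class `crypt_cohort`: list with `config`, `reference`,
#'   `metadata` (per-crypt table), `truth` (per-mutation truth records),
#'   `patients` (per patient: `variants`, `alt`/`depth` matrices, `metrics`,
#'   `tree`, `vaf_true`), and `catalog`.
#' @export
generate_cohort <- function(config, reference = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  if (is.null(reference)) {
    reference <- generate_reference(config$genome_length,
                                    seed = config$seed + 104729)
  }
  set.seed(config$seed)
  ctx_index <- context_index(reference)
  catalog <- config$catalog
  ch <- sbs_channels()
  regions <- names(config$sbs_rate_per_year)

  n_pat <- config$n_patients
  ages <- round(seq(config$age_range[1], config$age_range[2],
                    length.out = max(n_pat, 2)))[seq_len(n_pat)]
  patient_ids <- sprintf("PT%02d", seq_len(n_pat))
  patient_region <- regions[(seq_len(n_pat) - 1) %% length(regions) + 1]
  celiac <- seq_len(n_pat) <= config$n_celiac

  # cohort-wide artifact sites (never overlapping somatic/germline positions:
  # positions are reserved through the shared `used` mask)
  used <- new.env()
  used$mask <- logical(ctx_index$length)
  n_art <- config$artifact_count + config$mapping_artifact_count
  art_pos <- integer(0)
  if (n_art > 0) {
    art_pos <- sample(2:(ctx_index$length - 1), n_art)
    used$mask[art_pos] <- TRUE
  }
  art_ref <- ctx_index$bases[art_pos]
  art_alt <- vapply(art_ref, function(r) sample(setdiff(BASES, r), 1),
                    character(1))
  art_type <- rep(c("systematic", "mapping"),
                  c(config$artifact_count, config$mapping_artifact_count))

  truth_all <- list()
  patients <- list()
  metadata <- list()
  kat_counter <- 0L

  for (pi in seq_len(n_pat)) {
    pid <- patient_ids[pi]
    age <- ages[pi]
    region <- patient_region[pi]
    sample_ids <- sprintf("%s_c%02d", pid, seq_len(config$crypts_per_patient))
    tree <- .simulate_fission_tree(config$crypts_per_patient, age,
                                   config$fission_age_range, sample_ids)
    br <- tree$branches

    # somatic mutation counts per branch: background mixture + celiac SBS1
    rate <- config$sbs_rate_per_year[[region]]
    sig_names <- names(config$signature_mix)
    rec <- list()
    for (bi in seq_len(nrow(br))) {
      n_mut <- stats::rpois(1, rate * br$duration[bi])
      sigs <- if (n_mut > 0) {
        sample(sig_names, n_mut, replace = TRUE,
               prob = config$signature_mix)
      } else character(0)
      if (celiac[pi] && config$celiac_sbs1_per_year > 0) {
        n_extra <- stats::rpois(1, config$celiac_sbs1_per_year *
                                  br$duration[bi])
        sigs <- c(sigs, rep("SBS1", n_extra))
      }
      burst <- stats::runif(1) < config$apobec_episode_prob
      kat_ids <- rep(NA_integer_, length(sigs))
      if (burst && config$apobec_burst_size > 0) {
        n_kat_total <- config$kataegis_per_burst *
          config$kataegis_cluster_size
        n_diffuse <- max(config$apobec_burst_size - n_kat_total, 0)
        bsigs <- sample(c("SBS2", "SBS13"), n_diffuse, replace = TRUE)
        sigs <- c(sigs, bsigs)
        kat_ids <- c(kat_ids, rep(NA_integer_, n_diffuse))
      }
      rec[[bi]] <- data.frame(branch_id = rep(br$branch_id[bi],
                                              length(sigs)),
                              signature = sigs,
                              kataegis_id = kat_ids,
                              stringsAsFactors = FALSE)
      attr(rec[[bi]], "burst") <- burst
    }

    muts <- do.call(rbind, rec)
    # channels from the generating signature, positions by context matching
    if (nrow(muts) > 0) {
      muts$channel <- NA_character_
      for (s in unique(muts$signature)) {
        sel <- muts$signature == s
        muts$channel[sel] <- sample(ch$channel, sum(sel), replace = TRUE,
                                    prob = catalog[, s])
      }
      muts$pos <- NA_integer_
      for (ctx in unique(ch$context[match(muts$channel, ch$channel)])) {
        sel <- ch$context[match(muts$channel, ch$channel)] == ctx
        muts$pos[sel] <- .sample_context_positions(ctx_index, ctx,
                                                   sum(sel), used)
      }
      al <- .forward_alleles(ctx_index, muts$pos,
                             ch$alt[match(muts$channel, ch$channel)])
      muts$ref <- al$ref
      muts$alt <- al$alt
    } else {
      muts$channel <- character(0); muts$pos <- integer(0)
      muts$ref <- character(0); muts$alt <- character(0)
    }

    # kataegis clusters on burst branches: TCN positions inside a short window
    for (bi in seq_len(nrow(br))) {
      if (!isTRUE(attr(rec[[bi]], "burst"))) next
      for (k in seq_len(config$kataegis_per_burst)) {
        kat_counter <- kat_counter + 1L
        kat <- .place_kataegis(ctx_index, used, config$kataegis_cluster_size,
                               config$kataegis_span)
        if (nrow(kat) == 0) next
        kat$branch_id <- br$branch_id[bi]
        kat$kataegis_id <- kat_counter
        muts <- rbind(muts, kat[, c("branch_id", "signature", "kataegis_id",
                                    "channel", "pos", "ref", "alt")])
      }
    }

    if (nrow(muts) > 0) {
      muts$label <- "somatic"
      muts$variant_class <- "SBS"
    }

    # indels on leaf branches (desk-scale: simple 1-bp insertions)
    id_rate <- config$id_rate_per_year[[region]]
    id_n <- stats::rpois(1, id_rate * sum(br$duration))
    if (id_n > 0) {
      id_branch <- sample(br$branch_id, id_n, replace = TRUE,
                          prob = br$duration)
      id_pos <- sample(which(!used$mask[2:(ctx_index$length - 1)]) + 1L, id_n)
      used$mask[id_pos] <- TRUE
      ids <- data.frame(branch_id = id_branch, signature = "ID",
                        kataegis_id = NA_integer_, channel = NA_character_,
                        pos = id_pos, ref = ctx_index$bases[id_pos],
                        alt = paste0(ctx_index$bases[id_pos], "A"),
                        label = "somatic", variant_class = "ID",
                        stringsAsFactors = FALSE)
      muts <- rbind(muts, ids)
    }

    # germline heterozygotes: VAF 0.5 in every crypt (0.95 on male X)
    g_n <- config$germline_het_count
    g_pos <- integer(0)
    if (g_n > 0) {
      g_pos <- sample(which(!used$mask[2:(ctx_index$length - 1)]) + 1L, g_n)
      used$mask[g_pos] <- TRUE
    }
    g_ref <- ctx_index$bases[g_pos]
    g_alt <- vapply(g_ref, function(r) sample(setdiff(BASES, r), 1),
                    character(1))
    g_chrom <- rep("chr1", g_n)
    if (config$male_x_germline && g_n >= 20) {
      g_chrom[seq_len(ceiling(g_n / 20))] <- "chrX"
    }
    germ <- data.frame(branch_id = rep(NA_integer_, g_n),
                       signature = rep(NA_character_, g_n),
                       kataegis_id = rep(NA_integer_, g_n),
                       channel = rep(NA_character_, g_n),
                       pos = g_pos, ref = g_ref, alt = g_alt,
                       label = rep("germline", g_n),
                       variant_class = rep("SBS", g_n),
                       stringsAsFactors = FALSE)
    germ$chrom <- g_chrom

    arts <- data.frame(branch_id = rep(NA_integer_, n_art),
                       signature = rep(NA_character_, n_art),
                       kataegis_id = rep(NA_integer_, n_art),
                       channel = rep(NA_character_, n_art),
                       pos = art_pos, ref = art_ref, alt = art_alt,
                       label = rep("artifact", n_art),
                       variant_class = rep("SBS", n_art),
                       stringsAsFactors = FALSE)
    arts$artifact_type <- art_type
    if (nrow(muts) > 0) {
      muts$chrom <- "chr1"
      muts$artifact_type <- NA_character_
    }
    germ$artifact_type <- rep(NA_character_, nrow(germ))
    arts$chrom <- rep("chr1", nrow(arts))

    cols <- c("chrom", "pos", "ref", "alt", "variant_class", "label",
              "branch_id", "signature", "channel", "kataegis_id",
              "artifact_type")
    tbl <- rbind(
      if (nrow(muts) > 0) muts[, cols] else NULL,
      germ[, cols], arts[, cols])
    tbl$patient <- rep(pid, nrow(tbl))
    tbl$variant_id <- sprintf("%s_v%06d", pid, seq_len(nrow(tbl)))

    # true VAF matrix: somatic 0.5 in carrier crypts, germline 0.5 (0.95 on
    # male X), artifacts beta-distributed around artifact_vaf per sample
    S <- length(sample_ids)
    V <- nrow(tbl)
    vaf <- matrix(0, V, S, dimnames = list(tbl$variant_id, sample_ids))
    somatic_rows <- which(tbl$label == "somatic")
    for (b in unique(tbl$branch_id[somatic_rows])) {
      rows <- somatic_rows[tbl$branch_id[somatic_rows] == b]
      vaf[rows, tree$leafsets[[b]]] <- 0.5
    }
    germ_rows <- which(tbl$label == "germline")
    vaf[germ_rows, ] <- 0.5
    if (config$male_x_germline) {
      vaf[germ_rows[tbl$chrom[germ_rows] == "chrX"], ] <- 0.95
    }
    art_rows <- which(tbl$label == "artifact")
    if (length(art_rows) > 0) {
      mu <- config$artifact_vaf; rho <- config$artifact_rho
      a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
      vaf[art_rows, ] <- stats::rbeta(length(art_rows) * S, a, b)
    }

    depth <- matrix(stats::rpois(V * S, config$mean_depth), V, S,
                    dimnames = dimnames(vaf))
    alt <- matrix(stats::rbinom(V * S, depth, vaf), V, S,
                  dimnames = dimnames(vaf))

    # read metrics: real variants map cleanly; mapping artifacts fail the
    # alignment-score/clipping predicate
    as_score <- pmin(pmax(round(stats::rnorm(V, 200, 15)), 0), 250)
    clipped <- stats::runif(V, 0, 0.3)
    map_rows <- which(tbl$label == "artifact" &
                        tbl$artifact_type == "mapping")
    as_score[map_rows] <- round(stats::runif(length(map_rows), 60, 135))
    clipped[map_rows] <- stats::runif(length(map_rows), 0.5, 0.9)
    metrics <- data.frame(variant_id = tbl$variant_id,
                          median_alignment_score = as_score,
                          clipped_fraction = clipped,
                          pindel_quality = rep(NA_real_, V),
                          min_supporting_depth = rep(NA_real_, V),
                          stringsAsFactors = FALSE)
    id_rows <- which(tbl$variant_class == "ID")
    metrics$pindel_quality[id_rows] <-
      round(stats::rnorm(length(id_rows), 500, 80))
    metrics$min_supporting_depth[id_rows] <-
      apply(depth[id_rows, , drop = FALSE], 1, max)

    truth_all[[pid]] <- tbl
    patients[[pid]] <- list(
      variants = tbl[, c("variant_id", "chrom", "pos", "ref", "alt",
                         "variant_class", "patient")],
      alt = alt, depth = depth, vaf_true = vaf,
      metrics = metrics, tree = tree)
    metadata[[pid]] <- data.frame(
      sample_id = sample_ids, patient = pid, age_years = age,
      region = region, celiac = as.integer(celiac[pi]),
      sex = if (config$male_x_germline) "M" else "F",
      chemotherapy = 0L,
      mean_coverage = colMeans(depth),
      stringsAsFactors = FALSE)
  }

  out <- list(config = config, reference = reference,
              metadata = do.call(rbind, c(metadata,
                                          make.row.names = FALSE)),
              truth = do.call(rbind, c(truth_all, make.row.names = FALSE)),
              patients = patients, catalog = catalog)
  class(out) <- "crypt_cohort"
  out
}

# Place one kataegis cluster: TCN-context positions within a window of at
# most `span` bases, mutated with SBS2 (C>T) / SBS13 (C>G, C>A) alternates.
.place_kataegis <- function(ctx_index, used, size, span) {
  tcn <- paste0("TC", BASES)
  pools <- unlist(ctx_index$pools[tcn], use.names = FALSE)
  pools <- sort(pools[!used$mask[pools]])
  for (try in 1:50) {
    anchor <- sample(pools, 1)
    win <- pools[pools >= anchor & pools <= anchor + span]
    if (length(win) >= size) {
      pos <- sort(sample(win, size))
      used$mask[pos] <- TRUE
      sig <- sample(c("SBS2", "SBS13"), size, replace = TRUE)
      pyr_alt <- ifelse(sig == "SBS2", "T",
                        sample(c("G", "A"), size, replace = TRUE,
                               prob = c(0.8, 0.2)))
      al <- .forward_alleles(ctx_index, pos, pyr_alt)
      b <- ctx_index$bases
      ctx <- paste0(b[pos - 1], b[pos], b[pos + 1])
      oriented <- pyrimidine_orient(ctx, al$ref, al$alt)
      return(data.frame(signature = sig, channel = oriented$channel,
                        pos = pos, ref = al$ref, alt = al$alt,
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(signature = character(0), channel = character(0),
             pos = integer(0), ref = character(0), alt = character(0))
}

#' Write a cohort to plain-text fixture files
#'
#' Emits the reference FASTA, long-format count table, metadata, read
#' metrics, truth records and a VCF v4.2 sites file. The count/metadata
#' tables round-trip bit-identically through [read_fixture()].
#'
#' @param cohort a `crypt_cohort`.
#' @param out_dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "crypt_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  paths <- c(reference = file.path(out_dir, "reference.fa"),
             counts = file.path(out_dir, "counts.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             metrics = file.path(out_dir, "metrics.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             vcf = file.path(out_dir, "sites.vcf"))
  write_reference_fasta(cohort$reference, paths["reference"])
  counts <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(variant_id = rep(rownames(p$alt), ncol(p$alt)),
               sample_id = rep(colnames(p$alt), each = nrow(p$alt)),
               alt = as.integer(p$alt), depth = as.integer(p$depth),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(counts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  metrics <- do.call(rbind, lapply(cohort$patients, `[[`, "metrics"))
  utils::write.table(metrics, paths["metrics"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  variants <- do.call(rbind, lapply(cohort$patients, `[[`, "variants"))
  .write_sites_vcf(variants, paths["vcf"])
  invisible(paths)
}

# Minimal VCF v4.2 sites writer (CHROM POS ID REF ALT QUAL FILTER INFO).
.write_sites_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=cryptomes synthetic cohort",
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                   "QUAL", "FILTER", "INFO"),
                                 collapse = "\t"))), con)
  if (nrow(variants) > 0) {
    v <- variants[order(variants$chrom, variants$pos), ]
    writeLines(paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".",
                     "PASS", ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Read fixture files back into per-patient count matrices
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `reference`, `counts` (long data.frame), `metadata`,
#'   `metrics`, `truth`, and `patients` (per patient `alt`/`depth` matrices).
#' @export
read_fixture <- function(dir) {
  counts <- utils::read.delim(file.path(dir, "counts.tsv"),
                              stringsAsFactors = FALSE)
  metadata <- utils::read.delim(file.path(dir, "metadata.tsv"),
                                stringsAsFactors = FALSE)
  metrics <- utils::read.delim(file.path(dir, "metrics.tsv"),
                               stringsAsFactors = FALSE)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  patients <- lapply(split(metadata$sample_id, metadata$patient),
                     function(samples) {
    sub <- counts[counts$sample_id %in% samples, ]
    vids <- unique(sub$variant_id)
    alt <- matrix(NA_integer_, length(vids), length(samples),
                  dimnames = list(vids, samples))
    depth <- alt
    alt[cbind(match(sub$variant_id, vids),
              match(sub$sample_id, samples))] <- sub$alt
    depth[cbind(match(sub$variant_id, vids),
                match(sub$sample_id, samples))] <- sub$depth
    list(alt = alt, depth = depth)
  })
  list(reference = read_reference_fasta(file.path(dir, "reference.fa")),
       counts = counts, metadata = metadata, metrics = metrics,
       truth = truth, patients = patients)
}
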