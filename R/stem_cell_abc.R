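# Crypt stem-cell dynamics: Moran-model simulation of a crypt's VAF
# distribution and rejection-ABC inference of the time to the crypt's most
# recent common ancestor.

#' Simulate one crypt under Moran stem-cell dynamics
#'
#' A niche of `n_stem` stem cells evolves by Moran replacement: at
#' exponential waiting times with total rate `n_stem x replacement_rate`, a
#' uniformly chosen stem cell's lineage replaces another's. Backwards in time
#' this is a coalescent in which, with j extant lineages, some pair merges at
#' rate `replacement_rate x j(j-1)/(n_stem - 1)`; lineage history is capped
#' at crypt founding (`sampling_age` years before sampling). Mutations accrue
#' on every lineage segment as Poisson(`mutation_rate` x years), each carried
#' by the stem lineages descending from the segment; with each surviving
#' lineage contributing equally to a fully differentiated crypt, a mutation's
#' cell fraction is its carrier-lineage share and its VAF is half that.
#' Observed VAFs are drawn through Poisson(`mean_depth`) depths and binomial
#' allele counts.
#'
#' @param n_stem stem cells in the niche (>= 1).
#' @param replacement_rate replacements per stem cell per year (>= 0).
#' @param mutation_rate mutations per lineage per year (genome-wide).
#' @param sampling_age crypt age in years at sampling.
#' @param mean_depth mean sequencing depth.
#' @param crypt_size differentiated cells in the crypt (retained for
#'   documentation of the model's scale; VAFs depend on lineage shares).
#' @param seed optional integer seed.
#' @return list: `vaf_true`, `vaf_obs` (alt/depth where depth > 0), `alt`,
#'   `depth`, `tmrca` (years before sampling of the extant lineages' common
#'   ancestor; `sampling_age` when lineages never fully coalesce).
#' @export
simulate_crypt <- function(n_stem, replacement_rate, mutation_rate,
                           sampling_age, mean_depth = 25, crypt_size = 1000,
                           seed = NULL) {
  stopifnot(n_stem >= 1, replacement_rate >= 0, mutation_rate >= 0,
            sampling_age > 0, crypt_size >= n_stem)
  if (!is.null(seed)) {
    restore <- .Random.seed_guard(seed)
    on.exit(restore(), add = TRUE)
  }
  if (n_stem == 1) {
    tmrca <- if (replacement_rate > 0) {
      min(stats::rexp(1, replacement_rate), sampling_age)
    } else sampling_age
    n_mut <- stats::rpois(1, mutation_rate * sampling_age)
    vaf <- rep(0.5, n_mut)
  } else {
    # backward-time coalescent of the n_stem extant lineages
    segs_dur <- numeric(0); segs_frac <- numeric(0)
    t <- 0
    desc <- rep(1L, n_stem)       # tips under each active lineage
    birth <- rep(0, n_stem)       # backward time each lineage appeared
    while (length(desc) > 1) {
      j <- length(desc)
      rate <- replacement_rate * j * (j - 1) / (n_stem - 1)
      if (rate <= 0) break
      t_next <- t + stats::rexp(1, rate)
      if (t_next > sampling_age) break
      t <- t_next
      pair <- sample.int(j, 2)
      segs_dur <- c(segs_dur, t - birth[pair])
      segs_frac <- c(segs_frac, desc[pair] / n_stem)
      desc <- c(desc[-pair], sum(desc[pair]))
      birth <- c(birth[-pair], t)
    }
    tmrca <- if (length(desc) == 1) t else sampling_age
    # remaining lineages persist back to crypt founding
    segs_dur <- c(segs_dur, sampling_age - birth)
    segs_frac <- c(segs_frac, desc / n_stem)
    n_seg_mut <- stats::rpois(length(segs_dur), mutation_rate * segs_dur)
    vaf <- rep(0.5 * segs_frac, n_seg_mut)
  }
  depth <- stats::rpois(length(vaf), mean_depth)
  alt <- stats::rbinom(length(vaf), depth, vaf)
  ok <- depth > 0
  list(vaf_true = vaf, vaf_obs = alt[ok] / depth[ok],
       alt = alt, depth = depth, tmrca = tmrca)
}

#' Distance between two VAF distributions
#'
#' Both samples are binned into 20 equal-width bins over (0.05, 0.55], each
#' histogram normalized to unit mass, and compared by Euclidean distance
#' (default) or 1-D Wasserstein distance on the binned masses. Zero iff the
#' normalized histograms coincide; symmetric.
#'
#' @param observed,simulated numeric VAF vectors.
#' @param bins bin edges (default `seq(0.05, 0.55, length.out = 21)`).
#' @param method "euclidean" or "wasserstein".
#' @return non-negative scalar.
#' @export
vaf_distance <- function(observed, simulated,
                         bins = seq(0.05, 0.55, length.out = 21),
                         method = c("euclidean", "wasserstein")) {
  method <- match.arg(method)
  h <- function(x) {
    x <- x[x > bins[1] & x <= bins[length(bins)]]
    if (length(x) == 0) return(rep(0, length(bins) - 1))
    counts <- tabulate(findInterval(x, bins, left.open = TRUE,
                                    all.inside = FALSE),
                       nbins = length(bins) - 1)
    counts / sum(counts)
  }
  a <- h(observed); b <- h(simulated)
  if (method == "euclidean") {
    sqrt(sum((a - b)^2))
  } else {
    sum(abs(cumsum(a) - cumsum(b))) * diff(bins)[1]
  }
}

#' Rejection-ABC inference of the time to a crypt's MRCA
#'
#' Draws stem-cell number and replacement rate from uniform priors, simulates
#' a crypt per draw with [simulate_crypt()], ranks draws by the VAF-histogram
#' distance to the observed crypt, accepts the best `accept` fraction and
#' summarises the accepted draws' true tMRCA values as the posterior.
#'
#' @param observed_vafs observed somatic VAFs of the crypt (>= 20 values).
#' @param mutation_rate fixed mutation rate (mutations/lineage/year),
#'   typically the patient's sensitivity-adjusted burden rate.
#' @param sampling_age patient age (years).
#' @param mean_depth sequencing depth of the crypt.
#' @param n_sims prior draws (default 50,000; reducible for testing).
#' @param accept accepted fraction (default 0.01, "best 1%").
#' @param priors list: `n_stem` (integer support) and `replacement_rate`
#'   (range).
#' @param distance_method passed to [vaf_distance()].
#' @param seed integer seed.
#' @return list of class `abc_posterior`: `tmrca` (accepted draws),
#'   `estimate` (posterior median), `ci` (central 95% interval), `accepted`
#'   (data.frame of accepted parameters and distances), `n_sims`, `n_accept`.
#' @export
abc_infer <- function(observed_vafs, mutation_rate, sampling_age,
                      mean_depth = 25, n_sims = 5e4, accept = 0.01,
                      priors = list(n_stem = 1:20,
                                    replacement_rate = c(0.1, 10)),
                      distance_method = "euclidean", seed = 1) {
  if (length(observed_vafs) < 20) {
    stop("need >= 20 observed somatic VAFs; the crypt's burden is below ",
         "the floor for VAF-distribution inference")
  }
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  n_stem_draw <- sample(priors$n_stem, n_sims, replace = TRUE)
  repl_draw <- stats::runif(n_sims, priors$replacement_rate[1],
                            priors$replacement_rate[2])
  dist <- numeric(n_sims)
  tmrca <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    sim <- simulate_crypt(n_stem_draw[i], repl_draw[i], mutation_rate,
                          sampling_age, mean_depth)
    dist[i] <- vaf_distance(observed_vafs, sim$vaf_obs,
                            method = distance_method)
    tmrca[i] <- sim$tmrca
  }
  n_accept <- as.integer(ceiling(accept * n_sims))
  sel <- order(dist)[seq_len(n_accept)]
  post <- tmrca[sel]
  out <- list(tmrca = post,
              estimate = stats::median(post),
              ci = stats::quantile(post, c(0.025, 0.975), names = FALSE),
              accepted = data.frame(n_stem = n_stem_draw[sel],
                                    replacement_rate = repl_draw[sel],
                                    tmrca = post, distance = dist[sel]),
              n_sims = n_sims, n_accept = n_accept)
  class(out) <- "abc_posterior"
  out
}
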