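# Kataegis detection: 10-bp event merging, 10-kb cluster candidates, the
# negative-binomial tail test on unmutated bases spanned, Bonferroni
# classification and rainfall-plot data.

#' Merge nearby mutations into mutagenic events
#'
#' Consecutive mutations no more than `gap` bases apart collapse into a
#' single event anchored at the first position; a polymerase processing a
#' short tract produces one event, not several.
#'
#' @param pos sorted integer positions on one chromosome.
#' @param gap merge distance in bases (default 10).
#' @return data.frame: `event_pos` (anchor), `n_mutations`, `first`, `last`.
#' @export
merge_events <- function(pos, gap = 10) {
  if (length(pos) == 0) {
    return(data.frame(event_pos = integer(0), n_mutations = integer(0),
                      first = integer(0), last = integer(0)))
  }
  stopifnot(!is.unsorted(pos))
  grp <- cumsum(c(1L, as.integer(diff(pos) > gap)))
  first <- as.numeric(tapply(pos, grp, min))
  last <- as.numeric(tapply(pos, grp, max))
  # positions may exceed .Machine$integer.max on genome scales; keep numeric
  data.frame(event_pos = first,
             n_mutations = as.integer(tapply(pos, grp, length)),
             first = first, last = last,
             row.names = NULL)
}

#' Candidate mutation clusters
#'
#' Maximal runs of at least two events in which every adjacent pair is closer
#' than `max_gap` bases; candidates are then restricted to spans of
#' `span_range` bases (narrower groups are merged events by construction,
#' wider runs are diffuse).
#'
#' @param events data.frame from [merge_events()] (one chromosome, sorted).
#' @param max_gap adjacency threshold (default 10,000; the rule is strictly
#'   "less than").
#' @param span_range allowed first-to-last span in bases.
#' @return data.frame: `start`, `end`, `n_events`, `n_mutations`, `r`, `k`,
#'   plus `members` (list of event anchors).
#' @export
find_clusters <- function(events, max_gap = 1e4, span_range = c(10, 1e4)) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_events = integer(0), n_mutations = integer(0),
                      r = integer(0), k = integer(0))
  empty$members <- list()
  if (nrow(events) < 2) return(empty)
  grp <- cumsum(c(1L, as.integer(diff(events$event_pos) >= max_gap)))
  out <- lapply(split(seq_len(nrow(events)), grp), function(idx) {
    if (length(idx) < 2) return(NULL)
    e <- events[idx, ]
    span <- max(e$last) - min(e$first) + 1
    if (span < span_range[1] || span > span_range[2]) return(NULL)
    d <- data.frame(start = min(e$first), end = max(e$last),
                    n_events = nrow(e),
                    n_mutations = sum(e$n_mutations),
                    r = sum(e$n_mutations) - 1,
                    k = span - nrow(e))
    d$members <- list(e$event_pos)
    d
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Negative-binomial cluster p-value
#'
#' Probability of spanning at most `k` unmutated bases before the r-th
#' mutation when each base mutates independently with probability `p`:
#' the lower tail `P(failures <= k) = sum_{j=0}^{k} C(j+r-1, j) (1-p)^j p^r`,
#' evaluated stably through the regularized incomplete beta function.
#'
#' @param r mutations minus one in the cluster (successes, >= 1).
#' @param k unmutated bases spanned (failures, >= 0).
#' @param p per-base mutation probability of the individual, in (0, 1).
#' @return p-value in [0, 1].
#' @export
nb_pvalue <- function(r, k, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  stopifnot(all(r >= 1), all(k >= 0))
  stats::pbeta(p, r, k + 1)
}

#' Classify candidate clusters as kataegis foci
#'
#' Computes the negative-binomial p-value of every candidate, Bonferroni
#' adjusts over the candidates tested in the sample, and keeps clusters with
#' adjusted P below `alpha`. Clusters sharing identical member positions
#' across crypts of one patient (mutations on a shared ancestral branch) are
#' counted once.
#'
#' @param candidates output of [find_clusters()], optionally with `sample_id`
#'   and `patient` columns (required for deduplication across crypts).
#' @param p per-base mutation rate of the individual: total passing
#'   substitutions across the patient's crypts / callable genome length.
#' @param alpha adjusted-p threshold (default 1e-4).
#' @return the candidates with `p_raw`, `n_tests`, `p_adj`, `kataegis`
#'   columns; deduplicated rows removed (kept once per patient).
#' @export
classify_clusters <- function(candidates, p, alpha = 1e-4) {
  if (nrow(candidates) == 0) {
    candidates$p_raw <- numeric(0)
    candidates$n_tests <- integer(0)
    candidates$p_adj <- numeric(0)
    candidates$kataegis <- logical(0)
    return(candidates)
  }
  cl <- candidates
  if (!"sample_id" %in% names(cl)) cl$sample_id <- "sample"
  if (!"patient" %in% names(cl)) cl$patient <- "patient"
  cl$p_raw <- nb_pvalue(cl$r, cl$k, p)
  tests <- table(cl$sample_id)
  cl$n_tests <- as.integer(tests[cl$sample_id])
  cl$p_adj <- pmin(1, cl$p_raw * cl$n_tests)
  cl$kataegis <- cl$p_adj < alpha
  # stable order, then deduplicate identical member sets within a patient
  cl <- cl[order(cl$patient, cl$sample_id, cl$start, cl$end), ]
  key <- paste(cl$patient,
               vapply(cl$members, paste, character(1), collapse = ","))
  cl[!duplicated(key), , drop = FALSE]
}

#' Rainfall data: inter-mutation distances
#'
#' Distance from each mutation to the previous one on the same chromosome;
#' the first mutation of each chromosome has no distance and is omitted.
#'
#' @param mutations data.frame with `chrom`, `pos` and optionally a
#'   substitution `class` label.
#' @return data.frame: `chrom`, `pos`, `distance`, `class`.
#' @export
rainfall <- function(mutations) {
  if (!"class" %in% names(mutations)) mutations$class <- NA_character_
  mutations <- mutations[order(mutations$chrom, mutations$pos), ]
  out <- lapply(split(mutations, mutations$chrom), function(m) {
    if (nrow(m) < 2) return(NULL)
    data.frame(chrom = m$chrom[-1], pos = m$pos[-1],
               distance = diff(m$pos), class = m$class[-1],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      distance = integer(0), class = character(0)))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' End-to-end kataegis detection for one sample
#'
#' @param pos sorted mutation positions (one chromosome).
#' @param p per-base mutation rate (see [classify_clusters()]).
#' @param sample_id,patient identifiers carried into the output.
#' @inheritParams classify_clusters
#' @return classified cluster table.
#' @export
detect_kataegis <- function(pos, p, sample_id = "sample",
                            patient = "patient", alpha = 1e-4) {
  events <- merge_events(sort(pos))
  cand <- find_clusters(events)
  if (nrow(cand) > 0) {
    cand$sample_id <- sample_id
    cand$patient <- patient
  }
  classify_clusters(cand, p, alpha = alpha)
}
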