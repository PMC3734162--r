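#' Aggregate spectral events into a protein-by-sample matrix
#'
#' Spectral counting: the (protein, sample) value is the number of retained
#' events; alternatively the sum of an intensity column.
#'
#' @param events data.frame with columns `protein_id`, `sample_id` and
#'   optionally an intensity column.
#' @param proteins,samples row/column universe of the output matrix (defaults
#'   to those present in `events`); proteins that lost all events simply drop
#'   out unless listed here.
#' @param aggregate `"count"` (default) or `"sum"`.
#' @param intensity_col column summed when `aggregate = "sum"`.
#' @return numeric matrix (proteins x samples).
#' @export
aggregate_events <- function(events, proteins = NULL, samples = NULL,
                             aggregate = c("count", "sum"),
                             intensity_col = "intensity") {
  aggregate <- match.arg(aggregate)
  if (is.null(proteins)) proteins <- sort(unique(events$protein_id))
  if (is.null(samples)) samples <- sort(unique(events$sample_id))
  m <- matrix(0, length(proteins), length(samples),
              dimnames = list(proteins, samples))
  i <- match(events$protein_id, proteins)
  j <- match(events$sample_id, samples)
  ok <- !is.na(i) & !is.na(j)
  w <- if (aggregate == "count") rep(1, sum(ok)) else events[[intensity_col]][ok]
  for (k in which(ok)) m[i[k], j[k]] <- m[i[k], j[k]] +
    (if (aggregate == "count") 1 else events[[intensity_col]][k])
  m
}

#' Sweep spectral-event quality thresholds
#'
#' For each proportion `q`, computes the `q`-quantiles of the two event
#' quality scores (e.g. XCorr and DeltaCn) over all events, retains only the
#' events strictly exceeding both quantiles, re-aggregates them into
#' protein-by-sample counts, re-merges with the secondary platform,
#' re-scores (correlations and bootstrap variances), and converts scores to
#' posteriors with the *frozen* mixture fit from the unfiltered data — no
#' refit. Proportion 0 keeps every event (the unfiltered baseline). Proteins
#' losing all their events exit the data, shrinking the surviving pair count.
#'
#' @param events data.frame with columns `protein_id`, `sample_id`,
#'   `score_1`, `score_2`.
#' @param proportions vector of threshold proportions in `[0, 1)`; the
#'   canonical grid is `c(0, 2^-(8:1))`.
#' @param secondary expression matrix of the second platform.
#' @param pairs pooled pair set linking protein IDs (primary) to secondary
#'   feature IDs.
#' @param frozen_fit the [mq_mixture()] fit from the unfiltered data.
#' @param params a [utility_params()] object.
#' @param mq_method,n_boot,master_seed,min_obs scoring settings, as in
#'   [score_all_pairs()].
#' @param aggregate,intensity_col event aggregation, as in
#'   [aggregate_events()].
#' @return data.frame with one row per proportion: `proportion`, `n_events`,
#'   `n_pairs`, `p_plus`, `eu_mean`, `eu_total`.
#' @export
threshold_sweep <- function(events, proportions, secondary, pairs, frozen_fit,
                            params = utility_params(),
                            mq_method = "pearson", n_boot = 200,
                            master_seed = 1L, min_obs = 4,
                            aggregate = "count", intensity_col = "intensity") {
  stopifnot(all(c("protein_id", "sample_id", "score_1", "score_2") %in%
                  names(events)))
  if (any(proportions >= 1) || any(proportions < 0)) {
    stop("threshold proportions must lie in [0, 1)")
  }
  rows <- lapply(proportions, function(q) {
    if (q == 0) {
      kept <- events
    } else {
      q1 <- stats::quantile(events$score_1, q, names = FALSE, type = 7)
      q2 <- stats::quantile(events$score_2, q, names = FALSE, type = 7)
      kept <- events[events$score_1 > q1 & events$score_2 > q2, , drop = FALSE]
    }
    if (nrow(kept) == 0L) {
      warning("no events survive proportion ", q)
      return(data.frame(proportion = q, n_events = 0L, n_pairs = 0L,
                        p_plus = NA_real_, eu_mean = 0, eu_total = 0))
    }
    counts <- aggregate_events(kept, samples = sort(unique(events$sample_id)),
                               aggregate = aggregate,
                               intensity_col = intensity_col)
    merged <- merge_by_sample(counts, secondary, pairs)
    scores <- tryCatch(
      suppressMessages(score_all_pairs(merged, method = mq_method,
                                       n_boot = n_boot,
                                       master_seed = master_seed,
                                       min_obs = min_obs)),
      error = function(e) NULL)
    if (is.null(scores)) {
      warning("all pairs degenerate at proportion ", q)
      return(data.frame(proportion = q, n_events = nrow(kept), n_pairs = 0L,
                        p_plus = NA_real_, eu_mean = 0, eu_total = 0))
    }
    post <- posterior_table(scores, frozen_fit)
    p <- weighted_p_plus(post)
    em <- eu_mean(p, params)
    data.frame(proportion = q, n_events = nrow(kept),
               n_pairs = nrow(scores), p_plus = p, eu_mean = em,
               eu_total = eu_total(nrow(scores), em))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
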