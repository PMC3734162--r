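#' Model-quality score for one ID pair
#'
#' The association between the two platforms' measurements across samples —
#' by default the Pearson correlation; Spearman is offered for monotone but
#' non-linear coupling. Vectors are reduced to pairwise-complete observations
#' first.
#'
#' @param x,y numeric vectors of equal length (one value per sample).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_obs minimum complete observations (default 4).
#' @return the correlation, or `NA` with attribute `"degenerate"` when there
#'   are too few complete observations or either vector is constant — the
#'   caller excludes such pairs.
#' @export
compute_mq <- function(x, y, method = c("pearson", "spearman"), min_obs = 4) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_obs || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(x, y, method = method)
}

#' Normal-theory variance of a Pearson correlation estimate
#'
#' Reference curve for the bootstrap variances. Two conventions are offered:
#' the default `(1 - rho^2) / (n - 3)` and, behind `squared = TRUE`, the
#' classical large-sample form `(1 - rho^2)^2 / (n - 3)`.
#'
#' @param rho correlation in `[-1, 1]`.
#' @param n number of observations, at least 4.
#' @param squared use the squared-numerator convention?
#' @return nonnegative variance.
#' @export
normal_theory_variance <- function(rho, n, squared = FALSE) {
  stopifnot(all(abs(rho) <= 1))
  if (any(n <= 3)) stop("n must exceed 3")
  num <- if (squared) (1 - rho^2)^2 else (1 - rho^2)
  num / (n - 3)
}

#' Bootstrap measurement-error variance of a pair's correlation
#'
#' Nonparametric case bootstrap: sample indices are drawn jointly for the two
#' vectors with replacement; the variance of the correlation over the
#' replicates estimates the measurement-error variance \eqn{\sigma^2_p}.
#' Replicates in which either resampled vector is constant (common for sparse
#' spectral counts) are redrawn up to `max_retry` times.
#'
#' @inheritParams compute_mq
#' @param n_boot number of bootstrap replications (default 200).
#' @param seed integer seed; the resampling is fully determined by it.
#' @param max_retry redraw budget per replicate for constant resamples.
#' @return nonnegative variance, or `NA` with attribute `"degenerate"` if the
#'   retry budget is exhausted or the pair itself is degenerate.
#' @export
bootstrap_variance <- function(x, y, method = c("pearson", "spearman"),
                               n_boot = 200, seed = 1L, max_retry = 100L) {
  method <- match.arg(method)
  stopifnot(n_boot >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  set.seed(seed)
  if (method == "spearman") {
    # ranks are recomputed within each resample via cor(method = "spearman")
  }
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    r <- NA_real_
    for (try in seq_len(max_retry)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) > 0 && stats::sd(yb) > 0) {
        r <- stats::cor(xb, yb, method = method)
        break
      }
    }
    if (is.na(r)) return(structure(NA_real_, degenerate = TRUE))
    reps[b] <- r
  }
  stats::var(reps)
}

#' Score every merged ID pair
#'
#' Computes, for each pair in a [merge_by_sample()] result, the association
#' score and its bootstrap measurement-error variance. Degenerate pairs (too
#' few complete observations, constant vectors, exhausted bootstrap retries)
#' are excluded and counted. Per-pair RNG seeds are derived from
#' `master_seed` and a stable hash of the pair IDs, so the score table does
#' not depend on pair ordering.
#'
#' @param merged object of class `"merged_pairs"`.
#' @param method association measure, `"pearson"` or `"spearman"`.
#' @param n_boot bootstrap replications per pair (default 200).
#' @param master_seed integer master seed.
#' @param min_obs minimum complete observations per pair (default 4).
#' @return data.frame with columns `primary_id`, `secondary_id`, `mq`,
#'   `sigma2`, `n_obs`, the per-method flags carried over from the pool, and
#'   attributes `n_excluded` and `methods`.
#' @export
score_all_pairs <- function(merged, method = c("pearson", "spearman"),
                            n_boot = 200, master_seed = 1L, min_obs = 4) {
  method <- match.arg(method)
  stopifnot(inherits(merged, "merged_pairs"))
  np <- nrow(merged$pairs)
  if (np == 0L) stop("merged table is empty")
  keys <- pair_key(merged$pairs$primary_id, merged$pairs$secondary_id)
  mq <- sigma2 <- rep(NA_real_, np)
  n_obs <- integer(np)
  for (i in seq_len(np)) {
    xi <- merged$x[i, ]; yi <- merged$y[i, ]
    ok <- is.finite(xi) & is.finite(yi)
    n_obs[i] <- sum(ok)
    r <- compute_mq(xi, yi, method = method, min_obs = min_obs)
    if (isTRUE(attr(r, "degenerate"))) next
    v <- bootstrap_variance(xi, yi, method = method, n_boot = n_boot,
                            seed = derive_seed(master_seed, keys[i]))
    if (isTRUE(attr(v, "degenerate"))) next
    mq[i] <- as.numeric(r)
    sigma2[i] <- as.numeric(v)
  }
  keep <- !is.na(mq)
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("all pairs degenerate; nothing to score")
  if (n_excluded > 0L) {
    message(n_excluded, " degenerate pair(s) excluded from scoring")
  }
  out <- data.frame(primary_id = merged$pairs$primary_id[keep],
                    secondary_id = merged$pairs$secondary_id[keep],
                    mq = mq[keep], sigma2 = sigma2[keep],
                    n_obs = n_obs[keep], stringsAsFactors = FALSE)
  methods <- pair_methods(merged$pairs)
  for (m in methods) out[[m]] <- merged$pairs[[m]][keep]
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded, methods = methods,
            n_boot = n_boot, mq_method = method, master_seed = master_seed)
}

#' Write / read a pair-score table
#'
#' Delimited text with columns `primary_id`, `secondary_id`, `mq`, `sigma2`,
#' `n_obs` and the per-method flags.
#'
#' @param scores score table from [score_all_pairs()].
#' @param path file path.
#' @param delimiter field separator.
#' @return `path` (writer) or the score table (reader).
#' @export
write_pair_scores <- function(scores, path, delimiter = "\t") {
  utils::write.table(scores, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_scores
#' @export
read_pair_scores <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("primary_id", "secondary_id", "mq", "sigma2", "n_obs")
  if (!all(needed %in% names(df))) {
    stop("score table lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  flag_cols <- setdiff(names(df), needed)
  for (m in flag_cols) df[[m]] <- as.logical(df[[m]])
  structure(df, methods = flag_cols)
}
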