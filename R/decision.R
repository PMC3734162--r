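#' Utility parameters for the decision analysis
#'
#' @param u_tp utility of including a correctly mapped ("true positive")
#'   pair; default 2.
#' @param l_fp loss of including an incorrectly mapped ("false positive")
#'   pair; default 1.
#' @param delta_plus proportion of correctly mapped pairs that are
#'   biologically coupled, in `(0, 1]`; the working default 1 assumes the
#'   decoupled "0" group is empty.
#' @return validated list of class `"utility_params"`.
#' @export
utility_params <- function(u_tp = 2, l_fp = 1, delta_plus = 1) {
  stopifnot(is.numeric(u_tp), u_tp > 0,
            is.numeric(l_fp), l_fp > 0,
            is.numeric(delta_plus), delta_plus > 0, delta_plus <= 1)
  structure(list(u_tp = u_tp, l_fp = l_fp, delta_plus = delta_plus),
            class = "utility_params")
}

#' Precision-weighted estimate of the proportion of correct pairs
#'
#' The optimally weighted mean of the posterior probabilities over a method's
#' pairs, with weights the reciprocal posterior variances:
#' \deqn{\hat P_{+M} = \sum_p \pi^*_{+p}/v^*_{+p} \Big/ \sum_p 1/v^*_{+p}.}
#' Down-weights pairs whose correlation is unstable (e.g. low variance on
#' either platform).
#'
#' The delta-method variance degenerates to zero for saturated posteriors
#' (its leading factor is \eqn{(\pi^* (1-\pi^*))^2}) and exactly at the
#' crossing score where the two component log-densities have equal slope, so
#' raw reciprocal weights would let a single extreme pair stand for the whole
#' method — whereas the evaluation is an aggregate by design ("a single ID
#' pair proves nothing"). The variances are therefore floored at
#' `median(v)/max_weight_ratio`, capping any record's weight at
#' `max_weight_ratio` times the typical record's; exact zeros are subsumed by
#' the same floor. If no record has positive variance the plain mean is
#' returned.
#'
#' @param records posterior table rows (see [posterior_table()]): needs
#'   columns `post_plus` and `post_var`.
#' @param max_weight_ratio cap on the weight of any record relative to the
#'   median-precision record (default 100).
#' @return weighted proportion in `[0, 1]`.
#' @export
weighted_p_plus <- function(records, max_weight_ratio = 100) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records: cannot form a weighted proportion")
  }
  p <- records$post_plus
  v <- records$post_var
  pos <- v[v > 0]
  if (length(pos) == 0L) return(mean(p))
  v <- pmax(v, stats::median(pos) / max_weight_ratio)
  sum(p / v) / sum(1 / v)
}

#' Expected utility per pair of adopting a method
#'
#' The Bayesian expected utility of keeping a method's whole pair set, per
#' pair:
#' \deqn{EU^{(1)} = P_{+M}\,[U_{TP}\delta_+^{-1} + L_{FP}(2 - \delta_+^{-1})]
#'   - L_{FP},}
#' which at \eqn{\delta_+ = 1} reduces to
#' \eqn{U_{TP} P_{+M} - L_{FP}(1 - P_{+M})}. The \eqn{\delta_+ < 1} form
#' credits the correctly mapped but decoupled pairs hiding in the "\eqn{-}"
#' component.
#'
#' @param p_plus (weighted) proportion of correct coupled pairs, in `[0,1]`.
#' @param params a [utility_params()] object.
#' @return expected utility per pair (an increasing linear function of
#'   `p_plus`).
#' @export
eu_mean <- function(p_plus, params = utility_params()) {
  stopifnot(all(p_plus >= 0 & p_plus <= 1))
  inv_d <- 1 / params$delta_plus
  p_plus * (params$u_tp * inv_d + params$l_fp * (2 - inv_d)) - params$l_fp
}

#' Total expected utility of adopting a method
#'
#' @param n_pairs number of pairs the method returns.
#' @param eu_mean_value expected utility per pair (see [eu_mean()]).
#' @return `n_pairs * eu_mean_value`.
#' @export
eu_total <- function(n_pairs, eu_mean_value) {
  stopifnot(all(n_pairs >= 0))
  n_pairs * eu_mean_value
}

#' Break-even proportion of correct pairs
#'
#' The `p_plus` at which the per-pair expected utility is zero:
#' `l_fp / (u_tp + l_fp)` (at `delta_plus = 1`).
#'
#' @param params a [utility_params()] object.
#' @return break-even proportion.
#' @export
break_even <- function(params = utility_params()) {
  params$l_fp / (params$u_tp + params$l_fp)
}

#' Evaluate candidate methods and Boolean combinations
#'
#' Builds the method-comparison table: for each candidate pair subset, the
#' number of pairs, the precision-weighted proportion of correct pairs, and
#' the per-pair and total expected utilities, plus a "Use All" row over the
#' full pool.
#'
#' @param records posterior table from [posterior_table()].
#' @param method_sets how to form the candidate subsets: `NULL` (default)
#'   uses the per-method flag columns of `records`; a character vector is
#'   read as Boolean expressions over the method names; a named list of
#'   logical vectors over the rows of `records` is used as-is.
#' @param params a [utility_params()] object.
#' @param include_all append the "Use All" row?
#' @param sort_by order rows by `"eu_mean"`, `"eu_total"`, or `"none"`.
#' @return data.frame with columns `method`, `n_pairs`, `p_plus`, `p_minus`,
#'   `eu_mean`, `eu_total`, `break_even`.
#' @export
evaluate_methods <- function(records, method_sets = NULL,
                             params = utility_params(), include_all = TRUE,
                             sort_by = c("none", "eu_mean", "eu_total")) {
  sort_by <- match.arg(sort_by)
  methods <- attr(records, "methods")
  if (is.null(method_sets)) {
    if (is.null(methods) || length(methods) == 0L) {
      stop("records carry no method flags and no method_sets were given")
    }
    method_sets <- lapply(methods, function(m) as.logical(records[[m]]))
    names(method_sets) <- methods
  } else if (is.character(method_sets)) {
    method_sets <- boolean_method_sets(records, method_sets)
  }
  stopifnot(is.list(method_sets), !is.null(names(method_sets)))
  if (include_all) {
    method_sets <- c(method_sets,
                     list("Use All" = rep(TRUE, nrow(records))))
  }
  rows <- lapply(names(method_sets), function(nm) {
    keep <- method_sets[[nm]]
    n <- sum(keep)
    if (n == 0L) {
      warning("method set '", nm, "' is empty")
      return(data.frame(method = nm, n_pairs = 0L, p_plus = NA_real_,
                        p_minus = NA_real_, eu_mean = 0, eu_total = 0,
                        break_even = break_even(params),
                        stringsAsFactors = FALSE))
    }
    p <- weighted_p_plus(records[keep, , drop = FALSE])
    em <- eu_mean(p, params)
    data.frame(method = nm, n_pairs = n, p_plus = p, p_minus = 1 - p,
               eu_mean = em, eu_total = eu_total(n, em),
               break_even = break_even(params), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (sort_by != "none") {
    out <- out[order(-out[[sort_by]]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Round a method-evaluation table for display
#'
#' The reporting convention of the comparison tables: `p_plus`/`p_minus` and
#' `eu_mean` to 3 decimals, `eu_total` to the nearest integer. Computation is
#' never performed on rounded values.
#'
#' @param evaluation output of [evaluate_methods()] or [threshold_sweep()].
#' @return the table with display rounding applied.
#' @export
format_evaluation <- function(evaluation) {
  for (col in intersect(c("p_plus", "p_minus", "eu_mean"), names(evaluation))) {
    evaluation[[col]] <- round(evaluation[[col]], 3)
  }
  if ("eu_total" %in% names(evaluation)) {
    evaluation$eu_total <- round(evaluation$eu_total)
  }
  evaluation
}
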