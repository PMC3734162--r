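#' Historical Affymetrix qualifier-tag filter
#'
#' Rejects probesets whose ID ends in an underscore, a single qualifier letter
#' from \{a, g, i, r, x, s, f\} and "_at" — the original Affymetrix annotation
#' tags flagging doubts about correct and unique hybridization.
#'
#' @param feature_id character vector of probeset IDs.
#' @return logical vector; `TRUE` = accept, `FALSE` = reject.
#' @examples
#' affytag_filter(c("201234_x_at", "201234_at", "201234_b_at"))
#' @export
affytag_filter <- function(feature_id) {
  stopifnot(is.character(feature_id), all(nzchar(feature_id)))
  !grepl("_[agirxsf]_at$", feature_id)
}

#' Read a filter-verdict table
#'
#' Column 1 is the feature ID; each remaining column is a named 0/1 accept
#' verdict for one filtering method.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return data.frame with column `feature_id` and one logical column per
#'   filter.
#' @export
read_filter_verdicts <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("verdict table needs >= 2 columns: ", path)
  names(df)[1L] <- "feature_id"
  df$feature_id <- as.character(df$feature_id)
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id in verdict table: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  }
  for (j in seq(2L, ncol(df))) df[[j]] <- as.logical(as.integer(df[[j]]))
  df
}

# Per-pair acceptance under each filter: a pair is accepted by filter f iff
# every feature of the pair that is subject to filtering (appears in the
# verdict table) is accepted by f. Pairs sharing a rejected feature therefore
# share its fate.
#' @keywords internal
#' @noRd
pair_filter_acceptance <- function(pairs, verdicts) {
  filters <- setdiff(names(verdicts), "feature_id")
  idx_p <- match(pairs$primary_id, verdicts$feature_id)
  idx_s <- match(pairs$secondary_id, verdicts$feature_id)
  out <- lapply(filters, function(f) {
    v <- verdicts[[f]]
    acc_p <- ifelse(is.na(idx_p), TRUE, v[idx_p])
    acc_s <- ifelse(is.na(idx_s), TRUE, v[idx_s])
    acc_p & acc_s
  })
  names(out) <- filters
  as.data.frame(out, optional = TRUE)
}

#' Apply a Boolean filter expression to a pair set
#'
#' Evaluates a Boolean combination of filter verdicts (connectives `AND`,
#' `OR`, `NOT`, parentheses; `&`, `|`, `!` also accepted) over the per-pair
#' acceptance of each filter. A pair is accepted by a filter iff every one of
#' its features subject to that filter is accepted; features absent from the
#' verdict table are not subject to filtering.
#'
#' @param pairs pooled pair set (see [pool_pairs()]), or any data.frame with
#'   `primary_id` and `secondary_id` columns.
#' @param verdicts verdict table from [read_filter_verdicts()] (or an
#'   equivalent data.frame).
#' @param expression single Boolean expression over filter names, e.g.
#'   `"PdbA30 AND Jetset"`.
#' @return the subset of `pairs` surviving the expression.
#' @export
apply_filters <- function(pairs, verdicts, expression) {
  acc <- pair_filter_acceptance(pairs, verdicts)
  keep <- eval_boolean(expression, acc)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "methods") <- attr(pairs, "methods")
  out
}

#' Materialize Boolean combinations of mapping methods as pair subsets
#'
#' Each expression is evaluated over the per-method membership flags of the
#' pooled pair set (`AND` = intersection, `OR` = union).
#'
#' @param pairs pooled pair set from [pool_pairs()].
#' @param expressions character vector of Boolean expressions over method
#'   names.
#' @return named list (one element per expression) of logical vectors over
#'   the rows of `pairs`.
#' @export
boolean_method_sets <- function(pairs, expressions) {
  methods <- pair_methods(pairs)
  if (length(methods) == 0L) stop("pair set carries no method flags")
  flags <- as.data.frame(pairs[, methods, drop = FALSE])
  out <- lapply(expressions, function(e) eval_boolean(e, flags))
  names(out) <- expressions
  out
}
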