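#' Read a pipeline run configuration
#'
#' A single flat YAML file; any key may be overridden programmatically (the
#' command-line dispatcher maps flags onto keys). Unknown keys are kept and
#' echoed into every report.
#'
#' @param path YAML config path.
#' @param overrides named list of values overriding the file's keys.
#' @return list of class `"run_config"` with defaults filled in.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  defaults <- list(mq_method = "pearson", n_boot = 200, master_seed = 1L,
                   min_obs = 4, tol = 1e-8, max_iter = 2000,
                   u_tp = 2, l_fp = 1, delta_plus = 1,
                   expressions = NULL, proportions = c(0, 2^-(8:1)),
                   min_mean_count = NULL, delimiter = "\t",
                   negative_coupling = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

#' @keywords internal
#' @noRd
config_echo <- function(config) {
  keep <- !vapply(config, is.null, logical(1))
  paste0("# ", yaml::as.yaml(unclass(config)[keep]))
}

#' @keywords internal
#' @noRd
write_report <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# idmeval ", as.character(utils::packageVersion("idmeval")),
                    " seed=", config$master_seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline verbs
#'
#' Thin, logged wrappers wiring the modules into the standard workflow:
#' `run_simulate` materializes a synthetic workspace, `run_score` reads
#' matrices and ID maps and writes the pair-score table, `run_fit` fits the
#' score mixture and serializes it, `run_evaluate` builds the
#' method-comparison report, and `run_sweep` runs the event-quality
#' threshold sweep against a frozen fit. Each verb returns its main result
#' invisibly and writes delimited-text outputs carrying a seed header.
#'
#' @param config a [read_run_config()] list. Keys used include `workspace`
#'   (directory of inputs), `out_dir`, `primary`, `secondary`, `maps`
#'   (directory of two-column map files), `scores`, `fit`, `events`,
#'   `expressions`, `proportions`, the scoring settings (`mq_method`,
#'   `n_boot`, `master_seed`, `min_obs`, `min_mean_count`) and the utility
#'   parameters (`u_tp`, `l_fp`, `delta_plus`).
#' @return see each verb.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  out <- config$out_dir %||% config$workspace
  if (is.null(out)) stop("config needs 'out_dir' (or 'workspace')")
  sc <- sim_config(seed = config$master_seed)
  for (k in intersect(names(config),
                      c("n_samples", "n_pairs", "psi_plus", "v_plus",
                        "v_minus", "noise_model", "coupled_corr_mean",
                        "coupled_corr_sd"))) {
    sc[[k]] <- config[[k]]
  }
  make_fixture_workspace(out, sc)
  message("synthetic workspace written to ", out)
  invisible(out)
}

#' @rdname pipeline
#' @export
run_score <- function(config) {
  ws <- config$workspace %||% "."
  primary <- read_expression_matrix(config$primary %||%
                                      file.path(ws, "primary.tsv"),
                                    config$delimiter)
  secondary <- read_expression_matrix(config$secondary %||%
                                        file.path(ws, "secondary.tsv"),
                                      config$delimiter)
  map_dir <- config$maps %||% file.path(ws, "maps")
  map_files <- list.files(map_dir, full.names = TRUE)
  if (length(map_files) == 0L) stop("no ID-map files under ", map_dir)
  maps <- lapply(map_files, read_id_map, delimiter = config$delimiter)
  names(maps) <- sub("\\.[^.]*$", "", basename(map_files))
  pairs <- pool_pairs(maps)
  merged <- merge_by_sample(primary, secondary, pairs,
                            min_mean_count = config$min_mean_count)
  scores <- score_all_pairs(merged, method = config$mq_method,
                            n_boot = config$n_boot,
                            master_seed = config$master_seed,
                            min_obs = config$min_obs)
  out <- config$scores %||% file.path(ws, "scores.tsv")
  write_pair_scores(scores, out, config$delimiter)
  message(nrow(scores), " pairs scored -> ", out)
  invisible(scores)
}

#' @rdname pipeline
#' @export
run_fit <- function(config) {
  ws <- config$workspace %||% "."
  scores <- read_pair_scores(config$scores %||% file.path(ws, "scores.tsv"),
                             config$delimiter)
  fit <- mq_mixture(scores, tol = config$tol, max_iter = config$max_iter,
                    negative_coupling = isTRUE(config$negative_coupling))
  out <- config$fit %||% file.path(ws, "fit.json")
  write_mixture_fit(fit, out)
  message("mixture fit (", fit$n_iter, " iterations) -> ", out)
  invisible(fit)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(config) {
  ws <- config$workspace %||% "."
  scores <- read_pair_scores(config$scores %||% file.path(ws, "scores.tsv"),
                             config$delimiter)
  fit <- read_mixture_fit(config$fit %||% file.path(ws, "fit.json"))
  post <- posterior_table(scores, fit)
  params <- utility_params(config$u_tp, config$l_fp, config$delta_plus)
  sets <- NULL
  if (!is.null(config$expressions)) {
    base <- lapply(attr(scores, "methods"),
                   function(m) as.logical(scores[[m]]))
    names(base) <- attr(scores, "methods")
    sets <- c(base, boolean_method_sets(post, unlist(config$expressions)))
  }
  ev <- evaluate_methods(post, method_sets = sets, params = params,
                         sort_by = config$sort_by %||% "none")
  out <- config$report %||% file.path(ws, "evaluation.tsv")
  write_report(format_evaluation(ev), out, config)
  message(nrow(ev), " method rows -> ", out)
  invisible(ev)
}

#' @rdname pipeline
#' @export
run_sweep <- function(config) {
  ws <- config$workspace %||% "."
  events <- utils::read.table(config$events %||% file.path(ws, "events.tsv"),
                              sep = config$delimiter, header = TRUE,
                              stringsAsFactors = FALSE)
  secondary <- read_expression_matrix(config$secondary %||%
                                        file.path(ws, "secondary.tsv"),
                                      config$delimiter)
  map_dir <- config$maps %||% file.path(ws, "maps")
  maps <- lapply(list.files(map_dir, full.names = TRUE), read_id_map,
                 delimiter = config$delimiter)
  names(maps) <- sub("\\.[^.]*$", "",
                     basename(list.files(map_dir)))
  pairs <- pool_pairs(maps)
  fit <- read_mixture_fit(config$fit %||% file.path(ws, "fit.json"))
  params <- utility_params(config$u_tp, config$l_fp, config$delta_plus)
  sweep <- threshold_sweep(events, unlist(config$proportions), secondary,
                           pairs, fit, params = params,
                           mq_method = config$mq_method,
                           n_boot = config$n_boot,
                           master_seed = config$master_seed,
                           min_obs = config$min_obs)
  out <- config$report %||% file.path(ws, "sweep.tsv")
  write_report(format_evaluation(sweep), out, config)
  message(nrow(sweep), " threshold rows -> ", out)
  invisible(sweep)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
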