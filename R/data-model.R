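#' Construct a feature-by-sample expression matrix
#'
#' A thin validating constructor around a base numeric matrix with feature IDs
#' as rownames and sample IDs as colnames — the container used for both
#' platforms (e.g. probeset signals and protein spectral counts).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Missing values are permitted.
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @return a numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature_ids and sample_ids are required")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("dimnames do not match matrix dimensions")
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) {
    stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

#' Read an expression matrix from delimited text
#'
#' Expects row 1 to hold sample IDs and column 1 feature IDs. Non-numeric body
#' cells become `NA`.
#'
#' @param path file path.
#' @param delimiter field separator, tab by default.
#' @return numeric matrix (features x samples) with dimnames.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, comment.char = "", quote = "\"")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or malformed matrix file: ", path)
  feature_ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                    dimnames = list(NULL, colnames(body))))
  expression_matrix(values, feature_ids = feature_ids,
                    sample_ids = colnames(body))
}

#' Write an expression matrix as delimited text
#'
#' @param x numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a two-column ID map
#'
#' One file per candidate mapping method: column 1 primary IDs (e.g. protein
#' accessions), column 2 secondary IDs (e.g. probesets). Duplicated rows are
#' dropped with a message.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @param header logical; does the file carry a header row?
#' @return data.frame with columns `primary_id`, `secondary_id`.
#' @export
read_id_map <- function(path, delimiter = "\t", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = header,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("ID map needs two columns: ", path)
  out <- data.frame(primary_id = df[[1L]], secondary_id = df[[2L]],
                    stringsAsFactors = FALSE)
  dup <- duplicated(pair_key(out$primary_id, out$secondary_id))
  if (any(dup)) {
    message(sum(dup), " duplicate pair(s) dropped from ", basename(path))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_id_map
#' @param map data.frame with columns `primary_id`, `secondary_id`.
#' @export
write_id_map <- function(map, path, delimiter = "\t") {
  utils::write.table(map[, c("primary_id", "secondary_id")], path,
                     sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool ID pairs across candidate mapping methods
#'
#' The full pool is the union of the pair sets asserted by the candidate
#' methods; each pooled pair carries one logical membership flag per method.
#' Duplicates inside one map are de-duplicated with a message.
#'
#' @param maps named list of ID maps — each a data.frame with columns
#'   `primary_id` and `secondary_id` (see [read_id_map()]), or a two-column
#'   matrix/list coercible to one.
#' @return data.frame with columns `primary_id`, `secondary_id` and one
#'   logical column per method; attribute `"methods"` lists the method names.
#' @export
pool_pairs <- function(maps) {
  if (length(maps) == 0L) stop("at least one ID map is required")
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    stop("maps must be a named list (one name per candidate method)")
  }
  maps <- lapply(maps, function(m) {
    m <- as.data.frame(m, stringsAsFactors = FALSE)
    data.frame(primary_id = as.character(m[[1L]]),
               secondary_id = as.character(m[[2L]]),
               stringsAsFactors = FALSE)
  })
  n_dup <- 0L
  maps <- lapply(maps, function(m) {
    dup <- duplicated(pair_key(m$primary_id, m$secondary_id))
    n_dup <<- n_dup + sum(dup)
    m[!dup, , drop = FALSE]
  })
  if (n_dup > 0L) message(n_dup, " duplicate pair(s) de-duplicated within maps")
  all_pairs <- unique(do.call(rbind, maps))
  all_pairs <- all_pairs[order(all_pairs$primary_id, all_pairs$secondary_id), ,
                         drop = FALSE]
  rownames(all_pairs) <- NULL
  keys <- pair_key(all_pairs$primary_id, all_pairs$secondary_id)
  for (m in names(maps)) {
    all_pairs[[m]] <- keys %in% pair_key(maps[[m]]$primary_id,
                                         maps[[m]]$secondary_id)
  }
  structure(all_pairs, methods = names(maps))
}

#' Method names attached to a pooled pair set
#' @param pairs output of [pool_pairs()].
#' @return character vector of candidate method names.
#' @export
pair_methods <- function(pairs) {
  m <- attr(pairs, "methods")
  if (is.null(m)) {
    m <- names(pairs)[vapply(pairs, is.logical, logical(1))]
  }
  m
}

#' Merge two platforms by sample for a set of ID pairs
#'
#' Aligns the two matrices on their shared samples (exact string match, sorted
#' lexicographically) and extracts, for every pooled pair present in both
#' matrices, the two value vectors over the shared samples. Pairs with either
#' ID absent are dropped and counted.
#'
#' @param primary expression matrix for the primary platform (rows indexed by
#'   `primary_id`).
#' @param secondary expression matrix for the secondary platform (rows indexed
#'   by `secondary_id`).
#' @param pairs pooled pair set from [pool_pairs()].
#' @param min_shared minimum number of shared samples required (default 4, the
#'   smallest n for which the normal-theory correlation variance is finite
#'   with slack).
#' @param min_mean_count optional minimum mean primary-platform value; pairs
#'   whose primary feature falls below it are excluded (no filtering by
#'   default). Mirrors restricting to proteins with a minimum average spectral
#'   count.
#' @return an object of class `"merged_pairs"`: a list with the retained
#'   `pairs` table, aligned value matrices `x` (primary) and `y` (secondary)
#'   with one row per pair, the shared `samples`, and drop counts.
#' @export
merge_by_sample <- function(primary, secondary, pairs, min_shared = 4,
                            min_mean_count = NULL) {
  shared <- sort(intersect(colnames(primary), colnames(secondary)))
  if (length(shared) == 0L) stop("no shared samples between the two platforms")
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " shared sample(s); need at least ", min_shared)
  }
  present <- pairs$primary_id %in% rownames(primary) &
    pairs$secondary_id %in% rownames(secondary)
  n_dropped_id <- sum(!present)
  kept <- pairs[present, , drop = FALSE]
  x <- primary[kept$primary_id, shared, drop = FALSE]
  y <- secondary[kept$secondary_id, shared, drop = FALSE]
  n_dropped_count <- 0L
  if (!is.null(min_mean_count)) {
    ok <- rowMeans(x, na.rm = TRUE) >= min_mean_count
    ok[is.na(ok)] <- FALSE
    n_dropped_count <- sum(!ok)
    kept <- kept[ok, , drop = FALSE]
    x <- x[ok, , drop = FALSE]
    y <- y[ok, , drop = FALSE]
  }
  rownames(kept) <- NULL
  rownames(x) <- rownames(y) <- NULL
  structure(list(pairs = kept, x = x, y = y, samples = shared,
                 n_dropped_id = n_dropped_id,
                 n_dropped_count = n_dropped_count),
            class = "merged_pairs")
}

#' @export
print.merged_pairs <- function(x, ...) {
  cat("Merged two-platform pair set\n")
  cat("  pairs:   ", nrow(x$pairs), "\n")
  cat("  samples: ", length(x$samples), " shared\n", sep = "")
  cat("  dropped: ", x$n_dropped_id, " (ID absent), ",
      x$n_dropped_count, " (below count cutoff)\n", sep = "")
  invisible(x)
}
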