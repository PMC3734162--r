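# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
pair_key <- function(primary_id, secondary_id) {
  paste(primary_id, secondary_id, sep = "\r")
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-pair RNG seeds from a master seed so scoring is independent of pair order.
#' @keywords internal
#' @noRd
stable_hash <- function(s) {
  mod <- 2147483647
  vapply(s, function(one) {
    h <- 0
    for (code in utf8ToInt(one)) h <- (h * 131 + code) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' @keywords internal
#' @noRd
derive_seed <- function(master_seed, key) {
  mod <- 2147483647
  as.integer((as.numeric(master_seed) %% mod * 48271 + stable_hash(key)) %% mod)
}

# Parse a Boolean expression over a known vocabulary of names. Accepts the word
# connectives AND / OR / NOT (any case) as well as & | ! and parentheses.
# Returns an R language object that only contains &, |, !, ( and known symbols.
#' @keywords internal
#' @noRd
parse_boolean <- function(expression, known_names) {
  stopifnot(is.character(expression), length(expression) == 1L)
  txt <- expression
  txt <- gsub("(?i)\\bAND\\b", "&", txt, perl = TRUE)
  txt <- gsub("(?i)\\bOR\\b", "|", txt, perl = TRUE)
  txt <- gsub("(?i)\\bNOT\\b", "!", txt, perl = TRUE)
  # the paper's tables separate names with commas ("N, E and D" = N & E & D)
  txt <- gsub(",", "&", txt, fixed = TRUE)
  ex <- tryCatch(str2lang(txt), error = function(e) {
    stop("cannot parse Boolean expression: ", expression, call. = FALSE)
  })
  check_node <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!nm %in% known_names) {
        stop("unknown name '", nm, "' in expression: ", expression, call. = FALSE)
      }
      return(invisible(NULL))
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% c("&", "|", "!", "(", "&&", "||")) {
        stop("unsupported operator '", op, "' in expression: ", expression,
             call. = FALSE)
      }
      for (i in seq_along(e)[-1L]) check_node(e[[i]])
      return(invisible(NULL))
    }
    stop("unsupported token in expression: ", expression, call. = FALSE)
  }
  check_node(ex)
  ex
}

#' @keywords internal
#' @noRd
eval_boolean <- function(expression, truth_table) {
  ex <- parse_boolean(expression, names(truth_table))
  out <- eval(ex, envir = truth_table, enclos = baseenv())
  as.logical(out)
}
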