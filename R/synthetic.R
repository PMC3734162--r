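#' Configuration for the synthetic two-platform study
#'
#' Defines the simulated study conditions: cohort size, pair population and
#' its three-group composition ("+" correctly mapped and coupled, "0"
#' correctly mapped but decoupled, "x" mis-identified or mis-mapped), the
#' coupling-strength distribution, the score-mixture parameters, the
#' measurement-noise model, and the candidate-method specifications.
#'
#' Defaults mirror the published study setting: 98 samples (91 cancer + 7
#' non-cancer), coupled pairs centred at correlation 0.45 with latent
#' variance 0.02, a pooled "\eqn{-}" latent variance of 0.01, prior weight
#' 0.40 on "+", per-pair measurement-error variances uniform on
#' \[0.002, 0.02\] for the score-level generator, sparse Poisson spectral
#' counts on the primary platform, and a background correlation spread of
#' 0.2 among all feature pairs (global sample-level variation: batch,
#' cellularity, sample quality) — the reason the "\eqn{-}" component of real
#' data is not a spike at zero.
#'
#' @param n_samples number of biological samples (default 98).
#' @param n_pairs number of ID pairs (default 500).
#' @param group_probs probabilities of the "+", "0" and "x" groups; must sum
#'   to 1.
#' @param psi_plus mean score of the "+" component (default 0.45).
#' @param v_plus,v_minus latent score variances of the "+" and pooled
#'   "\eqn{-}" components (score-level generator).
#' @param coupled_corr_mean,coupled_corr_sd distribution of the target
#'   correlation of "+" pairs in the two-platform generator.
#' @param background_corr_sd spread of the nuisance correlation every pair
#'   carries regardless of mapping correctness (default 0.2).
#' @param sigma2_range range of per-pair measurement-error variances for the
#'   score-level generator.
#' @param noise_model marginal model for the primary platform:
#'   `"poisson_counts"` (default; spectral-count realism), `"gaussian"` or
#'   `"negative_binomial_counts"`.
#' @param count_mean mean count at average abundance for the count noise
#'   models (default 2.5 — sparse, like spectral counts).
#' @param method_specs list of candidate-method specifications, each a list
#'   with `name`, `n_pairs` and `frac_correct` (fraction of the method's
#'   pairs drawn from the correctly mapped pool).
#' @param seed integer seed driving every generator.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 98, n_pairs = 500,
                       group_probs = c(plus = 0.40, zero = 0.10, x = 0.50),
                       psi_plus = 0.45, v_plus = 0.02, v_minus = 0.01,
                       coupled_corr_mean = 0.45, coupled_corr_sd = 0.14,
                       background_corr_sd = 0.2,
                       sigma2_range = c(0.002, 0.02),
                       noise_model = c("poisson_counts", "gaussian",
                                       "negative_binomial_counts"),
                       count_mean = 2.5,
                       method_specs = list(
                         list(name = "A", n_pairs = round(0.6 * n_pairs),
                              frac_correct = 0.6),
                         list(name = "B", n_pairs = round(0.6 * n_pairs),
                              frac_correct = 0.4)),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_samples >= 4, n_pairs >= 1,
            length(group_probs) == 3, all(group_probs >= 0),
            abs(sum(group_probs) - 1) < 1e-8,
            length(sigma2_range) == 2, all(sigma2_range >= 0))
  names(group_probs) <- c("plus", "zero", "x")
  structure(list(n_samples = n_samples, n_pairs = n_pairs,
                 group_probs = group_probs, psi_plus = psi_plus,
                 v_plus = v_plus, v_minus = v_minus,
                 coupled_corr_mean = coupled_corr_mean,
                 coupled_corr_sd = coupled_corr_sd,
                 background_corr_sd = background_corr_sd,
                 sigma2_range = sigma2_range, noise_model = noise_model,
                 count_mean = count_mean,
                 method_specs = method_specs, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate association scores directly from the score mixture
#'
#' Draws the latent group of each pair from the three-group prior, then the
#' score from a normal with the group mean (psi_plus for "+", 0 otherwise),
#' the group latent variance, and a per-pair measurement-error variance
#' drawn uniformly from `sigma2_range`. True labels are returned for oracle
#' checks.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `mq`, `sigma2`, `group` (one of
#'   `"+", "0", "x"`).
#' @export
simulate_scores <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_pairs
  g <- sample(c("+", "0", "x"), n, replace = TRUE, prob = config$group_probs)
  sigma2 <- stats::runif(n, config$sigma2_range[1], config$sigma2_range[2])
  mu <- ifelse(g == "+", config$psi_plus, 0)
  v <- ifelse(g == "+", config$v_plus, config$v_minus)
  mq <- stats::rnorm(n, mu, sqrt(v + sigma2))
  data.frame(mq = mq, sigma2 = sigma2, group = g, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
platform_transform <- function(z, noise_model, count_mean = 2.5) {
  switch(noise_model,
         gaussian = 6 + 1.5 * z,
         poisson_counts = {
           lam <- exp(log(count_mean) + 0.8 * z)
           matrix(stats::rpois(length(lam), lam), nrow = nrow(z),
                  dimnames = dimnames(z))
         },
         negative_binomial_counts = {
           mu <- exp(log(count_mean) + 0.8 * z)
           matrix(stats::rnbinom(length(mu), mu = mu, size = 4), nrow = nrow(z),
                  dimnames = dimnames(z))
         })
}

#' Simulate two-platform expression data with a labelled true pair map
#'
#' Emulates a proteotranscriptomic study: a primary (protein-like) and a
#' secondary (transcript-like) matrix over the same samples. For "+" pairs
#' the secondary feature is a linear function of the primary latent signal
#' plus noise, calibrated to a target correlation drawn from the configured
#' coupling distribution. "x" pairs are realized by rewiring — the secondary
#' feature is coupled to a *different* primary feature, so mis-mapped
#' features keep realistic marginals while being unrelated to their listed
#' partner; "0" pairs load on nothing but noise. On top of that every pair
#' carries a small nuisance correlation with its listed primary (spread
#' `background_corr_sd`), emulating the global sample-level variation —
#' batch, cellularity, RNA quality — that makes the "\eqn{-}" score
#' component of real data a broad hump rather than a spike at zero. Count
#' noise models push the primary matrix through a sparse Poisson or
#' negative-binomial link for spectral-count realism, which attenuates
#' observed correlations and inflates their bootstrap variances exactly as
#' spectral counting does.
#'
#' @param config a [sim_config()].
#' @return list with `primary` and `secondary` matrices and `true_map` — a
#'   data.frame of `primary_id`, `secondary_id`, `group`, `target_corr`.
#' @export
simulate_two_platform_data <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  n <- config$n_pairs
  ns <- config$n_samples
  primary_ids <- sprintf("PROT%05d", seq_len(n))
  secondary_ids <- sprintf("%05d_s%02d_at", seq_len(n), seq_len(n) %% 89)
  samples <- sprintf("S%03d", seq_len(ns))
  g <- sample(c("+", "0", "x"), n, replace = TRUE, prob = config$group_probs)
  z <- matrix(stats::rnorm(n * ns), n, ns,
              dimnames = list(primary_ids, samples))
  target <- rep(NA_real_, n)
  coupled <- g != "0"
  target[coupled] <- pmin(pmax(
    stats::rnorm(sum(coupled), config$coupled_corr_mean,
                 config$coupled_corr_sd), 0.05), 0.9)
  # nuisance coupling to the listed primary, present for every pair
  bg <- pmin(pmax(stats::rnorm(n, 0, config$background_corr_sd), -0.6), 0.6)
  # donor latent signal: own primary for "+", a rewired wrong primary for "x"
  donor <- seq_len(n)
  if (any(g == "x")) {
    idx <- which(g == "x")
    donor[idx] <- vapply(idx, function(i) {
      j <- sample.int(n, 1L)
      while (j == i) j <- sample.int(n, 1L)
      j
    }, integer(1))
  }
  eps <- matrix(stats::rnorm(n * ns), n, ns)
  zs <- matrix(0, n, ns)
  for (i in seq_len(n)) {
    co_own <- bg[i]
    co_donor <- 0
    if (g[i] == "+") {
      co_own <- min(target[i] + bg[i], 0.95)
    } else if (g[i] == "x") {
      co_donor <- target[i]
    }
    resid <- sqrt(max(1 - co_own^2 - co_donor^2, 0.05))
    zs[i, ] <- co_own * z[i, ] + co_donor * z[donor[i], ] + resid * eps[i, ]
  }
  dimnames(zs) <- list(secondary_ids, samples)
  primary <- platform_transform(z, config$noise_model, config$count_mean)
  dimnames(primary) <- list(primary_ids, samples)
  secondary <- 6 + 1.5 * zs  # microarray-like log-scale signal
  true_map <- data.frame(primary_id = primary_ids,
                         secondary_id = secondary_ids, group = g,
                         target_corr = ifelse(g == "+", target, NA_real_),
                         stringsAsFactors = FALSE)
  list(primary = primary, secondary = secondary, true_map = true_map)
}

#' Simulate candidate ID-mapping methods of controlled quality
#'
#' Each candidate draws `n_pairs * frac_correct` of its pairs uniformly from
#' the correctly mapped pool ("+" and "0") and the remainder from the
#' mis-mapped "x" pool. Uniform sampling from the correct pool gives every
#' method the same expected coupled fraction among its correct pairs — the
#' common-delta-plus condition under which observed proportions of strong
#' correlations rank mapping quality consistently.
#'
#' @param true_map labelled pair map from [simulate_two_platform_data()].
#' @param method_specs list of specs, each `list(name, n_pairs,
#'   frac_correct)`.
#' @param seed integer seed.
#' @return named list of ID maps (data.frames with `primary_id`,
#'   `secondary_id`), one per method.
#' @export
simulate_methods <- function(true_map, method_specs, seed = 1L) {
  nms <- vapply(method_specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("method names must be distinct")
  set.seed(seed)
  correct_pool <- which(true_map$group %in% c("+", "0"))
  wrong_pool <- which(true_map$group == "x")
  out <- lapply(method_specs, function(spec) {
    n_corr <- min(round(spec$n_pairs * spec$frac_correct), length(correct_pool))
    n_wrong <- min(spec$n_pairs - n_corr, length(wrong_pool))
    idx <- c(sample(correct_pool, n_corr), sample(wrong_pool, n_wrong))
    true_map[sort(idx), c("primary_id", "secondary_id"), drop = FALSE]
  })
  names(out) <- nms
  out
}

#' Simulate candidate filter-verdict tables
#'
#' Each filter accepts secondary features of correctly mapped pairs with
#' probability `accept_correct` and features of mis-mapped pairs with
#' probability `accept_wrong`, so better filters are enriched for correct
#' features.
#'
#' @param true_map labelled pair map from [simulate_two_platform_data()].
#' @param filter_specs list of specs, each
#'   `list(name, accept_correct, accept_wrong)`.
#' @param seed integer seed.
#' @return verdict data.frame: `feature_id` plus one logical column per
#'   filter.
#' @export
simulate_filter_verdicts <- function(true_map, filter_specs, seed = 1L) {
  set.seed(seed)
  correct <- true_map$group %in% c("+", "0")
  out <- data.frame(feature_id = true_map$secondary_id,
                    stringsAsFactors = FALSE)
  for (spec in filter_specs) {
    p <- ifelse(correct, spec$accept_correct, spec$accept_wrong)
    out[[spec$name]] <- stats::runif(nrow(out)) < p
  }
  out
}

#' Simulate a tandem-MS spectral event table
#'
#' Generates per-event records (protein, sample, two quality scores such as
#' XCorr and DeltaCn) on top of a two-platform simulation. Genuine events
#' follow the latent protein abundance and carry high quality scores; a
#' configurable fraction of events are mis-assigned — counted toward a
#' random wrong protein — and carry low scores, so quantile filtering on the
#' scores removes mostly mis-assignments and improves cross-platform
#' coupling.
#'
#' @param config a [sim_config()] (the count link is forced to Poisson for
#'   the genuine events).
#' @param noise_fraction fraction of all events that are mis-assigned
#'   low-quality events (default 0.3).
#' @param mean_events mean genuine events per (protein, sample) at average
#'   abundance (default 6).
#' @return list of class `"event_sim"`: `events` (data.frame `protein_id`,
#'   `sample_id`, `score_1`, `score_2`), `secondary` matrix, `pairs` (pooled
#'   pair set, single method `"All"`), `true_map`, and `true_counts` — the
#'   genuine-event count matrix before mis-assignment.
#' @export
simulate_event_table <- function(config = sim_config(), noise_fraction = 0.3,
                                 mean_events = 6) {
  stopifnot(noise_fraction >= 0, noise_fraction < 1)
  # count realism enters through the events themselves; the base simulation
  # stays on the latent gaussian scale
  config$noise_model <- "gaussian"
  sim <- simulate_two_platform_data(config)
  set.seed(config$seed + 2L)
  n <- nrow(sim$true_map); ns <- config$n_samples
  proteins <- sim$true_map$primary_id
  samples <- colnames(sim$primary)
  # latent abundance recovered from the gaussian primary scale
  z <- (sim$primary - 6) / 1.5
  lam <- mean_events * exp(0.5 * z)
  counts <- matrix(stats::rpois(n * ns, lam), n, ns,
                   dimnames = list(proteins, samples))
  idx <- which(counts > 0, arr.ind = TRUE)
  good <- data.frame(
    protein_id = proteins[rep(idx[, 1], counts[idx])],
    sample_id = samples[rep(idx[, 2], counts[idx])],
    stringsAsFactors = FALSE)
  n_good <- nrow(good)
  good$score_1 <- stats::rnorm(n_good, 3.0, 0.5)
  good$score_2 <- stats::rnorm(n_good, 0.35, 0.06)
  n_noise <- round(noise_fraction / (1 - noise_fraction) * n_good)
  if (n_noise > 0) {
    noise <- data.frame(
      protein_id = proteins[sample.int(n, n_noise, replace = TRUE)],
      sample_id = samples[sample.int(ns, n_noise, replace = TRUE)],
      score_1 = stats::rnorm(n_noise, 1.2, 0.15),
      score_2 = stats::rnorm(n_noise, 0.10, 0.02),
      stringsAsFactors = FALSE)
    events <- rbind(good, noise)
  } else {
    events <- good
  }
  events <- events[sample.int(nrow(events)), , drop = FALSE]
  rownames(events) <- NULL
  pairs <- pool_pairs(list(All = sim$true_map[, c("primary_id",
                                                  "secondary_id")]))
  structure(list(events = events, secondary = sim$secondary, pairs = pairs,
                 true_map = sim$true_map, true_counts = counts,
                 config = config),
            class = "event_sim")
}

#' Materialize a complete synthetic demo workspace on disk
#'
#' Writes, under `dir`: the two expression matrices, one ID-map file per
#' candidate method, the labelled truth table, a filter-verdict table, the
#' spectral event table, and a config echo — everything the pipeline verbs
#' read.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param noise_fraction passed to [simulate_event_table()].
#' @return `dir`, invisibly.
#' @export
make_fixture_workspace <- function(dir, config = sim_config(),
                                   noise_fraction = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_platform_data(config)
  write_expression_matrix(sim$primary, file.path(dir, "primary.tsv"))
  write_expression_matrix(sim$secondary, file.path(dir, "secondary.tsv"))
  maps <- simulate_methods(sim$true_map, config$method_specs,
                           seed = config$seed + 3L)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  for (m in names(maps)) {
    write_id_map(maps[[m]], file.path(dir, "maps", paste0(m, ".tsv")))
  }
  utils::write.table(sim$true_map, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  verdicts <- simulate_filter_verdicts(
    sim$true_map,
    list(list(name = "strict", accept_correct = 0.8, accept_wrong = 0.2),
         list(name = "lenient", accept_correct = 0.95, accept_wrong = 0.7)),
    seed = config$seed + 4L)
  utils::write.table(
    data.frame(feature_id = verdicts$feature_id,
               lapply(verdicts[-1], as.integer), check.names = FALSE),
    file.path(dir, "verdicts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ev <- simulate_event_table(config, noise_fraction = noise_fraction)
  utils::write.table(ev$events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$method_specs <- lapply(cfg$method_specs, unclass)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
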