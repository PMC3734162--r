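test_that("the weighted proportion is a precision-weighted convex combination", {
  # equal variances: plain mean
  rec <- data.frame(post_plus = c(0.2, 0.4, 0.9), post_var = 0.05)
  expect_equal(weighted_p_plus(rec), mean(rec$post_plus))
  # hand computation with two records
  rec2 <- data.frame(post_plus = c(0.9, 0.1), post_var = c(0.01, 1.0))
  expect_equal(weighted_p_plus(rec2), (0.9 / 0.01 + 0.1 / 1) / (1 / 0.01 + 1),
               tolerance = 1e-12)
  # single record
  expect_equal(weighted_p_plus(data.frame(post_plus = 0.7, post_var = 0.2)),
               0.7)
  # convexity: always inside the member range
  set.seed(3)
  for (i in 1:10) {
    rec3 <- data.frame(post_plus = runif(20), post_var = rexp(20, 10))
    w <- weighted_p_plus(rec3)
    expect_gte(w, min(rec3$post_plus))
    expect_lte(w, max(rec3$post_plus))
  }
  # zero-variance records stay finite and dominate at the weight cap only
  rec4 <- data.frame(post_plus = c(1, rep(0.4, 9)),
                     post_var = c(0, rep(0.01, 9)))
  w4 <- weighted_p_plus(rec4)
  expect_true(is.finite(w4) && w4 < 1 && w4 > 0.4)
  expect_error(weighted_p_plus(rec4[0, ]), "no records")
})

test_that("per-pair expected utility reproduces the published comparison arithmetic", {
  params <- utility_params(u_tp = 2, l_fp = 1, delta_plus = 1)
  expect_equal(round(eu_mean(0.431, params), 3), 0.293)
  expect_equal(round(eu_mean(0.493, params), 3), 0.479)
  expect_equal(round(eu_total(887, eu_mean(0.431, params))), 260)
  expect_equal(round(eu_total(1434, eu_mean(0.330, params))), -14)
  expect_equal(eu_total(0, eu_mean(0.9, params)), 0)
})

test_that("the break-even proportion zeroes the expected utility", {
  params <- utility_params(u_tp = 2, l_fp = 1)
  expect_equal(break_even(params), 1 / 3)
  expect_equal(break_even(utility_params(u_tp = 1, l_fp = 1)), 0.5)
  set.seed(10)
  for (i in 1:10) {
    pr <- utility_params(u_tp = runif(1, 0.1, 5), l_fp = runif(1, 0.1, 5))
    expect_equal(eu_mean(break_even(pr), pr), 0, tolerance = 1e-12)
  }
})

test_that("the coupled-fraction adjustment reduces to the simple utility at delta = 1", {
  set.seed(11)
  for (i in 1:25) {
    u <- runif(1, 0.1, 5); l <- runif(1, 0.1, 5); p <- runif(1)
    expect_equal(eu_mean(p, utility_params(u, l, delta_plus = 1)),
                 u * p - l * (1 - p), tolerance = 1e-14)
    # increasing linear in p whenever the utility outweighs the
    # delta-discounted loss (u > l(1 - 2 delta); always true at u >= l)
    d <- runif(1, 0.1, 1)
    if (u > l * (1 - 2 * d)) {
      pr <- utility_params(u, l, d)
      expect_gt(eu_mean(p + 1e-3, pr), eu_mean(p, pr))
    }
  }
})

test_that("method evaluation tables are internally consistent and rank by composition", {
  fit <- quick_fit()
  scores <- data.frame(mq = fit$data$mq, sigma2 = fit$data$sigma2)
  post <- posterior_table(scores, fit)
  n <- nrow(post)
  sets <- list(all = rep(TRUE, n), half = seq_len(n) <= n / 2)
  ev <- evaluate_methods(post, method_sets = sets)
  # the full-pool method equals the Use All row
  expect_equal(ev$p_plus[ev$method == "all"],
               ev$p_plus[ev$method == "Use All"], tolerance = 1e-12)
  expect_equal(ev$eu_total[ev$method == "all"],
               ev$eu_total[ev$method == "Use All"], tolerance = 1e-12)
  # identity eu_total = n_pairs * eu_mean pre-rounding
  expect_equal(ev$eu_total, ev$n_pairs * ev$eu_mean, tolerance = 1e-12)
  # weighted proportion inside the member posterior range
  expect_true(all(ev$p_plus >= 0 & ev$p_plus <= 1))
  # empty set warns and yields a zero row
  expect_warning(ev0 <- evaluate_methods(post,
                                         method_sets = list(none = rep(FALSE, n)),
                                         include_all = FALSE), "empty")
  expect_identical(ev0$n_pairs, 0L)

  # a set enriched for truly coupled pairs must outrank a noise-enriched set
  sim <- simulate_scores(sim_config(n_pairs = 2000, seed = 44))
  fit2 <- mq_mixture(sim$mq, sim$sigma2)
  post2 <- posterior_table(sim[, c("mq", "sigma2")], fit2)
  good <- sim$group == "+"
  mixed <- c(which(good)[1:200], which(!good)[1:600])
  pure <- which(good)[201:800]
  ev2 <- evaluate_methods(post2,
                          method_sets = list(enriched = seq_len(2000) %in% pure,
                                             diluted = seq_len(2000) %in% mixed),
                          include_all = FALSE)
  expect_gt(ev2$eu_mean[ev2$method == "enriched"],
            ev2$eu_mean[ev2$method == "diluted"])
})

test_that("scaling both utilities rescales expected utility but never the ranking", {
  fit <- quick_fit()
  post <- posterior_table(data.frame(mq = fit$data$mq,
                                     sigma2 = fit$data$sigma2), fit)
  n <- nrow(post)
  set.seed(13)
  sets <- lapply(1:4, function(i) runif(n) < runif(1, 0.3, 0.8))
  names(sets) <- paste0("M", 1:4)
  ev1 <- evaluate_methods(post, sets, params = utility_params(2, 1))
  ev2 <- evaluate_methods(post, sets, params = utility_params(2 * 7.3, 7.3))
  expect_identical(order(ev1$eu_mean), order(ev2$eu_mean))
  expect_identical(order(ev1$eu_total), order(ev2$eu_total))
  expect_equal(ev2$eu_mean, 7.3 * ev1$eu_mean, tolerance = 1e-10)
})

test_that("Boolean method combinations agree with a set-operation oracle", {
  set.seed(19)
  n <- 60
  pairs <- data.frame(primary_id = sprintf("p%d", 1:n),
                      secondary_id = sprintf("s%d", 1:n),
                      N = runif(n) < 0.5, E = runif(n) < 0.5,
                      D = runif(n) < 0.5)
  attr(pairs, "methods") <- c("N", "E", "D")
  sets <- boolean_method_sets(pairs, c("N and E and D", "N and E", "N or E",
                                       "N or E or D", "E and not D"))
  # brute-force oracle via set operations on row indices
  iN <- which(pairs$N); iE <- which(pairs$E); iD <- which(pairs$D)
  expect_identical(which(sets[["N and E"]]), intersect(iN, iE))
  expect_identical(which(sets[["N or E"]]), sort(union(iN, iE)))
  expect_identical(which(sets[["E and not D"]]), setdiff(iE, iD))
  # nesting chain
  expect_true(all(sets[["N and E and D"]] <= sets[["N and E"]]))
  expect_true(all(sets[["N and E"]] <= sets[["N or E"]]))
  expect_true(all(sets[["N or E"]] <= sets[["N or E or D"]]))
  # disjoint methods intersect to nothing
  pairs2 <- pairs
  pairs2$E <- !pairs2$N
  pairs2$D <- FALSE
  attr(pairs2, "methods") <- c("N", "E", "D")
  expect_identical(sum(boolean_method_sets(pairs2, "N and E")[[1]]), 0L)
  expect_error(boolean_method_sets(pairs, "N and Q"), "unknown")
})
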