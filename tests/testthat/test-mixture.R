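test_that("the ECM fit resolves clean two-point data", {
  set.seed(17)
  n <- 400
  mq <- c(rnorm(n / 2, 0, 1e-3), rnorm(n / 2, 0.6, 1e-3))
  fit <- mq_mixture(mq, sigma2 = 0)
  expect_equal(fit$psi_plus, 0.6, tolerance = 0.01)
  expect_equal(fit$pi_plus, 0.5, tolerance = 0.02)
  expect_lt(fit$v_plus, 1e-4)
  expect_lt(fit$v_minus, 1e-4)
  expect_true(fit$converged)
})

test_that("the observed-data log-likelihood ascends at every ECM iteration", {
  for (s in c(2, 9, 23)) {
    sim <- simulate_scores(sim_config(n_pairs = 400, seed = s))
    fit <- mq_mixture(sim$mq, sim$sigma2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 * (1 + abs(fit$loglik))))
    # and the fit improves on its deterministic initialization
    expect_gte(fit$loglik, fit$loglik_trace[1])
  }
})

test_that("the posterior probability equals a directly coded Bayes-rule oracle", {
  fit <- quick_fit()
  # independent oracle: plain Bayes rule on component densities
  oracle <- function(mq, s2) {
    f1 <- dnorm(mq, fit$psi_plus, sqrt(fit$v_plus + s2))
    f0 <- dnorm(mq, 0, sqrt(fit$v_minus + s2))
    fit$pi_plus * f1 / (fit$pi_plus * f1 + (1 - fit$pi_plus) * f0)
  }
  set.seed(4)
  mq <- runif(100, -0.9, 0.9)
  s2 <- runif(100, 0, 0.05)
  expect_equal(posterior_probability(mq, s2, fit), oracle(mq, s2),
               tolerance = 1e-12)
  # symmetry: equal priors and variances, score midway between the means
  sym <- fit
  sym$pi_plus <- 0.5; sym$v_plus <- sym$v_minus <- 0.02; sym$psi_plus <- 0.5
  expect_equal(posterior_probability(0.25, 0, sym), 0.5, tolerance = 1e-12)
  # limits saturate cleanly
  expect_equal(posterior_probability(50, 0.01, sym), 1)
  expect_equal(posterior_probability(-50, 0.01, sym), 0)
})

test_that("the delta-method posterior variance matches a finite-difference oracle", {
  fit <- quick_fit()
  set.seed(6)
  mq <- runif(40, -0.5, 0.7)
  s2 <- runif(40, 0.001, 0.05)
  h <- 1e-6
  dp <- (posterior_probability(mq + h, s2, fit) -
           posterior_probability(mq - h, s2, fit)) / (2 * h)
  v_fd <- s2 * dp^2
  v <- posterior_variance(mq, s2, fit)
  expect_equal(v, v_fd, tolerance = 1e-6)
  # structural zeros
  expect_equal(posterior_variance(0.3, 0, fit), 0)
  crossing <- fit$psi_plus * (fit$v_minus) / (fit$v_minus - fit$v_plus)
  if (is.finite(crossing)) {
    b <- crossing / (fit$v_minus) - (crossing - fit$psi_plus) / (fit$v_plus)
    expect_equal(b, 0, tolerance = 1e-8)
  }
  expect_true(all(posterior_variance(mq, s2, fit) >= 0))
})

test_that("posterior probability is monotone in the score when the variances are equal", {
  fit <- quick_fit()
  eq <- fit
  eq$v_plus <- eq$v_minus <- 0.02
  grid <- seq(-1, 1, length.out = 201)
  p <- posterior_probability(grid, 0.01, eq)
  expect_true(all(diff(p) > 0))
})

test_that("a large measurement variance washes out the score and kills the posterior variance", {
  fit <- quick_fit()
  s2 <- 10^seq(-2, 3, length.out = 30)
  p <- posterior_probability(0.6, s2, fit)
  # limit is set by the prior odds and the variance ratio, not the score
  lim <- tail(p, 1)
  expect_lt(abs(p[length(p)] - p[length(p) - 1]), 1e-4)
  expect_gt(abs(p[1] - lim), 0.05)
  # the bracket decays like 1/sigma2, so the posterior variance vanishes
  v <- posterior_variance(0.6, s2, fit)
  expect_lt(tail(v, 1), max(v) / 100)
  expect_lt(tail(v, 1), 1e-4)
  expect_true(all(diff(v[s2 > 1]) < 0))
})

test_that("posterior tables are self-consistent under the fitted model", {
  fit <- quick_fit()
  scores <- data.frame(mq = fit$data$mq, sigma2 = fit$data$sigma2)
  post <- posterior_table(scores, fit)
  expect_identical(nrow(post), nrow(scores))
  expect_true(all(post$post_var >= 0))
  expect_true(all(post$post_plus >= 0 & post$post_plus <= 1))
  # law of total probability: mean posterior tracks the prior weight on
  # data simulated from the fitted model, improving with size
  errs <- vapply(c(500, 2000, 8000), function(n) {
    sim <- simulate(fit, seed = n, sigma2 = rep(0.01, n))
    abs(mean(posterior_probability(sim$mq, sim$sigma2, fit)) - fit$pi_plus)
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("reflected (negative-coupling) fits mirror the standard fit", {
  sim <- simulate_scores(sim_config(n_pairs = 1000, seed = 12))
  fit_pos <- mq_mixture(sim$mq, sim$sigma2)
  fit_neg <- mq_mixture(-sim$mq, sim$sigma2, negative_coupling = TRUE)
  expect_equal(fit_neg$psi_plus, fit_pos$psi_plus, tolerance = 1e-6)
  expect_equal(fit_neg$loglik, fit_pos$loglik, tolerance = 1e-6)
  expect_equal(posterior_probability(-0.5, 0.01, fit_neg),
               posterior_probability(0.5, 0.01, fit_pos), tolerance = 1e-10)
})

test_that("mixture fits serialize to JSON and back", {
  fit <- quick_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_mixture_fit(fit, path)
  back <- read_mixture_fit(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_identical(back$converged, fit$converged)
  set.seed(1); mq <- runif(20, -1, 1); s2 <- runif(20, 0, 0.05)
  expect_equal(posterior_probability(mq, s2, back),
               posterior_probability(mq, s2, fit), tolerance = 1e-12)
})

test_that("model-object methods behave like standard fitted models", {
  fit <- quick_fit()
  expect_named(coef(fit), c("psi_plus", "pi_plus", "v_minus", "v_plus"))
  expect_s3_class(logLik(fit), "logLik")
  expect_identical(attr(logLik(fit), "df"), 4L)
  expect_output(print(fit), "ECM")
  expect_output(print(summary(fit)), "Posterior")
  p <- predict(fit, data.frame(mq = c(0, 0.5), sigma2 = c(0.01, 0.01)))
  expect_lt(p[1], p[2])
  d <- predict(fit, data.frame(mq = 0.2, sigma2 = 0.01), type = "density")
  expect_gt(d, 0)
  expect_identical(length(residuals(fit)), fit$n)
  expect_error(mq_mixture(rnorm(5)), "at least")
})
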