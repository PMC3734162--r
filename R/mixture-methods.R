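#' @export
print.mq_mixture <- function(x, digits = 4, ...) {
  cat("Two-component measurement-error mixture (ECM fit)\n")
  cat("  scores:", x$n, "  iterations:", x$n_iter,
      if (x$converged) " (converged)\n" else " (NOT converged)\n")
  print(round(coef(x), digits))
  cat("log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  if (x$negative_coupling) cat("(scores reflected: negative coupling)\n")
  invisible(x)
}

#' @export
coef.mq_mixture <- function(object, ...) {
  c(psi_plus = object$psi_plus, pi_plus = object$pi_plus,
    v_minus = object$v_minus, v_plus = object$v_plus)
}

#' @export
logLik.mq_mixture <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = object$n, class = "logLik")
}

#' @export
summary.mq_mixture <- function(object, ...) {
  p <- if (!is.null(object$data)) {
    posterior_probability(
      if (object$negative_coupling) -object$data$mq else object$data$mq,
      object$data$sigma2, object)
  } else NULL
  structure(list(fit = object, post = p), class = "summary.mq_mixture")
}

#' @export
print.summary.mq_mixture <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$post)) {
    cat("\nPosterior Pr(+) over the training scores:\n")
    print(round(summary(x$post), digits))
    cat("expected number of correctly coupled pairs:",
        round(sum(x$post), 1), "of", x$fit$n, "\n")
  }
  invisible(x)
}

#' Posterior predictions from a fitted score mixture
#'
#' @param object an [mq_mixture()] fit.
#' @param newdata optional data.frame with columns `mq` and `sigma2`;
#'   defaults to the training scores.
#' @param type `"posterior"` for the plug-in posterior probability of the
#'   "+" group, `"variance"` for its delta-method variance, `"density"` for
#'   the marginal mixture density at the scores.
#' @param ... unused.
#' @return numeric vector, one value per row of `newdata`.
#' @export
predict.mq_mixture <- function(object, newdata = NULL,
                               type = c("posterior", "variance", "density"),
                               ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("fit carries no data; supply newdata")
    mq <- object$data$mq
    if (object$negative_coupling) mq <- -mq  # undo internal reflection
    sigma2 <- object$data$sigma2
  } else {
    mq <- newdata$mq
    sigma2 <- newdata$sigma2
  }
  switch(type,
         posterior = posterior_probability(mq, sigma2, object),
         variance = posterior_variance(mq, sigma2, object),
         density = {
           mq_w <- if (object$negative_coupling) -mq else mq
           s2 <- rep_len(as.numeric(sigma2), length(mq_w))
           object$pi_plus *
             stats::dnorm(mq_w, object$psi_plus,
                          sqrt(pmax(object$v_plus + s2, 1e-12))) +
             (1 - object$pi_plus) *
             stats::dnorm(mq_w, 0, sqrt(pmax(object$v_minus + s2, 1e-12)))
         })
}

#' Simulate scores from a fitted mixture
#'
#' Draws group labels from the fitted prior and scores from the fitted
#' component distributions, using the training (or supplied) per-pair
#' measurement-error variances — the parametric-bootstrap counterpart of the
#' fit.
#'
#' @param object an [mq_mixture()] fit.
#' @param nsim number of replicate score sets.
#' @param seed optional integer seed.
#' @param sigma2 measurement-error variances to simulate under; defaults to
#'   the training values.
#' @param ... unused.
#' @return data.frame with columns `sim`, `mq`, `sigma2`, `group`.
#' @export
simulate.mq_mixture <- function(object, nsim = 1, seed = NULL, sigma2 = NULL,
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma2)) {
    if (is.null(object$data)) stop("fit carries no data; supply sigma2")
    sigma2 <- object$data$sigma2
  }
  n <- length(sigma2)
  out <- lapply(seq_len(nsim), function(s) {
    plus <- stats::runif(n) < object$pi_plus
    mu <- ifelse(plus, object$psi_plus, 0)
    v <- ifelse(plus, object$v_plus, object$v_minus)
    mq <- stats::rnorm(n, mu, sqrt(pmax(v + sigma2, 1e-12)))
    if (object$negative_coupling) mq <- -mq
    data.frame(sim = s, mq = mq, sigma2 = sigma2,
               group = ifelse(plus, "+", "-"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
residuals.mq_mixture <- function(object, ...) {
  if (is.null(object$data)) stop("fit carries no data")
  mq <- object$data$mq
  p <- stats::plogis(log(object$pi_plus) - log1p(-object$pi_plus) +
    stats::dnorm(mq, object$psi_plus,
                 sqrt(pmax(object$v_plus + object$data$sigma2, 1e-12)),
                 log = TRUE) -
    stats::dnorm(mq, 0,
                 sqrt(pmax(object$v_minus + object$data$sigma2, 1e-12)),
                 log = TRUE))
  # raw score minus its posterior-weighted component mean
  mq - p * object$psi_plus
}

#' Diagnostic plot of a fitted score mixture
#'
#' Histogram of the observed scores overlaid with the fitted marginal mixture
#' density (averaged over the per-pair measurement variances) and its two
#' weighted components.
#'
#' @param x an [mq_mixture()] fit.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.mq_mixture <- function(x, ...) {
  if (is.null(x$data)) stop("fit carries no data")
  mq <- x$data$mq
  graphics::hist(mq, breaks = 40, freq = FALSE,
                 main = "Score mixture fit", xlab = "association score (MQ)",
                 border = "grey70", ...)
  grid <- seq(min(mq) - 0.1, max(mq) + 0.1, length.out = 300)
  s2 <- x$data$sigma2
  comp <- function(mu, v, w) {
    vapply(grid, function(g) {
      w * mean(stats::dnorm(g, mu, sqrt(pmax(v + s2, 1e-12))))
    }, numeric(1))
  }
  d_plus <- comp(x$psi_plus, x$v_plus, x$pi_plus)
  d_minus <- comp(0, x$v_minus, 1 - x$pi_plus)
  graphics::lines(grid, d_plus + d_minus, lwd = 2)
  graphics::lines(grid, d_minus, lty = 2, col = "firebrick")
  graphics::lines(grid, d_plus, lty = 3, col = "forestgreen")
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3), lwd = c(2, 1, 1),
                   col = c("black", "firebrick", "forestgreen"),
                   legend = c("mixture", "decoupled/mismapped (-)",
                              "coupled (+)"))
  invisible(x)
}
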