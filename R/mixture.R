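#' Constrained two-component mixture for pair association scores
#'
#' Fits, by an expectation-conditional-maximization (ECM) algorithm, the
#' measurement-error mixture underlying the mapping-evaluation paradigm: each
#' pair's observed score is
#' \deqn{MQ_p \sim N(\psi_{G(p)},\; V_{G(p)} + \sigma^2_p)}
#' where the latent group \eqn{G(p)} is "+" (correctly mapped and coupled,
#' prior weight \eqn{\pi_+}, mean \eqn{\psi_+}, latent variance \eqn{V_+})
#' or "\eqn{-}" (decoupled or mis-mapped, weight \eqn{1-\pi_+}, mean
#' constrained to 0, pooled latent variance \eqn{V_-}), and \eqn{\sigma^2_p}
#' is the known (bootstrap-estimated) measurement-error variance of pair
#' \eqn{p}. The "0" (decoupled) and "x" (mis-mapped) groups are empirically
#' indistinguishable from one data set and are pooled into "\eqn{-}".
#'
#' The E-step computes responsibilities from the current parameters; the
#' CM-steps update \eqn{\pi_+} (mean responsibility) and \eqn{\psi_+}
#' (responsibility- and precision-weighted mean) in closed form, then
#' \eqn{V_+} and \eqn{V_-} each by one-dimensional bounded maximization of
#' the expected complete-data log-likelihood — no closed form exists under
#' heteroscedastic \eqn{\sigma^2_p}. Every cycle ascends the observed-data
#' log-likelihood.
#'
#' @param mq numeric vector of association scores, or a data.frame carrying
#'   columns `mq` and `sigma2` (e.g. the output of [score_all_pairs()]).
#' @param sigma2 numeric vector of per-pair measurement-error variances
#'   (recycled if scalar); ignored when `mq` is a data.frame.
#' @param init optional named list with starting values `psi_plus`,
#'   `pi_plus`, `v_plus`, `v_minus`. By default \eqn{\pi_+} starts at the
#'   fraction of scores above 0.25, \eqn{\psi_+} at their mean, and both
#'   variances at `max(var(mq) - mean(sigma2), 1e-4)`.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum ECM cycles (default 2000).
#' @param min_scores minimum number of scores required (default 20).
#' @param negative_coupling set `TRUE` when correct mappings manifest as
#'   strong *negative* association (e.g. microRNA vs target transcript);
#'   scores are reflected before fitting and the fit records the reflection.
#' @param v_max upper bound for the latent variances in the CM line searches.
#' @param fisher_z model Fisher z-transformed scores instead of raw
#'   correlations (off by default; the raw-correlation scale is the working
#'   scale of the paradigm).
#' @return an object of class `"mq_mixture"`: list with elements `psi_plus`,
#'   `pi_plus`, `v_plus`, `v_minus`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `n`, the (possibly reflected/transformed) `data`, and the
#'   call.
#' @seealso [posterior_probability()], [posterior_table()],
#'   [predict.mq_mixture()], [simulate.mq_mixture()]
#' @examples
#' set.seed(1)
#' sim <- simulate_scores(sim_config(n_pairs = 400, seed = 1))
#' fit <- mq_mixture(sim$mq, sim$sigma2)
#' coef(fit)
#' @export
mq_mixture <- function(mq, sigma2 = 0, init = NULL, tol = 1e-8,
                       max_iter = 2000, min_scores = 20,
                       negative_coupling = FALSE, v_max = 10,
                       fisher_z = FALSE) {
  cl <- match.call()
  if (is.data.frame(mq)) {
    if (!all(c("mq", "sigma2") %in% names(mq))) {
      stop("data.frame input must carry columns 'mq' and 'sigma2'")
    }
    sigma2 <- mq$sigma2
    mq <- mq$mq
  }
  mq <- as.numeric(mq)
  sigma2 <- rep_len(as.numeric(sigma2), length(mq))
  if (length(mq) < min_scores) {
    stop("need at least ", min_scores, " scores to fit the mixture")
  }
  if (!all(is.finite(mq)) || !all(is.finite(sigma2)) || any(sigma2 < 0)) {
    stop("scores and variances must be finite, variances nonnegative")
  }
  if (negative_coupling) mq <- -mq
  if (fisher_z) {
    mq <- atanh(pmin(pmax(mq, -1 + 1e-12), 1 - 1e-12))
  }

  if (is.null(init)) {
    hi <- mq > 0.25
    pi0 <- min(max(mean(hi), 0.05), 0.95)
    psi0 <- if (any(hi)) mean(mq[hi]) else 0.3
    v0 <- max(stats::var(mq) - mean(sigma2), 1e-4)
    init <- list(psi_plus = psi0, pi_plus = pi0, v_plus = v0, v_minus = v0)
  }
  psi <- init$psi_plus; pi_p <- init$pi_plus
  vp <- init$v_plus; vm <- init$v_minus

  floor_v <- 1e-12
  obs_ll <- function(psi, pi_p, vp, vm) {
    l1 <- stats::dnorm(mq, psi, sqrt(pmax(vp + sigma2, floor_v)), log = TRUE)
    l0 <- stats::dnorm(mq, 0, sqrt(pmax(vm + sigma2, floor_v)), log = TRUE)
    a <- log(pi_p) + l1
    b <- log1p(-pi_p) + l0
    m <- pmax(a, b)
    sum(m + log(exp(a - m) + exp(b - m)))
  }

  ll <- obs_ll(psi, pi_p, vp, vm)
  if (!is.finite(ll)) stop("non-finite likelihood at initialization")
  trace <- ll
  converged <- FALSE
  iter <- 0L
  # expected complete-data contribution of one component in its variance;
  # weights w are responsibilities (or their complement), mean mu fixed
  q_component <- function(v, w, mu) {
    tau <- pmax(v + sigma2, floor_v)
    -0.5 * sum(w * (log(tau) + (mq - mu)^2 / tau))
  }
  for (iter in seq_len(max_iter)) {
    # E-step
    l1 <- stats::dnorm(mq, psi, sqrt(pmax(vp + sigma2, floor_v)), log = TRUE)
    l0 <- stats::dnorm(mq, 0, sqrt(pmax(vm + sigma2, floor_v)), log = TRUE)
    r <- stats::plogis(log(pi_p) - log1p(-pi_p) + l1 - l0)
    # CM-steps
    pi_p <- min(max(mean(r), 1e-10), 1 - 1e-10)
    wp <- r / pmax(vp + sigma2, floor_v)
    psi <- sum(wp * mq) / sum(wp)
    op <- stats::optimize(q_component, c(0, v_max), w = r, mu = psi,
                          maximum = TRUE, tol = 1e-10)
    vp <- if (q_component(0, r, psi) >= op$objective) 0 else op$maximum
    om <- stats::optimize(q_component, c(0, v_max), w = 1 - r, mu = 0,
                          maximum = TRUE, tol = 1e-10)
    vm <- if (q_component(0, 1 - r, 0) >= om$objective) 0 else om$maximum

    ll_new <- obs_ll(psi, pi_p, vp, vm)
    if (!is.finite(ll_new)) stop("non-finite likelihood during ECM")
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    warning("ECM did not converge in ", max_iter, " iterations")
  }
  structure(list(psi_plus = psi, pi_plus = pi_p, v_plus = vp, v_minus = vm,
                 loglik = ll, loglik_trace = trace, n_iter = iter,
                 converged = converged, n = length(mq),
                 negative_coupling = negative_coupling, fisher_z = fisher_z,
                 data = list(mq = mq, sigma2 = sigma2), call = cl),
            class = "mq_mixture")
}

#' Posterior probability of correct, coupled mapping
#'
#' Empirical-Bayes plug-in posterior for membership in the "+" component:
#' prior odds \eqn{\hat\pi_+/\hat\pi_-} times the ratio of the two normal
#' densities \eqn{N(mq;\hat\psi_+, \hat V_+ + \sigma^2)} and
#' \eqn{N(mq; 0, \hat V_- + \sigma^2)}, computed in log space.
#'
#' @param mq numeric vector of association scores (on the scale the fit was
#'   trained on; reflection/z-transform applied automatically).
#' @param sigma2 measurement-error variances (recycled).
#' @param fit an [mq_mixture()] fit.
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_probability <- function(mq, sigma2, fit) {
  stopifnot(inherits(fit, "mq_mixture"))
  n <- max(length(mq), length(sigma2))
  mq <- rep_len(as.numeric(mq), n)
  sigma2 <- rep_len(as.numeric(sigma2), n)
  if (fit$negative_coupling) mq <- -mq
  if (fit$fisher_z) mq <- atanh(pmin(pmax(mq, -1 + 1e-12), 1 - 1e-12))
  floor_v <- 1e-12
  l1 <- stats::dnorm(mq, fit$psi_plus,
                     sqrt(pmax(fit$v_plus + sigma2, floor_v)), log = TRUE)
  l0 <- stats::dnorm(mq, 0, sqrt(pmax(fit$v_minus + sigma2, floor_v)),
                     log = TRUE)
  stats::plogis(log(fit$pi_plus) - log1p(-fit$pi_plus) + l1 - l0)
}

#' Delta-method variance of the posterior probability
#'
#' Converts the bootstrap estimate of the score's sampling variance into a
#' variance for the posterior probability:
#' \deqn{v^*_{+p} = \sigma^2_p\,(\pi^*_{+p}\pi^*_{-p})^2
#'   \left[\frac{mq_p - \hat\psi_-}{\hat V_- + \sigma^2_p}
#'       - \frac{mq_p - \hat\psi_+}{\hat V_+ + \sigma^2_p}\right]^2}
#' with \eqn{\hat\psi_- = 0}. A large measurement variance drives the
#' bracket, hence the posterior variance, toward zero: such a pair carries
#' little information and its posterior is insensitive to the score.
#'
#' @inheritParams posterior_probability
#' @return nonnegative variances of the posterior probabilities.
#' @export
posterior_variance <- function(mq, sigma2, fit) {
  stopifnot(inherits(fit, "mq_mixture"))
  n <- max(length(mq), length(sigma2))
  mq <- rep_len(as.numeric(mq), n)
  sigma2 <- rep_len(as.numeric(sigma2), n)
  p <- posterior_probability(mq, sigma2, fit)
  mq_w <- if (fit$negative_coupling) -mq else mq
  if (fit$fisher_z) mq_w <- atanh(pmin(pmax(mq_w, -1 + 1e-12), 1 - 1e-12))
  floor_v <- 1e-12
  bracket <- (mq_w - 0) / pmax(fit$v_minus + sigma2, floor_v) -
    (mq_w - fit$psi_plus) / pmax(fit$v_plus + sigma2, floor_v)
  sigma2 * (p * (1 - p))^2 * bracket^2
}

#' Posterior table for a score set
#'
#' One row per scored pair: the score, its measurement-error variance, the
#' plug-in posterior probability of correct coupled mapping and its
#' delta-method variance, plus the per-method flags and the `1/post_var`
#' weights (useful for downstream weighted regressions).
#'
#' @param scores score table from [score_all_pairs()] (any data.frame with
#'   `mq` and `sigma2` columns works).
#' @param fit an [mq_mixture()] fit.
#' @return data.frame with columns of `scores` plus `post_plus`, `post_var`
#'   and `weight`; attribute `"methods"` carried over.
#' @export
posterior_table <- function(scores, fit) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0)
  out <- scores
  out$post_plus <- posterior_probability(scores$mq, scores$sigma2, fit)
  out$post_var <- posterior_variance(scores$mq, scores$sigma2, fit)
  pos <- out$post_var[out$post_var > 0]
  out$weight <- if (length(pos)) {
    1 / pmax(out$post_var, min(pos))
  } else {
    rep(1, nrow(out))
  }
  structure(out, methods = attr(scores, "methods"))
}

#' Serialize / restore a mixture fit
#'
#' Flat JSON with the parameter estimates and fit diagnostics — enough to
#' reuse a frozen fit (e.g. in the quality-threshold sweep, which rescores
#' the data but keeps the original mixture).
#'
#' @param fit an [mq_mixture()] fit.
#' @param path file path.
#' @return `path` (writer); an `"mq_mixture"` object without training data
#'   (reader).
#' @export
write_mixture_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mq_mixture"))
  obj <- list(psi_plus = fit$psi_plus, pi_plus = fit$pi_plus,
              v_plus = fit$v_plus, v_minus = fit$v_minus,
              loglik = fit$loglik, n_iter = fit$n_iter,
              converged = fit$converged, n = fit$n,
              negative_coupling = fit$negative_coupling,
              fisher_z = fit$fisher_z)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_fit
#' @export
read_mixture_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(psi_plus = obj$psi_plus, pi_plus = obj$pi_plus,
                 v_plus = obj$v_plus, v_minus = obj$v_minus,
                 loglik = obj$loglik, loglik_trace = NULL,
                 n_iter = obj$n_iter, converged = obj$converged, n = obj$n,
                 negative_coupling = isTRUE(obj$negative_coupling),
                 fisher_z = isTRUE(obj$fisher_z),
                 data = NULL, call = NULL),
            class = "mq_mixture")
}
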