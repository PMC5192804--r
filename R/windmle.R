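# Core maximum-likelihood wind estimator.
#
# Model: scalar airspeed along the wind-compensated track is a stationary
# AR(1) process with mean a, autocorrelation phi and innovation variance
# sigma^2 (GPS velocity error is absorbed into sigma^2). The wind vector is
# the value that minimises the unexplained airspeed variance s^2 over the
# window; the mean airspeed has a closed-form MLE given the wind, and the
# error covariance of the wind estimate is the inverse Hessian of the
# profile negative log likelihood.

vs_g <- function(G) {
  if (inherits(G, "velocity_seq")) G$g else matrix(as.numeric(G), ncol = 2)
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0 || phi >= 1) {
    stop("phi must lie in [0, 1)")
  }
  phi
}

#' Scalar airspeeds at a candidate wind
#'
#' The wind-compensated speed of each ground-velocity vector,
#' `a[i] = ||g[i] - w||`.
#'
#' @param G a [velocity_seq()] or n x 2 matrix of ground velocities, m/s.
#' @param w candidate wind vector `c(wx, wy)`, m/s.
#' @return Numeric vector of non-negative airspeeds, m/s.
#' @export
airspeeds <- function(G, w) {
  g <- vs_g(G)
  sqrt((g[, 1] - w[1])^2 + (g[, 2] - w[2])^2)
}

#' Closed-form MLE of the mean airspeed under the AR(1) model
#'
#' For a stationary AR(1) airspeed sequence with known autocorrelation
#' `phi`, the maximum-likelihood estimate of the mean is
#' \deqn{\hat a = \frac{a_1 + (1-\phi)\sum_{i=2}^{n-1} a_i + a_n}
#'                     {2 + (n-2)(1-\phi)}.}
#' For `phi = 0` this is the arithmetic mean; as `phi` approaches 1 it tends
#' to the mean of the two endpoints.
#'
#' @param atilde numeric vector of scalar airspeeds (length >= 3).
#' @param phi AR(1) autocorrelation coefficient in `[0, 1)`.
#' @return The mean-airspeed estimate, m/s.
#' @export
airspeed_mle <- function(atilde, phi) {
  check_phi(phi)
  n <- length(atilde)
  if (n < 3) stop("need at least 3 airspeed samples")
  (atilde[1] + (1 - phi) * sum(atilde[2:(n - 1)]) + atilde[n]) /
    (2 + (n - 2) * (1 - phi))
}

# Unexplained variance from a ready airspeed vector (internal fast path).
s2_from_airspeeds <- function(atilde, phi) {
  n <- length(atilde)
  ahat <- (atilde[1] + (1 - phi) * sum(atilde[2:(n - 1)]) + atilde[n]) /
    (2 + (n - 2) * (1 - phi))
  pred <- (1 - phi) * ahat + phi * atilde[1:(n - 1)]
  ((atilde[1] - ahat)^2 * (1 - phi^2) + sum((atilde[2:n] - pred)^2)) / (n - 1)
}

#' Unexplained airspeed variance at a candidate wind
#'
#' The Bessel-corrected residual variance of the scalar airspeeds around
#' their AR(1) prediction at their own mean-airspeed MLE:
#' \deqn{s^2(G, w) = \frac{1}{n-1}\Big[(a_1-\hat a)^2 (1-\phi^2) +
#'   \sum_{i=2}^{n} \big(a_i - [(1-\phi)\hat a + \phi a_{i-1}]\big)^2\Big].}
#' This is the objective minimised over `w` by [estimate_wind()].
#'
#' @inheritParams airspeeds
#' @param phi AR(1) autocorrelation coefficient in `[0, 1)`.
#' @return Non-negative variance, (m/s)^2.
#' @export
unexplained_variance <- function(G, w, phi) {
  check_phi(phi)
  atilde <- airspeeds(G, w)
  if (length(atilde) < 3) stop("need at least 3 velocity samples")
  s2_from_airspeeds(atilde, phi)
}

#' Profile negative log likelihood of a window given a wind vector
#'
#' \deqn{l(G, w) = \tfrac12\big[n \log\sigma^2 - \log(1-\phi^2) +
#'   (n/\sigma^2)\, s^2(G, w)\big]} (additive constants omitted). Monotone
#' increasing in `s^2` at fixed `sigma2`, so minimising `s^2` maximises the
#' likelihood.
#'
#' @inheritParams unexplained_variance
#' @param sigma2 innovation variance of the airspeed AR(1) process, (m/s)^2.
#' @return Scalar negative log likelihood.
#' @export
neg_log_likelihood <- function(G, w, phi, sigma2) {
  check_phi(phi)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  n <- nrow(vs_g(G))
  s2 <- unexplained_variance(G, w, phi)
  0.5 * (n * log(sigma2) - log(1 - phi^2) + n / sigma2 * s2)
}

# Central-difference Hessian of f at 2-vector x, symmetrized.
hessian2 <- function(f, x, h) {
  f0 <- f(x)
  e1 <- c(h, 0); e2 <- c(0, h)
  h11 <- (f(x + e1) - 2 * f0 + f(x - e1)) / h^2
  h22 <- (f(x + e2) - 2 * f0 + f(x - e2)) / h^2
  h12 <- (f(x + e1 + e2) - f(x + e1 - e2) - f(x - e1 + e2) + f(x - e1 - e2)) /
    (4 * h^2)
  matrix(c(h11, h12, h12, h22), 2, 2)
}

#' Estimate the horizontal wind vector from a circling window
#'
#' Minimises the unexplained airspeed variance `s^2(G, w)` over the wind
#' vector with a Nelder-Mead simplex (restarted once from its own solution
#' for polish). The error covariance of the estimate is
#' \deqn{\Sigma = \Big[\frac{n}{2\hat\sigma^2} H\Big]^{-1}}
#' with `H` the central-difference Hessian of `s^2` at the optimum.
#'
#' Degenerate cases: when the fitted variance is (numerically) zero, the
#' covariance is reported as the zero matrix with `degenerate = TRUE`; when
#' the Hessian is not positive definite (e.g. straight flight, where the
#' wind component along track is unidentifiable), `cov_valid = FALSE` and
#' the point estimate is retained.
#'
#' @param G a [velocity_seq()] or n x 2 velocity matrix (n >= 5; heading
#'   curvature is needed for identifiability).
#' @param phi AR(1) autocorrelation coefficient in `[0, 1)`.
#' @param init optional starting wind vector; defaults to the mean ground
#'   velocity of the window (the drift of the circle).
#' @param tol absolute convergence tolerance on the `s^2` simplex spread.
#' @param max_iter maximum simplex iterations.
#' @param hessian_step central-difference step for the Hessian, m/s.
#' @return Object of class `wind_estimate`: `w`, `cov`, `sigma2_hat`,
#'   `a_hat`, `phi`, `n`, `converged`, `cov_valid`, `degenerate`,
#'   `neg_log_lik`.
#' @export
estimate_wind <- function(G, phi = 0, init = NULL, tol = 1e-14,
                          max_iter = 1000, hessian_step = 1e-3) {
  check_phi(phi)
  g <- vs_g(G)
  n <- nrow(g)
  if (n < 5) stop("need at least 5 velocity samples to identify the wind")
  if (is.null(init)) init <- colMeans(g)
  obj <- function(w) {
    atilde <- sqrt((g[, 1] - w[1])^2 + (g[, 2] - w[2])^2)
    s2_from_airspeeds(atilde, phi)
  }
  ctrl <- list(maxit = max_iter, abstol = tol, reltol = 1e-14)
  fit <- stats::optim(init, obj, method = "Nelder-Mead", control = ctrl)
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead", control = ctrl)
  if (fit2$value <= fit$value) fit <- fit2
  w_hat <- as.numeric(fit$par)
  sigma2_hat <- fit$value
  a_hat <- airspeed_mle(airspeeds(g, w_hat), phi)
  H <- hessian2(obj, w_hat, hessian_step)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  cov_valid <- all(ev > 0) && min(ev) > max(ev) * 1e-10
  degenerate <- sigma2_hat < 1e-12
  if (degenerate) {
    cov <- matrix(0, 2, 2)
    nll <- -Inf
  } else {
    cov <- if (cov_valid) solve(n / (2 * sigma2_hat) * (H + t(H)) / 2) else
      matrix(NA_real_, 2, 2)
    nll <- 0.5 * (n * log(sigma2_hat) - log(1 - phi^2) + n)
  }
  structure(list(w = w_hat, cov = cov, sigma2_hat = sigma2_hat, a_hat = a_hat,
                 phi = phi, n = n, converged = fit$convergence == 0,
                 cov_valid = cov_valid, degenerate = degenerate,
                 neg_log_lik = nll),
            class = "wind_estimate")
}

#' @export
print.wind_estimate <- function(x, ...) {
  cat(sprintf("<wind_estimate> w = (%.3f, %.3f) m/s  |w| = %.3f m/s\n",
              x$w[1], x$w[2], sqrt(sum(x$w^2))))
  cat(sprintf("  a_hat = %.3f m/s  sigma2_hat = %.4g (m/s)^2  phi = %.2f  n = %d\n",
              x$a_hat, x$sigma2_hat, x$phi, x$n))
  if (x$degenerate) cat("  degenerate fit (zero residual variance)\n")
  else if (!x$cov_valid) cat("  covariance invalid (Hessian not positive definite)\n")
  else cat(sprintf("  sd(wx) = %.3f  sd(wy) = %.3f m/s\n",
                   sqrt(x$cov[1, 1]), sqrt(x$cov[2, 2])))
  invisible(x)
}

# Maximized log likelihood of one segment at a fixed phi: profile out w and
# sigma^2 (sigma2_hat = s2 at the optimum, so n/sigma2 * s2 = n).
segment_max_loglik <- function(G, phi, init = NULL) {
  est <- estimate_wind(G, phi = phi, init = init)
  s2 <- max(est$sigma2_hat, 1e-12)
  list(loglik = -0.5 * (est$n * log(s2) - log(1 - phi^2) + est$n),
       w = est$w)
}

#' Estimate the global airspeed autocorrelation coefficient
#'
#' Profiles the summed per-segment maximized log likelihood over the AR(1)
#' coefficient: for each candidate `phi`, every segment is re-optimised over
#' the wind (with warm starts) and `sigma^2` is profiled out; the sum over
#' segments is then maximised over `phi` by golden-section search.
#'
#' @param segments list of [velocity_seq()] windows (each n >= 5).
#' @param interval search interval for `phi`.
#' @param tol tolerance of the 1-D search.
#' @param grid candidate values at which the returned profile is tabulated
#'   (the endpoints of `interval` are always included).
#' @return List with `phi_hat`, `log_lik` (summed maximized log likelihood
#'   at `phi_hat`) and `profile` (data frame of `phi`, `log_lik`).
#' @export
estimate_phi <- function(segments, interval = c(0, 0.99), tol = 1e-3,
                         grid = seq(0, 0.9, by = 0.1)) {
  if (length(segments) == 0) stop("need at least one segment")
  warm <- vector("list", length(segments))
  profile_ll <- function(phi) {
    total <- 0
    for (j in seq_along(segments)) {
      r <- segment_max_loglik(segments[[j]], phi, init = warm[[j]])
      warm[[j]] <<- r$w
      total <- total + r$loglik
    }
    total
  }
  opt <- stats::optimize(profile_ll, interval = interval, maximum = TRUE,
                         tol = tol)
  grid <- sort(unique(c(interval[1], grid, opt$maximum)))
  prof <- data.frame(phi = grid,
                     log_lik = vapply(grid, profile_ll, numeric(1)))
  list(phi_hat = opt$maximum, log_lik = opt$objective, profile = prof)
}
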