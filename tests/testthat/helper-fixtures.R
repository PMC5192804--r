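# Fixtures built in code. make_circle_vs() constructs exact circling
# velocity sequences directly from the kinematics, independent of the
# package's simulator, so simulator and estimator can check each other.

make_circle_vs <- function(n = 19, a = 9.37, omega = 9.37 / 20.31,
                           w = c(2, 1), dt = 1, heading0 = 0, climb = 1,
                           z0 = 500) {
  theta <- heading0 + omega * dt * (0:(n - 1))
  g <- cbind(a * cos(theta) + w[1], a * sin(theta) + w[2])
  velocity_seq(g, z = z0 + climb * dt * (0:(n - 1)), dt = dt,
               t = (0:(n - 1)) * dt,
               pos = dt * rbind(c(0, 0),
                                apply(g[-n, , drop = FALSE], 2, cumsum)))
}

# Velocity sequence of a simulated window, via the Doppler columns.
sim_window_vs <- function(config) {
  s <- simulate_track(config)
  ground_velocities(project_local(s$track), method = "doppler")
}

# Brute-force 1-D minimiser of the AR(1) quadratic form over the mean
# airspeed (oracle for the closed-form mean-airspeed MLE).
numeric_mean_mle <- function(atilde, phi) {
  n <- length(atilde)
  qform <- function(a) {
    (atilde[1] - a)^2 * (1 - phi^2) +
      sum((atilde[2:n] - ((1 - phi) * a + phi * atilde[1:(n - 1)]))^2)
  }
  a <- stats::optimize(qform, range(atilde) + c(-5, 5), tol = 1e-10)$minimum
  # Newton polish with numerical derivatives (optimize() stalls near
  # sqrt(machine eps); the quadratic form makes these steps exact)
  h <- 1e-4
  for (i in 1:2) {
    d1 <- (qform(a + h) - qform(a - h)) / (2 * h)
    d2 <- (qform(a + h) - 2 * qform(a) + qform(a - h)) / h^2
    a <- a - d1 / d2
  }
  a
}

# A fake wind_estimate with a given covariance (for validation-layer tests).
fake_estimate <- function(w, cov, sigma2 = 0.2) {
  structure(list(w = w, cov = cov, sigma2_hat = sigma2, a_hat = 9.4,
                 phi = 0.47, n = 19, converged = TRUE, cov_valid = TRUE,
                 degenerate = FALSE, neg_log_lik = 0),
            class = "wind_estimate")
}
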