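test_that("airspeeds are wind-compensated vector norms", {
  g <- rbind(c(3, 4), c(0, 5), c(2, 1))
  expect_equal(airspeeds(g, c(0, 0)), c(5, 5, sqrt(5)))
  expect_equal(airspeeds(g, c(2, 1))[3], 0)
  vs <- make_circle_vs(n = 12, a = 9, w = c(2, 1))
  expect_equal(airspeeds(vs, c(2, 1)), rep(9, 12))
})

test_that("closed-form mean-airspeed MLE matches brute-force minimization", {
  set.seed(1)
  for (r in 1:100) {
    n <- sample(5:30, 1)
    atilde <- runif(n, 5, 15)
    phi <- runif(1, 0, 0.95)
    expect_equal(airspeed_mle(atilde, phi), numeric_mean_mle(atilde, phi),
                 tolerance = 1e-8)
  }
})

test_that("mean-airspeed MLE limiting cases", {
  expect_equal(airspeed_mle(c(8, 9, 10), 0), 9)
  expect_equal(airspeed_mle(c(8, 9, 10), 1 - 1e-10), 9, tolerance = 1e-8)
  set.seed(2)
  atilde <- runif(10, 8, 11)
  expect_equal(airspeed_mle(atilde, 0), mean(atilde))
  expect_equal(airspeed_mle(atilde, 1 - 1e-10),
               (atilde[1] + atilde[10]) / 2, tolerance = 1e-7)
  expect_error(airspeed_mle(atilde, 1), "phi")
  expect_error(airspeed_mle(atilde, -0.1), "phi")
})

test_that("unexplained variance: hand-computed and degenerate cases", {
  # airspeeds (9, 10, 9) at w = 0, phi = 0: mean 28/3, s2 = 1/3
  g <- rbind(c(9, 0), c(0, 10), c(-9, 0))
  expect_equal(unexplained_variance(g, c(0, 0), 0), 1 / 3)
  # constant airspeed is an exact AR(1) path at its own mean: s2 = 0
  vs <- make_circle_vs(n = 9, a = 8.5, w = c(1, -2))
  for (phi in c(0, 0.47, 0.9)) {
    expect_equal(unexplained_variance(vs, c(1, -2), phi), 0, tolerance = 1e-24)
  }
})

test_that("s2 at the true wind estimates the innovation variance", {
  # pure AR(1) airspeeds (no GPS noise): E[s2 | true wind, true phi] = sigma_a^2
  set.seed(3)
  s2 <- replicate(400, {
    s <- thermalwind:::sim_velocities(19, 1, 0.46, 9.37, 0.46, 0.47, 0,
                                      wind = c(2, 1))
    unexplained_variance(s$v_obs, c(2, 1), 0.47)
  })
  expect_lt(abs(mean(s2) - 0.46^2) / 0.46^2, 0.1)
})

test_that("negative log likelihood matches a from-scratch AR(1) density", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    g <- matrix(rnorm(2 * n, 5, 2), n, 2)
    w <- rnorm(2)
    phi <- runif(1, 0, 0.9)
    sigma2 <- runif(1, 0.05, 1)
    atl <- airspeeds(g, w)
    ahat <- airspeed_mle(atl, phi)
    # independent route: dnorm() evaluation of the stationary AR(1) density
    # at the fitted mean, unpacked to the quadratic form Q
    nld <- -(dnorm(atl[1], ahat, sqrt(sigma2 / (1 - phi^2)), log = TRUE) +
               sum(dnorm(atl[2:n], (1 - phi) * ahat + phi * atl[1:(n - 1)],
                         sqrt(sigma2), log = TRUE)))
    Q <- 2 * sigma2 * (nld - n / 2 * log(2 * pi) - n / 2 * log(sigma2) +
                         0.5 * log(1 - phi^2))
    expected <- 0.5 * (n * log(sigma2) - log(1 - phi^2) +
                         n / sigma2 * Q / (n - 1))
    expect_equal(neg_log_likelihood(g, w, phi, sigma2), expected,
                 tolerance = 1e-8)
  }
})

test_that("negative log likelihood is monotone in s2 and rejects bad sigma2", {
  vs <- sim_window_vs(sim_config(n = 19, seed = 5))
  w_good <- estimate_wind(vs, phi = 0.47)$w
  w_bad <- w_good + c(3, 0)
  expect_lt(neg_log_likelihood(vs, w_good, 0.47, 0.3),
            neg_log_likelihood(vs, w_bad, 0.47, 0.3))
  # phi = 0 drops the stationary-variance penalty
  n <- length(vs)
  s2 <- unexplained_variance(vs, w_good, 0)
  expect_equal(neg_log_likelihood(vs, w_good, 0, 0.3),
               0.5 * (n * log(0.3) + n / 0.3 * s2))
  expect_error(neg_log_likelihood(vs, w_good, 0.47, 0), "sigma2")
})

test_that("noiseless drifting circle: exact wind recovery", {
  vs <- make_circle_vs(n = 19, a = 9.37, omega = 9.37 / 20.31, w = c(2, 1))
  est <- estimate_wind(vs, phi = 0)
  expect_lt(max(abs(est$w - c(2, 1))), 1e-6)
  expect_lt(est$sigma2_hat, 1e-10)
  expect_true(est$degenerate)
  expect_equal(est$cov, matrix(0, 2, 2))
  expect_equal(est$a_hat, 9.37, tolerance = 1e-6)
  # any window covering at least half a circle still identifies the wind
  vs_half <- make_circle_vs(n = 8, a = 9.37, omega = 0.46, w = c(-3, 2))
  est_half <- estimate_wind(vs_half, phi = 0)
  expect_lt(max(abs(est_half$w - c(-3, 2))), 1e-5)
})

test_that("wind estimate is translation and rotation equivariant", {
  for (seed in 1:5) {
    vs <- sim_window_vs(sim_config(n = 19, seed = seed))
    est0 <- estimate_wind(vs, phi = 0.47)
    # translation
    cvec <- c(3, -2)
    est_t <- estimate_wind(sweep(vs$g, 2, -cvec), phi = 0.47)
    expect_equal(est_t$w, est0$w + cvec, tolerance = 1e-6)
    expect_equal(est_t$sigma2_hat, est0$sigma2_hat, tolerance = 1e-8)
    expect_equal(est_t$a_hat, est0$a_hat, tolerance = 1e-6)
    expect_equal(est_t$cov, est0$cov, tolerance = 1e-4)
    # rotation
    alpha <- 0.7
    R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
    est_r <- estimate_wind(vs$g %*% t(R), phi = 0.47)
    expect_equal(est_r$w, as.numeric(R %*% est0$w), tolerance = 1e-6)
    expect_equal(est_r$sigma2_hat, est0$sigma2_hat, tolerance = 1e-8)
    expect_equal(est_r$cov, R %*% est0$cov %*% t(R), tolerance = 1e-4)
  }
})

test_that("straight flight leaves the wind unidentified", {
  g <- matrix(rep(c(10, 0), each = 9), 9, 2)  # constant velocity, no turning
  est <- estimate_wind(g, phi = 0)
  expect_false(est$cov_valid)
  expect_error(estimate_wind(g[1:3, ], phi = 0), "at least 5")
})

test_that("residual variance estimate is nearly unbiased at n = 100", {
  set.seed(6)
  s2 <- replicate(200, {
    s <- thermalwind:::sim_velocities(100, 1, 0.46, 9.37, 0.46, 0.47, 0,
                                      wind = c(2, 1))
    estimate_wind(s$v_obs, phi = 0.47)$sigma2_hat
  })
  expect_lt(abs(mean(s2) - 0.46^2) / 0.46^2, 0.05)
})

test_that("phi profile: white-noise airspeeds give phi_hat near zero", {
  set.seed(7)
  segs <- lapply(1:60, function(i) {
    s <- thermalwind:::sim_velocities(19, 1, 0.46, 9.37, 0.46, 0, 0.3,
                                      wind = c(2, 1))
    velocity_seq(s$v_obs, z = rep(500, 19), dt = 1)
  })
  fit <- estimate_phi(segs)
  expect_lt(fit$phi_hat, 0.1)
  expect_s3_class(fit$profile, "data.frame")
  # optimiser noise across warm starts is ~0.1 log-lik units
  expect_true(all(fit$log_lik >= fit$profile$log_lik - 1))
  expect_error(estimate_phi(list()), "at least one")
})

test_that("phi profile favours positive phi on autocorrelated airspeeds", {
  set.seed(8)
  segs <- lapply(1:60, function(i) {
    s <- thermalwind:::sim_velocities(19, 1, 0.46, 9.37, 0.46, 0.47, 0,
                                      wind = c(2, 1))
    velocity_seq(s$v_obs, z = rep(500, 19), dt = 1)
  })
  fit <- estimate_phi(segs)
  ll0 <- fit$profile$log_lik[fit$profile$phi == 0]
  expect_gt(fit$phi_hat, 0)
  expect_gt(fit$log_lik, ll0)
})
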