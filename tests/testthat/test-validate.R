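test_that("partial deviances decompose the difference on the eigenaxes", {
  e1 <- fake_estimate(c(0, 0), diag(2) * 0.5)
  e2 <- fake_estimate(c(3, 4), diag(2) * 0.5)
  pc <- pair_partial_deviances(e1, e2)
  expect_equal(sort(abs(c(pc$d_major, pc$d_minor))), c(3, 4))
  expect_equal(c(pc$sigma2_major, pc$sigma2_minor), c(1, 1))
  expect_equal(pc$d_major^2 + pc$d_minor^2, 25)
  # identical estimates: zero deviances
  pc0 <- pair_partial_deviances(e1, e1)
  expect_equal(c(pc0$d_major, pc0$d_minor), c(0, 0))
  # anisotropic case: major axis carries the larger eigenvalue
  e3 <- fake_estimate(c(1, 0), matrix(c(0.4, 0.1, 0.1, 0.1), 2))
  pc3 <- pair_partial_deviances(e1, e3)
  expect_gte(pc3$sigma2_major, pc3$sigma2_minor)
  bad <- fake_estimate(c(0, 0), diag(2)); bad$cov_valid <- FALSE
  expect_error(pair_partial_deviances(e1, bad), "valid covariance")
})

test_that("standardized deviances from simulated pairs are standard normal", {
  set.seed(50)
  z <- numeric(0)
  for (p in 1:150) {
    pr <- simulate_pair(sim_config(n = 19, seed = NULL), separation = 15)
    es <- lapply(pr$tracks, function(tr)
      estimate_wind(ground_velocities(project_local(tr$track),
                                      method = "doppler"), phi = 0.47))
    if (es[[1]]$cov_valid && es[[2]]$cov_valid) {
      pc <- pair_partial_deviances(es[[1]], es[[2]])
      z <- c(z, pc$d_major / sqrt(pc$sigma2_major),
             pc$d_minor / sqrt(pc$sigma2_minor))
    }
  }
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
  expect_gt(sd(z), 0.85)
  expect_lt(sd(z), 1.15)
})

test_that("observed-vs-predicted calibration detects miscalibration", {
  set.seed(51)
  pred <- runif(400, 0.02, 0.3)
  dev <- rnorm(400, 0, sqrt(pred + 0.05))
  # correct covariances plus turbulence floor: slope 1, intercept ~ 0.05
  ovp <- observed_vs_predicted(data.frame(deviance = dev, pred_var = pred))
  expect_equal(unname(ovp$fit["slope"]), 1, tolerance = 0.3)
  expect_equal(unname(ovp$fit["intercept"]), 0.05, tolerance = 0.6)
  expect_equal(nrow(ovp$groups), 4)
  expect_true(all(ovp$groups$ci_lo < ovp$groups$obs_var))
  expect_true(all(ovp$groups$ci_hi > ovp$groups$obs_var))
  # halving the claimed covariances doubles the slope
  ovp2 <- observed_vs_predicted(data.frame(deviance = dev,
                                           pred_var = pred / 2))
  expect_equal(unname(ovp2$fit["slope"]), 2, tolerance = 0.3)
  expect_error(observed_vs_predicted(data.frame(deviance = 1:4,
                                                pred_var = 1:4)),
               "at least")
})

test_that("CI half-widths summarise the worst direction", {
  es <- list(fake_estimate(c(0, 0), diag(2) * 0.04),
             fake_estimate(c(0, 0), matrix(c(0.09, 0, 0, 0.01), 2)))
  q <- ci_halfwidth_quantiles(es, probs = c(0.25, 0.5, 0.75))
  expect_equal(unname(q[["50%"]]), mean(c(1.96 * 0.2, 1.96 * 0.3)))
  expect_true(all(diff(q) >= 0))
  expect_equal(unname(ci_halfwidth_quantiles(es[1], probs = 0.5)),
               0.392, tolerance = 1e-10)
})

test_that("heading occupancy is exactly uniform for an even circle", {
  w <- c(1, 0)
  theta <- (0:23) * (2 * pi / 24) + 0.01
  ev <- structure(list(
    estimate = fake_estimate(w, diag(2) * 0.01),
    window = velocity_seq(cbind(9 * cos(theta) + w[1], 9 * sin(theta) + w[2]),
                          z = rep(500, 24), dt = 1)),
    class = "circling_event")
  h <- heading_wind_histogram(list(ev), nbins = 24)
  expect_equal(h$freq, rep(1, 24))
  # doubling the upwind half doubles those bins relative to downwind
  up <- theta[cos(theta) < 0]
  ev2 <- structure(list(
    estimate = fake_estimate(w, diag(2) * 0.01),
    window = velocity_seq(
      cbind(9 * cos(c(theta, up)) + w[1], 9 * sin(c(theta, up)) + w[2]),
      z = rep(500, 36), dt = 1)),
    class = "circling_event")
  h2 <- heading_wind_histogram(list(ev2), nbins = 4)
  upwind <- mean(h2$freq[abs(h2$bin_mid_deg) >= 135])
  downwind <- mean(h2$freq[abs(h2$bin_mid_deg) <= 45])
  expect_equal(upwind / downwind, 2, tolerance = 1e-9)
})

test_that("noisy circling at the estimated wind samples headings evenly", {
  set.seed(52)
  evs <- list()
  for (r in 1:60) {
    res <- classify_window(sim_window_vs(
      sim_config(n = 19, heading0 = runif(1, 0, 2 * pi), seed = NULL)),
      phi = 0.47)
    if (res$accepted) evs[[length(evs) + 1]] <- res$event
  }
  h <- heading_wind_histogram(evs, nbins = 12)
  expect_true(all(abs(h$freq - 1) < 0.15))
})

test_that("thermal profiles group, sort and smooth by height", {
  set.seed(53)
  ev <- data.frame(lon = 8.95, lat = 47.75, time = 100,
                   height = sample(seq(400, 1000, by = 25)),
                   wind_speed = 3, w_z = 1.5)
  pr <- thermal_profiles(ev)
  expect_equal(length(unique(paste(pr$cx, pr$cy, pr$tb))), 1)
  expect_true(all(diff(pr$height) >= 0))
  expect_true(all(pr$smoothed))
  expect_equal(nrow(pr), nrow(ev) - 10 + 1)  # running means of 10
  # permutation invariance
  perm <- sample(nrow(ev))
  expect_equal(thermal_profiles(ev[perm, ]), pr)
  # small groups are returned unsmoothed and flagged
  pr_small <- thermal_profiles(ev[1:5, ])
  expect_false(any(pr_small$smoothed))
  expect_equal(nrow(pr_small), 5)
})

test_that("raster binning is half-open: boundary events go to the upper cell", {
  ev <- data.frame(lon = c(0.0999999, 0.1), lat = 47.05, time = 10,
                   height = c(500, 600), wind_speed = 2, w_z = 1)
  pr <- thermal_profiles(ev)
  expect_equal(sort(unique(pr$cx)), c(0, 1))
})

test_that("a stepped wind profile is recovered from a simulated flock", {
  profile <- data.frame(height = c(400, 949.9, 950, 1400),
                        wx = c(2, 2, 5, 5), wy = 0,
                        updraft = c(2.5, 2.5, 1.5, 1.5))
  col <- simulate_thermal_column(profile, birds = 12,
                                 config = sim_config(n = 120, seed = 54))
  evs <- list()
  for (tr in col$tracks) {
    bursts <- segment_bursts(tr$track, min_len = 19, method = "doppler")
    det <- detect_circling_events(bursts, phi = 0.47)
    evs <- c(evs, det$events)
  }
  tab <- events_table(evs)
  expect_gt(nrow(tab), 30)
  pr <- thermal_profiles(tab)
  low <- pr$wind_speed[pr$height < 850 & pr$smoothed]
  high <- pr$wind_speed[pr$height > 1050 & pr$smoothed]
  expect_equal(mean(low), 2, tolerance = 0.15)
  expect_equal(mean(high), 5, tolerance = 0.15)
  # thermal strength drops across the boundary-layer top
  expect_gt(mean(pr$w_z[pr$height < 850 & pr$smoothed]),
            mean(pr$w_z[pr$height > 1050 & pr$smoothed]))
})

test_that("median regression recovers exact linear structure and resists outliers", {
  set.seed(55)
  r <- runif(400, 12, 30)
  ev <- data.frame(radius = r, airspeed = 6.73 + 0.13 * r,
                   c_l = 2.23 - 0.042 * r, gz = 1)
  fits <- radius_behavior_fits(ev, boot = 25)
  expect_equal(unname(fits$fit_airspeed$estimate),
               c(6.73, 0.13), tolerance = 1e-6)
  expect_equal(unname(fits$fit_cl$estimate),
               c(2.23, -0.042), tolerance = 1e-6)
  expect_true(all(diff(fits$groups$airspeed) > 0))
  # constant airspeed: zero slope
  ev2 <- ev; ev2$airspeed <- 9.4
  expect_equal(unname(radius_behavior_fits(ev2, boot = 0)$fit_airspeed$estimate),
               c(9.4, 0), tolerance = 1e-8)
  # 10% gross outliers barely move the median fit
  ev3 <- ev
  out <- sample(400, 40)
  ev3$airspeed[out] <- ev3$airspeed[out] + 5
  fit3 <- radius_behavior_fits(ev3, boot = 0)$fit_airspeed$estimate
  expect_equal(unname(fit3), c(6.73, 0.13), tolerance = 0.02)
  # climb selection removes weak events
  ev4 <- ev; ev4$gz[1:200] <- 0.2
  expect_lt(nrow(radius_behavior_fits(ev4, boot = 0)$groups), 11)
})
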