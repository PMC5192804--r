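# Synthetic thermalling-track generator with known truth.
#
# Forward simulation of the estimator's assumed data-generating process:
# heading advances at a constant angular rate, scalar airspeed follows a
# stationary AR(1) process (optionally with a deterministic sinusoidal
# modulation as a function of heading relative to a designated wind
# direction), ground velocity is airspeed along the heading plus a constant
# horizontal wind, and the observed velocities carry circularly symmetric
# bivariate normal GPS error. Positions integrate the observed velocities,
# so position-difference and Doppler-column velocity sequences agree
# exactly.

#' Simulation configuration
#'
#' Defaults are the study conditions for thermalling white storks: mean
#' airspeed 9.37 m/s, time per circle 13.65 s (angular rate 0.46 rad/s,
#' radius ~20 m), AR(1) airspeed noise with phi 0.47 and innovation sd
#' 0.46 m/s, GPS velocity error sd 0.3 m/s, climb 0.92 m/s, 1 Hz sampling,
#' a 5-minute burst, and a drift of ~2.2 m/s.
#'
#' @param wind horizontal wind vector `c(wx east, wy north)`, m/s.
#' @param airspeed mean airspeed `a`, m/s.
#' @param sigma_a AR(1) innovation standard deviation, m/s (the stationary
#'   airspeed sd is `sigma_a / sqrt(1 - phi^2)`).
#' @param phi AR(1) autocorrelation coefficient in `[0, 1)`.
#' @param omega angular rate, rad/s; the sign sets the turn direction
#'   (positive counterclockwise). Zero gives straight flight.
#' @param sigma_g GPS velocity error standard deviation per component, m/s.
#' @param n number of fixes.
#' @param dt sampling interval, seconds.
#' @param climb vertical ground speed, m/s; ignored when `updraft` is given.
#' @param updraft optional vertical air speed, m/s; when set, the climb is
#'   derived as `updraft - sink_rate(airspeed, |omega|)` with the default
#'   stork aerodynamics.
#' @param modulation_amp amplitude `a_c` of the deterministic airspeed
#'   modulation `-(a_c/2) cos(heading - modulation_dir)`; 0 disables.
#' @param modulation_dir designated wind direction of the modulation,
#'   radians (mathematical convention, east = 0).
#' @param heading0 initial heading, radians (mathematical convention).
#' @param height0 initial height, metres.
#' @param start `c(lon, lat)` of the first fix.
#' @param t0 timestamp of the first fix, seconds since epoch.
#' @param position_noise optional sd of independent position noise, metres
#'   (off by default; when on, position-derived velocities no longer equal
#'   the Doppler columns).
#' @param id individual identifier written to the track.
#' @param seed optional integer seed.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(wind = c(2, 1), airspeed = 9.37, sigma_a = 0.46,
                       phi = 0.47, omega = 2 * pi / 13.65, sigma_g = 0.3,
                       n = 300, dt = 1, climb = 0.92, updraft = NULL,
                       modulation_amp = 0, modulation_dir = 0,
                       heading0 = 0, height0 = 500,
                       start = c(8.9340, 47.7530),
                       t0 = as.numeric(as.POSIXct("2014-09-01 12:00:00",
                                                  tz = "UTC")),
                       position_noise = 0, id = "sim-01", seed = NULL) {
  stopifnot(sigma_a >= 0, sigma_g >= 0, phi >= 0, phi < 1, n >= 2, dt > 0,
            position_noise >= 0, modulation_amp >= 0)
  structure(list(wind = wind, airspeed = airspeed, sigma_a = sigma_a,
                 phi = phi, omega = omega, sigma_g = sigma_g, n = n, dt = dt,
                 climb = climb, updraft = updraft,
                 modulation_amp = modulation_amp,
                 modulation_dir = modulation_dir, heading0 = heading0,
                 height0 = height0, start = start, t0 = t0,
                 position_noise = position_noise, id = id, seed = seed),
            class = "sim_config")
}

#' Sample airspeed variability across circling events
#'
#' Draws per-event airspeed-noise standard deviations from a lognormal
#' matched to the observed distribution of airspeed variability in
#' thermalling storks (median 0.46 m/s, 5%/95% quantiles 0.26/0.84 m/s).
#' Real circling events are heterogeneous in turbulence level; simulations
#' of event populations (e.g. pairwise calibration) should reproduce that
#' heterogeneity, since grouping by estimated variance is only informative
#' when the underlying variance actually varies.
#'
#' @param n number of draws.
#' @param median_sd,q95_sd the matched quantiles, m/s.
#' @return Numeric vector of standard deviations, m/s.
#' @export
sample_airspeed_sd <- function(n, median_sd = 0.46, q95_sd = 0.84) {
  stats::rlnorm(n, log(median_sd), log(q95_sd / median_sd) / stats::qnorm(0.95))
}

# Sink rate of steady circling at airspeed a and angular rate omega with
# the given aerodynamics (used to derive climb from a set updraft).
steady_sink <- function(a, omega, params = stork_params()) {
  bl <- banking_and_lift(a, abs(omega), params)
  drag_and_sink(a, bl$lift_acc, params)$sink_rate
}

# Core velocity engine. omega, climb may be scalars or length-n; wind may be
# a 2-vector or an n x 2 matrix. Draws from the current RNG stream.
sim_velocities <- function(n, dt, omega, a, sigma_a, phi, sigma_g,
                           mod_amp = 0, mod_dir = 0, heading0 = 0,
                           wind = c(0, 0)) {
  om <- rep(omega, length.out = n)
  theta <- heading0 + c(0, cumsum(om[-n] * dt))
  s <- numeric(n)
  s[1] <- a + stats::rnorm(1, 0, if (sigma_a > 0) sigma_a / sqrt(1 - phi^2) else 0)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sigma_a)
    for (i in 2:n) s[i] <- (1 - phi) * a + phi * s[i - 1] + eps[i - 1]
  }
  if (mod_amp > 0) s <- s - mod_amp / 2 * cos(theta - mod_dir)
  W <- if (is.matrix(wind)) wind else matrix(wind, n, 2, byrow = TRUE)
  v_true <- cbind(s * cos(theta), s * sin(theta)) + W
  v_obs <- v_true + matrix(stats::rnorm(2 * n, 0, sigma_g), n, 2)
  list(theta = theta, airspeed = s, v_true = v_true, v_obs = v_obs)
}

# Assemble a track + truth record from engine output.
assemble_track <- function(config, sim, climb, wind) {
  n <- config$n; dt <- config$dt
  pos <- rbind(c(0, 0), apply(sim$v_obs[-n, , drop = FALSE] * dt, 2, cumsum))
  if (config$position_noise > 0) {
    pos <- pos + matrix(stats::rnorm(2 * n, 0, config$position_noise), n, 2)
  }
  cl <- rep(climb, length.out = n)
  z <- config$height0 + c(0, cumsum(cl[-n] * dt))
  lonlat <- local_to_lonlat(pos, config$start)
  track <- as_track(data.frame(
    timestamp = config$t0 + (0:(n - 1)) * dt,
    lon = lonlat[, 1], lat = lonlat[, 2], height = z,
    speed = sqrt(rowSums(sim$v_obs^2)),
    heading = (atan2(sim$v_obs[, 1], sim$v_obs[, 2]) * 180 / pi) %% 360,
    id = config$id))
  truth <- list(config = config, theta = sim$theta, airspeed = sim$airspeed,
                v_true = sim$v_true, v_obs = sim$v_obs, pos = pos, z = z,
                wind = wind, climb = cl, ref = config$start)
  list(track = track, truth = truth)
}

#' Simulate a thermalling track
#'
#' Forward simulation of the assumed generative model (see [sim_config()]).
#' Identical configuration and seed give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return List with `track` (a [as_track()] with Doppler speed/heading
#'   columns) and `truth` (all generator-internal quantities: headings,
#'   airspeeds, true and observed velocities, planar positions, wind,
#'   climb).
#' @export
simulate_track <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  climb <- if (!is.null(config$updraft)) {
    config$updraft - steady_sink(config$airspeed, config$omega)
  } else config$climb
  sim <- sim_velocities(config$n, config$dt, config$omega, config$airspeed,
                        config$sigma_a, config$phi, config$sigma_g,
                        config$modulation_amp, config$modulation_dir,
                        config$heading0, config$wind)
  assemble_track(config, sim, climb, config$wind)
}

#' Simulate a burst alternating circling and straight glides
#'
#' Each span is either `"circle"` (angular rate from the configuration) or
#' `"straight"` (zero angular rate); airspeed, wind and noise continue
#' across span boundaries. Per-fix truth labels mark the circling spans.
#'
#' @param config a [sim_config()]; its `n` is ignored.
#' @param spans data frame with columns `type` (`"circle"`/`"straight"`)
#'   and `n` (fixes per span).
#' @return As [simulate_track()], with `truth$label` a per-fix character
#'   vector of span types.
#' @export
simulate_mixed_burst <- function(config, spans) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- sum(spans$n)
  config$n <- n
  om <- rep(ifelse(spans$type == "circle", config$omega, 0), spans$n)
  sim <- sim_velocities(n, config$dt, om, config$airspeed, config$sigma_a,
                        config$phi, config$sigma_g, config$modulation_amp,
                        config$modulation_dir, config$heading0, config$wind)
  out <- assemble_track(config, sim, config$climb, config$wind)
  out$truth$label <- rep(as.character(spans$type), spans$n)
  out
}

#' Simulate a pair of birds circling in the same thermal
#'
#' Two independent tracks share the same mean wind; each bird may receive
#' an additional independent bivariate normal wind perturbation of sd
#' `sigma_t` (turbulence-driven difference between nearby locations). The
#' second bird starts `separation` metres to the east and, when
#' `opposite_directions`, turns the opposite way.
#'
#' @param config a [sim_config()] shared by both birds.
#' @param separation horizontal distance between the circle centres, m.
#' @param opposite_directions flip the second bird's turn direction
#'   (the calibration analysis uses opposite-direction pairs).
#' @param sigma_t per-bird wind perturbation sd, m/s.
#' @return List with `tracks` (two [simulate_track()] results) and `truth`
#'   (shared wind, per-bird winds, separation and its distance category,
#'   one of `[0,25)`, `[25,50)`, `[50,100)` m).
#' @export
simulate_pair <- function(config = sim_config(), separation = 15,
                          opposite_directions = TRUE, sigma_t = 0) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg1 <- cfg2 <- config
  cfg1$seed <- cfg2$seed <- NULL
  cfg1$wind <- config$wind + stats::rnorm(2, 0, sigma_t)
  cfg2$wind <- config$wind + stats::rnorm(2, 0, sigma_t)
  cfg2$start <- as.numeric(local_to_lonlat(c(separation, 0), config$start))
  if (opposite_directions) cfg2$omega <- -config$omega
  cfg1$id <- paste0(config$id, "-a")
  cfg2$id <- paste0(config$id, "-b")
  b1 <- simulate_track(cfg1)
  b2 <- simulate_track(cfg2)
  category <- cut(separation, breaks = c(0, 25, 50, 100), right = FALSE,
                  labels = c("0-25", "25-50", "50-100"))
  list(tracks = list(b1, b2),
       truth = list(wind = config$wind, wind1 = cfg1$wind, wind2 = cfg2$wind,
                    separation = separation, category = as.character(category),
                    opposite_directions = opposite_directions))
}

#' Simulate a flock climbing through a structured thermal column
#'
#' Wind and updraft vary with height according to a piecewise-linear
#' profile; each bird climbs through the column (climb = updraft at height
#' minus the steady-circling sink rate), with starting heights staggered
#' across the profile so that the column is covered.
#'
#' @param profile data frame with columns `height` (m, increasing), `wx`,
#'   `wy` (m/s) and `updraft` (m/s).
#' @param birds number of birds.
#' @param config a [sim_config()]; `wind`, `climb` and `updraft` are taken
#'   from the profile.
#' @param jitter_m horizontal jitter of each bird's start position, m.
#' @return List with `tracks` (one [simulate_track()]-shaped result per
#'   bird) and `truth` (the profile and the per-bird height series).
#' @export
simulate_thermal_column <- function(profile, birds = 20,
                                    config = sim_config(), jitter_m = 50) {
  stopifnot(!is.unsorted(profile$height))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n; dt <- config$dt
  sink <- steady_sink(config$airspeed, config$omega)
  interp <- function(v, z) stats::approx(profile$height, v, z, rule = 2)$y
  z_range <- range(profile$height)
  z_starts <- seq(z_range[1], max(z_range[1], z_range[2] - 50),
                  length.out = birds)
  tracks <- vector("list", birds)
  for (b in seq_len(birds)) {
    # height recursion: climb depends on the current height
    z <- numeric(n)
    z[1] <- z_starts[b]
    cl <- numeric(n)
    for (i in seq_len(n)) {
      cl[i] <- interp(profile$updraft, z[i]) - sink
      if (i < n) z[i + 1] <- z[i] + cl[i] * dt
    }
    W <- cbind(interp(profile$wx, z), interp(profile$wy, z))
    cfg <- config
    cfg$seed <- NULL
    cfg$height0 <- z[1]
    cfg$id <- sprintf("%s-bird%02d", config$id, b)
    cfg$start <- as.numeric(local_to_lonlat(stats::rnorm(2, 0, jitter_m),
                                            config$start))
    sim <- sim_velocities(n, dt, config$omega, config$airspeed,
                          config$sigma_a, config$phi, config$sigma_g,
                          config$modulation_amp, config$modulation_dir,
                          config$heading0 + stats::runif(1, 0, 2 * pi), W)
    out <- assemble_track(cfg, sim, cl, W)
    out$truth$z_true <- z
    tracks[[b]] <- out
  }
  list(tracks = tracks, truth = list(profile = profile, sink = sink,
                                     z_starts = z_starts))
}
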