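# Detection of thermalling (circling) windows in 1-Hz bursts.
#
# A window is a circling event when, after wind compensation, all
# consecutive turn angles share one sign, the cumulative turn before and
# after the central fix each exceed 180 degrees, and the mean vertical
# ground speed over the window is positive (the bird is climbing).

#' Signed turn angles of a wind-compensated velocity sequence
#'
#' The angle between consecutive airspeed vectors `(g[i] - w)` and
#' `(g[i+1] - w)`, computed with the two-argument arctangent of their cross
#' and dot products; positive for counterclockwise turning.
#'
#' @inheritParams airspeeds
#' @return Numeric vector of length n-1 with values in `(-pi, pi]`.
#' @export
turn_angles <- function(G, w) {
  g <- vs_g(G)
  a <- cbind(g[, 1] - w[1], g[, 2] - w[2])
  len <- sqrt(rowSums(a^2))
  if (any(len == 0)) {
    stop("zero-length wind-compensated vector at index ", which(len == 0)[1],
         "; turn angle undefined")
  }
  n <- nrow(a)
  i <- seq_len(n - 1)
  cross <- a[i, 1] * a[i + 1, 2] - a[i, 2] * a[i + 1, 1]
  dot <- a[i, 1] * a[i + 1, 1] + a[i, 2] * a[i + 1, 2]
  atan2(cross, dot)
}

#' Classify one window as circling or not
#'
#' Runs the wind estimator on the window, computes turn angles at the
#' estimated wind, and applies the circling criteria: consistent turn sign
#' (a zero angle fails), cumulative turn strictly greater than pi both
#' before and after the central fix, and mean vertical ground speed
#' (endpoint height difference over elapsed time) strictly positive.
#'
#' @param window a [velocity_seq()] of odd length (default configuration 19).
#' @param phi AR(1) autocorrelation coefficient used by the estimator.
#' @param ... passed to [estimate_wind()].
#' @return A list: `accepted` (logical); when accepted, `event` (class
#'   `circling_event`); otherwise `reason`, the first failed criterion
#'   (`"estimation-failed"`, `"turn-sign"`, `"cumulative-angle"`,
#'   `"vertical-speed"`).
#' @export
classify_window <- function(window, phi = 0, ...) {
  n <- length(window)
  if (n %% 2 != 1) stop("window length must be odd (n = 2m + 1)")
  m <- (n - 1) %/% 2
  est <- tryCatch(estimate_wind(window, phi = phi, ...),
                  error = function(e) NULL)
  if (is.null(est)) return(list(accepted = FALSE, reason = "estimation-failed"))
  ang <- tryCatch(turn_angles(window, est$w), error = function(e) NULL)
  if (is.null(ang)) return(list(accepted = FALSE, reason = "estimation-failed"))
  s <- sign(ang)
  if (any(s == 0) || length(unique(s)) != 1) {
    return(list(accepted = FALSE, reason = "turn-sign"))
  }
  before <- sum(ang[1:m])
  after <- sum(ang[(m + 1):(n - 1)])
  if (abs(before) <= pi || abs(after) <= pi) {
    return(list(accepted = FALSE, reason = "cumulative-angle"))
  }
  gz <- vertical_ground_speed(window$z, window$dt)
  if (gz <= 0) return(list(accepted = FALSE, reason = "vertical-speed"))
  event <- structure(
    list(center = m + 1, start = 1L, end = n, estimate = est,
         direction = as.integer(s[1]), gz = gz, window = window),
    class = "circling_event")
  list(accepted = TRUE, event = event)
}

#' @export
print.circling_event <- function(x, ...) {
  cat(sprintf("<circling_event> %s, w = (%.2f, %.2f) m/s, climb %.2f m/s\n",
              if (x$direction > 0) "counterclockwise" else "clockwise",
              x$estimate$w[1], x$estimate$w[2], x$gz))
  invisible(x)
}

# Classify all sliding windows of one burst; returns accepted events with
# their start index set.
scan_burst <- function(vs, window_length, phi, burst_id) {
  n <- length(vs)
  events <- list()
  if (n < window_length) return(events)
  for (start in seq_len(n - window_length + 1)) {
    res <- classify_window(vs_window(vs, start, window_length), phi = phi)
    if (res$accepted) {
      ev <- res$event
      ev$burst <- burst_id
      ev$start <- start
      ev$end <- start + window_length - 1L
      ev$center <- start + (window_length - 1L) %/% 2L
      events[[length(events) + 1]] <- ev
    }
  }
  events
}

# Greedy earliest-first overlap removal within one burst: accept a window,
# then skip ahead to the first window starting after it ends.
remove_overlaps <- function(events) {
  if (length(events) == 0) return(events)
  starts <- vapply(events, function(e) e$start, numeric(1))
  events <- events[order(starts)]
  kept <- list()
  next_free <- -Inf
  for (ev in events) {
    if (ev$start >= next_free) {
      kept[[length(kept) + 1]] <- ev
      next_free <- ev$end + 1
    }
  }
  kept
}

#' Detect circling events in a set of bursts
#'
#' Two-pass detection: a first pass classifies every sliding window with
#' `phi = 0` (no autocorrelation) and removes overlapping windows greedily
#' (earliest first); the global autocorrelation coefficient is then
#' estimated from the pass-1 events by profile likelihood
#' ([estimate_phi()]); a second pass re-classifies all windows with the
#' estimated `phi` and removes overlaps again.
#'
#' @param bursts list of [velocity_seq()] bursts at uniform dt.
#' @param window_length number of velocity samples per window (default 19,
#'   i.e. 18 s at 1 Hz: the upper tail of observed time per circle plus a
#'   small margin).
#' @param phi `"estimate"` (default, the two-pass procedure) or a fixed
#'   numeric value in `[0, 1)` (single pass).
#' @return List with `events` (disjoint `circling_event`s), `phi_hat`
#'   (NA when no candidate windows were found or `phi` was fixed),
#'   `profile` (the phi profile, or NULL) and `n_pass1`.
#' @export
detect_circling_events <- function(bursts, window_length = 19,
                                   phi = "estimate") {
  stopifnot(window_length %% 2 == 1)
  if (is.numeric(phi)) {
    events <- list()
    for (b in seq_along(bursts)) {
      evs <- remove_overlaps(scan_burst(bursts[[b]], window_length, phi, b))
      events <- c(events, evs)
    }
    return(list(events = events, phi_hat = NA_real_, profile = NULL,
                n_pass1 = length(events)))
  }
  pass1 <- list()
  for (b in seq_along(bursts)) {
    pass1 <- c(pass1, remove_overlaps(scan_burst(bursts[[b]], window_length, 0, b)))
  }
  if (length(pass1) == 0) {
    return(list(events = list(), phi_hat = NA_real_, profile = NULL,
                n_pass1 = 0L))
  }
  fit <- estimate_phi(lapply(pass1, function(e) e$window))
  events <- list()
  for (b in seq_along(bursts)) {
    events <- c(events,
                remove_overlaps(scan_burst(bursts[[b]], window_length,
                                           fit$phi_hat, b)))
  }
  list(events = events, phi_hat = fit$phi_hat, profile = fit$profile,
       n_pass1 = length(pass1))
}

#' Drop events with poorly fitting airspeed model
#'
#' Removes circling events whose residual airspeed standard deviation
#' `sqrt(sigma2_hat)` exceeds `max_sd` (default 1.0 m/s): large unexplained
#' variance signals a poor model fit and an unreliable wind estimate.
#'
#' @param events list of `circling_event`s.
#' @param max_sd threshold on the residual airspeed standard deviation, m/s.
#' @return The retained events, with kept/dropped counts in
#'   `attr(x, "kept")` / `attr(x, "dropped")`.
#' @export
filter_quality <- function(events, max_sd = 1.0) {
  keep <- vapply(events, function(e) sqrt(e$estimate$sigma2_hat) <= max_sd,
                 logical(1))
  out <- events[keep]
  attr(out, "kept") <- sum(keep)
  attr(out, "dropped") <- sum(!keep)
  out
}
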