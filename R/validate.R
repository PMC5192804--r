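# Internal-validation statistics: pairwise partial deviances and
# observed-vs-predicted variance calibration, CI half-width summaries,
# heading-relative-to-wind occupancy, vertical thermal profiles, and
# radius-behaviour fits.

#' Partial deviances of a pair of independent wind estimates
#'
#' If two nearby birds see the same wind and the error covariances are
#' correct, the difference vector `w2 - w1` is mean-zero bivariate normal
#' with covariance `S = cov1 + cov2` (plus any turbulence term). Projecting
#' the difference onto the eigenaxes of `S` yields two independent "partial
#' deviances" with predicted variances equal to the eigenvalues.
#'
#' @param e1,e2 `wind_estimate` objects with valid covariances.
#' @return Object of class `pair_comparison`: `d` (difference vector),
#'   `d_major`, `d_minor`, `sigma2_major`, `sigma2_minor`.
#' @export
pair_partial_deviances <- function(e1, e2) {
  if (!isTRUE(e1$cov_valid) || !isTRUE(e2$cov_valid)) {
    stop("both estimates must carry a valid covariance")
  }
  S <- e1$cov + e2$cov
  ed <- eigen((S + t(S)) / 2, symmetric = TRUE)  # values in decreasing order
  d <- e2$w - e1$w
  proj <- drop(d %*% ed$vectors)
  structure(list(d = d, d_major = proj[1], d_minor = proj[2],
                 sigma2_major = ed$values[1], sigma2_minor = ed$values[2]),
            class = "pair_comparison")
}

#' Long-format table of partial deviances
#'
#' Expands a list of [pair_partial_deviances()] results into one row per
#' deviance (two per pair), carrying the predicted variance and optional
#' metadata columns.
#'
#' @param pairs list of `pair_comparison` objects.
#' @param category optional per-pair distance category labels.
#' @return Data frame with columns `pair`, `axis`, `deviance`, `pred_var`
#'   and (optionally) `category`.
#' @export
pair_deviance_df <- function(pairs, category = NULL) {
  n <- length(pairs)
  out <- data.frame(
    pair = rep(seq_len(n), each = 2),
    axis = rep(c("major", "minor"), n),
    deviance = as.numeric(vapply(pairs, function(p) c(p$d_major, p$d_minor),
                                 numeric(2))),
    pred_var = as.numeric(vapply(pairs,
                                 function(p) c(p$sigma2_major, p$sigma2_minor),
                                 numeric(2))))
  if (!is.null(category)) out$category <- rep(category, each = 2)
  out
}

#' Observed-versus-predicted variance calibration
#'
#' Splits the partial deviances into groups of equal size ordered by their
#' predicted variance; within each group computes the mean predicted
#' variance, the observed variance (mean squared deviance: deviances are
#' mean-zero by construction) and a chi-square 95% confidence interval; and
#' fits a least-squares line through the group points. A slope of 1
#' indicates accurate error covariances; a positive intercept measures the
#' extra between-bird (turbulence) variance.
#'
#' @param devs data frame from [pair_deviance_df()] (one category at a
#'   time), with columns `deviance` and `pred_var`.
#' @param n_groups number of equal-size groups.
#' @param conf confidence level of the per-group interval.
#' @return List with `groups` (data frame: `mean_pred`, `obs_var`, `ci_lo`,
#'   `ci_hi`, `n`) and `fit` (`c(intercept, slope)`).
#' @export
observed_vs_predicted <- function(devs, n_groups = 4, conf = 0.95) {
  k <- nrow(devs)
  if (k < 2 * n_groups) stop("need at least ", 2 * n_groups, " partial deviances")
  ord <- order(devs$pred_var)
  grp <- ceiling(seq_len(k) * n_groups / k)
  alpha <- 1 - conf
  rows <- lapply(split(ord, grp), function(idx) {
    m <- length(idx)
    obs <- mean(devs$deviance[idx]^2)
    data.frame(mean_pred = mean(devs$pred_var[idx]), obs_var = obs,
               ci_lo = m * obs / stats::qchisq(1 - alpha / 2, m),
               ci_hi = m * obs / stats::qchisq(alpha / 2, m),
               n = m)
  })
  groups <- do.call(rbind, rows)
  rownames(groups) <- NULL
  fit <- stats::lm(obs_var ~ mean_pred, data = groups)
  cf <- summary(fit)$coefficients
  list(groups = groups,
       fit = stats::setNames(cf[, "Estimate"], c("intercept", "slope")),
       fit_se = stats::setNames(cf[, "Std. Error"], c("intercept", "slope")),
       fit_df = fit$df.residual)
}

#' Quantiles of the maximum-axis 95% CI half-widths
#'
#' A direction-independent error summary per event: the 95% confidence
#' half-width in the direction of maximum error,
#' `1.96 * sqrt(largest eigenvalue of the covariance)`.
#'
#' @param estimates list of `wind_estimate`s (or `circling_event`s).
#' @param probs quantile levels.
#' @return Named vector of half-width quantiles, m/s.
#' @export
ci_halfwidth_quantiles <- function(estimates, probs = c(0.5, 0.95)) {
  ests <- lapply(estimates, function(e) if (inherits(e, "circling_event")) e$estimate else e)
  hw <- vapply(ests, function(e) {
    if (!isTRUE(e$cov_valid)) return(NA_real_)
    1.96 * sqrt(max(eigen((e$cov + t(e$cov)) / 2, symmetric = TRUE,
                          only.values = TRUE)$values))
  }, numeric(1))
  stats::quantile(hw, probs, na.rm = TRUE)
}

#' Occupancy of heading relative to the wind
#'
#' Per-fix heading of the wind-compensated velocity minus the wind
#' direction, binned into equal angular bins (half-open `[lo, hi)`) and
#' normalised to mean 1. A bird sampling all circle sections equally gives
#' a flat histogram; systematically more time upwind shows up as bins > 1
#' around 180 degrees.
#'
#' @param events list of `circling_event`s.
#' @param nbins number of angular bins (default 24, i.e. 15 degrees).
#' @return Data frame with `bin_mid_deg` (centre of each bin, degrees
#'   relative to the direction the wind blows toward) and `freq`
#'   (normalised frequency, mean 1).
#' @export
heading_wind_histogram <- function(events, nbins = 24) {
  rel <- unlist(lapply(events, function(ev) {
    w <- ev$estimate$w
    a <- cbind(ev$window$g[, 1] - w[1], ev$window$g[, 2] - w[2])
    (atan2(a[, 2], a[, 1]) - atan2(w[2], w[1])) %% (2 * pi)
  }))
  breaks <- seq(0, 2 * pi, length.out = nbins + 1)
  idx <- findInterval(rel, breaks, rightmost.closed = FALSE)
  idx[idx > nbins] <- 1L  # rel == 2*pi wraps to the first bin
  counts <- tabulate(idx, nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  mids_deg <- ((mids * 180 / pi + 180) %% 360) - 180
  data.frame(bin_mid_deg = mids_deg, freq = counts / mean(counts))
}

#' Vertical profiles of wind speed and thermal strength
#'
#' Groups events into individual "thermals" by rasterising the
#' longitude-latitude plane into `cell_deg` squares and time into
#' `window_min` intervals (half-open bins; an event exactly on a boundary
#' falls into the higher cell). Within each group, events are sorted by
#' height and smoothed with running means over `smooth` subsequent points.
#'
#' @param events data frame with columns `lon`, `lat`, `time` (s), `height`
#'   (m), `wind_speed` (m/s) and `w_z` (m/s) - see [events_table()].
#' @param cell_deg raster cell size, degrees.
#' @param window_min time bin, minutes.
#' @param smooth running-mean window (points).
#' @return Data frame with one row per profile point: cell/bin identifiers,
#'   `height`, `wind_speed`, `w_z`, `n_events` and `smoothed` (FALSE for
#'   groups smaller than `smooth`, which are returned unsmoothed).
#' @export
thermal_profiles <- function(events, cell_deg = 0.1, window_min = 15,
                             smooth = 10) {
  key <- data.frame(cx = floor(events$lon / cell_deg),
                    cy = floor(events$lat / cell_deg),
                    tb = floor(events$time / (window_min * 60)))
  groups <- split(seq_len(nrow(events)), interaction(key, drop = TRUE))
  rows <- lapply(groups, function(idx) {
    idx <- idx[order(events$height[idx])]
    m <- length(idx)
    k <- key[idx[1], ]
    if (m >= smooth) {
      data.frame(cx = k$cx, cy = k$cy, tb = k$tb,
                 height = zoo::rollmean(events$height[idx], smooth),
                 wind_speed = zoo::rollmean(events$wind_speed[idx], smooth),
                 w_z = zoo::rollmean(events$w_z[idx], smooth),
                 n_events = m, smoothed = TRUE)
    } else {
      data.frame(cx = k$cx, cy = k$cy, tb = k$tb,
                 height = events$height[idx],
                 wind_speed = events$wind_speed[idx],
                 w_z = events$w_z[idx],
                 n_events = m, smoothed = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cx, out$cy, out$tb, out$height), ]
  rownames(out) <- NULL
  out
}

# Median (L1) regression via iteratively reweighted least squares.
median_regression <- function(x, y, max_iter = 100, eps = 1e-8) {
  b <- stats::coef(stats::lm(y ~ x))
  X <- cbind(1, x)
  for (it in seq_len(max_iter)) {
    r <- drop(y - X %*% b)
    w <- 1 / pmax(abs(r), eps)
    b_new <- stats::coef(stats::lm.wfit(X, y, w))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  stats::setNames(as.numeric(b), c("intercept", "slope"))
}

#' Airspeed and lift coefficient versus circling radius
#'
#' Restricts to events climbing faster than `min_climb`, bins the radius
#' into `bin_m`-wide groups (groups with fewer than `min_bin` events
#' omitted), reports the per-bin medians, and fits median (tau = 0.5)
#' regressions of airspeed and lift coefficient on radius over the retained
#' events, with bootstrap standard errors.
#'
#' @param events data frame with columns `radius`, `airspeed`, `c_l` and
#'   `gz` - see [events_table()].
#' @param min_climb minimum mean vertical ground speed, m/s.
#' @param bin_m radius bin width, m.
#' @param min_bin minimum events per retained bin.
#' @param boot bootstrap replicates for the standard errors (0 to skip).
#' @return List with `groups` (per-bin medians), `fit_airspeed` and
#'   `fit_cl` (each `estimate` = intercept/slope and `se`).
#' @export
radius_behavior_fits <- function(events, min_climb = 0.5, bin_m = 2,
                                 min_bin = 10, boot = 199) {
  ev <- events[events$gz > min_climb, , drop = FALSE]
  rbin <- floor(ev$radius / bin_m) * bin_m
  counts <- table(rbin)
  keep_bins <- as.numeric(names(counts)[counts >= min_bin])
  ev <- ev[rbin %in% keep_bins, , drop = FALSE]
  rbin <- rbin[rbin %in% keep_bins]
  if (length(unique(rbin)) < 2) stop("fewer than 2 usable radius bins")
  groups <- do.call(rbind, lapply(split(seq_len(nrow(ev)), rbin), function(idx) {
    data.frame(radius_bin = floor(ev$radius[idx[1]] / bin_m) * bin_m,
               radius = stats::median(ev$radius[idx]),
               airspeed = stats::median(ev$airspeed[idx]),
               c_l = stats::median(ev$c_l[idx]),
               n = length(idx))
  }))
  rownames(groups) <- NULL
  fit_one <- function(y) {
    est <- median_regression(ev$radius, y)
    se <- c(intercept = NA_real_, slope = NA_real_)
    if (boot > 0) {
      bs <- replicate(boot, {
        idx <- sample.int(nrow(ev), replace = TRUE)
        median_regression(ev$radius[idx], y[idx])
      })
      se <- apply(bs, 1, stats::sd)
    }
    list(estimate = est, se = se)
  }
  list(groups = groups,
       fit_airspeed = fit_one(ev$airspeed),
       fit_cl = fit_one(ev$c_l))
}
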