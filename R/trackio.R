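#' Movebank-style column mapping for track CSV files
#'
#' Maps the internal track fields to the column names found in the input file.
#' The defaults follow the Movebank CSV dialect. Any entry may be overridden,
#' e.g. `movebank_dialect(lon = "longitude")`.
#'
#' @param timestamp,lon,lat,height,speed,heading,id column names in the file.
#'   `speed`, `heading` and `id` are optional columns: they are read when
#'   present and ignored otherwise.
#' @return A named list of column names.
#' @export
movebank_dialect <- function(timestamp = "timestamp",
                             lon = "location-long",
                             lat = "location-lat",
                             height = "height-above-ellipsoid",
                             speed = "ground-speed",
                             heading = "heading",
                             id = "individual-local-identifier") {
  list(timestamp = timestamp, lon = lon, lat = lat, height = height,
       speed = speed, heading = heading, id = id)
}

#' Construct a track from a data frame
#'
#' A track is a data frame of time-ordered GPS fixes with numeric columns
#' `timestamp` (seconds since epoch), `lon`, `lat` (degrees WGS84), `height`
#' (metres) and optionally `speed` (m/s), `heading` (compass degrees) and
#' `id`.
#'
#' @param df data frame with at least `timestamp`, `lon`, `lat`, `height`.
#' @return An object of class `track`.
#' @export
as_track <- function(df) {
  required <- c("timestamp", "lon", "lat", "height")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("track is missing required column(s): ", paste(missing, collapse = ", "))
  }
  df$timestamp <- as.numeric(df$timestamp)
  if (nrow(df) > 1 && any(diff(df$timestamp) <= 0)) {
    stop("track timestamps must be strictly increasing")
  }
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude out of range [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude out of range [-180, 180]")
  class(df) <- c("track", "data.frame")
  df
}

parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  # ISO-8601, with or without 'T' separator / fractional seconds
  t <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  alt <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  t[is.na(t)] <- alt[is.na(t)]
  bad <- which(is.na(t) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    stop("unparseable timestamp at data row ", bad[1], ": '", x[bad[1]], "'")
  }
  as.numeric(t)
}

#' Read a GPS track from a CSV file
#'
#' Reads a Movebank-dialect CSV (see [movebank_dialect()]), sorts fixes by
#' time and drops duplicate timestamps (keeping the first occurrence). Lines
#' starting with `#` are treated as comments.
#'
#' @param path path to the CSV file.
#' @param dialect column mapping, see [movebank_dialect()].
#' @return A [as_track()] object. The number of dropped duplicate rows is
#'   available as `attr(x, "dropped")`.
#' @export
read_track <- function(path, dialect = movebank_dialect()) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  for (field in c("timestamp", "lon", "lat", "height")) {
    if (!dialect[[field]] %in% names(raw)) {
      stop("missing required column '", dialect[[field]], "' in ", path)
    }
  }
  df <- data.frame(
    timestamp = parse_timestamps(raw[[dialect$timestamp]]),
    lon = as.numeric(raw[[dialect$lon]]),
    lat = as.numeric(raw[[dialect$lat]]),
    height = as.numeric(raw[[dialect$height]])
  )
  for (field in c("speed", "heading", "id")) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) df[[field]] <- raw[[col]]
  }
  df <- df[order(df$timestamp), , drop = FALSE]
  dup <- duplicated(df$timestamp)
  dropped <- sum(dup)
  if (dropped > 0) {
    warning(dropped, " fix(es) with duplicate timestamps dropped (kept first)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  out <- as_track(df)
  attr(out, "dropped") <- dropped
  out
}

#' Write a track to a CSV file
#'
#' Inverse of [read_track()]: writes the Movebank-dialect columns, with
#' timestamps formatted as ISO-8601 UTC (millisecond precision). Optional
#' header comment lines (prefixed `#`) can carry provenance metadata.
#'
#' @param track a `track` object.
#' @param path output path.
#' @param dialect column mapping, see [movebank_dialect()].
#' @param header optional character vector of comment lines written first.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, dialect = movebank_dialect(), header = NULL) {
  out <- data.frame(
    format(as.POSIXct(track$timestamp, tz = "UTC", origin = "1970-01-01"),
           "%Y-%m-%d %H:%M:%OS3"),
    track$lon, track$lat, track$height,
    check.names = FALSE
  )
  names(out) <- c(dialect$timestamp, dialect$lon, dialect$lat, dialect$height)
  for (field in c("speed", "heading", "id")) {
    if (!is.null(track[[field]])) out[[dialect[[field]]]] <- track[[field]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Project a track onto a local tangent plane
#'
#' Azimuthal-equidistant projection around a reference point: each fix is
#' placed at (x, y) = (d sin az, d cos az) where d and az are the WGS84
#' geodesic distance and azimuth from the reference (x east, y north,
#' metres). The projection is locally isometric; within the ~1 km footprint
#' of a thermal, pairwise distance distortion is far below 0.1%.
#'
#' @param track a `track` object.
#' @param ref reference `c(lon, lat)`; defaults to the first fix.
#' @param max_range_m maximum allowed distance of any fix from `ref`
#'   (thermals are local; default 50 km).
#' @return The track with `x` and `y` columns added and the reference stored
#'   as `attr(x, "ref")`.
#' @export
project_local <- function(track, ref = NULL, max_range_m = 5e4) {
  if (is.null(ref)) ref <- c(track$lon[1], track$lat[1])
  gi <- geosphere::geodesic_inverse(matrix(ref, ncol = 2),
                                    cbind(track$lon, track$lat))
  d <- gi[, "distance"]
  if (any(d > max_range_m)) {
    stop("fix ", which.max(d), " is ", round(max(d) / 1000, 1),
         " km from the reference point (limit ", max_range_m / 1000, " km)")
  }
  az <- gi[, "azimuth1"] * pi / 180
  track$x <- d * sin(az)
  track$y <- d * cos(az)
  attr(track, "ref") <- ref
  track
}

#' Convert local planar coordinates back to longitude/latitude
#'
#' Inverse of [project_local()], using the same WGS84 geodesic engine so the
#' round trip is exact to machine precision.
#'
#' @param xy two-column matrix of (x east, y north) metres.
#' @param ref reference `c(lon, lat)`.
#' @return Two-column matrix of (lon, lat) degrees.
#' @export
local_to_lonlat <- function(xy, ref) {
  xy <- matrix(xy, ncol = 2)
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  az <- atan2(xy[, 1], xy[, 2]) * 180 / pi
  p <- geosphere::geodesic(matrix(ref, ncol = 2), az, d)
  cbind(lon = p[, "longitude"], lat = p[, "latitude"])
}

#' Construct a uniform-rate ground-velocity sequence
#'
#' @param g n x 2 matrix of ground-velocity vectors (x east, y north), m/s.
#' @param z heights aligned to the velocity index, metres.
#' @param dt sampling interval, seconds.
#' @param origin list with `lon`, `lat`, `timestamp` of the first fix.
#' @param t fix timestamps aligned to the velocity index (optional).
#' @param pos n x 2 matrix of planar fix positions aligned to the velocity
#'   index (optional; used for pairing and profiling).
#' @return An object of class `velocity_seq`.
#' @export
velocity_seq <- function(g, z, dt, origin = NULL, t = NULL, pos = NULL) {
  g <- matrix(as.numeric(g), ncol = 2)
  if (!all(is.finite(g))) stop("velocity sequence contains non-finite vectors")
  if (length(z) != nrow(g)) stop("heights must align with the velocity index")
  if (dt <= 0) stop("dt must be positive")
  structure(list(g = g, z = as.numeric(z), dt = dt, origin = origin,
                 t = t, pos = pos),
            class = "velocity_seq")
}

#' @export
print.velocity_seq <- function(x, ...) {
  cat("<velocity_seq> n =", nrow(x$g), " dt =", x$dt, "s\n")
  cat("  mean ground speed:", round(mean(sqrt(rowSums(x$g^2))), 2), "m/s\n")
  invisible(x)
}

#' @export
length.velocity_seq <- function(x) nrow(x$g)

# Subset a velocity sequence to a window of consecutive indices.
vs_window <- function(vs, start, len) {
  idx <- start:(start + len - 1)
  velocity_seq(vs$g[idx, , drop = FALSE], vs$z[idx], vs$dt, vs$origin,
               t = vs$t[idx], pos = vs$pos[idx, , drop = FALSE])
}

#' Derive ground velocities from a planar track
#'
#' With `method = "positions"` the velocity at fix i is the forward
#' difference (p[i+1] - p[i]) / dt (the step vectors connecting subsequent
#' positions; sequence length n-1). With `method = "doppler"` the receiver's
#' instantaneous speed and compass heading are used directly:
#' g[i] = speed[i] * (sin heading, cos heading) (length n).
#'
#' @param track a projected track (see [project_local()]; projection to the
#'   first fix is applied automatically when missing).
#' @param method `"positions"` (default) or `"doppler"`.
#' @param dt_tol relative tolerance on sampling-interval uniformity.
#' @return A [velocity_seq()] with heights and timestamps carried through
#'   aligned to the velocity index.
#' @export
ground_velocities <- function(track, method = c("positions", "doppler"),
                              dt_tol = 0.1) {
  method <- match.arg(method)
  if (is.null(track$x)) track <- project_local(track)
  n <- nrow(track)
  if (n < 2) stop("need at least two fixes")
  dts <- diff(track$timestamp)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > dt_tol * dt)) {
    stop("non-uniform sampling interval; split the track with segment_bursts() first")
  }
  origin <- list(lon = track$lon[1], lat = track$lat[1],
                 timestamp = track$timestamp[1])
  if (method == "positions") {
    g <- cbind(diff(track$x), diff(track$y)) / dt
    keep <- seq_len(n - 1)
  } else {
    if (is.null(track$speed) || is.null(track$heading)) {
      stop("doppler method requires 'speed' and 'heading' columns")
    }
    th <- track$heading * pi / 180  # compass: clockwise from north
    g <- cbind(track$speed * sin(th), track$speed * cos(th))
    keep <- seq_len(n)
  }
  velocity_seq(g, track$height[keep], dt, origin,
               t = track$timestamp[keep],
               pos = cbind(track$x, track$y)[keep, , drop = FALSE])
}

#' Segment a track into uniform-rate bursts
#'
#' Finds maximal runs of fixes whose inter-fix interval is within
#' `dt_tol` of `dt`, discards runs shorter than `min_len` fixes, and returns
#' the remaining runs as ground-velocity sequences.
#'
#' @param track a `track` object.
#' @param dt nominal sampling interval, seconds.
#' @param min_len minimum number of fixes per burst.
#' @param ref projection reference passed to [project_local()].
#' @param method velocity derivation method, see [ground_velocities()].
#' @param dt_tol relative tolerance on the inter-fix interval.
#' @return List of [velocity_seq()] bursts; the number of discarded short
#'   runs is available as `attr(x, "discarded")`.
#' @export
segment_bursts <- function(track, dt = 1, min_len = 19, ref = NULL,
                           method = "positions", dt_tol = 0.1) {
  if (is.null(track$x)) track <- project_local(track, ref = ref)
  n <- nrow(track)
  if (n < 2) return(structure(list(), discarded = as.integer(n > 0)))
  ok <- abs(diff(track$timestamp) - dt) <= dt_tol * dt
  # run starts: fix i starts a run if interval i-1 is broken (or i == 1)
  breaks <- c(0, which(!ok), n)
  bursts <- list()
  discarded <- 0L
  for (j in seq_len(length(breaks) - 1)) {
    idx <- (breaks[j] + 1):breaks[j + 1]
    if (length(idx) >= min_len) {
      bursts[[length(bursts) + 1]] <-
        ground_velocities(track[idx, , drop = FALSE], method = method,
                          dt_tol = dt_tol)
    } else {
      discarded <- discarded + 1L
    }
  }
  attr(bursts, "discarded") <- discarded
  bursts
}
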