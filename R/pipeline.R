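# Pipeline wiring: per-event output tables, CSV/JSON artifacts, and the
# subcommand runner used by the exec/thermalwind command-line script.

#' Flatten circling events into an output table
#'
#' One row per event with the wind estimate, its covariance, fit
#' diagnostics and the full set of flight characteristics; this is the
#' schema written to `events.csv` by the pipeline.
#'
#' @param events list of `circling_event`s.
#' @param params [stork_params()] aerodynamic parameters.
#' @return Data frame; see column names in the source. `lon`, `lat`,
#'   `time` and `height` are window means, for pairing and profiling.
#' @export
events_table <- function(events, params = stork_params()) {
  if (length(events) == 0) return(NULL)
  rows <- lapply(events, function(ev) {
    est <- ev$estimate
    fc <- flight_characteristics(ev, params)
    vs <- ev$window
    center <- colMeans(vs$pos)
    ll <- if (!is.null(vs$origin)) {
      local_to_lonlat(center, c(vs$origin$lon, vs$origin$lat))
    } else matrix(NA_real_, 1, 2)
    data.frame(
      burst = if (is.null(ev$burst)) NA_integer_ else ev$burst,
      start = ev$start, end = ev$end,
      t_start = vs$t[1], t_end = vs$t[length(vs)],
      time = mean(vs$t), lon = ll[1, 1], lat = ll[1, 2],
      height = mean(vs$z),
      wind_x = est$w[1], wind_y = est$w[2],
      wind_speed = sqrt(sum(est$w^2)),
      cov_xx = est$cov[1, 1], cov_xy = est$cov[1, 2], cov_yy = est$cov[2, 2],
      sigma2 = est$sigma2_hat, airspeed = est$a_hat, phi = est$phi,
      converged = est$converged, cov_valid = est$cov_valid,
      direction = ev$direction, gz = fc$gz, omega = fc$omega,
      radius = fc$radius, circle_time = fc$circle_time,
      beta_deg = fc$beta_deg, c_l = fc$c_l, c_d = fc$c_d, drag = fc$drag,
      sink_rate = fc$sink_rate, w_z = fc$w_z)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Polynomial rolling hash of a deparsed object, for provenance headers.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(config, seed) {
  # hash only analysis-relevant settings, not file-system paths
  cfg <- config[setdiff(names(config),
                        c("input", "out", "profiles_out", "truth", "workdir"))]
  c(paste0("thermalwind ", as.character(utils::packageVersion("thermalwind"))),
    paste0("config_hash=", config_hash(cfg)),
    paste0("seed=", if (is.null(seed)) "NA" else seed))
}

write_table_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output CSV (events, pairs or profiles)
#'
#' @param path CSV path; `#` header comment lines are skipped.
#' @return Data frame.
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

config_default <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

config_error <- function(...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

pipeline_detect <- function(config, seed) {
  input <- config$input
  if (is.null(input)) config_error("missing required config key: input")
  if (!file.exists(input)) config_error("input file does not exist: ", input)
  track <- read_track(input)
  bursts <- segment_bursts(track,
                           dt = config_default(config, "dt", 1),
                           min_len = config_default(config, "window_length", 19),
                           method = config_default(config, "method", "positions"))
  phi <- config_default(config, "phi", "estimate")
  det <- detect_circling_events(bursts,
                                window_length = config_default(config, "window_length", 19),
                                phi = phi)
  events <- filter_quality(det$events,
                           max_sd = config_default(config, "max_sd", 1.0))
  message(sprintf("detect: %d burst(s), %d event(s) (%d dropped by quality), phi_hat = %s",
                  length(bursts), length(events), attr(events, "dropped"),
                  format(det$phi_hat, digits = 3)))
  list(events = events, det = det)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic track), `detect-circles`
#' (track -> events.csv with flight characteristics), `estimate-wind`
#' (wind per disjoint window, without circling classification),
#' `flight-chars` (alias of detect-circles), `validate-pairs` (two tracks
#' assumed co-thermalling -> pairwise partial deviances), `profiles`
#' (events.csv -> vertical thermal profiles) and `end-to-end`
#' (simulate or read -> detect -> events.csv + profiles.csv).
#'
#' All outputs carry a `#` header with the package version, a config hash
#' and the seed. Config validation failures signal a `config_error`
#' condition (exit status 2 in the command-line wrapper); data errors
#' signal ordinary errors (exit status 1).
#'
#' @param subcommand one of the names above.
#' @param config named list of options; see the source of each stage for
#'   the recognised keys (`input`, `out`, `window_length`, `phi`,
#'   `max_sd`, `sim`, `truth`, `seed`, ...).
#' @return The primary result of the stage, invisibly.
#' @export
run_pipeline <- function(subcommand, config = list()) {
  seed <- config$seed
  hdr <- output_header(config, seed)
  out <- config_default(config, "out", NULL)
  result <- switch(
    subcommand,
    "simulate" = {
      if (is.null(out)) config_error("missing required config key: out")
      sim_args <- config_default(config, "sim", list())
      sim_args$seed <- if (!is.null(seed)) seed else sim_args$seed
      sim <- simulate_track(do.call(sim_config, sim_args))
      write_track(sim$track, out, header = hdr)
      if (!is.null(config$truth)) {
        truth <- sim$truth
        truth$config$seed <- sim_args$seed
        truth$config <- unclass(truth$config)
        jsonlite::write_json(truth[c("config", "wind", "climb")],
                             config$truth, auto_unbox = TRUE, digits = NA)
      }
      sim
    },
    "detect-circles" = ,
    "flight-chars" = {
      res <- pipeline_detect(config, seed)
      tab <- events_table(res$events)
      if (!is.null(out)) {
        if (is.null(tab)) tab <- data.frame()
        write_table_csv(tab, out, hdr)
      }
      res$events
    },
    "estimate-wind" = {
      input <- config$input
      if (is.null(input)) config_error("missing required config key: input")
      if (!file.exists(input)) config_error("input file does not exist: ", input)
      wl <- config_default(config, "window_length", 19)
      phi <- config_default(config, "phi", 0)
      track <- read_track(input)
      bursts <- segment_bursts(track, dt = config_default(config, "dt", 1),
                               min_len = wl)
      rows <- list()
      for (b in seq_along(bursts)) {
        n <- length(bursts[[b]])
        for (s in seq(1, n - wl + 1, by = wl)) {
          win <- vs_window(bursts[[b]], s, wl)
          est <- estimate_wind(win, phi = if (is.numeric(phi)) phi else 0)
          rows[[length(rows) + 1]] <- data.frame(
            burst = b, start = s, t_start = win$t[1],
            wind_x = est$w[1], wind_y = est$w[2],
            cov_xx = est$cov[1, 1], cov_xy = est$cov[1, 2],
            cov_yy = est$cov[2, 2], sigma2 = est$sigma2_hat,
            airspeed = est$a_hat, converged = est$converged,
            cov_valid = est$cov_valid)
        }
      }
      tab <- do.call(rbind, rows)
      if (!is.null(out)) write_table_csv(tab, out, hdr)
      tab
    },
    "validate-pairs" = {
      inputs <- config$input
      if (is.null(inputs) || length(inputs) != 2) {
        config_error("validate-pairs needs config$input with two track paths")
      }
      evs <- lapply(inputs, function(p) {
        cfg <- config
        cfg$input <- p
        pipeline_detect(cfg, seed)$events
      })
      n <- min(length(evs[[1]]), length(evs[[2]]))
      if (n == 0) config_error("no overlapping circling events to pair")
      rows <- lapply(seq_len(n), function(i) {
        pc <- pair_partial_deviances(evs[[1]][[i]]$estimate,
                                     evs[[2]][[i]]$estimate)
        data.frame(pair = i, d_x = pc$d[1], d_y = pc$d[2],
                   d_major = pc$d_major, d_minor = pc$d_minor,
                   sigma2_major = pc$sigma2_major,
                   sigma2_minor = pc$sigma2_minor)
      })
      tab <- do.call(rbind, rows)
      if (!is.null(out)) write_table_csv(tab, out, hdr)
      tab
    },
    "profiles" = {
      input <- config$input
      if (is.null(input)) config_error("missing required config key: input")
      if (!file.exists(input)) config_error("input file does not exist: ", input)
      ev <- read_events_csv(input)
      prof <- thermal_profiles(ev,
                               cell_deg = config_default(config, "cell_deg", 0.1),
                               window_min = config_default(config, "window_min", 15),
                               smooth = config_default(config, "smooth", 10))
      if (!is.null(out)) write_table_csv(prof, out, hdr)
      prof
    },
    "end-to-end" = {
      workdir <- config_default(config, "workdir", tempdir())
      track_path <- config$input
      if (is.null(track_path)) {
        track_path <- file.path(workdir, "track.csv")
        run_pipeline("simulate", list(sim = config_default(config, "sim", list()),
                                      seed = seed, out = track_path))
      } else if (!file.exists(track_path)) {
        config_error("input file does not exist: ", track_path)
      }
      events_path <- config_default(config, "out",
                                    file.path(workdir, "events.csv"))
      cfg <- config
      cfg$input <- track_path
      cfg$out <- events_path
      events <- run_pipeline("detect-circles", cfg)
      prof_path <- config_default(config, "profiles_out",
                                  file.path(workdir, "profiles.csv"))
      tab <- events_table(events)
      if (!is.null(tab) && nrow(tab) > 0) {
        prof <- thermal_profiles(tab)
        write_table_csv(prof, prof_path, hdr)
      }
      list(events = events, events_csv = events_path,
           profiles_csv = prof_path)
    },
    config_error("unknown subcommand: ", subcommand)
  )
  invisible(result)
}
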