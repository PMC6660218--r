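# Interchange formats: comma-delimited text with fixed headers, hours and
# arbitrary units throughout.

#' Read and write trace and trajectory files
#'
#' Single-channel traces use the header `time_hr,intensity,channel,replicate`;
#' dual-channel traces `time_hr,green,red,replicate`; simulated trajectories
#' `time_hr,R,NP,MP`; metric tables `metric,channel,value,units`; inferred
#' activity `time_hr,f_est,mp_smooth,clamped`.
#'
#' @param path File path.
#' @return `read_trace()` returns a validated data.frame.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_hr", "intensity")
  if (!all(need %in% names(df)))
    stop("trace file must have columns time_hr,intensity[,channel,replicate]",
         call. = FALSE)
  df
}

#' @rdname read_trace
#' @param df Data to write (columns as above).
#' @export
write_trace <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @param sim A `simulation_result`.
#' @export
write_simulation <- function(sim, path) {
  utils::write.csv(sim[, c("time_hr", "R", "NP", "MP")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @param series List of dual-channel replicate data.frames.
#' @export
write_dual_series <- function(series, path) {
  if (is.data.frame(series)) series <- list(series)
  df <- do.call(rbind, lapply(series, function(x)
    x[, c("time_hr", "green", "red", "replicate")]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' One YAML document per run. Top-level keys: `command` (one of simulate,
#' metrics, fit_halflife, deconvolve, synth), `out_prefix`, `seed`, plus the
#' command-specific blocks (`reporter`, `reporter_red`, `cascade`, `program`,
#' `grid`, `acquisition`, `inference`, `input`, `decay`). Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to the YAML config.
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed <- c("command", "out_prefix", "seed", "log_level", "reporter",
               "reporter_red", "cascade", "program", "grid", "acquisition",
               "inference", "input", "decay")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$command) ||
      !cfg$command %in% c("simulate", "metrics", "fit_halflife",
                          "deconvolve", "synth"))
    stop("config 'command' must be one of simulate, metrics, fit_halflife, ",
         "deconvolve, synth", call. = FALSE)
  if (is.null(cfg$out_prefix))
    stop("config requires 'out_prefix'", call. = FALSE)
  cfg
}

cfg_reporter <- function(block) {
  if (is.null(block)) stop("config requires a 'reporter' block", call. = FALSE)
  do.call(reporter_params, block)
}

cfg_program <- function(block) {
  if (is.null(block)) stop("config requires a 'program' block", call. = FALSE)
  if (!is.null(block$table)) block$table <- as.data.frame(block$table)
  do.call(promoter_program, block)
}

write_resolved_config <- function(cfg, prefix) {
  cfg$package_version <- as.character(utils::packageVersion("transtimer"))
  yaml::write_yaml(cfg, paste0(prefix, "_config.yml"))
}

#' Run one configured analysis step
#'
#' Dispatches a validated config (see [read_run_config()]) to the matching
#' analysis: forward simulation (single, dual, or Gal4-cascade), trace
#' metrics, half-life fitting, promoter deconvolution, or synthetic data
#' generation. Every run writes its outputs under `out_prefix` plus the
#' resolved configuration (`<prefix>_config.yml`), and is deterministic given
#' config and seed.
#'
#' @param cfg Config list or path to a YAML config.
#' @return Invisible character vector of the files written.
#' @export
run_command <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  files <- switch(cfg$command,
    simulate = run_simulate(cfg),
    metrics = run_metrics(cfg),
    fit_halflife = run_fit_halflife(cfg),
    deconvolve = run_deconvolve(cfg),
    synth = run_synth(cfg))
  write_resolved_config(cfg, cfg$out_prefix)
  invisible(c(files, paste0(cfg$out_prefix, "_config.yml")))
}

run_simulate <- function(cfg) {
  grid <- cfg$grid
  if (is.null(grid$t_end) || is.null(grid$dt))
    stop("config 'grid' must give t_end and dt", call. = FALSE)
  program <- cfg_program(cfg$program)
  out <- character(0)
  if (!is.null(cfg$cascade)) {
    cas <- cfg$cascade
    cas$reporter <- cfg_reporter(cfg$reporter)
    sim <- simulate_gal4_cascade(do.call(cascade_params, cas), program,
                                 grid$t_end, grid$dt)
    out <- paste0(cfg$out_prefix, "_cascade.csv")
    write_simulation(sim, out)
  } else if (!is.null(cfg$reporter_red)) {
    dual <- simulate_dual(cfg_reporter(cfg$reporter),
                          cfg_reporter(cfg$reporter_red),
                          program, grid$t_end, grid$dt)
    dual$replicate <- 1L
    out <- paste0(cfg$out_prefix, "_dual.csv")
    write_dual_series(dual, out)
  } else {
    sim <- simulate_reporter(cfg_reporter(cfg$reporter), program,
                             grid$t_end, grid$dt)
    out <- paste0(cfg$out_prefix, "_sim.csv")
    write_simulation(sim, out)
  }
  out
}

run_metrics <- function(cfg) {
  if (is.null(cfg$input)) stop("config requires 'input'", call. = FALSE)
  df <- read_trace(cfg$input)
  if (!nrow(df)) stop("input trace file is empty", call. = FALSE)
  opts <- cfg$inference
  rows <- list()
  for (ch in unique(df$channel %||% "signal")) {
    sub <- if (is.null(df$channel)) df else df[df$channel == ch, ]
    pk <- peak_intensity(sub$time_hr, sub$intensity)
    rows[[length(rows) + 1L]] <-
      data.frame(metric = c("peak_intensity", "peak_time"), channel = ch,
                 value = c(pk$value, pk$time), units = c("AU", "hr"))
    for (dir in c("on", "off")) {
      t50 <- tryCatch(response_time(sub$time_hr, sub$intensity, dir),
                      error = function(e) NA_real_)
      if (!is.na(t50))
        rows[[length(rows) + 1L]] <-
          data.frame(metric = paste0("t50_", dir), channel = ch,
                     value = t50, units = "hr")
    }
    if (!is.null(opts$period)) {
      dr <- tryCatch(dynamic_range(sub$time_hr, sub$intensity, opts$period),
                     error = function(e) NA_real_)
      if (!is.na(dr))
        rows[[length(rows) + 1L]] <-
          data.frame(metric = "dynamic_range", channel = ch,
                     value = dr, units = "dimensionless")
    }
  }
  out <- paste0(cfg$out_prefix, "_metrics.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE,
                   quote = FALSE)
  out
}

run_fit_halflife <- function(cfg) {
  if (is.null(cfg$input)) stop("config requires 'input'", call. = FALSE)
  df <- read_trace(cfg$input)
  opts <- cfg$inference
  if (!is.null(opts$background)) df$intensity <- df$intensity - opts$background
  if (!is.null(opts$bleach_per_frame)) {
    # per replicate, frames are consecutive acquisition indices
    for (r in unique(df$replicate %||% 1L)) {
      idx <- if (is.null(df$replicate)) seq_len(nrow(df))
             else which(df$replicate == r)
      df$intensity[idx] <- correct_bleach(df$intensity[idx],
                                          opts$bleach_per_frame)
    }
  }
  win <- if (!is.null(opts$t_window)) unlist(opts$t_window)
  fit <- fit_halflife(df$time_hr, df$intensity, t_window = win)
  out <- paste0(cfg$out_prefix, "_halflife.csv")
  utils::write.csv(
    data.frame(metric = c("halflife", "ci95_low", "ci95_high", "slope",
                          "intercept", "r_squared", "n_points"),
               channel = df$channel[1L] %||% "signal",
               value = c(fit$halflife, fit$ci95[1L], fit$ci95[2L], fit$slope,
                         fit$intercept, fit$r_squared, fit$n_points),
               units = c("hr", "hr", "hr", "1/hr", "log-AU", "", "count")),
    out, row.names = FALSE, quote = FALSE)
  out
}

run_deconvolve <- function(cfg) {
  if (is.null(cfg$input)) stop("config requires 'input'", call. = FALSE)
  df <- read_trace(cfg$input)
  params <- cfg_reporter(cfg$reporter)
  opts <- cfg$inference
  dec <- deconvolve_promoter(df$time_hr, df$intensity, params,
                             use_maturation = isTRUE(opts$use_maturation),
                             clamp = !isFALSE(opts$clamp),
                             window = opts$window,
                             order = opts$order %||% 4L)
  out <- paste0(cfg$out_prefix, "_activity.csv")
  utils::write.csv(dec[, c("time_hr", "f_est", "mp_smooth", "clamped")],
                   out, row.names = FALSE, quote = FALSE)
  out
}

run_synth <- function(cfg) {
  if (is.null(cfg$acquisition))
    stop("config requires an 'acquisition' block", call. = FALSE)
  acq_block <- cfg$acquisition
  if (is.null(acq_block$seed)) acq_block$seed <- cfg$seed
  acq <- do.call(acquisition_config, acq_block)
  series <- if (!is.null(cfg$decay)) {
    make_decay_experiment(unlist(cfg$decay$true_halflives),
                          unlist(cfg$decay$mp0 %||% c(1, 1)), acq)
  } else {
    make_reporter_timecourse(cfg_program(cfg$program),
                             cfg_reporter(cfg$reporter),
                             cfg_reporter(cfg$reporter_red %||%
                                            cfg$reporter), acq)
  }
  out <- paste0(cfg$out_prefix, "_synth.csv")
  write_dual_series(series, out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
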