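# Run code with a local RNG state derived from 'seed', restoring the global
# state afterwards so the generator never perturbs user code.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Acquisition settings for synthetic time-lapse traces
#'
#' Describes the imaging conditions the generator emulates: frame interval
#' (5-10 min is typical for light-sheet time-lapse), total span, number of
#' independent replicates, multiplicative intensity noise, additive
#' background, and per-exposure photobleaching.
#'
#' @param span Total acquisition span (hr), > 0.
#' @param interval Frame interval (hr); default 1/12 hr (5 min).
#' @param n_replicates Number of replicates (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   intensity noise (default 0.05).
#' @param background Additive background (AU, default 0.02 on the unit signal
#'   scale).
#' @param bleach_per_frame Fraction of signal lost per exposure
#'   (default 0.002).
#' @param seed Integer seed; mandatory so every dataset is reproducible.
#' @param scale_jitter Optional per-replicate intensity scale CV (default 0,
#'   i.e. replicates differ only in noise).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(span, interval = 1 / 12, n_replicates = 3L,
                               noise_cv = 0.05, background = 0.02,
                               bleach_per_frame = 0.002, seed,
                               scale_jitter = 0) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory (reproducibility contract)", call. = FALSE)
  stopifnot(is.numeric(span), span > 0, is.numeric(interval), interval > 0,
            n_replicates >= 1L, noise_cv >= 0, background >= 0,
            bleach_per_frame >= 0, bleach_per_frame < 1, scale_jitter >= 0)
  structure(list(span = span, interval = interval,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, background = background,
                 bleach_per_frame = bleach_per_frame,
                 seed = as.integer(seed), scale_jitter = scale_jitter),
            class = "acquisition_config")
}

acq_times <- function(acq) seq(0, acq$span, by = acq$interval)

# Shared observation model: true signal -> bleach -> multiplicative noise
# (truncated at zero) -> additive background.
observe_signal <- function(signal, acq, scale = 1) {
  frames <- seq_along(signal) - 1L
  bleach <- (1 - acq$bleach_per_frame)^frames
  noise <- pmax(0, 1 + acq$noise_cv * stats::rnorm(length(signal)))
  scale * signal * bleach * noise + acq$background
}

#' Synthetic transcription-blocked decay experiment
#'
#' Emulates an Actinomycin chase: transcription stops at t = 0 and the mature
#' green and red signals decay exponentially with their true half-lives. Each
#' replicate shares the true trajectory and differs only in noise (plus an
#' optional per-replicate scale jitter). Observation model per channel:
#' exponential decay x cumulative per-frame bleach x truncated multiplicative
#' Gaussian noise + constant background. Deterministic given the seed.
#'
#' @param true_halflives Named or ordered pair `c(green, red)` of true
#'   half-lives (hr), > 0.
#' @param mp0 Initial intensities `c(green, red)` (AU), > 0.
#' @param acq An [acquisition_config()].
#' @return List of data.frames (`time_hr, green, red, replicate`), one per
#'   replicate, with the generating truth attached as attribute `truth`.
#' @export
make_decay_experiment <- function(true_halflives = c(green = 2, red = 20),
                                  mp0 = c(green = 1, red = 1), acq) {
  stopifnot(inherits(acq, "acquisition_config"),
            length(true_halflives) == 2L, all(true_halflives > 0),
            length(mp0) == 2L, all(mp0 > 0))
  times <- acq_times(acq)
  truth_g <- mp0[[1L]] * 2^(-times / true_halflives[[1L]])
  truth_r <- mp0[[2L]] * 2^(-times / true_halflives[[2L]])
  with_local_seed(acq$seed, {
    lapply(seq_len(acq$n_replicates), function(r) {
      scale <- if (acq$scale_jitter > 0)
        max(0, 1 + acq$scale_jitter * stats::rnorm(1L)) else 1
      out <- data.frame(time_hr = times,
                        green = observe_signal(truth_g, acq, scale),
                        red = observe_signal(truth_r, acq, scale),
                        replicate = r)
      attr(out, "truth") <- list(halflives = true_halflives, mp0 = mp0,
                                 green = truth_g, red = truth_r, acq = acq)
      out
    })
  })
}

#' Synthetic dual-reporter time-lapse under a promoter program
#'
#' Forward-simulates both timer channels with the reporter model, samples the
#' mature-fluorophore trajectories on the acquisition grid, and applies the
#' bleach / noise / background observation model per replicate. The noiseless
#' limit (cv = 0, bleach = 0, background = 0) equals the simulator output at
#' the acquisition times.
#'
#' @param program A [promoter_program()].
#' @param params_green,params_red [reporter_params()] for the two channels.
#' @param acq An [acquisition_config()].
#' @return List of data.frames (`time_hr, green, red, replicate`) with the
#'   generating program, parameters and true trajectories in attribute
#'   `truth`.
#' @export
make_reporter_timecourse <- function(program,
                                     params_green = dgfp_params(),
                                     params_red = rfp_params(), acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  sim <- simulate_dual(params_green, params_red, program,
                       t_end = acq$span, dt = acq$interval)
  with_local_seed(acq$seed, {
    lapply(seq_len(acq$n_replicates), function(r) {
      scale <- if (acq$scale_jitter > 0)
        max(0, 1 + acq$scale_jitter * stats::rnorm(1L)) else 1
      out <- data.frame(time_hr = sim$time_hr,
                        green = observe_signal(sim$green, acq, scale),
                        red = observe_signal(sim$red, acq, scale),
                        replicate = r)
      attr(out, "truth") <- list(program = program,
                                 params_green = params_green,
                                 params_red = params_red,
                                 green = sim$green, red = sim$red,
                                 acq = acq)
      out
    })
  })
}

#' Photobleaching calibration series and estimator
#'
#' `make_bleach_calibration()` emulates the standard control of continuously
#' imaging a constant sample: intensity = signal x (1 - b)^frame x
#' multiplicative noise (no background; the control is bright, and
#' [estimate_bleach()] expects background-subtracted input).
#' `estimate_bleach()` recovers the per-frame bleach fraction by log-linear
#' regression of intensity on frame index, and [correct_bleach()] divides a
#' trace by the cumulative bleach factor.
#'
#' @param n_frames Number of consecutive frames (>= 10, default 50).
#' @param acq An [acquisition_config()] supplying `noise_cv`,
#'   `bleach_per_frame` and the seed.
#' @param signal True constant intensity (AU).
#' @return `make_bleach_calibration()`: data.frame
#'   (`frame, time_hr, intensity`). `estimate_bleach()`: estimated per-frame
#'   bleach fraction. `correct_bleach()`: corrected intensities.
#' @export
make_bleach_calibration <- function(n_frames = 50L, acq, signal = 1) {
  stopifnot(inherits(acq, "acquisition_config"), signal > 0)
  n_frames <- as.integer(n_frames)
  if (n_frames < 10L)
    stop("insufficient data: need at least 10 frames", call. = FALSE)
  frames <- 0:(n_frames - 1L)
  with_local_seed(acq$seed, {
    noise <- pmax(0, 1 + acq$noise_cv * stats::rnorm(n_frames))
    data.frame(frame = frames, time_hr = frames * acq$interval,
               intensity = signal * (1 - acq$bleach_per_frame)^frames * noise)
  })
}

#' @rdname make_bleach_calibration
#' @param intensity Background-subtracted calibration intensities, one per
#'   consecutive frame, all > 0.
#' @export
estimate_bleach <- function(intensity) {
  if (is.data.frame(intensity)) intensity <- intensity$intensity
  stopifnot(is.numeric(intensity))
  if (length(intensity) < 10L)
    stop("insufficient data: need at least 10 frames", call. = FALSE)
  if (any(intensity <= 0))
    stop("calibration intensities must be positive (background-subtracted)",
         call. = FALSE)
  frame <- seq_along(intensity) - 1L
  slope <- unname(stats::coef(stats::lm(log(intensity) ~ frame))[2L])
  1 - exp(slope)
}

#' @rdname make_bleach_calibration
#' @param values Intensities to correct, one per consecutive frame.
#' @param bleach_per_frame Per-frame bleach fraction (from
#'   [estimate_bleach()] or known).
#' @export
correct_bleach <- function(values, bleach_per_frame) {
  stopifnot(is.numeric(values), bleach_per_frame >= 0, bleach_per_frame < 1)
  frames <- seq_along(values) - 1L
  values / (1 - bleach_per_frame)^frames
}
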