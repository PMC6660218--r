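# Accepts either (times, values) vectors or a two-column data.frame in the
# first argument; returns list(times, values).
as_trace <- function(times, values = NULL) {
  if (is.null(values)) {
    stopifnot(is.data.frame(times), ncol(times) >= 2L)
    values <- times[[2L]]
    times <- times[[1L]]
  }
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 3L)
    stop("a trace needs at least 3 points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("intensities must be finite", call. = FALSE)
  list(times = times, values = values)
}

# First time values crosses 'target' in the given direction, linearly
# interpolated between grid points; NA if never.
first_crossing <- function(times, values, target, rising) {
  hit <- if (rising) values >= target else values <= target
  if (hit[1L]) return(times[1L])
  i <- which(hit)
  if (!length(i)) return(NA_real_)
  i <- i[1L]
  y0 <- values[i - 1L]; y1 <- values[i]
  if (y1 == y0) return(times[i])
  times[i - 1L] + (target - y0) / (y1 - y0) * (times[i] - times[i - 1L])
}

#' Response time of a reporter trace
#'
#' Time for the signal to reach (`direction = "on"`) or fall to
#' (`direction = "off"`) `level` (default 50%) of its maximal intensity. For
#' switch-on the reference maximum is the plateau, taken as the final value of
#' the trace (the trace should extend to >= 10 protein half-lives so the
#' plateau is reached); for switch-off it is the initial value, which must be
#' the trace maximum. Crossing times are linearly interpolated; the first
#' crossing wins. Invariant under positive rescaling of the intensities.
#'
#' @param times,values The trace (hours, AU); `times` may instead be a
#'   two-column data.frame.
#' @param direction `"on"` or `"off"`.
#' @param level Fraction of the reference maximum, in (0, 1).
#' @return Crossing time (hr).
#' @export
response_time <- function(times, values = NULL,
                          direction = c("on", "off"), level = 0.5) {
  direction <- match.arg(direction)
  tr <- as_trace(times, values)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  if (direction == "on") {
    ref <- tr$values[length(tr$values)]
    target <- level * ref
    if (ref <= 0 || tr$values[1L] >= target)
      stop("no 'on' crossing: series does not start below ", level,
           " of its plateau", call. = FALSE)
    tc <- first_crossing(tr$times, tr$values, target, rising = TRUE)
    if (is.na(tc))
      stop("no 'on' crossing: series never reaches ", level,
           " of its plateau", call. = FALSE)
  } else {
    ref <- tr$values[1L]
    if (ref <= 0 || ref < max(tr$values) * (1 - 1e-9))
      stop("no 'off' crossing: series does not start at its maximum",
           call. = FALSE)
    target <- level * ref
    tc <- first_crossing(tr$times, tr$values, target, rising = FALSE)
    if (is.na(tc))
      stop("no 'off' crossing: series never falls to ", level,
           " of its initial maximum", call. = FALSE)
  }
  tc
}

#' Peak intensity of a trace
#'
#' @inheritParams response_time
#' @return List with `value` (AU) and `time` (hr) of the first maximum;
#'   ties are broken toward the earlier time.
#' @export
peak_intensity <- function(times, values = NULL) {
  tr <- as_trace(times, values)
  i <- which.max(tr$values)
  list(value = tr$values[i], time = tr$times[i])
}

#' Oscillation dynamic range of a trace
#'
#' (peak - valley) / mean over the final full oscillation period; the trace
#' must cover at least three full periods so the transient can be discarded.
#' For a linear reporter this is invariant under positive rescaling and under
#' translation by whole periods; it falls with protein half-life (low-pass
#' filtering) and grows with the oscillation period.
#'
#' @inheritParams response_time
#' @param period Oscillation period (hr).
#' @return Dimensionless dynamic range.
#' @export
dynamic_range <- function(times, values = NULL, period) {
  tr <- as_trace(times, values)
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("'period' must be strictly positive", call. = FALSE)
  span <- tr$times[length(tr$times)] - tr$times[1L]
  if (span < 3 * period * (1 - 1e-9))
    stop("insufficient data: the trace must cover at least 3 full periods",
         call. = FALSE)
  t_end <- tr$times[length(tr$times)]
  sel <- tr$times >= t_end - period * (1 + 1e-9)
  v <- tr$values[sel]
  m <- mean(v)
  if (m == 0) return(0)
  (max(v) - min(v)) / m
}

#' Classify the timer phase from a green/red intensity pair
#'
#' Implements the color logic of the dual reporter: after normalizing each
#' channel to its own maximum, both channels below `on_threshold` means the
#' promoter is `off`; green exceeding red by more than a relative margin
#' `ratio_band` means recent activation (`rising`); red exceeding green means
#' the promoter has shut off and only the stable channel persists
#' (`decaying`); balanced channels mean `sustained` activity. The margin is
#' relative (`g > r * (1 + ratio_band)`), which keeps the labels ordered
#' rising -> sustained -> decaying -> off along a step-on/step-off
#' trajectory.
#'
#' @param green,red Intensities (AU), non-negative; vectorized.
#' @param green_max,red_max Channel normalization constants, > 0.
#' @param on_threshold Normalized level below which a channel counts as dark.
#' @param ratio_band Relative margin for calling one channel dominant.
#' @return A data.frame with columns `label` (factor: rising, sustained,
#'   decaying, off) and `green_fraction` = g/(g+r) (0.5 when both zero).
#' @export
classify_phase <- function(green, red, green_max, red_max,
                           on_threshold = 0.2, ratio_band = 0.25) {
  stopifnot(is.numeric(green), is.numeric(red),
            length(green) == length(red))
  if (any(green < 0) || any(red < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (!is.numeric(green_max) || green_max <= 0 ||
      !is.numeric(red_max) || red_max <= 0)
    stop("channel maxima must be strictly positive", call. = FALSE)
  g <- green / green_max
  r <- red / red_max
  label <- ifelse(g < on_threshold & r < on_threshold, "off",
           ifelse(g > r * (1 + ratio_band), "rising",
           ifelse(r > g * (1 + ratio_band), "decaying", "sustained")))
  gf <- ifelse(g + r == 0, 0.5, g / (g + r))
  data.frame(label = factor(label,
                            levels = c("rising", "sustained",
                                       "decaying", "off")),
             green_fraction = gf)
}
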