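#' Estimate a reporter half-life from transcription-blocked decay
#'
#' Fits ordinary least squares of log intensity on time, the standard
#' analysis of an Actinomycin-chase experiment. The fitted slope gives the
#' half-life `-log(2)/slope`; its t-based 95% confidence interval is mapped
#' through the same transform. Background must be subtracted (and any
#' photobleaching corrected, see [correct_bleach()]) before fitting:
#' non-positive intensities are refused rather than silently offset.
#'
#' @param times,values The decay trace (hours, AU); `times` may be a
#'   two-column data.frame. Points from several replicates may be pooled.
#' @param t_window Optional `c(start, end)` restricting the fit window (hr).
#' @return An object of class `halflife_fit`: list with `halflife`, `ci95`
#'   (low, high), `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
fit_halflife <- function(times, values = NULL, t_window = NULL) {
  if (is.null(values)) {
    stopifnot(is.data.frame(times), ncol(times) >= 2L)
    values <- times[[2L]]
    times <- times[[1L]]
  }
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (!is.null(t_window)) {
    stopifnot(is.numeric(t_window), length(t_window) == 2L)
    keep <- times >= t_window[1L] & times <= t_window[2L]
    times <- times[keep]; values <- values[keep]
  }
  if (length(times) < 4L)
    stop("need at least 4 points in the fit window", call. = FALSE)
  if (any(values <= 0))
    stop("non-positive intensities in the fit window: subtract the ",
         "background before fitting", call. = FALSE)
  fit <- stats::lm(log(values) ~ times)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop("no decay: fitted slope is non-negative", call. = FALSE)
  # noiseless input is legitimate (calibration / oracle data); keep lm's
  # "essentially perfect fit" advisory quiet
  quiet_perfect <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ci_slope <- quiet_perfect(stats::confint(fit, "times", level = 0.95))
  # slope CI (both negative): the more negative bound maps to the shorter
  # half-life
  ci <- sort(-log(2) / ci_slope)
  structure(list(halflife = -log(2) / slope,
                 ci95 = c(low = ci[1L], high = ci[2L]),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = quiet_perfect(summary(fit)$r.squared),
                 n_points = length(times)),
            class = "halflife_fit")
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("half-life %.3f hr (95%% CI %.3f-%.3f), R^2 %.4f, n = %d\n",
              x$halflife, x$ci95[1L], x$ci95[2L], x$r_squared, x$n_points))
  invisible(x)
}

#' Polynomial smoothing with analytic derivatives
#'
#' Fits one global least-squares polynomial (default order 4) to the trace
#' and evaluates the fitted value and its first three derivatives
#' analytically at the input times. Times are centred and scaled internally
#' for conditioning; the chain rule maps the derivatives back. With exactly
#' `order + 1` points the fit is an exact interpolation.
#'
#' @inheritParams fit_halflife
#' @param order Polynomial order, default 4.
#' @return List with `smooth`, `d1`, `d2`, `d3` (same length as the input)
#'   and `coefficients` (in the scaled variable).
#' @export
polyfit_derivatives <- function(times, values = NULL, order = 4L) {
  if (is.null(values)) {
    stopifnot(is.data.frame(times), ncol(times) >= 2L)
    values <- times[[2L]]
    times <- times[[1L]]
  }
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1", call. = FALSE)
  if (length(times) < order + 1L)
    stop("insufficient data: need at least order + 1 = ", order + 1L,
         " points", call. = FALSE)
  ctr <- mean(times)
  scl <- stats::sd(times)
  if (scl == 0) stop("times are degenerate", call. = FALSE)
  u <- (times - ctr) / scl
  X <- outer(u, 0:order, `^`)
  cf <- stats::lm.fit(X, values)$coefficients
  cf[is.na(cf)] <- 0
  eval_poly <- function(cf, u) drop(outer(u, seq_along(cf) - 1L, `^`) %*% cf)
  dcf <- function(cf) {
    if (length(cf) <= 1L) return(0)
    cf[-1L] * seq_len(length(cf) - 1L)
  }
  c1 <- dcf(cf); c2 <- dcf(c1); c3 <- dcf(c2)
  list(smooth = eval_poly(cf, u),
       d1 = eval_poly(c1, u) / scl,
       d2 = eval_poly(c2, u) / scl^2,
       d3 = eval_poly(c3, u) / scl^3,
       coefficients = cf)
}

# Piecewise polynomial smoothing: windows of 'window' hours with 50% overlap,
# estimates averaged where windows overlap. Returns the same shape as
# polyfit_derivatives.
piecewise_polyfit <- function(times, values, order, window) {
  t0 <- times[1L]; t1 <- times[length(times)]
  starts <- seq(t0, max(t0, t1 - window), by = window / 2)
  # last window must reach the end of the trace
  if (max(starts) + window < t1) starts <- c(starts, t1 - window)
  n <- length(times)
  acc <- list(smooth = numeric(n), d1 = numeric(n), d2 = numeric(n),
              d3 = numeric(n))
  cnt <- numeric(n)
  for (s in starts) {
    idx <- which(times >= s - 1e-9 & times <= s + window + 1e-9)
    if (length(idx) < order + 2L) next
    pf <- polyfit_derivatives(times[idx], values[idx], order)
    for (nm in names(acc)) acc[[nm]][idx] <- acc[[nm]][idx] + pf[[nm]]
    cnt[idx] <- cnt[idx] + 1
  }
  if (any(cnt == 0))
    return(polyfit_derivatives(times, values, order))
  lapply(acc, function(v) v / cnt)
}

#' Deconvolve promoter activity from a mature-reporter trace
#'
#' Inverts the first-order reporter model to recover the promoter activity
#' F(t) that produced an observed mature-fluorophore trace. With
#' `use_maturation = FALSE` (instantaneous maturation, adequate for the
#' fast-folding green reporter whose 0.1 hr maturation is far below its 2 hr
#' half-life):
#' \deqn{F = [MP'' + (k_m + k_p) MP' + k_m k_p MP] / k_{tl}}
#' With `use_maturation = TRUE` the full chain is inverted stage by stage
#' (requires the third derivative):
#' \deqn{NP = (MP' + k_p MP)/k_{mat},\; R = (NP' + (k_{mat}+k_p) NP)/k_{tl},\;
#'   F = R' + k_m R.}
#' Derivatives come from polynomial smoothing ([polyfit_derivatives()]):
#' one global order-4 polynomial for windows up to ~8 hr, piecewise windows
#' with 50% overlap beyond that. Negative estimates are clamped to zero by
#' default and flagged. The first and last 10% of the window carry polynomial
#' edge bias and are marked low-confidence.
#'
#' @inheritParams fit_halflife
#' @param params A first-order [reporter_params()] for the observed channel.
#' @param use_maturation Invert the full three-stage model (TRUE) or the
#'   simplified two-stage model (FALSE, default).
#' @param clamp Clamp negative activity estimates to zero (default TRUE).
#' @param window Piecewise smoothing window (hr); `NULL` picks a global fit
#'   for spans <= 8 hr and 4 hr windows beyond.
#' @param order Polynomial order for smoothing, default 4.
#' @return A `deconvolution_result`: data.frame with `time_hr`, `f_est`,
#'   `mp_smooth`, `clamped`, `low_confidence`; attributes record the options.
#' @export
deconvolve_promoter <- function(times, values = NULL, params,
                                use_maturation = FALSE, clamp = TRUE,
                                window = NULL, order = 4L) {
  if (is.null(values)) {
    stopifnot(is.data.frame(times), ncol(times) >= 2L)
    values <- times[[2L]]
    times <- times[[1L]]
  }
  stopifnot(inherits(params, "reporter_params"))
  if (!is.null(params$mm_mrna) || !is.null(params$mm_protein))
    stop("deconvolution is only defined for the first-order model",
         call. = FALSE)
  span <- times[length(times)] - times[1L]
  if (is.null(window)) window <- if (span <= 8) Inf else 4
  pf <- if (is.finite(window) && window < span)
    piecewise_polyfit(times, values, order, window)
  else polyfit_derivatives(times, values, order)

  k_m <- rate_from_halflife(params$mrna_halflife)
  k_p <- rate_from_halflife(params$protein_halflife)
  k_mat <- rate_from_halflife(params$maturation_time)
  k_tl <- params$translation_rate
  if (use_maturation) {
    np <- (pf$d1 + k_p * pf$smooth) / k_mat
    np1 <- (pf$d2 + k_p * pf$d1) / k_mat
    np2 <- (pf$d3 + k_p * pf$d2) / k_mat
    r <- (np1 + (k_mat + k_p) * np) / k_tl
    r1 <- (np2 + (k_mat + k_p) * np1) / k_tl
    f_est <- r1 + k_m * r
  } else {
    f_est <- (pf$d2 + (k_m + k_p) * pf$d1 + k_m * k_p * pf$smooth) / k_tl
  }
  clamped <- rep(FALSE, length(f_est))
  if (clamp) {
    clamped <- f_est < 0
    f_est[clamped] <- 0
  }
  edge <- 0.10 * span
  low_conf <- times < times[1L] + edge | times > times[length(times)] - edge
  res <- data.frame(time_hr = times, f_est = f_est, mp_smooth = pf$smooth,
                    clamped = clamped, low_confidence = low_conf)
  attr(res, "params") <- params
  attr(res, "use_maturation") <- use_maturation
  attr(res, "poly_order") <- order
  attr(res, "window") <- window
  class(res) <- c("deconvolution_result", "data.frame")
  res
}

#' Lead of inferred transcription over detectable fluorescence
#'
#' Time by which the inferred promoter activity crosses a detection threshold
#' (a fraction of its own maximum) before the observed mature-reporter signal
#' crosses the same fraction of its maximum. Positive values mean
#' transcription leads fluorescence, as expected for a causal synthesis
#' cascade; the lead grows with the reporter half-life.
#'
#' @param decon A [deconvolve_promoter()] result.
#' @param times,values The observed reporter trace (may be a data.frame).
#' @param detect_fraction Detection threshold as a fraction of each signal's
#'   maximum (default 0.1).
#' @return Lead time (hr).
#' @export
estimate_onset_lead <- function(decon, times = NULL, values = NULL,
                                detect_fraction = 0.1) {
  stopifnot(inherits(decon, "deconvolution_result"))
  if (is.null(times)) {
    times <- decon$time_hr
    values <- decon$mp_smooth
  } else if (is.null(values)) {
    stopifnot(is.data.frame(times), ncol(times) >= 2L)
    values <- times[[2L]]
    times <- times[[1L]]
  }
  t_f <- first_crossing(decon$time_hr, decon$f_est,
                        detect_fraction * max(decon$f_est), rising = TRUE)
  t_mp <- first_crossing(times, values,
                         detect_fraction * max(values), rising = TRUE)
  if (is.na(t_f))
    stop("no crossing: inferred activity never reaches its detection ",
         "threshold", call. = FALSE)
  if (is.na(t_mp))
    stop("no crossing: reporter signal never reaches its detection ",
         "threshold", call. = FALSE)
  t_mp - t_f
}
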