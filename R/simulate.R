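# Degradation velocity for one species: first-order k*X or Michaelis-Menten
# Vmax*X/(Km+X). Returns a function of concentration.
deg_velocity <- function(halflife, mm) {
  if (is.null(mm)) {
    k <- rate_from_halflife(halflife)
    function(x) k * x
  } else {
    vmax <- mm$vmax; km <- mm$km
    function(x) vmax * x / (km + x)
  }
}

#' Closed-form steady state of the first-order reporter model
#'
#' For constant promoter activity `f0` the linear cascade has the steady state
#' \deqn{R = f_0/k_m,\quad NP = k_{tl} R/(k_{mat}+k_p),\quad MP = k_{mat} NP/k_p}
#' with \eqn{k_m = \ln 2/T_{m1/2}}, \eqn{k_{mat} = \ln 2/\tau_{m1/2}},
#' \eqn{k_p = \ln 2/T_{p1/2}}. MP is approximately proportional to
#' \eqn{T_{p1/2} T_{m1/2}} when maturation is much faster than degradation.
#'
#' @param params A [reporter_params()] with first-order kinetics only.
#' @param f0 Constant promoter activity (AU/hr), >= 0.
#' @return Named numeric vector `c(R, NP, MP)`.
#' @export
steady_state <- function(params, f0) {
  stopifnot(inherits(params, "reporter_params"))
  if (!is.null(params$mm_mrna) || !is.null(params$mm_protein))
    stop("steady_state() is only defined for first-order kinetics; ",
         "Michaelis-Menten steady states are not supported", call. = FALSE)
  if (!is.numeric(f0) || length(f0) != 1L || f0 < 0)
    stop("'f0' must be a single non-negative rate", call. = FALSE)
  k_m <- rate_from_halflife(params$mrna_halflife)
  k_mat <- rate_from_halflife(params$maturation_time)
  k_p <- rate_from_halflife(params$protein_halflife)
  R <- f0 / k_m
  NP <- params$translation_rate * R / (k_mat + k_p)
  MP <- k_mat * NP / k_p
  c(R = R, NP = NP, MP = MP)
}

#' Simulate the three-stage reporter model
#'
#' Integrates
#' \deqn{dR/dt = F(t) - deg_m(R)}
#' \deqn{dNP/dt = k_{tl} R - k_{mat} NP - deg_p(NP)}
#' \deqn{dMP/dt = k_{mat} NP - deg_p(MP)}
#' where degradation is first-order or Michaelis-Menten per `params`.
#' Integration uses an adaptive stiff-capable solver (lsoda, relative
#' tolerance 1e-8, absolute 1e-10), restarted at program discontinuities, and
#' the solution is reported on the uniform grid `seq(0, t_end, by = dt)`.
#' Dilution by cell division is not modelled.
#'
#' @param params A [reporter_params()].
#' @param program A [promoter_program()].
#' @param t_end End time (hr), > 0.
#' @param dt Output grid spacing (hr), > 0.
#' @param initial Initial `c(R, NP, MP)`; defaults to dark unexpressed tissue
#'   `c(0, 0, 0)`.
#' @param from_steady_state If `TRUE`, start at `steady_state(params, F(0))`
#'   (switch-off experiments); overrides `initial`.
#' @param rtol,atol Integrator tolerances.
#' @return A `simulation_result`: data.frame with columns
#'   `time_hr, R, NP, MP` and attributes `params`, `program`.
#' @export
simulate_reporter <- function(params, program, t_end, dt = 0.01,
                              initial = c(0, 0, 0),
                              from_steady_state = FALSE,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "reporter_params"),
            inherits(program, "promoter_program"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("'t_end' must be strictly positive", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be strictly positive", call. = FALSE)
  if (from_steady_state)
    initial <- steady_state(params, program_activity(program, 0))
  if (length(initial) != 3L || any(initial < 0))
    stop("'initial' must be three non-negative values (R, NP, MP)",
         call. = FALSE)

  k_tl <- params$translation_rate
  k_mat <- rate_from_halflife(params$maturation_time)
  vm <- deg_velocity(params$mrna_halflife, params$mm_mrna)
  vp <- deg_velocity(params$protein_halflife, params$mm_protein)
  deriv <- function(t, y, p) {
    f <- program_activity(program, t)
    list(c(f - vm(y[1L]),
           k_tl * y[1L] - k_mat * y[2L] - vp(y[2L]),
           k_mat * y[2L] - vp(y[3L])))
  }

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  breaks <- program_breakpoints(program, t_end)
  segs <- unique(c(0, breaks, t_end))
  y <- unname(c(initial))
  out <- matrix(NA_real_, nrow = length(times), ncol = 3L)
  out[1L, ] <- y
  for (i in seq_len(length(segs) - 1L)) {
    a <- segs[i]; b <- segs[i + 1L]
    idx <- which(times > a & times <= b)
    seg_times <- unique(c(a, times[idx], b))
    sol <- deSolve::lsoda(y = y, times = seg_times, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    if (length(idx))
      out[idx, ] <- sol[match(times[idx], sol[, 1L]), 2:4, drop = FALSE]
    y <- sol[nrow(sol), 2:4]
  }
  out[out < 0 & out > -10 * atol] <- 0  # clip integrator-level negatives
  res <- data.frame(time_hr = times, R = out[, 1L], NP = out[, 2L],
                    MP = out[, 3L])
  attr(res, "params") <- params
  attr(res, "program") <- program
  class(res) <- c("simulation_result", "data.frame")
  res
}

#' Simulate both channels of the dual-color timer
#'
#' Runs [simulate_reporter()] for the green (fast-maturing, short-lived) and
#' red (slow-maturing, stable) reporters under the same promoter program and
#' returns the mature-fluorophore trajectories on a shared grid. The green
#' signal leads the red at switch-on and decays first at switch-off, which is
#' the timer's "green front, red rear" phase logic.
#'
#' @param params_green,params_red [reporter_params()]; default to
#'   [dgfp_params()] and [rfp_params()].
#' @inheritParams simulate_reporter
#' @return A `dual_reporter_series`: data.frame `time_hr, green, red` with the
#'   two full `simulation_result`s attached as attributes.
#' @export
simulate_dual <- function(params_green = dgfp_params(),
                          params_red = rfp_params(),
                          program, t_end, dt = 0.01,
                          from_steady_state = FALSE, ...) {
  g <- simulate_reporter(params_green, program, t_end, dt,
                         from_steady_state = from_steady_state, ...)
  r <- simulate_reporter(params_red, program, t_end, dt,
                         from_steady_state = from_steady_state, ...)
  res <- data.frame(time_hr = g$time_hr, green = g$MP, red = r$MP)
  attr(res, "green_full") <- g
  attr(res, "red_full") <- r
  class(res) <- c("dual_reporter_series", "data.frame")
  res
}

#' Gal4/UAS cascade parameters
#'
#' The binary expression system inserts a Gal4 relay between the enhancer and
#' the reporter: enhancer activity F(t) drives Gal4 mRNA and protein
#' (first-order kinetics), and Gal4 protein drives the downstream UAS
#' promoter. `uas_gain` is the steady-state amplification of the relay: for
#' constant F the downstream promoter activity equals `uas_gain * F`. The
#' relay adds delay, so the effective reporter half-life grows roughly as the
#' sum of the Gal4 and fluorophore half-lives.
#'
#' @param gal4_mrna_halflife,gal4_protein_halflife Gal4 kinetic constants (hr).
#' @param gal4_translation_rate Gal4 translation rate (default 1).
#' @param uas_gain Steady-state amplification factor, > 0.
#' @param reporter [reporter_params()] of the downstream reporter.
#' @return An object of class `cascade_params`.
#' @export
cascade_params <- function(gal4_mrna_halflife = 0.5,
                           gal4_protein_halflife = 2,
                           gal4_translation_rate = 1,
                           uas_gain = 1,
                           reporter = dgfp_params()) {
  for (nm in c("gal4_mrna_halflife", "gal4_protein_halflife",
               "gal4_translation_rate", "uas_gain")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  stopifnot(inherits(reporter, "reporter_params"))
  structure(list(gal4_mrna_halflife = gal4_mrna_halflife,
                 gal4_protein_halflife = gal4_protein_halflife,
                 gal4_translation_rate = gal4_translation_rate,
                 uas_gain = uas_gain, reporter = reporter),
            class = "cascade_params")
}

#' Simulate a reporter driven through the Gal4/UAS relay
#'
#' Five-stage chain: F(t) -> Gal4 mRNA -> Gal4 protein -> downstream promoter
#' activity (`uas_gain` times the relay's normalized Gal4 level) -> the
#' standard three-stage reporter model. All Gal4 stages are first-order.
#'
#' @param cascade A [cascade_params()].
#' @inheritParams simulate_reporter
#' @return A `simulation_result` (reporter species) with additional columns
#'   `G_mrna` and `G_protein` for the relay.
#' @export
simulate_gal4_cascade <- function(cascade, program, t_end, dt = 0.01,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cascade, "cascade_params"),
            inherits(program, "promoter_program"))
  if (t_end <= 0 || dt <= 0)
    stop("'t_end' and 'dt' must be strictly positive", call. = FALSE)
  rp <- cascade$reporter
  if (!is.null(rp$mm_mrna) || !is.null(rp$mm_protein))
    stop("the cascade model is first-order only", call. = FALSE)
  k_mG <- rate_from_halflife(cascade$gal4_mrna_halflife)
  k_pG <- rate_from_halflife(cascade$gal4_protein_halflife)
  k_tlG <- cascade$gal4_translation_rate
  # DC normalization: constant F gives Gal4_ss = k_tlG*F/(k_mG*k_pG), so the
  # downstream activity uas_gain * relay_norm * Gal4 equals uas_gain * F.
  relay_norm <- k_mG * k_pG / k_tlG
  k_m <- rate_from_halflife(rp$mrna_halflife)
  k_mat <- rate_from_halflife(rp$maturation_time)
  k_p <- rate_from_halflife(rp$protein_halflife)
  k_tl <- rp$translation_rate
  gain <- cascade$uas_gain

  deriv <- function(t, y, p) {
    f <- program_activity(program, t)
    f2 <- gain * relay_norm * y[2L]
    list(c(f - k_mG * y[1L],
           k_tlG * y[1L] - k_pG * y[2L],
           f2 - k_m * y[3L],
           k_tl * y[3L] - (k_mat + k_p) * y[4L],
           k_mat * y[4L] - k_p * y[5L]))
  }
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  breaks <- program_breakpoints(program, t_end)
  segs <- unique(c(0, breaks, t_end))
  y <- rep(0, 5L)
  out <- matrix(NA_real_, nrow = length(times), ncol = 5L)
  out[1L, ] <- y
  for (i in seq_len(length(segs) - 1L)) {
    a <- segs[i]; b <- segs[i + 1L]
    idx <- which(times > a & times <= b)
    seg_times <- unique(c(a, times[idx], b))
    sol <- deSolve::lsoda(y = y, times = seg_times, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    if (length(idx))
      out[idx, ] <- sol[match(times[idx], sol[, 1L]), 2:6, drop = FALSE]
    y <- sol[nrow(sol), 2:6]
  }
  out[out < 0 & out > -10 * atol] <- 0
  res <- data.frame(time_hr = times, R = out[, 3L], NP = out[, 4L],
                    MP = out[, 5L], G_mrna = out[, 1L], G_protein = out[, 2L])
  attr(res, "params") <- rp
  attr(res, "program") <- program
  attr(res, "cascade") <- cascade
  class(res) <- c("simulation_result", "data.frame")
  res
}

#' Apparent half-life of Michaelis-Menten decay
#'
#' With transcription blocked (F = 0) and no immature pool, mature protein
#' decays as \eqn{dMP/dt = -V_{max} MP/(K_m + MP)}. The time for MP to fall
#' from `mp0` to `mp0/2` depends on the starting concentration: near
#' first-order (\eqn{\ln 2 \, K_m/V_{max}}) when `mp0` is far below `km`,
#' approaching the zero-order value \eqn{mp_0/(2 V_{max})} when the
#' degradation machinery is saturated. This is why over-expression prolongs
#' the observed half-life.
#'
#' @param params A [reporter_params()] whose `mm_protein` is set.
#' @param mp0 Initial mature-protein concentration (AU), > 0.
#' @param dt Output grid used to locate the crossing (hr); the crossing is
#'   interpolated between grid points.
#' @return Apparent half-life (hr).
#' @export
apparent_decay_halflife <- function(params, mp0, dt = NULL) {
  stopifnot(inherits(params, "reporter_params"))
  if (is.null(params$mm_protein))
    stop("'params$mm_protein' must be set (Michaelis-Menten decay)",
         call. = FALSE)
  if (!is.numeric(mp0) || length(mp0) != 1L || mp0 <= 0)
    stop("'mp0' must be strictly positive", call. = FALSE)
  vmax <- params$mm_protein$vmax; km <- params$mm_protein$km
  # analytic upper bound for the crossing time (integrated MM decay law)
  t_cross <- (mp0 / 2 + km * log(2)) / vmax
  t_end <- 1.25 * t_cross
  if (is.null(dt)) dt <- t_end / 2000
  sim <- simulate_reporter(params, promoter_program("step_on", amplitude = 0),
                           t_end = t_end, dt = dt,
                           initial = c(0, 0, mp0))
  below <- which(sim$MP <= mp0 / 2)
  if (!length(below))
    stop("decay did not reach mp0/2 within the simulated window",
         call. = FALSE)
  i <- below[1L]
  if (i == 1L) return(0)
  t0 <- sim$time_hr[i - 1L]; t1 <- sim$time_hr[i]
  y0 <- sim$MP[i - 1L]; y1 <- sim$MP[i]
  t0 + (y0 - mp0 / 2) / (y0 - y1) * (t1 - t0)
}
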