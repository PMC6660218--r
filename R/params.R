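#' Michaelis-Menten degradation parameters
#'
#' Saturable degradation \eqn{v(X) = V_{max} X / (K_m + X)}. In the limit
#' \eqn{X \ll K_m} this reduces to first-order decay with rate constant
#' \eqn{V_{max}/K_m}; at \eqn{X \gg K_m} degradation is zero-order at
#' \eqn{V_{max}}, which is what makes the apparent half-life of an
#' over-expressed fluorescent protein concentration-dependent.
#'
#' @param vmax Maximal degradation rate (AU/hr), > 0.
#' @param km Michaelis constant (AU), > 0.
#' @return An object of class `mm_params`.
#' @export
mm_params <- function(vmax, km) {
  stopifnot(is.numeric(vmax), length(vmax) == 1L, is.finite(vmax),
            is.numeric(km), length(km) == 1L, is.finite(km))
  if (vmax <= 0) stop("'vmax' must be strictly positive", call. = FALSE)
  if (km <= 0) stop("'km' must be strictly positive", call. = FALSE)
  structure(list(vmax = vmax, km = km), class = "mm_params")
}

#' Kinetic parameters of one fluorescent reporter species
#'
#' Bundles the constants of the three-stage reporter model: mRNA half-life,
#' maturation half-time of the fluorophore, mature/immature protein half-life,
#' and the translation rate. Degradation of mRNA and protein is first-order by
#' default; supplying an [mm_params()] object for `mm_mrna` or `mm_protein`
#' replaces the corresponding first-order law with Michaelis-Menten
#' degradation. Both the immature (NP) and mature (MP) protein pools are
#' degraded by the same protein-degradation law; maturation and degradation
#' are independent processes.
#'
#' @param mrna_halflife mRNA half-life (hr), > 0.
#' @param maturation_time Maturation half-time of the fluorophore (hr), > 0;
#'   the maturation rate constant is `log(2) / maturation_time`.
#' @param protein_halflife Protein half-life (hr), > 0.
#' @param translation_rate Translation rate (AU/hr of protein per AU of mRNA),
#'   default 1 (intensities are in arbitrary units).
#' @param mm_mrna,mm_protein Optional [mm_params()] overriding the first-order
#'   degradation of mRNA / protein.
#' @return An object of class `reporter_params`.
#' @seealso [dgfp_params()], [rfp_params()] for the default green/red timer
#'   constants.
#' @export
reporter_params <- function(mrna_halflife, maturation_time, protein_halflife,
                            translation_rate = 1,
                            mm_mrna = NULL, mm_protein = NULL) {
  for (nm in c("mrna_halflife", "maturation_time", "protein_halflife",
               "translation_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (!is.null(mm_mrna) && !inherits(mm_mrna, "mm_params"))
    stop("'mm_mrna' must be built with mm_params()", call. = FALSE)
  if (!is.null(mm_protein) && !inherits(mm_protein, "mm_params"))
    stop("'mm_protein' must be built with mm_params()", call. = FALSE)
  structure(list(mrna_halflife = mrna_halflife,
                 maturation_time = maturation_time,
                 protein_halflife = protein_halflife,
                 translation_rate = translation_rate,
                 mm_mrna = mm_mrna, mm_protein = mm_protein),
            class = "reporter_params")
}

#' Default destabilized-GFP and stable-RFP constants
#'
#' Green channel: fast-folding destabilized GFP (mRNA half-life 0.5 hr,
#' maturation 0.1 hr, protein half-life 2 hr). Red channel: slow-folding
#' stable RFP (maturation 1.5 hr, protein half-life 20 hr). These are the
#' constants of the dual-color transcriptional timer.
#'
#' @param protein_halflife Protein half-life (hr); override to explore other
#'   destabilization strengths.
#' @return A `reporter_params` object.
#' @export
dgfp_params <- function(protein_halflife = 2) {
  reporter_params(mrna_halflife = 0.5, maturation_time = 0.1,
                  protein_halflife = protein_halflife)
}

#' @rdname dgfp_params
#' @export
rfp_params <- function(protein_halflife = 20) {
  reporter_params(mrna_halflife = 0.5, maturation_time = 1.5,
                  protein_halflife = protein_halflife)
}

#' Convert a half-life to a first-order rate constant
#'
#' @param halflife Half-life (hr), > 0.
#' @return Rate constant `log(2) / halflife` (1/hr).
#' @examples
#' rate_from_halflife(1)  # 0.6931
#' @export
rate_from_halflife <- function(halflife) {
  if (!is.numeric(halflife) || any(!is.finite(halflife)) || any(halflife <= 0))
    stop("'halflife' must be strictly positive", call. = FALSE)
  log(2) / halflife
}

#' Promoter activity programs
#'
#' Defines the instantaneous transcription rate F(t) (AU/hr) driving the
#' reporter. Supported shapes:
#' \describe{
#'   \item{step_on}{`baseline` before `onset`, `baseline + amplitude` after.}
#'   \item{step_off}{`baseline + amplitude` up to and including `onset`,
#'     `baseline` after; with `onset = 0` and a steady-state start this is a
#'     switch-off at time zero.}
#'   \item{pulse}{rectangular pulse of `duration` hours starting at `onset`.}
#'   \item{sinusoid}{`baseline + amplitude * (1 + sin(2*pi*(t - onset)/period))/2`;
#'     offset so activity never goes negative.}
#'   \item{sigmoid}{logistic ramp-on centred at `onset` with timescale
#'     `duration`: `baseline + amplitude / (1 + exp(-(t - onset)/duration))`.}
#'   \item{tabulated}{linear interpolation of a `(time, rate)` table, clamped
#'     at the endpoints.}
#' }
#'
#' @param kind Program shape, one of the above.
#' @param onset Onset / centre time (hr).
#' @param duration Pulse duration or sigmoid rise timescale (hr).
#' @param amplitude Maximal added activity F_max (AU/hr).
#' @param period Oscillation period (hr, sinusoid only).
#' @param baseline Basal activity (AU/hr), default 0.
#' @param table Two-column data.frame or matrix `(time, rate)` (tabulated only).
#' @return An object of class `promoter_program`.
#' @export
promoter_program <- function(kind = c("step_on", "step_off", "pulse",
                                      "sinusoid", "sigmoid", "tabulated"),
                             onset = 0, duration = NULL, amplitude = 1,
                             period = NULL, baseline = 0, table = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(onset), length(onset) == 1L, is.finite(onset))
  if (!is.numeric(baseline) || baseline < 0)
    stop("'baseline' must be non-negative (F(t) >= 0)", call. = FALSE)
  if (kind != "tabulated") {
    if (!is.numeric(amplitude) || amplitude < 0)
      stop("'amplitude' must be non-negative (F(t) >= 0)", call. = FALSE)
  }
  if (kind == "pulse" || kind == "sigmoid") {
    if (is.null(duration) || !is.numeric(duration) || duration <= 0)
      stop("'", kind, "' requires a strictly positive 'duration'",
           call. = FALSE)
  }
  if (kind == "sinusoid") {
    if (is.null(period) || !is.numeric(period) || period <= 0)
      stop("'sinusoid' requires a strictly positive 'period'", call. = FALSE)
  }
  if (kind == "tabulated") {
    if (is.null(table)) stop("'tabulated' requires a 'table'", call. = FALSE)
    table <- as.data.frame(table)
    if (ncol(table) < 2L || nrow(table) < 2L)
      stop("'table' needs >= 2 rows of (time, rate)", call. = FALSE)
    names(table)[1:2] <- c("time", "rate")
    if (is.unsorted(table$time, strictly = TRUE))
      stop("'table' times must be strictly increasing", call. = FALSE)
    if (any(table$rate < 0))
      stop("tabulated rates must be non-negative (F(t) >= 0)", call. = FALSE)
  }
  structure(list(kind = kind, onset = onset, duration = duration,
                 amplitude = amplitude, period = period, baseline = baseline,
                 table = table),
            class = "promoter_program")
}

#' Evaluate a promoter program
#'
#' @param program A [promoter_program()].
#' @param t Times (hr), vectorized.
#' @return F(t) in AU/hr, always >= 0.
#' @export
program_activity <- function(program, t) {
  stopifnot(inherits(program, "promoter_program"), is.numeric(t))
  b <- program$baseline
  a <- program$amplitude
  switch(program$kind,
    step_on  = b + a * as.numeric(t >= program$onset),
    step_off = b + a * as.numeric(t <= program$onset),
    pulse    = b + a * as.numeric(t >= program$onset &
                                  t < program$onset + program$duration),
    sinusoid = b + a * (1 + sin(2 * pi * (t - program$onset) /
                                  program$period)) / 2,
    sigmoid  = b + a / (1 + exp(-(t - program$onset) / program$duration)),
    tabulated = stats::approx(program$table$time, program$table$rate,
                              xout = t, rule = 2)$y
  )
}

# Times at which F(t) is discontinuous or non-smooth on [0, t_end];
# the integrator is restarted there.
program_breakpoints <- function(program, t_end) {
  br <- switch(program$kind,
    step_on  = program$onset,
    step_off = program$onset,
    pulse    = c(program$onset, program$onset + program$duration),
    tabulated = program$table$time,
    numeric(0))
  sort(unique(br[br > 0 & br < t_end]))
}
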