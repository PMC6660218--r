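test_that("log-linear fit is exact on noiseless exponentials", {
  t <- seq(0, 4.5, by = 1 / 12)
  for (hl in c(0.1, 2.6, 26, 100)) {
    fit <- fit_halflife(t, 3 * 2^(-t / hl))
    expect_equal(fit$halflife, hl, tolerance = 1e-9)
    expect_lt(diff(fit$ci95), 1e-6 * hl)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("half-life fit guards its window and positivity preconditions", {
  t <- seq(0, 4, by = 0.5)
  y <- 2^(-t / 2)
  expect_error(fit_halflife(t, y - 0.3), "background")
  expect_error(fit_halflife(t, rev(y)), "no decay")
  expect_error(fit_halflife(t[1:3], y[1:3]), "4 points")
  # window restricts the fit
  y2 <- y
  y2[t > 3] <- y2[t > 3] * 5  # corrupt the tail
  fit <- fit_halflife(t, y2, t_window = c(0, 3))
  expect_equal(fit$halflife, 2, tolerance = 1e-9)
})

test_that("noisy synthetic decay is recovered within 15%", {
  acq <- acquisition_config(span = 4.5, interval = 1 / 12, seed = 7,
                            noise_cv = 0.10, background = 0.02)
  reps <- make_decay_experiment(c(green = 3.7, red = 20), c(1, 1), acq)
  y <- unlist(lapply(reps, function(r)
    correct_bleach(r$green - acq$background, acq$bleach_per_frame)))
  t <- unlist(lapply(reps, function(r) r$time_hr))
  fit <- fit_halflife(t, y)
  expect_lt(abs(fit$halflife - 3.7) / 3.7, 0.15)
})

test_that("polynomial smoothing reproduces polynomials and their derivatives", {
  t <- seq(-1, 3, by = 0.1)
  y <- 2 - t + 0.5 * t^2 - 0.1 * t^3 + 0.02 * t^4
  pf <- polyfit_derivatives(t, y, order = 4)
  expect_equal(pf$smooth, y, tolerance = 1e-9)
  expect_equal(pf$d1, -1 + t - 0.3 * t^2 + 0.08 * t^3, tolerance = 1e-8)
  expect_equal(pf$d2, 1 - 0.6 * t + 0.24 * t^2, tolerance = 1e-7)
  expect_equal(pf$d3, -0.6 + 0.48 * t, tolerance = 1e-6)

  # exactly order+1 points: exact interpolation
  t5 <- c(0, 1, 2, 3.5, 5)
  y5 <- c(1, -2, 0.5, 4, 3)
  pf5 <- polyfit_derivatives(t5, y5, order = 4)
  expect_equal(pf5$smooth, y5, tolerance = 1e-8)
  expect_error(polyfit_derivatives(t5[1:4], y5[1:4], order = 4),
               "insufficient")
})

test_that("order-4 smoothing differentiates a half-period sine to <2%", {
  t <- seq(0, pi, length.out = 40)
  pf <- polyfit_derivatives(t, sin(t), order = 4)
  expect_lt(max(abs(pf$d1 - cos(t))), 0.02)
})

test_that("deconvolution at steady state returns the constant activity", {
  p <- dgfp_params()
  s <- simulate_reporter(p, promoter_program("step_on", amplitude = 2),
                         t_end = 40, dt = 0.1)
  sel <- s$time_hr >= 30
  t <- s$time_hr[sel] - 30
  # full inversion: exact
  d4 <- deconvolve_promoter(t, s$MP[sel], p, use_maturation = TRUE)
  expect_lt(max(abs(d4$f_est - 2)) / 2, 0.01)
  # simplified inversion: carries the known maturation-neglect factor
  d4p <- deconvolve_promoter(t, s$MP[sel], p, use_maturation = FALSE)
  kmat <- log(2) / p$maturation_time; kp <- log(2) / p$protein_halflife
  expect_equal(mean(d4p$f_est), 2 * kmat / (kmat + kp), tolerance = 0.01)
})

test_that("deconvolution round trip recovers smooth programs", {
  p <- dgfp_params()
  prog <- promoter_program("sigmoid", onset = 4, duration = 0.75)
  s <- simulate_reporter(p, prog, t_end = 12, dt = 1 / 12)
  truth <- program_activity(prog, s$time_hr)
  rms <- function(um) {
    d <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = um,
                             clamp = FALSE)
    keep <- !d$low_confidence
    sqrt(mean((d$f_est[keep] - truth[keep])^2)) / max(truth)
  }
  expect_lt(rms(TRUE), 0.02)
  expect_lt(rms(FALSE), 0.05)

  prog2 <- promoter_program("sinusoid", period = 8, amplitude = 1)
  s2 <- simulate_reporter(p, prog2, t_end = 32, dt = 1 / 12)
  truth2 <- program_activity(prog2, s2$time_hr)
  d2 <- deconvolve_promoter(s2$time_hr, s2$MP, p, use_maturation = TRUE,
                            clamp = FALSE, window = 4)
  keep <- !d2$low_confidence
  expect_lt(sqrt(mean((d2$f_est[keep] - truth2[keep])^2)) / max(truth2),
            0.02)
})

test_that("full and simplified inversions agree as maturation vanishes", {
  prog <- promoter_program("sigmoid", onset = 4, duration = 0.75)
  gap <- vapply(c(0.1, 0.01), function(tau) {
    p <- reporter_params(0.5, tau, 2)
    s <- simulate_reporter(p, prog, t_end = 12, dt = 1 / 12)
    d_full <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = TRUE,
                                  clamp = FALSE)
    d_simp <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = FALSE,
                                  clamp = FALSE)
    keep <- !d_full$low_confidence
    max(abs(d_full$f_est[keep] - d_simp$f_est[keep])) / max(d_full$f_est)
  }, numeric(1))
  expect_lt(gap[2], gap[1] / 5)
})

test_that("unclamped activity is unbiased over a full oscillation period", {
  p <- dgfp_params()
  prog <- promoter_program("sinusoid", period = 8, amplitude = 1)
  s <- simulate_reporter(p, prog, t_end = 32, dt = 1 / 12)
  d <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = TRUE,
                           clamp = FALSE, window = 4)
  sel <- s$time_hr >= 16 & s$time_hr <= 24
  truth <- program_activity(prog, s$time_hr)
  expect_equal(mean(d$f_est[sel]) / mean(truth[sel]), 1, tolerance = 0.03)
})

test_that("negative inferred activity is clamped and flagged", {
  p <- dgfp_params()
  prog <- promoter_program("pulse", onset = 2, duration = 1)
  s <- simulate_reporter(p, prog, t_end = 12, dt = 1 / 12)
  d <- deconvolve_promoter(s$time_hr, s$MP, p)
  expect_true(all(d$f_est >= 0))
  dn <- deconvolve_promoter(s$time_hr, s$MP, p, clamp = FALSE)
  expect_true(any(dn$f_est < 0))  # a sharp pulse overshoots somewhere
  expect_true(all(d$clamped == (dn$f_est < 0)))
  pm <- reporter_params(0.5, 0.1, 2, mm_protein = mm_params(1, 1))
  expect_error(deconvolve_promoter(s$time_hr, s$MP, pm), "first-order")
})

test_that("inferred transcription leads detectable fluorescence", {
  prog <- promoter_program("sigmoid", onset = 4, duration = 0.75)
  leads <- vapply(c(1, 2, 5), function(tp) {
    p <- dgfp_params(tp)
    s <- simulate_reporter(p, prog, t_end = 16 + 2 * tp, dt = 1 / 12)
    d <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = TRUE,
                             window = 4)
    estimate_onset_lead(d, s$time_hr, s$MP)
  }, numeric(1))
  expect_true(all(leads > 0))
  expect_true(all(diff(leads) > 0))  # lead grows with the half-life
  # ~2 hr in advance for the default 2 hr reporter
  expect_equal(leads[2], 2, tolerance = 0.25)

  # identical signal and activity: zero lead
  p <- dgfp_params()
  s <- simulate_reporter(p, prog, t_end = 16, dt = 1 / 12)
  d <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = TRUE)
  expect_equal(estimate_onset_lead(d, d$time_hr, d$f_est), 0,
               tolerance = 1e-9)
})
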