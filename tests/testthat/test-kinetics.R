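test_that("half-life to rate conversion and its domain", {
  expect_equal(rate_from_halflife(1), log(2))
  expect_equal(rate_from_halflife(2), log(2) / 2)
  expect_error(rate_from_halflife(0), "positive")
  expect_error(rate_from_halflife(-1), "positive")
})

test_that("closed-form steady state solves the balance equations", {
  p <- reporter_params(0.5, 0.1, 2)
  expect_equal(steady_state(p, 0), c(R = 0, NP = 0, MP = 0))

  ss <- steady_state(p, 1)
  # hand-solved: R = f0 Tm/ln2; NP = R/(ln2/0.1 + ln2/2); MP = NP * (ln2/0.1)/(ln2/2)
  expect_equal(unname(ss["R"]), 0.5 / log(2), tolerance = 1e-12)
  expect_equal(unname(ss["R"]), 0.7213, tolerance = 1e-4)
  expect_equal(unname(ss["NP"]), 0.0991, tolerance = 1e-3)
  expect_equal(unname(ss["MP"]), 1.982, tolerance = 1e-3)
  # the balance equations themselves hold at the returned point
  km <- log(2) / 0.5; kmat <- log(2) / 0.1; kp <- log(2) / 2
  expect_equal(1 - km * ss[["R"]], 0)
  expect_equal(ss[["R"]] - (kmat + kp) * ss[["NP"]], 0, tolerance = 1e-12)
  expect_equal(kmat * ss[["NP"]] - kp * ss[["MP"]], 0, tolerance = 1e-12)

  pm <- reporter_params(0.5, 0.1, 2, mm_protein = mm_params(1, 1))
  expect_error(steady_state(pm, 1), "first-order")
})

test_that("destabilization causes ~90% steady-state signal loss", {
  r <- steady_state(dgfp_params(2), 1)[["MP"]] /
    steady_state(dgfp_params(20), 1)[["MP"]]
  expect_lt(abs(100 * r - 10), 0.5)
})

test_that("simulation is null on a null program and matches the steady state", {
  off <- promoter_program("step_on", amplitude = 0)
  s <- simulate_reporter(dgfp_params(), off, t_end = 5, dt = 0.1)
  expect_true(all(s$R == 0 & s$NP == 0 & s$MP == 0))

  p <- dgfp_params()
  son <- promoter_program("step_on", amplitude = 1)
  s <- simulate_reporter(p, son, t_end = 50 * p$protein_halflife, dt = 0.5)
  expect_equal(s$MP[nrow(s)], steady_state(p, 1)[["MP"]], tolerance = 1e-3)
})

test_that("numerical solution matches the analytic cascade for a pulse", {
  p <- reporter_params(0.5, 0.1, 2)
  prog <- promoter_program("pulse", onset = 1, duration = 2, amplitude = 1.5)
  times <- seq(0, 10, by = 0.05)
  s <- simulate_reporter(p, prog, t_end = 10, dt = 0.05)
  segs <- data.frame(t_start = c(0, 1, 3), f = c(0, 1.5, 0))
  ora <- analytic_cascade(p, segs, times)
  for (sp in c("R", "NP", "MP"))
    expect_lt(max(abs(s[[sp]] - ora[, sp])) / max(ora[, sp]), 1e-5)
})

test_that("first-order model is linear in the promoter amplitude", {
  p <- dgfp_params()
  prog1 <- promoter_program("pulse", onset = 0.5, duration = 1, amplitude = 1)
  prog3 <- promoter_program("pulse", onset = 0.5, duration = 1, amplitude = 3)
  s1 <- simulate_reporter(p, prog1, t_end = 8, dt = 0.05)
  s3 <- simulate_reporter(p, prog3, t_end = 8, dt = 0.05)
  expect_lt(max(abs(s3$MP - 3 * s1$MP)) / max(s3$MP), 1e-6)
  expect_lt(max(abs(s3$R - 3 * s1$R)) / max(s3$R), 1e-6)
})

test_that("trajectories stay non-negative for arbitrary programs and parameters", {
  set.seed(42)
  kinds <- c("step_on", "step_off", "pulse", "sinusoid")
  for (i in 1:8) {
    p <- reporter_params(runif(1, 0.1, 3), runif(1, 0.05, 2),
                         runif(1, 0.5, 20), runif(1, 0.2, 5))
    kind <- sample(kinds, 1)
    prog <- promoter_program(kind, onset = runif(1, 0, 2),
                             duration = runif(1, 0.5, 2),
                             amplitude = runif(1, 0, 3),
                             period = runif(1, 1, 8),
                             baseline = runif(1, 0, 0.5))
    s <- simulate_reporter(p, prog, t_end = 12, dt = 0.1,
                           initial = runif(3, 0, 2))
    expect_true(all(s$R >= 0 & s$NP >= 0 & s$MP >= 0),
                info = paste("kind =", kind))
  }
})

test_that("promoter programs respect their invariants", {
  t <- seq(-2, 20, by = 0.01)
  sin_prog <- promoter_program("sinusoid", period = 4, amplitude = 2,
                               baseline = 0.1)
  expect_true(all(program_activity(sin_prog, t) >= 0))
  tab <- promoter_program("tabulated",
                          table = data.frame(time = c(0, 1, 2),
                                             rate = c(0, 2, 1)))
  # clamped at the endpoints, linear inside
  expect_equal(program_activity(tab, c(-1, 0.5, 1.5, 5)), c(0, 1, 1.5, 1))
  expect_error(promoter_program("sinusoid", amplitude = -1, period = 2),
               "non-negative")
  expect_error(promoter_program("pulse"), "duration")
})

test_that("dual timer: green leads at switch-on and decays first at switch-off", {
  on <- promoter_program("step_on")
  d <- simulate_dual(program = on, t_end = 150, dt = 0.1)
  t50_g <- response_time(d$time_hr, d$green, "on")
  t50_r <- response_time(d$time_hr, d$red, "on")
  expect_lt(t50_g, t50_r)

  off <- promoter_program("step_off", onset = 0)
  doff <- simulate_dual(program = off, t_end = 150, dt = 0.1,
                        from_steady_state = TRUE)
  expect_lt(response_time(doff$time_hr, doff$green, "off"),
            response_time(doff$time_hr, doff$red, "off"))

  null <- promoter_program("step_on", amplitude = 0)
  dz <- simulate_dual(program = null, t_end = 5, dt = 0.1)
  expect_true(all(dz$green == 0 & dz$red == 0))
})

test_that("Gal4/UAS relay amplifies, delays, and reduces to the direct reporter", {
  son <- promoter_program("step_on")
  plateaus <- vapply(c(1, 5, 20), function(g) {
    s <- simulate_gal4_cascade(cascade_params(uas_gain = g), son, 80, 0.2)
    s$MP[nrow(s)]
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
  expect_equal(plateaus[2] / plateaus[1], 5, tolerance = 1e-6)

  # vanishing Gal4 half-lives at unit gain: an instantaneous relay
  fast <- cascade_params(0.002, 0.002, uas_gain = 1, reporter = dgfp_params())
  sc <- simulate_gal4_cascade(fast, son, 20, 0.05)
  sd <- simulate_reporter(dgfp_params(), son, 20, 0.05)
  expect_lt(max(abs(sc$MP - sd$MP)) / max(sd$MP), 0.01)

  # switch-off delay grows with the Gal4 protein half-life
  poff <- promoter_program("step_off", onset = 100)
  t50s <- vapply(c(0.5, 2, 5), function(tg) {
    s <- simulate_gal4_cascade(cascade_params(0.5, tg), poff, 180, 0.1)
    i0 <- which.max(s$MP)
    response_time(s$time_hr[i0:nrow(s)] - 100, s$MP[i0:nrow(s)], "off")
  }, numeric(1))
  expect_true(all(diff(t50s) > 0))
  # the added delay is on the scale of the added Gal4 half-life
  direct <- simulate_reporter(dgfp_params(),
                              promoter_program("step_off", onset = 0),
                              30, 0.05, from_steady_state = TRUE)
  t50_direct <- response_time(direct$time_hr, direct$MP, "off")
  delta <- t50s - t50_direct
  expect_true(all(delta > 0))
  expect_gt(stats::cor(delta, c(0.5, 2, 5)), 0.99)
})

test_that("saturated degradation prolongs the apparent half-life", {
  p <- reporter_params(0.5, 0.1, 2,
                       mm_protein = mm_params(vmax = log(2) / 2, km = 1))
  # low-concentration limit: first-order with k = vmax/km
  expect_equal(apparent_decay_halflife(p, 1e-3), 2, tolerance = 0.02)
  expect_gt(apparent_decay_halflife(p, 10), apparent_decay_halflife(p, 0.1))
  # zero-order regime, against the closed-form halving time
  h <- apparent_decay_halflife(p, 1000)
  expect_equal(h, mm_halving_time(1000, log(2) / 2, 1), tolerance = 0.005)
  expect_equal(h / (1000 / (2 * log(2) / 2)), 1, tolerance = 0.01)
  expect_error(apparent_decay_halflife(p, 0), "positive")
  expect_error(apparent_decay_halflife(dgfp_params(), 1), "mm_protein")
})

test_that("steady-state plateau is ~proportional to Tp*Tm across the grid", {
  grid <- expand.grid(tp = c(0.5, 1, 2, 5, 10, 20), tm = c(0.5, 1, 2, 3))
  ratio <- mapply(function(tp, tm) {
    steady_state(reporter_params(tm, 0.1, tp), 1)[["MP"]] / (tp * tm)
  }, grid$tp, grid$tm)
  expect_lt(max(abs(ratio - mean(ratio))) / mean(ratio), 0.15)
})
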