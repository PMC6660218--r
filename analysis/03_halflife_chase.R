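#!/usr/bin/env Rscript
# In-silico Actinomycin chase: transcription is blocked at t = 0 and the
# decay of the destabilized green channel is followed for 4.5 hr at 5 min
# intervals in 3 replicates. Photobleaching is calibrated from a 50-frame
# constant-sample series, the traces are background-subtracted and
# bleach-corrected, and the reporter half-life is estimated by log-linear
# regression with a 95% CI. A 200-seed Monte Carlo reports estimator accuracy
# and CI coverage.

suppressPackageStartupMessages(library(transtimer))
dir.create("results", showWarnings = FALSE)

truth <- 2.6  # hr, destabilized reporter; stable channel 20 hr

# bleaching calibration (50 frames over 10 min)
cal_acq <- acquisition_config(span = 1 / 6, interval = 1 / 300, seed = 101,
                              noise_cv = 0.02, bleach_per_frame = 0.002)
b_hat <- estimate_bleach(make_bleach_calibration(50, cal_acq)$intensity)
cat(sprintf("bleach calibration: b_hat = %.5f per frame (true 0.00200)\n",
            b_hat))

acq <- acquisition_config(span = 4.5, interval = 1 / 12, seed = 101)
reps <- make_decay_experiment(c(green = truth, red = 20), c(1, 1), acq)
write_dual_series(reps, "results/chase_traces.csv")

prep <- function(r, ch) correct_bleach(r[[ch]] - acq$background, b_hat)
t_all <- unlist(lapply(reps, function(r) r$time_hr))
fit_g <- fit_halflife(t_all, unlist(lapply(reps, prep, "green")))
fit_r <- fit_halflife(t_all, unlist(lapply(reps, prep, "red")))
cat("green (destabilized): "); print(fit_g)
cat("red (stable):         "); print(fit_r)
write.csv(data.frame(
  channel = c("green", "red"),
  true_halflife_hr = c(truth, 20),
  halflife_hr = c(fit_g$halflife, fit_r$halflife),
  ci95_low = c(fit_g$ci95[1], fit_r$ci95[1]),
  ci95_high = c(fit_g$ci95[2], fit_r$ci95[2]),
  r_squared = c(fit_g$r_squared, fit_r$r_squared)),
  "results/chase_fits.csv", row.names = FALSE, quote = FALSE)

# Monte Carlo over 200 seeds
mc <- t(vapply(1:200, function(s) {
  a <- acquisition_config(span = 4.5, interval = 1 / 12, seed = s)
  rr <- make_decay_experiment(c(green = truth, red = 20), c(1, 1), a)
  y <- unlist(lapply(rr, function(r)
    correct_bleach(r$green - a$background, a$bleach_per_frame)))
  f <- fit_halflife(unlist(lapply(rr, function(r) r$time_hr)), y)
  c(est = f$halflife,
    cover = as.numeric(f$ci95[[1]] <= truth & truth <= f$ci95[[2]]))
}, numeric(2)))
cat(sprintf("\nMonte Carlo (200 seeds): mean estimate %.3f hr, max |error| %.1f%%, CI coverage %.1f%%\n",
            mean(mc[, "est"]), 100 * max(abs(mc[, "est"] - truth) / truth),
            100 * mean(mc[, "cover"])))
write.csv(data.frame(seed = 1:200, halflife_hr = mc[, "est"],
                     covered = mc[, "cover"]),
          "results/chase_montecarlo.csv", row.names = FALSE, quote = FALSE)

# the red channel over the same window is barely informative: note the CI
cat(sprintf("stable-channel CI spans %.1f-%.1f hr over a 4.5 hr window\n",
            fit_r$ci95[1], fit_r$ci95[2]))
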