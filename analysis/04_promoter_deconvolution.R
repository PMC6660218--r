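#!/usr/bin/env Rscript
# Promoter-activity deconvolution: a sigmoid transcriptional onset drives the
# dual timer; the promoter activity F(t) is then reconstructed from the
# mature green-channel trace alone by polynomial-derivative inversion of the
# kinetic model, on (i) the noiseless trajectory and (ii) a noisy synthetic
# acquisition. Reports recovery error and the lead of inferred transcription
# over detectable fluorescence.

suppressPackageStartupMessages(library(transtimer))
dir.create("results", showWarnings = FALSE)

prog <- promoter_program("sigmoid", onset = 4, duration = 0.75)
p <- dgfp_params()

s <- simulate_reporter(p, prog, t_end = 12, dt = 1 / 12)
truth <- program_activity(prog, s$time_hr)

runs <- list(full = TRUE, simplified = FALSE)
out <- list()
for (nm in names(runs)) {
  d <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = runs[[nm]],
                           clamp = FALSE)
  keep <- !d$low_confidence
  rms <- sqrt(mean((d$f_est[keep] - truth[keep])^2)) / max(truth)
  cat(sprintf("noiseless %s inversion: RMS error %.2f%% of peak activity\n",
              nm, 100 * rms))
  out[[nm]] <- data.frame(inversion = nm, noise = "none",
                          d[, c("time_hr", "f_est", "mp_smooth", "clamped")])
}

# noisy acquisition (one replicate of the synthetic time-lapse)
acq <- acquisition_config(span = 12, interval = 1 / 12, seed = 202)
rep1 <- make_reporter_timecourse(prog, acq = acq)[[1]]
y <- pmax(correct_bleach(rep1$green - acq$background, acq$bleach_per_frame), 0)
dn <- deconvolve_promoter(rep1$time_hr, y, p, use_maturation = TRUE,
                          window = 4)
keep <- !dn$low_confidence
cat(sprintf("noisy acquisition: recovered mean activity %.3f vs true %.3f (%.1f%% error)\n",
            mean(dn$f_est[keep]), mean(truth[keep]),
            100 * abs(mean(dn$f_est[keep]) - mean(truth[keep])) /
              mean(truth[keep])))
out$noisy <- data.frame(inversion = "full", noise = "cv0.05",
                        dn[, c("time_hr", "f_est", "mp_smooth", "clamped")])
write.csv(do.call(rbind, out), "results/deconvolution.csv",
          row.names = FALSE, quote = FALSE)

# onset lead: transcription is visible before the fluorophore
d <- deconvolve_promoter(s$time_hr, s$MP, p, use_maturation = TRUE)
lead <- estimate_onset_lead(d, s$time_hr, s$MP)
cat(sprintf("inferred transcription leads detectable green signal by %.2f hr\n",
            lead))
leads <- vapply(c(1, 2, 5), function(tp) {
  pp <- dgfp_params(tp)
  ss <- simulate_reporter(pp, prog, t_end = 16 + 2 * tp, dt = 1 / 12)
  dd <- deconvolve_promoter(ss$time_hr, ss$MP, pp, use_maturation = TRUE,
                            window = 4)
  estimate_onset_lead(dd, ss$time_hr, ss$MP)
}, numeric(1))
write.csv(data.frame(protein_halflife_hr = c(1, 2, 5), onset_lead_hr = leads),
          "results/onset_lead.csv", row.names = FALSE, quote = FALSE)
cat("onset lead grows with half-life:",
    paste(sprintf("%.2f", leads), collapse = ", "), "hr\n")
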