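#!/usr/bin/env Rscript
# Forward-simulates a destabilized (2 hr) vs a stable (20 hr) reporter under
# the four canonical promoter programs — switch-on, switch-off, 1 hr pulse,
# and a 2 hr-period oscillation — and tabulates the trajectories and the
# 50%-response times. Shows the core trade-off: the destabilized reporter
# responds ~90% faster but plateaus ~10x lower.

suppressPackageStartupMessages(library(transtimer))
dir.create("results", showWarnings = FALSE)

programs <- list(
  switch_on = promoter_program("step_on"),
  switch_off = promoter_program("step_off", onset = 0),
  pulse_1hr = promoter_program("pulse", onset = 0, duration = 1),
  oscillation_2hr = promoter_program("sinusoid", period = 2)
)

rows <- list()
traj <- list()
for (nm in names(programs)) {
  for (tp in c(2, 20)) {
    s <- simulate_reporter(dgfp_params(tp), programs[[nm]],
                           t_end = if (nm == "pulse_1hr") 12 else 120,
                           dt = 0.05,
                           from_steady_state = nm == "switch_off")
    traj[[length(traj) + 1L]] <-
      data.frame(program = nm, protein_halflife_hr = tp,
                 s[, c("time_hr", "R", "NP", "MP")])
    t50 <- tryCatch(
      response_time(s$time_hr, s$MP,
                    if (nm == "switch_off") "off" else "on"),
      error = function(e) NA_real_)
    pk <- peak_intensity(s$time_hr, s$MP)
    rows[[length(rows) + 1L]] <-
      data.frame(program = nm, protein_halflife_hr = tp,
                 t50_hr = t50, peak = pk$value, peak_time_hr = pk$time)
  }
}
summary_df <- do.call(rbind, rows)
write.csv(do.call(rbind, traj), "results/program_trajectories.csv",
          row.names = FALSE, quote = FALSE)
write.csv(summary_df, "results/program_summary.csv", row.names = FALSE,
          quote = FALSE)

print(summary_df, row.names = FALSE)
on2 <- summary_df$t50_hr[summary_df$program == "switch_on" &
                           summary_df$protein_halflife_hr == 2]
on20 <- summary_df$t50_hr[summary_df$program == "switch_on" &
                            summary_df$protein_halflife_hr == 20]
cat(sprintf("\nswitch-on t50 reduction (2 vs 20 hr): %.1f%%\n",
            100 * (1 - on2 / on20)))
p2 <- summary_df$peak[summary_df$program == "pulse_1hr" &
                        summary_df$protein_halflife_hr == 2]
p20 <- summary_df$peak[summary_df$program == "pulse_1hr" &
                         summary_df$protein_halflife_hr == 20]
cat(sprintf("1 hr pulse peak reduction (2 vs 20 hr): %.1f%%\n",
            100 * (1 - p2 / p20)))
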