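# transtimer

Kinetic modelling and inference for dual-color destabilized fluorescent
transcriptional reporters.

Transcriptional reporters read promoter activity out as fluorescence, but a
stable fluorescent protein (half-life > 20 hr) low-pass filters the signal
and hides transcriptional dynamics; destabilizing it (half-life ~2 hr)
restores temporal resolution at the cost of ~90% of the intensity. Pairing a
fast-maturing, short-lived green protein with a slow-maturing, stable red
one makes a transcriptional timer whose green/red ratio encodes time since
activation. This package is for quantitative biologists working with such
reporters: it simulates the underlying kinetics, quantifies the
speed-vs-brightness trade-off, and inverts observed traces back to
half-lives and promoter activity.

## The model

One reporter species is a three-stage cascade driven by promoter activity
F(t) (AU/hr):

    dR/dt  = F(t) − deg_m(R)                     (mRNA)
    dNP/dt = k_tl·R − k_mat·NP − deg_p(NP)       (immature protein)
    dMP/dt = k_mat·NP − deg_p(MP)                (mature fluorophore)

with deg(X) = k·X, k = ln2/T½ (first-order) or Vmax·X/(Km+X)
(Michaelis–Menten, for saturable degradation). Around the forward model the
package provides:

* **Simulation** — `simulate_reporter()`, `simulate_dual()` (both timer
  channels), `simulate_gal4_cascade()` (the Gal4/UAS relay: amplification
  plus delay), canonical promoter programs (step, pulse, sinusoid, sigmoid,
  tabulated), closed-form steady states, and `apparent_decay_halflife()`
  for concentration-dependent half-lives under saturated degradation.
* **Metrics** — `response_time()` (t50 on/off), `peak_intensity()`,
  `dynamic_range()` (oscillations), `classify_phase()` (the green/red
  timer logic).
* **Inference** — `fit_halflife()` (log-linear regression of
  transcription-blocked decay, 95% CI), `deconvolve_promoter()`
  (polynomial-derivative inversion of the cascade, full or
  instantaneous-maturation form), `estimate_onset_lead()`.
* **Synthetic data** — seeded generators of imaging-like traces
  (multiplicative noise, background, per-frame photobleaching, replicates)
  plus the bleaching calibration/correction pair.
* **Configured runs** — `run_command()` executes one YAML-configured step
  (simulate / metrics / fit_halflife / deconvolve / synth) and writes CSV
  outputs next to a resolved config; the `analysis/` scripts chain these
  into the full study.

## Worked example

An in-silico transcription-block chase: the destabilized green channel
(true half-life 2.6 hr) is sampled every 5 min for 4.5 hr in 3 replicates
with noise, background and photobleaching, then background-subtracted,
bleach-corrected and fitted:

```r
library(transtimer)

acq  <- acquisition_config(span = 4.5, interval = 1/12, seed = 101)
reps <- make_decay_experiment(c(green = 2.6, red = 20), c(1, 1), acq)
y <- unlist(lapply(reps, function(r)
  correct_bleach(r$green - acq$background, acq$bleach_per_frame)))
t <- unlist(lapply(reps, function(r) r$time_hr))
fit_halflife(t, y)
#> half-life 2.561 hr (95% CI 2.510-2.614), R^2 0.9833, n = 165
```

The estimate recovers the 2.6 hr truth within 1.5% and the CI covers it.
The timer's asymmetry is one simulation away:

```r
d <- simulate_dual(program = promoter_program("step_on"), t_end = 150, dt = 0.1)
response_time(d$time_hr, d$green, "on")   # 2.93 hr
response_time(d$time_hr, d$red,  "on")    # 22.6 hr
```

— after switch-on the green channel reaches half its plateau almost an
order of magnitude sooner than the red, which is what makes the green/red
ratio a clock.

The numbered scripts under `analysis/` run the full study (program
comparisons, performance sweeps, the chase Monte Carlo, deconvolution, the
Gal4 relay) and write their tables under `results/`.

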