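# ecosyn

Synthetic ECoG cohorts and quantification of epileptiform activity in the
lithium–pilocarpine rat model of status epilepticus.

## What this package is for

In the lithium–pilocarpine preparation, an anaesthetized rat receives
scopolamine (T = 0 min), two pilocarpine doses (T = 30, T = 60) and a low
dose of diazepam (T = 120) while a single-channel electrocorticogram (ECoG)
is recorded. Experiments comparing a static skull magnet (tSMS) against a
sham replica ask whether the magnet potentiates diazepam's anticonvulsant
effect. `ecosyn` provides the full quantification chain for that design —
and, because such recordings are rarely shared, a synthetic ECoG generator
with ground-truth event logs so the whole chain is testable end to end.

The core quantities, per subject and analysis phase (baseline /
prediazepam / postdiazepam):

* **Epileptiform spike rate** — a discharge is a segment where the Hilbert
  envelope exceeds 2× the median baseline envelope for ≥ 0.3 s; rates are
  normalized per subject by the prediazepam rate.
* **RMS amplitude** — √(mean x²) per epoch, and its percent reduction
  relative to baseline.
* **Band powers** — Welch PSD (4-s Hann segments, 50 % overlap) integrated
  over delta [0, 4), theta [4, 8), alpha [8, 12) and beta [12, 30) Hz.
* **Ripples (HFOs)** — after 80–200 Hz zero-phase filtering, trains of ≥ 4
  per-cycle peaks above mean + 3 SD with inter-peak gaps ≤ 12.5 ms; rates
  per hour and mean in-train frequency.

Inference is the classical two-way mixed repeated-measures ANOVA —
CONDITION (sham/magnet, between-subject) × TIME (three phases,
within-subject) — with the Greenhouse–Geisser epsilon estimated from the
pooled within-group covariance, and Tukey HSD post-hoc comparisons on the
studentized-range distribution.

## Worked example

Simulate one magnet-condition recording on a compressed timeline (5-min
induction steps), detect events, and quantify each phase:

```r
library(ecosyn)

tl  <- timeline(0, 300, 600, 1200)            # compressed injection schedule
sim <- simulate_recording(sim_params(fs = 1000), condition = "magnet",
                          duration = 2400, seed = 8, t0 = -600, tl = tl)
sim$recording
#> <ecosyn_recording> s1 (magnet): 2400000 samples @ 1000 Hz, t = [-600, 1800] s

base <- estimate_baseline(as_epoch(sim$recording, -600, 60))
round(base$baseline_amp, 1)                    # median Hilbert envelope, uV
#> 178.3

spikes <- detect_spikes(as_epoch(sim$recording, 600, 600), base)
nrow(spikes)                                   # detected in the prediazepam window
#> 121  (127 in the ground-truth log)

m <- subject_metrics(sim$recording)
m$phase[, c("phase", "spike_rate", "rms", "rms_reduction", "ripple_rate")]
#>          phase spike_rate   rms rms_reduction ripple_rate
#> 1     baseline        2.2 155.0           0.0          24
#> 2  prediazepam       12.1 188.0         -21.3          84
#> 3 postdiazepam        1.9  87.2          43.8          36
```

The phase table reads directly: pilocarpine raises the spike rate from
2.2/min to 12.1/min and the RMS above baseline (a negative "reduction"),
and diazepam on a magnet-treated subject drops spiking to 1.9/min and the
RMS by 43.8 %. Ripple rates rise with pilocarpine and fall after diazepam.

A full cohort with statistics, through the one-call pipeline:

```r
res <- run_pipeline(demo_config("demo_run", seed = 1))   # 6 sham vs 6 magnet
res$report$fits$spike_rate_norm
#> Mixed rm-ANOVA: 12 subjects (6+6), 3 time levels; GG epsilon = 0.688
#>          effect df_num df_den         F gg_epsilon p_uncorrected      p_gg p_selected
#>       condition      1     10    0.9288         NA     3.579e-01 3.579e-01  3.579e-01
#>            time      2     20 2539.0763     0.6884     8.633e-25 1.117e-17  1.117e-17
#>  condition:time      2     20   12.6234     0.6884     2.847e-04 1.732e-03  1.732e-03
```

The significant CONDITION × TIME interaction (p_gg ≈ 0.0017) is the
synergy signature: the time course of normalized spike rates differs
between magnet and sham animals, with the magnet group ending lower after
diazepam. `run_pipeline()` writes every table (per-phase and per-epoch
metrics, detected and ground-truth events, ANOVA and Tukey reports, the
resolved configuration) into the output directory as CSV/YAML, all
byte-reproducible given the seed.

## Package layout

* `R/` — simulator (`simulate_recording`, `simulate_cohort`,
  `simulate_rate_table`), I/O (`read_recording`/`write_recording` for EDF +
  YAML sidecar, `read_events`/`write_events` for CSV), preprocessing
  (`downsample`, `bandpass`, `extract_epochs`, `phase_windows`), detectors
  (`detect_spikes`, `detect_ripples`), metrics (`rms`, `band_power`,
  `phase_band_power`), statistics (`mixed_rm_anova`, `tukey_posthoc`,
  `synergy_analysis`) and orchestration (`run_pipeline`, `demo_config`).
* `vignettes/ecog-quantification.Rmd` — the model, every tunable parameter
  with its default and rationale, numerical choices, and what the synthetic
  studies do and do not demonstrate.
* `tests/testthat/` — unit, property and end-to-end suites, all fixtures
  generated in code.
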