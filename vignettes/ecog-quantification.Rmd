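---
title: "Quantifying epileptiform ECoG under combined magnet and diazepam treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epileptiform ECoG under combined magnet and diazepam treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package models

In the lithium–pilocarpine model of status epilepticus, an anaesthetized rat
receives scopolamine (T = 0 min), two doses of pilocarpine (T = 30 and
T = 60) and a low dose of diazepam (T = 120), while a single-channel
electrocorticogram (ECoG) is recorded continuously. Half of the animals
carry a strong static magnet on the skull during the first hour
(transcranial static magnetic stimulation, tSMS); the other half carry an
identical non-magnetic replica (sham). The scientific question is whether
the magnet potentiates the anticonvulsant action of diazepam.

`ecosyn` implements the complete quantification chain for this design:

* a **synthetic ECoG generator** that produces cohorts of recordings with
  logged ground-truth events, so every downstream stage is testable without
  animal data;
* **signal conditioning**: anti-aliased downsampling to 1 kHz, zero-phase
  band-pass filtering, automatic 60-s epoch extraction every 30 min, and
  the three one-hour analysis windows (baseline / prediazepam /
  postdiazepam);
* **event detectors** for epileptiform spikes and 80–200 Hz ripples;
* **metrics**: spike rate (normalized per subject), RMS amplitude and its
  percent reduction, and Welch band powers (delta 0–4, theta 4–8, alpha
  8–12, beta 12–30 Hz);
* **inference**: a two-way mixed repeated-measures ANOVA
  (CONDITION × TIME) with Greenhouse–Geisser correction and Tukey HSD
  post-hoc comparisons, applied to every measure.

## The synthetic generator

### Background

The anaesthetized cortex alternates between depolarized "up" states and
silent "down" states at roughly 1 Hz. The generator models this as a
square-ish alternation `A·tanh(12·sin(2πft))` between the up- and
down-state amplitudes (default ±150 µV at 1 Hz). The steepness constant
gives ~25 ms state transitions, which matters for realism in two ways: the
oscillation then carries power through the beta band, as real up/down
states do, while still leaking nothing measurable into the 80–200 Hz ripple
band. On top of this sits 1/f ("pink") noise with 20 µV SD, representing
instrumental noise and distant sources.

After the diazepam injection the *slow oscillation* is scaled down with a
60-s time constant, to 0.6 of its amplitude in sham animals and 0.4 under
the magnet — diazepam suppresses cortical activity, and the modelled
synergy makes the suppression deeper in pre-treated animals. The noise
floor is deliberately left phase-independent: it does not originate in the
local cortex, and a stationary 80–200 Hz floor is also what makes a
fixed-multiplier SD threshold well behaved across phase windows.

### Epileptiform spikes

Spikes are biphasic difference-of-Gaussians transients. Their duration is
drawn uniformly from 0.4–0.8 s and their peak amplitude is
`amp_ratio` (default 3) times the *median Hilbert envelope* of the clean
background — i.e. they are calibrated in exactly the units the detector's
"two times baseline" criterion uses. During a spike the ongoing background
is locally suppressed (raised-cosine window), as an epileptiform discharge
interrupts the ongoing oscillation; the smooth window edges keep the
discharge from ringing into the ripple band.

Spike arrivals follow an inhomogeneous Poisson process: a 2/min baseline
rate, an exponential ramp (τ = 300 s) to the 30/min pilocarpine plateau
after the first pilocarpine dose, and an exponential decay (τ = 60 s)
after diazepam toward a residual rate of 3/min (sham) or 0.9/min (magnet).
Under the magnet the plateau itself is also halved, reflecting the
protective effect of the field during induction. Same-kind events are
redrawn unless separated by at least 0.1 s, so the ground truth stays
unambiguous for an envelope detector that merges segments closer than
50 ms. The literature reports no absolute rates for this preparation
(published axes are normalized), so these defaults are model choices
selected once to reproduce the qualitative phenomenology: severe
spiking during status epilepticus, a clear diazepam effect, and a deeper
effect under the magnet.

### Ripples

Ripples are flat-top (Tukey-windowed) sinusoid bursts, frequency uniform in
80–200 Hz, 6–10 cycles, with peak amplitude 5 SD of the band-filtered
background — comfortably above the detector's 3 SD threshold, while 3-cycle
bursts stay undetectable by the ≥4-peak rule. Their rate rises from 20/h to
120/h with pilocarpine and decays to 40/h after diazepam, *identically in
both conditions*: the magnet has no programmed effect on ripples, which is
the null the ripple analysis should (and does) fail to reject.

### Cohorts

`simulate_cohort()` draws per-subject log-normal rate factors (sdlog 0.2 by
default) for spikes and ripples independently — the between-subject
variance component that the mixed ANOVA's subject stratum absorbs — and a
derived seed per subject. `simulate_rate_table()` exposes the same
distributional skeleton (jitter × Poisson counts per phase window) without
waveform synthesis, which is what the large replicate studies of the
inferential layer run on.

### What the generator does *not* emulate

No biophysics (neural-mass dynamics, pharmacokinetics), no electrode
artifacts, no line noise, no anesthesia-depth drift, no seizure
electrographic evolution beyond rate changes. Detector fidelity measured on
this generator therefore shows that the implementations honor their stated
criteria — not that those criteria are clinically optimal on real ECoG.

## Detector definitions

The published criteria leave several quantities undefined; the package
resolves them as follows, and these resolutions are part of the detector
contracts:

* **Spike amplitude and "baseline".** Amplitude is the Hilbert envelope of
  the 1 kHz signal; baseline is the *median* envelope of a baseline-phase
  epoch. The criterion is then: envelope above `ratio × baseline`
  (default 2) continuously for at least 0.3 s, after merging supra-threshold
  segments separated by less than 50 ms (a biphasic discharge must not be
  split at its zero crossing). The envelope makes the ratio well defined for
  oscillatory backgrounds and polarity-free; the median is robust to the
  spikes themselves.
* **Ripple peaks.** The signal is band-passed to 80–200 Hz (zero-phase
  Butterworth, order 4) and thresholded at `mean + 3 SD` computed over the
  analysis window, so the threshold tracks slow non-stationarity across
  phases. Peaks are local maxima of the *signed* filtered signal — one per
  oscillation cycle — and a train of ≥4 peaks with inter-peak gaps of at
  most one 80 Hz period (12.5 ms) is a ripple. Counting one peak per cycle
  keeps the three parts of the rule mutually consistent: the 12.5 ms
  "consecutive" gap is exactly one period at the band edge, and the mean
  frequency of a train is simply `(n_peaks − 1) / (t_last − t_first)`.
  (Counting rectified half-cycle peaks instead would double that formula
  and, empirically, lets narrowband noise excursions form spurious
  half-cycle trains at a rate that would swamp realistic ripple counts.)

## Statistical model

Each measure (normalized spike rate, RMS percent reduction, each band
power, ripple rate) yields one value per subject per phase. The package
fits the classical two-way mixed ANOVA: CONDITION (sham/magnet) is
between-subject — each animal received only one treatment — and TIME
(baseline/prediazepam/postdiazepam) is within-subject. Sums of squares are
decomposed with the subject-within-condition error stratum; the
between-effect is tested against subjects-within-condition and the
within-effects against the subject × time residual.

Sphericity of the within-subject covariance is never assumed: the
Greenhouse–Geisser epsilon is estimated from the pooled within-group
covariance (bounded in `[1/(k−1), 1]`) and always reported. Following
common practice, the `p_selected` column applies the GG-corrected p-value
when ε < 0.75 and the uncorrected one otherwise; both are always available.
α = 0.05 throughout. Subjects with missing cells are excluded listwise with
a warning — the simplest defensible rule for a complete-design ANOVA.

Tukey HSD comparisons use the studentized-range distribution with the error
stratum appropriate to the family: the subject stratum for condition means,
the within-stratum for time means, and — for the headline contrast, magnet
vs sham *at a given time* — the pooled between + within stratum with all
condition × time cell means as the family.

**Spike-rate normalization.** The analysis divides each subject's rates by
its own prediazepam rate, mirroring the normalized spikes-per-minute
convention for this preparation. This choice is also statistically
load-bearing: the per-subject division removes the multiplicative
between-subject rate factor, which otherwise inflates the subject × time
error term at the high pilocarpine plateau. In replicate studies on the
generator's rate model (phase-window rates, n = 6 per group, jitter
sd 0.2), the normalized analysis holds the interaction test's type-I error
at the nominal 5% under the null and detects a programmed post-diazepam
rate ratio of 0.4 with essentially full power, whereas the raw-rate
analysis falls short of 80% power under the same conditions. Subjects with
a zero reference rate cannot be normalized and are flagged and excluded.

## Numerical choices

* **Downsampling** (20 kHz → 1 kHz) uses a linear-phase FIR low-pass
  (Hamming-windowed, cutoff 0.4 × target rate, unit DC gain) applied with
  exact group-delay compensation, then decimation. Only integer ratios are
  supported; 20 → 1 kHz is exact, and exactness keeps the oracles simple.
* **Band-pass filters** are zero-phase (forward–backward) Butterworth,
  order 4; the effective magnitude response is squared, which tests account
  for.
* **Welch PSD**: 4-s Hann segments, 50% overlap, per-segment mean removal,
  one-sided density. 4-s segments give 0.25 Hz resolution — fine enough to
  resolve the 0–4 Hz delta band. Band intervals are half-open `[lo, hi)`,
  so 4 Hz belongs to theta, deterministically.
* **Phase boundaries** are half-open and start-inclusive: an epoch starting
  exactly at the diazepam injection is postdiazepam. Epochs extending past
  the end of a recording are dropped.
* **EDF I/O** fixes the physical range at ±5000 µV, making the 16-bit
  quantization step (~0.153 µV) deterministic for round-trip tests.
  Metadata EDF cannot carry (condition, experiment-clock start, injection
  timeline) travels in a YAML sidecar.
* **Degenerate inputs** error loudly: all-zero baseline epochs, zero
  reference RMS, windows shorter than two Welch segments, incomplete ANOVA
  designs after exclusion.

## Problem sizes used by the test-suite studies

The package's studies run at reduced scale, chosen as the smallest sizes at
which each property is sharply testable: detector fidelity uses twenty
11-min recordings at 1 kHz with constant 20/min spike and 240/h ripple
rates (~3,500 spikes and ~700 ripples judged); the end-to-end pattern
study uses a 6-vs-6 cohort on a compressed timeline (5-min induction steps,
10-min phase windows) generated directly at 1 kHz; the calibration studies
use 1000 null and 500 alternative replicates of the rate model. Generating
at 1 kHz rather than 20 kHz changes nothing downstream — the analysis chain
operates at 1 kHz — and the compressed timeline preserves every rate
regime of the full 4-h protocol.

## Known limitations

* The ANOVA is the classical sums-of-squares mixed model; REML/mixed-effect
  alternatives, nonparametric tests and Bayesian reanalysis are out of
  scope.
* Single channel only: no montages, re-referencing, or artifact rejection.
* The ripple false-positive rate of the 3 SD / ≥4-peak rule on real,
  artifact-laden ECoG will exceed what the stationary synthetic background
  exhibits; on real data the per-window threshold and a human review of
  detections remain advisable.
* `rms_reduction` is reported relative to the baseline window. During
  ongoing status epilepticus the RMS exceeds baseline, so reductions can
  legitimately be negative; the condition contrast, not the sign, is the
  scientifically meaningful output.
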