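# Spike and ripple detectors: criterion behaviour on constructed signals.

# background-only recording (no events) for detector negative controls
quiet_background <- function(seed = 2, duration = 1800) {
  p <- sim_params(fs = 1000,
                  spikes = list(baseline_rate = 0, pilocarpine_rate = 0,
                                postdiazepam_rate_sham = 0,
                                postdiazepam_rate_magnet = 0),
                  ripples = list(baseline_rate = 0, pilocarpine_rate = 0,
                                 postdiazepam_rate = 0))
  simulate_recording(p, "sham", duration = duration, seed = seed,
                     t0 = -300, tl = tl_short())$recording
}

test_that("baseline amplitude is the median Hilbert envelope", {
  t <- seq(0, 60, by = 1e-3)[-1]
  rec <- recording(sin(2 * pi * 5 * t), 1000, t0 = -300, tl = tl_short())
  ep <- as_epoch(rec, -300, 60)
  expect_identical(ep$phase, "baseline")
  b <- estimate_baseline(ep)
  expect_lt(abs(b$baseline_amp - 1), 0.05)

  # homogeneity: scaling the signal scales the estimate
  rec2 <- recording(35 * sin(2 * pi * 5 * t), 1000, t0 = -300, tl = tl_short())
  b2 <- estimate_baseline(as_epoch(rec2, -300, 60))
  expect_equal(b2$baseline_amp, 35 * b$baseline_amp, tolerance = 1e-9)

  zed <- recording(c(0, rep(0, 999)), 1000, t0 = -300, tl = tl_short())
  expect_error(estimate_baseline(as_epoch(zed, -300, 1)), "all-zero")
})

test_that("spike detection applies the duration and amplitude-ratio criterion", {
  rec <- quiet_background()
  base <- estimate_baseline(as_epoch(rec, -300, 60))

  # the baseline signal itself is sub-threshold by construction
  none <- detect_spikes(as_epoch(rec, -240, 60), base)
  expect_identical(nrow(none), 0L)

  inject <- function(rec, at_rel, dur, ratio) {
    idx <- at_rel * 1000 + seq_len(dur * 1000)
    u <- (seq_along(idx) - 1) / (length(idx) - 1)
    rec$samples[idx] <- rec$samples[idx] *
      (1 - ecosyn:::spike_suppression_window(u)) +
      ecosyn:::spike_waveform(u, ratio * base$baseline_amp)
    rec
  }

  # one 0.5-s transient at 3x baseline -> exactly one event, >= 0.3 s
  r1 <- inject(rec, 350, 0.5, 3)
  ev <- detect_spikes(as_epoch(r1, 30, 60), base)
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$duration, 0.3)
  expect_gte(ev$prop_amp_ratio, 2)
  expect_lt(abs(ev$onset - 350), 0.2)            # onset near injection

  # too short (0.1 s) or too weak (1.5x) -> no events
  r2 <- inject(rec, 350, 0.1, 3)
  expect_identical(nrow(detect_spikes(as_epoch(r2, 30, 60), base)), 0L)
  r3 <- inject(rec, 350, 0.5, 1.5)
  expect_identical(nrow(detect_spikes(as_epoch(r3, 30, 60), base)), 0L)
})

test_that("spike detection is invariant to a common scale factor", {
  sim <- fidelity_recording(31)
  rec <- sim$recording
  base <- estimate_baseline(as_epoch(rec, -300, 60))
  ep <- as_epoch(rec, -240, 120)
  ev1 <- detect_spikes(ep, base)

  rec_scaled <- recording(5 * rec$samples, rec$fs, rec$subject_id,
                          rec$condition, rec$t0, rec$timeline)
  base_scaled <- estimate_baseline(as_epoch(rec_scaled, -300, 60))
  ev2 <- detect_spikes(as_epoch(rec_scaled, -240, 120), base_scaled)
  expect_identical(nrow(ev1), nrow(ev2))
  expect_equal(ev1$onset, ev2$onset, tolerance = 1e-9)
})

test_that("spike rates and normalization follow their definitions", {
  ev <- events_table(kind = rep("spike", 12), onset = seq_len(12),
                     duration = rep(0.4, 12))
  expect_equal(spike_rate(ev, 60), 12)
  expect_equal(spike_rate(events_table(), 60), 0)

  d <- data.frame(subject = "a", time = c("prediazepam", "postdiazepam"),
                  value = c(10, 5))
  n <- normalize_rates(d, reference_time = "prediazepam")
  expect_equal(n$value_norm, c(1, 0.5))

  d0 <- data.frame(subject = c("a", "a", "b", "b"),
                   time = rep(c("prediazepam", "postdiazepam"), 2),
                   value = c(10, 5, 0, 3))
  expect_warning(n0 <- normalize_rates(d0, reference_time = "prediazepam"),
                 "zero reference")
  expect_identical(attr(n0, "flagged_subjects"), "b")
  expect_true(all(is.na(n0$value_norm[n0$subject == "b"])))
})

test_that("ripple detection applies the peak-count and amplitude criterion", {
  set.seed(6)
  fs <- 1000
  noise <- rnorm(120 * fs, sd = 5)
  band_sd <- sd(ecosyn:::bandpass_vector(noise, fs, c(80, 200)))
  tt <- (seq_along(noise) - 1) / fs

  mk <- function(freq, n_cycles, amp_sd, at = 60) {
    dur <- n_cycles / freq
    noise + ecosyn:::ripple_waveform(tt, at, dur, freq, amp_sd * band_sd)
  }
  as_rec <- function(x) recording(x, fs, t0 = -300, tl = tl_short())

  # 100 Hz, 6 cycles, 5 SD -> exactly one event with the right frequency
  ev <- detect_ripples(as_rec(mk(100, 6, 5)))
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$prop_n_peaks, 4)
  expect_lt(abs(ev$prop_mean_freq - 100), 10)
  expect_lt(abs(ev$onset - 60), 0.1)
  expect_gt(ev$prop_max_amp_sd, 3)

  # 3 cycles can never yield 4 consecutive peaks
  expect_identical(nrow(detect_ripples(as_rec(mk(100, 3, 5)))), 0L)
  expect_identical(nrow(detect_ripples(as_rec(mk(150, 3, 8)))), 0L)
})

test_that("every reported ripple satisfies the type invariants", {
  sim <- fidelity_recording(77)
  ev <- detect_ripples(sim$recording, window = c(0, 660))
  expect_gt(nrow(ev), 10)
  expect_true(all(ev$prop_n_peaks >= 4))
  expect_true(all(ev$prop_max_amp_sd > 3))
  expect_true(all(ev$prop_mean_freq >= 60 & ev$prop_mean_freq <= 220))
  # non-overlapping, sorted
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$onset[-1] >= (ev$onset + ev$duration)[-nrow(ev)]))
})

test_that("raising the threshold or peak count never adds detections", {
  sim <- fidelity_recording(78)
  rec <- sim$recording
  n_by_sd <- vapply(c(3, 4, 5, 6), function(sdm)
    nrow(detect_ripples(rec, sd_mult = sdm, window = c(0, 660))), numeric(1))
  expect_true(all(diff(n_by_sd) <= 0))
  n_by_pk <- vapply(c(4, 5, 6, 8), function(mp)
    nrow(detect_ripples(rec, min_peaks = mp, window = c(0, 660))), numeric(1))
  expect_true(all(diff(n_by_pk) <= 0))
})

test_that("ripple rates and mean frequency summarize events correctly", {
  ev <- events_table(kind = rep("ripple", 10), onset = seq(0, 3599, length.out = 10) + 0.5,
                     duration = rep(0.05, 10), mean_freq = rep(c(90, 100), 5))
  expect_equal(ripple_rate(ev, c(0, 3600)), 10)
  expect_equal(mean_ripple_frequency(ev), 95)
  expect_equal(ripple_rate(events_table(), c(0, 3600)), 0)
  expect_true(is.na(mean_ripple_frequency(events_table())))
})
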