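# Synthetic ECoG generator: determinism, degenerate settings, cohort
# structure, and agreement of event counts with the programmed rates.

test_that("identical params and seed reproduce the recording and ground truth", {
  a <- fidelity_recording(42)
  b <- fidelity_recording(42)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$spikes, b$truth$spikes)
  expect_identical(a$truth$ripples, b$truth$ripples)
})

test_that("zero event rates give a pure-background recording", {
  p <- sim_params(fs = 1000,
                  spikes = list(baseline_rate = 0, pilocarpine_rate = 0,
                                postdiazepam_rate_sham = 0,
                                postdiazepam_rate_magnet = 0),
                  ripples = list(baseline_rate = 0, pilocarpine_rate = 0,
                                 postdiazepam_rate = 0))
  sim <- simulate_recording(p, "sham", duration = 1500, seed = 3,
                            t0 = -300, tl = tl_short())
  expect_identical(nrow(sim$truth$spikes), 0L)
  expect_identical(nrow(sim$truth$ripples), 0L)
})

test_that("no noise and no events give a deterministic periodic waveform", {
  p <- sim_params(fs = 1000,
                  background = list(pink_noise_sd = 0),
                  spikes = list(baseline_rate = 0, pilocarpine_rate = 0,
                                postdiazepam_rate_sham = 0,
                                postdiazepam_rate_magnet = 0),
                  ripples = list(baseline_rate = 0, pilocarpine_rate = 0,
                                 postdiazepam_rate = 0))
  sim <- simulate_recording(p, "sham", duration = 1800, seed = 1,
                            t0 = -300, tl = tl_short())
  x <- sim$recording$samples
  # periodic at the 1 Hz slow-oscillation period (pre-diazepam part)
  pre <- x[1:200000]
  expect_lt(max(abs(pre[1:199000] - pre[1001:200000])), 1e-9)
  # matches the closed-form background
  tt <- -300 + (seq_along(x) - 1) / 1000
  expect_equal(x[1:1000], 150 * tanh(12 * sin(2 * pi * tt[1:1000])),
               tolerance = 1e-12)
})

test_that("simulated cohorts have the right structure and are reproducible", {
  p <- fidelity_params()
  coh <- simulate_cohort(2, p, seed = 9, duration = 660, t0 = -300,
                         tl = tl_tiny())
  expect_length(coh, 4L)
  conds <- vapply(coh, function(s) s$recording$condition, character(1))
  expect_identical(sum(conds == "sham"), 2L)
  expect_identical(sum(conds == "magnet"), 2L)
  ids <- vapply(coh, function(s) s$recording$subject_id, character(1))
  expect_identical(anyDuplicated(ids), 0L)

  coh2 <- simulate_cohort(2, p, seed = 9, duration = 660, t0 = -300,
                          tl = tl_tiny())
  expect_identical(lapply(coh, function(s) s$truth$spikes),
                   lapply(coh2, function(s) s$truth$spikes))
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulate_cohort(0, fidelity_params()), "n_per_group")
  expect_error(simulate_recording(fidelity_params(), "sham", duration = 100,
                                  seed = 1, t0 = -300, tl = tl_tiny()),
               "cover")
  expect_error(sim_params(spikes = list(amp_ratio = 1.5)), "amp_ratio")
  expect_error(sim_params(spikes = list(duration_range = c(0.1, 0.5))),
               "duration_range")
  expect_error(sim_params(ripples = list(n_cycles_range = c(3, 8))),
               "n_cycles_range")
  expect_error(sim_params(ripples = list(freq_range = c(50, 200))),
               "freq_range")
})

test_that("ground-truth spike counts follow the programmed Poisson rates", {
  # default parameters, full injection timeline: during the prediazepam hour
  # the rate has reached the pilocarpine plateau (30/min), so the logged
  # count over that hour should fall within 4 sqrt(lambda) of 1800
  sim <- simulate_recording(sim_params(fs = 1000), "sham", duration = 7260,
                            seed = 1, t0 = 0)
  tr <- sim$truth$spikes
  onset_abs <- tr$onset + sim$recording$t0
  n_pre <- sum(onset_abs >= 3600 & onset_abs < 7200)
  expect_gt(n_pre, 1800 - 4 * sqrt(1800))
  expect_lt(n_pre, 1800 + 4 * sqrt(1800))
})

test_that("event counts over seeds match programmed rates within 3 SE", {
  # constant 20/min spike rate, 11-min recordings: expected 220 per seed
  n_seeds <- 12
  counts <- vapply(seq_len(n_seeds), function(s)
    nrow(fidelity_recording(s + 100)$truth$spikes), numeric(1))
  expected <- 20 * 11 * n_seeds
  se <- sqrt(expected)
  expect_lt(abs(sum(counts) - expected), 3 * se)
})

test_that("the rate-model cohort reproduces the design and normalization", {
  d <- simulate_rate_table(6, sim_params(fs = 1000), seed = 5)
  expect_identical(nrow(d), 36L)
  expect_true(all(d$value[d$time == "prediazepam"] == 1))
  d2 <- simulate_rate_table(6, sim_params(fs = 1000), seed = 5)
  expect_identical(d, d2)
  # jitter 0, no normalization: expected rates equal the programmed ones
  d3 <- simulate_rate_table(2, sim_params(fs = 1000), seed = 1,
                            jitter_sd = 0, normalize = FALSE)
  sham_base <- d3$value[d3$condition == "sham" & d3$time == "baseline"]
  expect_lt(abs(mean(sham_base) - 2), 4 * sqrt(2 / 60) / sqrt(2))
})
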