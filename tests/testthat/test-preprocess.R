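# Signal conditioning: downsampling, band-pass filtering, epoching and
# phase windows.

test_that("downsampling preserves DC and in-band amplitude", {
  tl <- tl_short()
  rec_c <- recording(rep(7.5, 40000), 20000, t0 = -300, tl = tl)
  dn <- downsample(rec_c, 1000)
  expect_identical(dn$fs, 1000)
  expect_identical(length(dn$samples), 2000L)
  expect_equal(max(abs(dn$samples - 7.5)), 0, tolerance = 1e-6)

  # 10 Hz unit sinusoid at 20 kHz survives decimation with < 1% amplitude error
  t <- seq(0, 4, by = 1 / 20000)[-1]
  rec_s <- recording(sin(2 * pi * 10 * t), 20000, t0 = -300, tl = tl)
  dn_s <- downsample(rec_s, 1000)
  mid <- dn_s$samples[500:3500]  # avoid filter edges
  expect_lt(abs(max(mid) - 1), 0.01)
  expect_lt(abs(sqrt(2) * rms(mid) - 1), 0.01)
})

test_that("non-integer decimation ratios are rejected", {
  rec <- recording(rnorm(3000), 1500, tl = tl_short())
  expect_error(downsample(rec, 1000), "integer multiple")
})

test_that("band-pass has the expected pass- and stop-band behaviour", {
  t <- seq(0, 10, by = 1e-3)[-1]
  tl <- tl_short()
  inband <- recording(sin(2 * pi * 100 * t), 1000, t0 = -300, tl = tl)
  out <- bandpass(inband, 80, 200)
  mid <- out$samples[2000:8000]
  # oracle: forward-backward filtering applies the squared magnitude
  # response; amplitude measured as sqrt(2) x RMS (the sample grid can
  # miss the sinusoid crest at 10 samples/cycle)
  bt <- signal::butter(4, c(80, 200) / 500, type = "pass")
  w <- pi * 100 / 500
  z <- exp(-1i * w * (seq_along(bt$b) - 1))
  expected_gain <- Mod(sum(bt$b * z) / sum(bt$a * z))^2
  expect_equal(sqrt(2) * rms(mid), expected_gain, tolerance = 0.01)
  expect_gt(sqrt(2) * rms(mid), 0.9)

  low <- recording(sin(2 * pi * 10 * t), 1000, t0 = -300, tl = tl)
  res <- bandpass(low, 80, 200)
  expect_lt(max(abs(res$samples[2000:8000])), 0.01)

  expect_error(bandpass(inband, 80, 600), "fs/2")
  expect_error(bandpass(inband, 0, 200), "fs/2")
})

test_that("filtering is zero-phase (no lag on an in-band burst)", {
  set.seed(4)
  t <- seq(0, 4, by = 1e-3)[-1]
  burst <- exp(-(t - 2)^2 / 0.01) * sin(2 * pi * 120 * t)
  rec <- recording(burst + 0.01 * rnorm(length(t)), 1000, t0 = -300,
                   tl = tl_short())
  filt <- bandpass(rec, 80, 200)$samples
  cc <- stats::ccf(filt, rec$samples, lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("epoch extraction follows the grid and drops truncated epochs", {
  # 7 epochs of 60 s every 30 min span 181 min of signal (k = 0..6)
  rec <- recording(rnorm(10860 * 10), 10, t0 = -3600)
  eps <- extract_epochs(rec, epoch_len = 60, interval = 30)
  expect_length(eps, 7L)
  expect_equal(vapply(eps, `[[`, numeric(1), "start"),
               -3600 + (0:6) * 1800)
  expect_true(all(vapply(eps, function(e) length(e$samples), numeric(1)) == 600))

  expect_warning(none <- extract_epochs(recording(rnorm(300), 10), 60, 30),
                 "shorter")
  expect_length(none, 0L)
})

test_that("epoch phase labels use start-inclusive half-open intervals", {
  rec <- recording(rnorm(10800 * 10), 10, t0 = 7200 - 30)
  eps <- extract_epochs(rec, epoch_len = 60, interval = 0.5)
  starts <- vapply(eps, `[[`, numeric(1), "start")
  phases <- vapply(eps, `[[`, character(1), "phase")
  expect_identical(phases[starts == 7200 - 30], "prediazepam")
  expect_identical(phases[starts == 7200], "postdiazepam")
  # no epoch carries two phases: labels are a function of start time only
  expect_identical(phases, phase_of(starts, rec$timeline))
})

test_that("phase windows follow the timeline and flag partial coverage", {
  rec <- recording(rnorm(14400 * 10), 10, t0 = -3600)
  win <- phase_windows(rec)
  expect_equal(c(win$prediazepam$from, win$prediazepam$to), c(3600, 7200))
  expect_equal(c(win$postdiazepam$from, win$postdiazepam$to), c(7200, 10800))
  expect_false(win$baseline$partial)

  short <- recording(rnorm(7900 * 10), 10, t0 = -600)
  w2 <- phase_windows(short)
  expect_true(w2$baseline$partial)
  expect_equal(w2$baseline$to - w2$baseline$from, 600)
  expect_true(w2$postdiazepam$partial)
})
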