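# Synthetic ECoG generator.
#
# The generator produces the three ingredients of the recordings the
# analysis pipeline expects, each with logged ground truth:
#
#   * background: a smoothed square alternation between up- and down-state
#     amplitudes at the slow-oscillation frequency (the up/down states of
#     sevoflurane anesthesia), plus 1/f noise. After the diazepam injection
#     the whole background is scaled down (stronger under the magnet),
#     emulating the drug-induced suppression of spontaneous activity.
#   * epileptiform spikes: biphasic difference-of-Gaussians transients whose
#     peak amplitude is a fixed multiple of the baseline background
#     amplitude. They arrive as an inhomogeneous Poisson process: a low
#     baseline rate, an exponential ramp to the pilocarpine plateau after
#     the first pilocarpine dose, and an exponential decay toward a
#     condition-specific rate after diazepam. During a spike the background
#     is locally suppressed, as an epileptiform discharge interrupts the
#     ongoing oscillation.
#   * ripples: Gaussian-windowed 80-200 Hz sinusoid bursts whose amplitude is
#     a fixed multiple of the SD of the band-filtered background. Their rate
#     rises with pilocarpine and falls with diazepam, identically in the two
#     conditions (the magnet has no effect on ripples).

#' Simulation parameters
#'
#' Builds the full parameter set of the synthetic ECoG generator, validating
#' the constraints that make injected events detectable by construction:
#' spike amplitude ratio >= 2, spike durations >= 0.3 s, ripple bursts with
#' >= 4 cycles inside 80-200 Hz, and a single condition-independent ripple
#' rate trajectory.
#'
#' @param fs sampling rate in Hz (default 20000, the acquisition rate;
#'   simulations meant for the 1 kHz analysis chain can generate at 1000
#'   directly). Must be >= 500 so the ripple band fits below Nyquist.
#' @param background list overriding any of: `slow_osc_freq` (Hz),
#'   `up_state_amp`, `down_state_amp`, `pink_noise_sd` (uV),
#'   `suppression_sham`, `suppression_magnet` (post-diazepam amplitude
#'   scale factors), `suppression_tau` (s).
#' @param spikes list overriding any of: `baseline_rate`, `pilocarpine_rate`,
#'   `postdiazepam_rate_sham`, `postdiazepam_rate_magnet` (events/min),
#'   `magnet_prediazepam_scale`, `amp_ratio` (>= 2), `duration_range`
#'   (s, min >= 0.3), `onset_ramp_tau`, `decay_tau` (s).
#' @param ripples list overriding any of: `baseline_rate`, `pilocarpine_rate`,
#'   `postdiazepam_rate` (events/h), `freq_range` (within 80-200 Hz),
#'   `n_cycles_range` (integers, min >= 4), `amp_sd_multiple` (>= 3).
#' @return a validated list of class `ecosyn_sim_params`.
#' @export
sim_params <- function(fs = 20000, background = list(), spikes = list(),
                       ripples = list()) {
  p <- list(
    fs = fs,
    background = list(slow_osc_freq = 1, up_state_amp = 150,
                      down_state_amp = 150, pink_noise_sd = 20,
                      suppression_sham = 0.6, suppression_magnet = 0.4,
                      suppression_tau = 60),
    spikes = list(baseline_rate = 2, pilocarpine_rate = 30,
                  postdiazepam_rate_sham = 3, postdiazepam_rate_magnet = 0.9,
                  magnet_prediazepam_scale = 0.5,
                  amp_ratio = 3, duration_range = c(0.4, 0.8),
                  onset_ramp_tau = 300, decay_tau = 60),
    ripples = list(baseline_rate = 20, pilocarpine_rate = 120,
                   postdiazepam_rate = 40, freq_range = c(80, 200),
                   n_cycles_range = c(6L, 10L), amp_sd_multiple = 5))
  p$background <- utils::modifyList(p$background, background)
  p$spikes <- utils::modifyList(p$spikes, spikes)
  p$ripples <- utils::modifyList(p$ripples, ripples)

  stopifnot_scalar_number(p$fs, "fs", positive = TRUE)
  if (p$fs < 500)
    abort_validation("fs must be >= 500 Hz so the 80-200 Hz ripple band fits")
  sp <- p$spikes; rp <- p$ripples
  rates <- c(sp$baseline_rate, sp$pilocarpine_rate, sp$postdiazepam_rate_sham,
             sp$postdiazepam_rate_magnet, rp$baseline_rate,
             rp$pilocarpine_rate, rp$postdiazepam_rate)
  if (any(rates < 0)) abort_validation("all event rates must be >= 0")
  if (sp$amp_ratio < 2)
    abort_validation("spikes$amp_ratio must be >= 2 so injected spikes satisfy the detection criterion")
  if (length(sp$duration_range) != 2L || sp$duration_range[1] < 0.3 ||
      diff(sp$duration_range) < 0)
    abort_validation("spikes$duration_range must be increasing with min >= 0.3 s")
  if (length(rp$freq_range) != 2L || rp$freq_range[1] < 80 ||
      rp$freq_range[2] > 200 || diff(rp$freq_range) < 0)
    abort_validation("ripples$freq_range must lie within [80, 200] Hz")
  if (rp$n_cycles_range[1] < 4)
    abort_validation("ripples$n_cycles_range minimum must be >= 4 so injected ripples satisfy the criterion")
  if (rp$amp_sd_multiple < 3)
    abort_validation("ripples$amp_sd_multiple must be >= 3")
  class(p) <- "ecosyn_sim_params"
  p
}

# condition-resolved event-rate trajectory (events per second) on time grid t
event_rate_trajectory <- function(t, kind = c("spike", "ripple"), params,
                                  condition, tl) {
  kind <- match.arg(kind)
  if (kind == "spike") {
    sp <- params$spikes
    base <- sp$baseline_rate / 60
    plateau <- sp$pilocarpine_rate / 60
    if (condition == "magnet") plateau <- plateau * sp$magnet_prediazepam_scale
    post <- (if (condition == "magnet") sp$postdiazepam_rate_magnet
             else sp$postdiazepam_rate_sham) / 60
    tau_up <- sp$onset_ramp_tau; tau_dn <- sp$decay_tau
  } else {
    rp <- params$ripples
    base <- rp$baseline_rate / 3600
    plateau <- rp$pilocarpine_rate / 3600
    post <- rp$postdiazepam_rate / 3600
    tau_up <- params$spikes$onset_ramp_tau; tau_dn <- params$spikes$decay_tau
  }
  r <- rep(base, length(t))
  up <- t >= tl$pilocarpine1_t & t < tl$diazepam_t
  r[up] <- plateau - (plateau - base) * exp(-(t[up] - tl$pilocarpine1_t) / tau_up)
  at_dz <- plateau - (plateau - base) *
    exp(-(tl$diazepam_t - tl$pilocarpine1_t) / tau_up)
  dn <- t >= tl$diazepam_t
  r[dn] <- post + (at_dz - post) * exp(-(t[dn] - tl$diazepam_t) / tau_dn)
  r
}

# Draw event onsets from an inhomogeneous Poisson process on [t0, t1) by
# inverse-CDF sampling of N ~ Poisson(integral of the rate). Events closer
# than `min_gap` seconds to an accepted event are redrawn (up to 50
# attempts each, then dropped), keeping the drawn count; the hard gap keeps
# the ground truth unambiguous for detectors that merge nearby segments.
draw_poisson_events <- function(t0, t1, rate_fun, dur_fun, min_gap = 0.1) {
  grid <- seq(t0, t1, by = 1)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)
  lam <- rate_fun(grid)
  cum <- c(0, cumsum((head(lam, -1) + tail(lam, -1)) / 2 * diff(grid)))
  total <- cum[length(cum)]
  n <- rpois(1L, total)
  if (n == 0L) return(data.frame(onset = numeric(), duration = numeric()))
  draw_onset <- function(k) stats::approx(cum, grid, xout = runif(k) * total,
                                          ties = "ordered")$y
  onset <- draw_onset(n)
  duration <- dur_fun(n)
  ord <- order(onset); onset <- onset[ord]; duration <- duration[ord]
  overlaps <- function(o, d, os, ds) {
    if (length(os) == 0) return(FALSE)
    any(pmin(o + d, os + ds) - pmax(o, os) > -min_gap)
  }
  keep_o <- numeric(0); keep_d <- numeric(0)
  for (i in seq_len(n)) {
    o <- onset[i]; d <- duration[i]
    tries <- 0L
    while ((overlaps(o, d, keep_o, keep_d) || o + d > t1) && tries < 50L) {
      o <- draw_onset(1L); d <- dur_fun(1L); tries <- tries + 1L
    }
    if (!overlaps(o, d, keep_o, keep_d) && o + d <= t1) {
      keep_o <- c(keep_o, o); keep_d <- c(keep_d, d)
    }
  }
  ord <- order(keep_o)
  data.frame(onset = keep_o[ord], duration = keep_d[ord])
}

# difference-of-Gaussians biphasic spike, peak amplitude ~ amp, duration d,
# sampled at times u in [0, 1] (fraction of d)
spike_waveform <- function(u, amp) {
  s <- 1 / 6
  amp * (exp(-(u - 0.3)^2 / (2 * s^2)) - exp(-(u - 0.7)^2 / (2 * s^2)))
}

# local background suppression during a spike: flat core with raised-cosine
# ramps over the outer 15% (a C1-continuous edge leaks far less power into
# the 80-200 Hz ripple band than a linear ramp would)
spike_suppression_window <- function(u) {
  a <- 0.15
  w <- rep(1, length(u))
  lo <- u < a; hi <- u > 1 - a
  w[lo] <- 0.5 * (1 - cos(pi * u[lo] / a))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / a))
  w
}

ripple_waveform <- function(tt, onset, duration, freq, amp) {
  # flat-top (Tukey) amplitude window: full amplitude over the central 70%
  # of the burst, cosine tapers over the outer 15% on each side, so nearly
  # every cycle's peak stays above the detector threshold
  u <- (tt - onset) / duration
  a <- 0.15
  w <- rep(1, length(u))
  lo <- u < a; hi <- u > 1 - a
  w[lo] <- 0.5 * (1 - cos(pi * u[lo] / a))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / a))
  w[u < 0 | u > 1] <- 0
  amp * w * sin(2 * pi * freq * (tt - onset))
}

#' Simulate one ECoG recording with ground truth
#'
#' Generates a single-channel recording following the injection timeline,
#' plus the ground-truth event log of every injected spike and ripple.
#' Identical `(params, condition, duration, t0, seed)` give identical output.
#'
#' @param params a [sim_params()] object.
#' @param condition `"sham"` or `"magnet"`.
#' @param duration recording length (s); must reach at least the diazepam
#'   injection of `tl`.
#' @param seed integer RNG seed.
#' @param t0 recording start (s, experiment clock); defaults to one hour
#'   before the scopolamine injection.
#' @param tl injection [timeline()].
#' @param subject_id subject label.
#' @param rate_scale named list with optional `spikes` and `ripples`
#'   multiplicative factors (per-subject random effects; used by
#'   [simulate_cohort()]).
#' @return a list with elements `recording` (an [recording()]) and `truth`
#'   (a list with `spikes` and `ripples` [events_table()]s, plus `params`,
#'   `condition` and `seed`).
#' @export
simulate_recording <- function(params = sim_params(), condition = c("sham", "magnet"),
                               duration = NULL, seed = 1, t0 = NULL,
                               tl = timeline(), subject_id = "s1",
                               rate_scale = list(spikes = 1, ripples = 1)) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "ecosyn_sim_params"))
  if (is.null(t0)) t0 <- tl$scopolamine_t - 3600
  if (is.null(duration)) duration <- (tl$diazepam_t + 3600) - t0
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  t_end <- t0 + duration
  if (t_end < tl$diazepam_t)
    abort_validation("recording duration does not cover the injection timeline (must reach diazepam)")

  fs <- params$fs
  n <- round(duration * fs)
  set.seed(seed)

  ## background: smoothed square slow oscillation + 1/f noise
  bgp <- params$background
  tt <- t0 + (seq_len(n) - 1L) / fs
  mid <- (bgp$up_state_amp - bgp$down_state_amp) / 2
  half <- (bgp$up_state_amp + bgp$down_state_amp) / 2
  # steepness 12 gives ~25 ms state transitions: the square-ish alternation
  # then carries power through the beta band (12-30 Hz) like real up/down
  # states, while leaking nothing measurable into the 80-200 Hz ripple band
  slow <- half * tanh(12 * sin(2 * pi * bgp$slow_osc_freq * tt)) + mid

  ## post-diazepam suppression acts on the cortical slow oscillation; the
  ## 1/f noise floor (instrumental + distant sources) is phase-independent
  supp <- if (condition == "magnet") bgp$suppression_magnet else bgp$suppression_sham
  post <- tt >= tl$diazepam_t
  scale <- rep(1, n)
  scale[post] <- 1 - (1 - supp) *
    (1 - exp(-(tt[post] - tl$diazepam_t) / bgp$suppression_tau))
  x <- slow * scale + pink_noise(n, bgp$pink_noise_sd)

  ## amplitude references, both measured on the clean background so injected
  ## events satisfy the detection criteria in the detectors' own units:
  ## spikes are scaled by the median Hilbert envelope (what the spike
  ## detector calls "baseline"), ripples by the SD of the band-filtered
  ## background (what the ripple threshold is computed from)
  ref_seg <- x[seq_len(min(n, 120 * fs))]
  env_ref <- median(hilbert_envelope(ref_seg))
  band_sd <- stats::sd(bandpass_vector(ref_seg, fs, params$ripples$freq_range))

  ## epileptiform spikes
  sp <- params$spikes
  spike_scale <- rate_scale$spikes %||% 1
  spikes <- draw_poisson_events(
    t0, t_end,
    rate_fun = function(t) spike_scale *
      event_rate_trajectory(t, "spike", params, condition, tl),
    dur_fun = function(k) runif(k, sp$duration_range[1], sp$duration_range[2]))
  base_amp <- env_ref
  if (nrow(spikes) > 0) {
    for (i in seq_len(nrow(spikes))) {
      i0 <- floor((spikes$onset[i] - t0) * fs) + 1L
      i1 <- min(n, i0 + round(spikes$duration[i] * fs) - 1L)
      idx <- i0:i1
      u <- (idx - i0) / (length(idx) - 1L)
      amp <- sp$amp_ratio * base_amp
      x[idx] <- x[idx] * (1 - spike_suppression_window(u)) + spike_waveform(u, amp)
    }
  }
  # event tables carry onsets relative to the recording start (>= 0);
  # add rec$t0 to place them on the experiment clock
  truth_spikes <- events_table(kind = rep("spike", nrow(spikes)),
                               onset = spikes$onset - t0,
                               duration = spikes$duration,
                               amp_ratio = rep(sp$amp_ratio, nrow(spikes)),
                               peak_amp = rep(sp$amp_ratio * base_amp, nrow(spikes)))

  ## ripples
  rp <- params$ripples
  ripple_scale <- rate_scale$ripples %||% 1
  rip <- draw_poisson_events(
    t0, t_end,
    rate_fun = function(t) ripple_scale *
      event_rate_trajectory(t, "ripple", params, condition, tl),
    # provisional durations spanning the burst-length range, for overlap
    # resolution only; frequency and cycle count are drawn per accepted event
    dur_fun = function(k) runif(k, rp$n_cycles_range[1] / rp$freq_range[2],
                                rp$n_cycles_range[2] / rp$freq_range[1]))
  nr <- nrow(rip)
  freq <- numeric(nr); ncyc <- integer(nr)
  if (nr > 0) {
    freq <- runif(nr, rp$freq_range[1], rp$freq_range[2])
    ncyc <- sample(seq(rp$n_cycles_range[1], rp$n_cycles_range[2]), nr, replace = TRUE)
    rip$duration <- ncyc / freq
    amp <- rp$amp_sd_multiple * band_sd
    for (i in seq_len(nr)) {
      i0 <- floor((rip$onset[i] - t0) * fs) + 1L
      i1 <- min(n, i0 + round(rip$duration[i] * fs) - 1L)
      idx <- i0:i1
      x[idx] <- x[idx] + ripple_waveform(tt[idx], rip$onset[i], rip$duration[i],
                                         freq[i], amp)
    }
  }
  truth_ripples <- events_table(kind = rep("ripple", nr),
                                onset = (if (nr > 0) rip$onset - t0 else numeric()),
                                duration = rip$duration,
                                freq = freq, n_cycles = as.numeric(ncyc),
                                amp_sd = rep(rp$amp_sd_multiple, nr))

  rec <- recording(x, fs, subject_id = subject_id, condition = condition,
                   t0 = t0, tl = tl)
  list(recording = rec,
       truth = list(spikes = truth_spikes, ripples = truth_ripples,
                    params = params, condition = condition, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-group cohort
#'
#' `n_per_group` sham and `n_per_group` magnet subjects, each with its own
#' derived seed and a per-subject log-normal multiplicative jitter on the
#' spike and ripple rates (the between-subject variance component of the
#' mixed design). Reproducible given `seed`.
#'
#' @inheritParams simulate_recording
#' @param n_per_group subjects per condition (>= 1).
#' @param jitter_sd sdlog of the log-normal per-subject rate factor.
#' @return list of per-subject results as returned by [simulate_recording()].
#' @export
simulate_cohort <- function(n_per_group, params = sim_params(), seed = 1,
                            jitter_sd = 0.2, duration = NULL, t0 = NULL,
                            tl = timeline()) {
  if (!is.numeric(n_per_group) || n_per_group < 1)
    abort_validation("`n_per_group` must be >= 1")
  n_per_group <- as.integer(n_per_group)
  set.seed(seed)
  n_tot <- 2L * n_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  jit_sp <- rlnorm(n_tot, 0, jitter_sd)
  jit_rp <- rlnorm(n_tot, 0, jitter_sd)
  conditions <- rep(c("sham", "magnet"), each = n_per_group)
  ids <- sprintf("%s%02d", conditions, c(seq_len(n_per_group), seq_len(n_per_group)))
  lapply(seq_len(n_tot), function(i)
    simulate_recording(params, conditions[i], duration = duration,
                       seed = seeds[i], t0 = t0, tl = tl, subject_id = ids[i],
                       rate_scale = list(spikes = jit_sp[i], ripples = jit_rp[i])))
}

#' Simulate per-subject phase spike rates from the generator's rate model
#'
#' The distributional skeleton of [simulate_cohort()] without waveform
#' synthesis: per subject, a log-normal rate factor and Poisson event counts
#' over one analysis window per phase, returned as a measure table ready for
#' [mixed_rm_anova()]. This is what large replicate studies of the
#' inferential layer (type-I error, power) run on.
#'
#' @inheritParams simulate_cohort
#' @param window_s analysis window length per phase (s); rates are reported
#'   in events/min.
#' @param normalize divide each subject's rates by its prediazepam rate
#'   (the normalized spikes-per-minute analysis). Subjects with a zero
#'   reference count are redrawn from their Poisson law, as a zero-rate
#'   reference leaves normalization undefined.
#' @return data.frame with columns subject, condition, time, value.
#' @export
simulate_rate_table <- function(n_per_group, params = sim_params(), seed = 1,
                                jitter_sd = 0.2, window_s = 3600,
                                normalize = TRUE) {
  if (!is.numeric(n_per_group) || n_per_group < 1)
    abort_validation("`n_per_group` must be >= 1")
  set.seed(seed)
  sp <- params$spikes
  rows <- vector("list", 2L * n_per_group)
  id <- 0L
  for (cond in c("sham", "magnet")) {
    plateau <- sp$pilocarpine_rate *
      (if (cond == "magnet") sp$magnet_prediazepam_scale else 1)
    post <- if (cond == "magnet") sp$postdiazepam_rate_magnet else sp$postdiazepam_rate_sham
    mu <- c(baseline = sp$baseline_rate, prediazepam = plateau, postdiazepam = post)
    for (s in seq_len(n_per_group)) {
      id <- id + 1L
      j <- rlnorm(1, 0, jitter_sd)
      cnt <- rpois(3L, j * mu * window_s / 60)
      if (normalize) {
        while (cnt[2L] == 0L) cnt[2L] <- rpois(1L, j * mu[2L] * window_s / 60)
      }
      val <- cnt * 60 / window_s
      if (normalize) val <- val / val[2L]
      rows[[id]] <- data.frame(subject = sprintf("%s%02d", cond, s),
                               condition = cond, time = names(mu),
                               value = as.numeric(val))
    }
  }
  do.call(rbind, rows)
}
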