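# Event detectors.
#
# Epileptiform spikes: the criterion is a discharge lasting at least 0.3 s
# with amplitude at least twice the baseline. "Amplitude" is the Hilbert
# envelope of the signal, and "baseline" is the median envelope of a
# baseline-phase epoch, which makes the 2x ratio well defined for an
# oscillatory background and insensitive to polarity.
#
# Ripples: band-pass 80-200 Hz, then an oscillation with 4 or more
# consecutive supra-threshold peaks counts as a ripple, where the threshold
# is mean + 3 SD of the band-filtered signal over the analysis window.
# Peaks are local maxima of the signed filtered signal (one per oscillation
# cycle), and "consecutive" means inter-peak gaps no longer than 12.5 ms,
# the period of the 80 Hz band edge; with one peak per cycle the mean
# frequency of a train is simply (n_peaks - 1) / (t_last - t_first).

#' Baseline amplitude statistics
#'
#' Robust amplitude of a baseline-phase epoch: the median of the Hilbert
#' envelope. This is the reference the spike criterion's "two times higher
#' than the baseline" is measured against.
#'
#' @param epoch a baseline-phase epoch from [extract_epochs()].
#' @return list with `baseline_amp` (uV) and `source_epoch`.
#' @export
estimate_baseline <- function(epoch) {
  stopifnot(inherits(epoch, "ecosyn_epoch"))
  if (all(epoch$samples == 0))
    abort_validation("baseline amplitude undefined for an all-zero epoch")
  env <- hilbert_envelope(epoch$samples)
  amp <- median(env)
  if (amp <= 0) abort_validation("baseline amplitude must be positive")
  structure(list(baseline_amp = amp,
                 source_epoch = list(subject_id = epoch$subject_id,
                                     start = epoch$start)),
            class = "ecosyn_baseline")
}

#' Detect epileptiform spikes in an epoch
#'
#' Contiguous segments where the Hilbert envelope exceeds
#' `ratio x baseline_amp` become candidate discharges; segments separated by
#' less than 50 ms are merged first (one biphasic discharge must not be
#' split at its zero crossing), then segments shorter than `min_duration`
#' are discarded.
#'
#' @param epoch an epoch (or any `ecosyn_epoch`) at the analysis rate.
#' @param base baseline statistics from [estimate_baseline()].
#' @param min_duration minimum discharge duration (s), default 0.3.
#' @param ratio envelope-to-baseline amplitude threshold, default 2.
#' @param merge_gap maximum sub-threshold gap merged into one discharge (s).
#' @return an [events_table()] of spikes, onsets in seconds from the
#'   recording start, sorted and non-overlapping, with `prop_peak_amp` (uV)
#'   and `prop_amp_ratio` (peak envelope / baseline).
#' @export
detect_spikes <- function(epoch, base, min_duration = 0.3, ratio = 2.0,
                          merge_gap = 0.05) {
  stopifnot(inherits(epoch, "ecosyn_epoch"), inherits(base, "ecosyn_baseline"))
  fs <- epoch$fs
  env <- hilbert_envelope(epoch$samples)
  thr <- ratio * base$baseline_amp
  segs <- runs_above(env > thr)
  if (nrow(segs) > 0 && merge_gap > 0) segs <- merge_runs(segs, merge_gap * fs)
  keep <- (segs$end - segs$start + 1L) / fs >= min_duration
  segs <- segs[keep, , drop = FALSE]
  n <- nrow(segs)
  peak <- vapply(seq_len(n), function(i)
    max(env[segs$start[i]:segs$end[i]]), numeric(1))
  events_table(kind = rep("spike", n),
               onset = epoch$start_rel + (segs$start - 1L) / fs,
               duration = (segs$end - segs$start + 1L) / fs,
               peak_amp = peak,
               amp_ratio = peak / base$baseline_amp)
}

# runs of TRUE as (start, end) sample indices
runs_above <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(segs, max_gap_samples) {
  if (nrow(segs) <= 1L) return(segs)
  out_s <- segs$start[1L]; out_e <- segs$end[1L]
  for (i in 2L:nrow(segs)) {
    if (segs$start[i] - out_e[length(out_e)] - 1L < max_gap_samples) {
      out_e[length(out_e)] <- segs$end[i]
    } else {
      out_s <- c(out_s, segs$start[i]); out_e <- c(out_e, segs$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Spike rate of an epoch
#' @param events an [events_table()] (spikes).
#' @param epoch_len epoch length (s) the events were counted in.
#' @return rate in events/min.
#' @export
spike_rate <- function(events, epoch_len) {
  stopifnot_scalar_number(epoch_len, "epoch_len", positive = TRUE)
  nrow(events) * 60 / epoch_len
}

#' Normalize per-subject rates to a reference time point
#'
#' Divides each subject's rates by that subject's rate at the reference
#' time level (by default the first prediazepam time point, i.e. the first
#' measurement after the second pilocarpine dose), so the reference value is
#' 1 for every subject. Subjects whose reference rate is zero cannot be
#' normalized; they are flagged and their normalized values set to `NA`.
#'
#' @param rates data.frame with columns `subject`, `time` (orderable) and
#'   `value`.
#' @param reference_time the time level to normalize by; default the
#'   smallest time level present (callers pass the first post-pilocarpine
#'   measurement).
#' @return the input with a `value_norm` column and an attribute
#'   `flagged_subjects` naming subjects with a zero reference rate.
#' @export
normalize_rates <- function(rates, reference_time = NULL) {
  stopifnot(all(c("subject", "time", "value") %in% names(rates)))
  if (is.null(reference_time)) reference_time <- min(rates$time)
  flagged <- character(0)
  rates$value_norm <- NA_real_
  for (s in unique(rates$subject)) {
    sel <- rates$subject == s
    ref <- rates$value[sel & rates$time == reference_time]
    if (length(ref) != 1L || ref == 0) {
      flagged <- c(flagged, s)
      next
    }
    rates$value_norm[sel] <- rates$value[sel] / ref
  }
  if (length(flagged) > 0)
    warning("zero reference rate; normalized values set to NA for: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  attr(rates, "flagged_subjects") <- flagged
  rates
}

#' Detect ripples (80-200 Hz high-frequency oscillations)
#'
#' Filters the signal to `band`, thresholds at `mean + sd_mult x SD` of the
#' band-filtered signal over the analysis window, finds local maxima of the
#' signed filtered signal above threshold (one candidate peak per
#' oscillation cycle), groups them into trains with inter-peak gaps of at
#' most one 80 Hz period (12.5 ms), and reports trains of at least
#' `min_peaks` peaks. With one peak per cycle the mean frequency of a train
#' is `(n_peaks - 1) / (t_last - t_first)`.
#'
#' Computing the threshold per analysis window (rather than once per
#' recording) tracks the non-stationarity of the background across phases;
#' pass `window` to restrict detection to one phase window at a time.
#'
#' @param rec an [recording()] at the analysis rate (>= 1 s long).
#' @param band analysis band (Hz), default `c(80, 200)`.
#' @param min_peaks minimum number of consecutive supra-threshold peaks.
#' @param sd_mult threshold in SD units above the mean, default 3.
#' @param window optional `c(from, to)` in seconds from the recording
#'   start; detection and the threshold statistics are confined to it.
#' @return an [events_table()] of ripples, onsets in seconds from the
#'   recording start, with `prop_n_peaks`, `prop_mean_freq` (Hz) and
#'   `prop_max_amp_sd` (peak amplitude in SD units).
#' @export
detect_ripples <- function(rec, band = c(80, 200), min_peaks = 4L,
                           sd_mult = 3.0, window = NULL) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  fs <- rec$fs
  x <- rec$samples
  off <- 0
  if (!is.null(window)) {
    if (length(window) != 2L || diff(window) <= 0)
      abort_validation("`window` must be an increasing interval")
    i0 <- max(1L, floor(window[1] * fs) + 1L)
    i1 <- min(length(x), ceiling(window[2] * fs))
    x <- x[i0:i1]
    off <- (i0 - 1L) / fs
  }
  if (length(x) < fs)
    abort_validation("ripple detection needs at least 1 s of signal")
  y <- bandpass_vector(x, fs, band)
  mu <- mean(y); sdv <- sd(y)
  if (sdv == 0) return(empty_ripples())
  thr <- mu + sd_mult * sdv
  n <- length(y)
  is_peak <- y > thr
  is_peak[c(1L, n)] <- FALSE
  core <- which(is_peak)
  core <- core[y[core] >= y[core - 1L] & y[core] > y[core + 1L]]
  if (length(core) == 0L) return(empty_ripples())
  max_gap <- ceiling(0.0125 * fs) + 1L   # one 80 Hz period, + sampling slack
  grp <- cumsum(c(1L, diff(core) > max_gap))
  out <- lapply(split(core, grp), function(pk) {
    if (length(pk) < min_peaks) return(NULL)
    t1 <- (pk[1L] - 1L) / fs; t2 <- (pk[length(pk)] - 1L) / fs
    data.frame(onset = off + t1, offset = off + t2,
               n_peaks = length(pk),
               mean_freq = (length(pk) - 1L) / (t2 - t1),
               max_amp_sd = (max(y[pk]) - mu) / sdv)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty_ripples())
  events_table(kind = rep("ripple", nrow(out)),
               onset = out$onset,
               duration = out$offset - out$onset,
               n_peaks = out$n_peaks,
               mean_freq = out$mean_freq,
               max_amp_sd = out$max_amp_sd)
}

empty_ripples <- function() events_table()

#' Ripple rate in a window
#' @param events ripple [events_table()] (onsets in recording-relative s).
#' @param window numeric length-2 interval (same clock as the onsets).
#' @return events per hour.
#' @export
ripple_rate <- function(events, window) {
  if (length(window) != 2L || diff(window) <= 0)
    abort_validation("`window` must be an increasing interval")
  n <- sum(events$onset >= window[1] & events$onset < window[2])
  n * 3600 / diff(window)
}

#' Mean ripple frequency in a window
#' @inheritParams ripple_rate
#' @param window optional interval; all events if omitted.
#' @return mean of the per-event mean frequencies (Hz), or `NA` if no events.
#' @export
mean_ripple_frequency <- function(events, window = NULL) {
  sel <- rep(TRUE, nrow(events))
  if (!is.null(window))
    sel <- events$onset >= window[1] & events$onset < window[2]
  if (!any(sel)) return(NA_real_)
  mean(events$prop_mean_freq[sel])
}
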