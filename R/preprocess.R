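# Signal conditioning: anti-aliased downsampling to the 1 kHz analysis rate,
# zero-phase band-pass filtering, automatic 60-s epoch extraction every
# 30 min, and the three one-hour phase windows.

#' Downsample a recording by an integer factor
#'
#' Anti-alias low-pass (zero-phase FIR, cutoff 0.4 x target rate) followed by
#' decimation. Only integer ratios are supported; the DC level is preserved.
#'
#' @param rec an [recording()].
#' @param target_fs target sampling rate (Hz), default 1000.
#' @return the downsampled [recording()].
#' @export
downsample <- function(rec, target_fs = 1000) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  stopifnot_scalar_number(target_fs, "target_fs", positive = TRUE)
  if (rec$fs == target_fs) return(rec)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    abort_validation(sprintf("fs (%g) must be an integer multiple of target_fs (%g)",
                             rec$fs, target_fs))
  ratio <- round(ratio)
  cutoff <- 0.4 * target_fs
  y <- fir_lowpass_zerophase(rec$samples, rec$fs, cutoff,
                             transition = 0.1 * target_fs)
  y <- y[seq(1L, length(y), by = ratio)]
  recording(y, target_fs, subject_id = rec$subject_id, condition = rec$condition,
            t0 = rec$t0, tl = rec$timeline)
}

# zero-phase Butterworth band-pass on a bare numeric vector
bandpass_vector <- function(x, fs, band, order = 4) {
  low <- band[1]; high <- band[2]
  if (!(low > 0 && low < high && high < fs / 2))
    abort_validation(sprintf("band edges must satisfy 0 < low < high < fs/2 (got [%g, %g] at fs=%g)",
                             low, high, fs))
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bt, x))
}

#' Zero-phase band-pass filter
#'
#' Butterworth filter of the given order applied forward and backward
#' (zero phase, squared magnitude response). Output length equals input
#' length.
#'
#' @param rec an [recording()].
#' @param low,high band edges (Hz), `0 < low < high < fs/2`.
#' @param order filter order (default 4).
#' @return the filtered [recording()].
#' @export
bandpass <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  y <- bandpass_vector(rec$samples, rec$fs, c(low, high), order)
  recording(y, rec$fs, subject_id = rec$subject_id, condition = rec$condition,
            t0 = rec$t0, tl = rec$timeline)
}

new_epoch <- function(rec, start, duration) {
  samples <- rec_slice(rec, start, start + duration)
  structure(list(subject_id = rec$subject_id, condition = rec$condition,
                 start = start, start_rel = start - rec$t0,
                 duration = duration, fs = rec$fs,
                 phase = phase_of(start, rec$timeline),
                 offset_from_diazepam = (start - rec$timeline$diazepam_t) / 60,
                 samples = samples),
            class = "ecosyn_epoch")
}

#' @export
print.ecosyn_epoch <- function(x, ...) {
  cat(sprintf("<ecosyn_epoch> %s (%s) t=%g s, %g s @ %g Hz, phase=%s\n",
              x$subject_id, x$condition, x$start, x$duration, x$fs,
              ifelse(is.na(x$phase), "<none>", x$phase)))
  invisible(x)
}

#' View an arbitrary stretch of a recording as an epoch
#'
#' @param rec an [recording()].
#' @param start epoch start (s, experiment clock).
#' @param duration epoch length (s).
#' @return an `ecosyn_epoch` carrying the samples, phase label and timing.
#' @export
as_epoch <- function(rec, start, duration) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (start < rec$t0 || start + duration > rec$t0 + rec_duration(rec) + 1e-9)
    abort_validation("epoch extends outside the recording")
  new_epoch(rec, start, duration)
}

#' Extract analysis epochs at a fixed interval
#'
#' Epochs of `epoch_len` seconds starting every `interval` minutes from the
#' beginning of the recording. Epochs that would extend past the end of the
#' recording are dropped. Each epoch is labelled with its analysis phase
#' (by its start time; half-open, start-inclusive intervals) and its offset
#' from the diazepam injection in minutes.
#'
#' @param rec an [recording()] at the analysis rate.
#' @param epoch_len epoch length (s), default 60.
#' @param interval epoch spacing (min), default 30.
#' @return list of epochs; empty (with a warning) if the recording is
#'   shorter than one epoch.
#' @export
extract_epochs <- function(rec, epoch_len = 60, interval = 30) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  stopifnot_scalar_number(epoch_len, "epoch_len", positive = TRUE)
  stopifnot_scalar_number(interval, "interval", positive = TRUE)
  dur <- rec_duration(rec)
  if (dur < epoch_len) {
    warning("recording shorter than one epoch; returning no epochs", call. = FALSE)
    return(list())
  }
  starts <- seq(rec$t0, rec$t0 + dur - epoch_len, by = interval * 60)
  lapply(starts, function(s) new_epoch(rec, s, epoch_len))
}

#' One-hour analysis windows per phase
#'
#' The three windows the phase-level analyses average over: the hour before
#' the scopolamine injection (baseline), the hour from the second
#' pilocarpine dose to diazepam (prediazepam), and the hour after diazepam
#' (postdiazepam). Windows are clipped to the recorded interval; a clipped
#' window is flagged `partial`, and a window with no recorded samples at all
#' is flagged `missing`.
#'
#' @param rec an [recording()].
#' @return named list of `list(from, to, partial, missing)` on the
#'   experiment clock, one per phase.
#' @export
phase_windows <- function(rec) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  tl <- rec$timeline
  t_lo <- rec$t0; t_hi <- rec$t0 + rec_duration(rec)
  win <- list(
    baseline = c(tl$scopolamine_t - 3600, tl$scopolamine_t),
    prediazepam = c(tl$pilocarpine2_t, tl$diazepam_t),
    postdiazepam = c(tl$diazepam_t, tl$diazepam_t + 3600))
  lapply(win, function(w) {
    from <- max(w[1], t_lo); to <- min(w[2], t_hi)
    list(from = from, to = to,
         partial = (from > w[1] || to < w[2]) && to > from,
         missing = to <= from)
  })
}
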