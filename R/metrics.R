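# Amplitude and spectral metrics: RMS per epoch, percent RMS reduction
# relative to baseline, and band-limited power from a Welch periodogram.

#' Root-mean-square amplitude
#'
#' `sqrt(mean(x^2))`: for a DC signal this is its absolute level, for a
#' sinusoid of amplitude A over whole cycles it is A/sqrt(2).
#'
#' @param samples non-empty numeric vector (uV).
#' @return RMS (uV).
#' @export
rms <- function(samples) {
  if (length(samples) == 0L) abort_validation("rms of an empty vector is undefined")
  if (!all(is.finite(samples))) abort_validation("samples must be finite")
  sqrt(mean(samples^2))
}

#' Percent reduction in RMS relative to a reference
#'
#' `100 * (1 - epoch_rms / reference_rms)`; negative values indicate an
#' increase over the reference.
#'
#' @param epoch_rms RMS of the epoch under study (uV).
#' @param reference_rms RMS of the reference (baseline) epoch (uV, > 0).
#' @return percent reduction.
#' @export
rms_reduction <- function(epoch_rms, reference_rms) {
  stopifnot_scalar_number(epoch_rms, "epoch_rms")
  stopifnot_scalar_number(reference_rms, "reference_rms", positive = TRUE)
  100 * (1 - epoch_rms / reference_rms)
}

#' Welch power spectral density
#'
#' One-sided PSD estimate from Hann-windowed segments with 50% overlap;
#' the per-segment mean is removed. With the default 4-s segments the
#' frequency resolution is 0.25 Hz, fine enough to resolve the 0-4 Hz delta
#' band. The integral of the PSD over frequency approximates the signal
#' variance.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length (s), default 4.
#' @param overlap fractional overlap between segments, default 0.5.
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = 4, overlap = 0.5) {
  nseg <- round(seg_len * fs)
  if (length(x) < nseg)
    abort_validation(sprintf("signal shorter than one %g-s Welch segment", seg_len))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  u <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2
    acc <- acc + P[seq_len(nfreq)]
  }
  psd <- acc / (length(starts) * fs * u)
  psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]  # one-sided (not DC/Nyquist)
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd)
}

# canonical EEG analysis bands, half-open [lo, hi)
eeg_bands <- list(delta = c(0, 4), theta = c(4, 8),
                  alpha = c(8, 12), beta = c(12, 30))

#' Band-limited power
#'
#' Integrates the Welch PSD over each half-open band `[lo, hi)`. With the
#' default bands (delta 0-4, theta 4-8, alpha 8-12, beta 12-30 Hz) the four
#' powers are additive: their sum equals the integral over 0-30 Hz.
#'
#' @param x numeric signal at the analysis rate.
#' @param fs sampling rate (Hz).
#' @param bands named list of `c(lo, hi)` band edges (Hz).
#' @param seg_len Welch segment length (s).
#' @return named numeric vector of band powers (uV^2).
#' @export
band_power <- function(x, fs, bands = eeg_bands, seg_len = 4) {
  if (length(x) < 2 * seg_len * fs)
    abort_validation("window too short for band-power estimation (need >= 2 Welch segments)")
  p <- welch_psd(x, fs, seg_len)
  df <- p$freq[2L] - p$freq[1L]
  vapply(bands, function(b) sum(p$psd[p$freq >= b[1] & p$freq < b[2]]) * df,
         numeric(1))
}

#' Band power per analysis phase
#'
#' Computes [band_power()] on each one-hour phase window of the recording
#' (see [phase_windows()]). Partially covered windows are flagged; windows
#' with no recorded data are reported missing rather than fabricated.
#'
#' @param rec an [recording()] at the analysis rate.
#' @param bands named list of band edges (Hz).
#' @return data.frame with one row per phase: subject, condition, phase,
#'   partial/missing flags and one column per band (uV^2, `NA` if missing).
#' @export
phase_band_power <- function(rec, bands = eeg_bands) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  win <- phase_windows(rec)
  rows <- lapply(names(win), function(ph) {
    w <- win[[ph]]
    row <- data.frame(subject_id = rec$subject_id, condition = rec$condition,
                      phase = ph, partial = w$partial, missing = w$missing)
    if (w$missing) {
      for (b in names(bands)) row[[b]] <- NA_real_
    } else {
      bp <- band_power(rec_slice(rec, w$from, w$to), rec$fs, bands)
      for (b in names(bands)) row[[b]] <- bp[[b]]
    }
    row
  })
  do.call(rbind, rows)
}
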