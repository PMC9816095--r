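#' Single-channel ECoG recording
#'
#' Container for a uniformly sampled single-channel voltage trace together
#' with the experimental metadata every analysis stage needs: subject id,
#' condition (magnet or sham replica), sampling rate, recording start on the
#' experiment clock, and the injection [timeline()].
#'
#' @param samples numeric vector of voltages (uV); all values must be finite.
#' @param fs sampling rate (Hz, > 0).
#' @param subject_id character scalar.
#' @param condition `"sham"` or `"magnet"`.
#' @param t0 recording start time (s, experiment clock; t = 0 is the
#'   scopolamine injection, so baseline recordings have negative `t0`).
#' @param tl an [timeline()] object.
#' @return an object of class `ecosyn_recording`.
#' @export
recording <- function(samples, fs, subject_id = "s1",
                      condition = c("sham", "magnet"), t0 = 0,
                      tl = timeline()) {
  condition <- match.arg(condition)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(t0, "t0")
  if (!is.numeric(samples) || length(samples) < 1L)
    abort_validation("`samples` must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    abort_validation("`samples` must be finite")
  stopifnot(inherits(tl, "ecosyn_timeline"))
  structure(list(subject_id = as.character(subject_id), condition = condition,
                 samples = as.numeric(samples), fs = fs, t0 = t0,
                 timeline = tl),
            class = "ecosyn_recording")
}

#' @export
print.ecosyn_recording <- function(x, ...) {
  cat(sprintf("<ecosyn_recording> %s (%s): %d samples @ %g Hz, t = [%g, %g] s\n",
              x$subject_id, x$condition, length(x$samples), x$fs,
              x$t0, x$t0 + rec_duration(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `ecosyn_recording`.
#' @return duration (s).
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$fs

# time axis on the experiment clock
rec_times <- function(rec) rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs

# extract samples for the experiment-clock interval [from, to)
rec_slice <- function(rec, from, to) {
  i0 <- max(1L, floor((from - rec$t0) * rec$fs) + 1L)
  i1 <- min(length(rec$samples), ceiling((to - rec$t0) * rec$fs))
  if (i1 < i0) return(numeric(0))
  rec$samples[i0:i1]
}
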