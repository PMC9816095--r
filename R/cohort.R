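# Cohort-level quantification: per-subject phase metrics (spike rate, RMS,
# RMS percent reduction, band powers, ripple rate and frequency), the
# epoch-by-epoch time course, and the CONDITION x TIME inferential report.

#' Quantify one recording over its analysis phases
#'
#' Runs the full single-subject chain: downsample to the analysis rate,
#' estimate the baseline amplitude from a baseline epoch, detect spikes in
#' each one-hour phase window, detect ripples over the whole recording, and
#' compute RMS, RMS percent reduction (relative to the baseline window) and
#' band powers per phase.
#'
#' @param rec an [recording()].
#' @param target_fs analysis rate (Hz), default 1000.
#' @param epoch_len baseline-epoch length (s) used for the amplitude
#'   reference, default 60.
#' @param spike_args,ripple_args named lists of detector settings passed to
#'   [detect_spikes()] / [detect_ripples()].
#' @return list with `phase` (data.frame, one row per phase), `spikes` and
#'   `ripples` (detected [events_table()]s with a subject column).
#' @export
subject_metrics <- function(rec, target_fs = 1000, epoch_len = 60,
                            spike_args = list(), ripple_args = list()) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  rec <- downsample(rec, target_fs)
  win <- phase_windows(rec)
  if (win$baseline$missing)
    abort_validation(sprintf("subject %s has no baseline data", rec$subject_id))
  bl_from <- win$baseline$from
  bl_epoch <- new_epoch(rec, bl_from, min(epoch_len, win$baseline$to - bl_from))
  base <- estimate_baseline(bl_epoch)
  rms_ref <- rms(rec_slice(rec, win$baseline$from, win$baseline$to))

  all_spikes <- NULL; all_ripples <- NULL
  rows <- lapply(names(win), function(ph) {
    w <- win[[ph]]
    row <- data.frame(subject = rec$subject_id, condition = rec$condition,
                      phase = ph, window_s = max(0, w$to - w$from),
                      partial = w$partial, missing = w$missing)
    if (w$missing) {
      row[c("spike_rate", "rms", "rms_reduction", "ripple_rate",
            "ripple_mean_freq", names(eeg_bands))] <- NA_real_
      return(row)
    }
    ep <- new_epoch(rec, w$from, w$to - w$from)
    sp <- do.call(detect_spikes, c(list(ep, base), spike_args))
    if (nrow(sp) > 0) {
      sp$subject <- rec$subject_id
      all_spikes <<- rbind(all_spikes, sp)
    }
    wrel <- c(w$from, w$to) - rec$t0
    # ripple threshold statistics are computed per phase window, tracking
    # the background non-stationarity across phases
    rp <- do.call(detect_ripples, c(list(rec, window = wrel), ripple_args))
    if (nrow(rp) > 0) {
      rp$subject <- rec$subject_id
      all_ripples <<- rbind(all_ripples, rp)
    }
    row$spike_rate <- spike_rate(sp, w$to - w$from)
    row$rms <- rms(ep$samples)
    row$rms_reduction <- rms_reduction(row$rms, rms_ref)
    row$ripple_rate <- ripple_rate(rp, wrel)
    row$ripple_mean_freq <- mean_ripple_frequency(rp, wrel)
    bp <- band_power(ep$samples, rec$fs)
    for (b in names(bp)) row[[b]] <- bp[[b]]
    row
  })
  list(phase = do.call(rbind, rows), spikes = all_spikes, ripples = all_ripples)
}

#' Quantify a cohort
#'
#' Applies [subject_metrics()] to every recording and binds the results,
#' plus the epoch-by-epoch spike-rate and RMS time course from
#' [extract_epochs()].
#'
#' @param recs list of [recording()]s, or the list returned by
#'   [simulate_cohort()] (whose `recording` elements are used).
#' @param epoch_interval epoch spacing for the time course (min).
#' @inheritParams subject_metrics
#' @return list with `phase` (data.frame), `epochs` (data.frame),
#'   `spikes`, `ripples` (event tables with subject columns).
#' @export
cohort_metrics <- function(recs, target_fs = 1000, epoch_len = 60,
                           epoch_interval = 30, spike_args = list(),
                           ripple_args = list()) {
  recs <- lapply(recs, function(r) if (inherits(r, "ecosyn_recording")) r else r$recording)
  per <- lapply(recs, function(rec) {
    m <- subject_metrics(rec, target_fs, epoch_len, spike_args, ripple_args)
    rec1k <- downsample(rec, target_fs)
    eps <- extract_epochs(rec1k, epoch_len, epoch_interval)
    win <- phase_windows(rec1k)
    bl_epoch <- new_epoch(rec1k, win$baseline$from,
                          min(epoch_len, win$baseline$to - win$baseline$from))
    base <- estimate_baseline(bl_epoch)
    rms_ref <- rms(bl_epoch$samples)
    ep_rows <- lapply(eps, function(ep) {
      sp <- do.call(detect_spikes, c(list(ep, base), spike_args))
      data.frame(subject = rec$subject_id, condition = rec$condition,
                 start = ep$start, phase = ifelse(is.na(ep$phase), NA, ep$phase),
                 offset_from_diazepam = ep$offset_from_diazepam,
                 spike_rate = spike_rate(sp, ep$duration),
                 rms = rms(ep$samples),
                 rms_reduction = rms_reduction(rms(ep$samples), rms_ref))
    })
    list(phase = m$phase, spikes = m$spikes, ripples = m$ripples,
         epochs = do.call(rbind, ep_rows))
  })
  list(phase = do.call(rbind, lapply(per, `[[`, "phase")),
       epochs = do.call(rbind, lapply(per, `[[`, "epochs")),
       spikes = do.call(rbind, lapply(per, `[[`, "spikes")),
       ripples = do.call(rbind, lapply(per, `[[`, "ripples")))
}

#' CONDITION x TIME inferential report over all measures
#'
#' Builds a measure table per quantity (normalized spike rate, RMS percent
#' reduction, each band power, ripple rate), runs [mixed_rm_anova()] and
#' [tukey_posthoc()] (condition at time) on each, and marks significance at
#' alpha = 0.05 using the epsilon-selected p-value. The spike-rate analysis
#' uses rates normalized per subject by the prediazepam rate (subjects with
#' a zero reference are excluded with a warning).
#'
#' @param phase_metrics the `phase` data.frame from [cohort_metrics()].
#' @param alpha significance level.
#' @return list with `anova` (one row per measure x effect), `tukey`
#'   (condition-at-time comparisons per measure) and `fits` (the raw
#'   [mixed_rm_anova()] objects).
#' @export
synergy_analysis <- function(phase_metrics, alpha = 0.05) {
  stopifnot(is.data.frame(phase_metrics))
  measures <- c("spike_rate_norm", "rms_reduction", names(eeg_bands), "ripple_rate")

  mk_table <- function(meas) {
    if (meas == "spike_rate_norm") {
      r <- phase_metrics[, c("subject", "condition", "phase", "spike_rate")]
      names(r)[3:4] <- c("time", "value")
      r <- suppressWarnings(normalize_rates(r, reference_time = "prediazepam"))
      r$value <- r$value_norm
      r <- r[!is.na(r$value), c("subject", "condition", "time", "value")]
    } else {
      r <- phase_metrics[, c("subject", "condition", "phase", meas)]
      names(r)[3:4] <- c("time", "value")
    }
    r
  }

  fits <- list(); anova_rows <- NULL; tukey_rows <- NULL
  for (meas in measures) {
    fit <- mixed_rm_anova(mk_table(meas))
    fits[[meas]] <- fit
    a <- fit$effects
    a$measure <- meas
    a$significant <- a$p_selected < alpha
    anova_rows <- rbind(anova_rows, a)
    tk <- tukey_posthoc(fit, "condition_at_time")
    tk$measure <- meas
    tk$significant <- tk$p_adj < alpha
    tukey_rows <- rbind(tukey_rows, tk)
  }
  list(anova = anova_rows, tukey = tukey_rows, fits = fits, alpha = alpha)
}
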