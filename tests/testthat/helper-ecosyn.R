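# Shared fixtures and oracles for the test suite. Everything is generated
# in code; no data files.

# compressed injection timeline: 5-min induction steps, diazepam at 20 min
tl_short <- function() timeline(0, 300, 600, 1200)

# very short timeline for detector-fidelity runs (diazepam at 5 min)
tl_tiny <- function() timeline(0, 60, 120, 300)

# greedy interval matching of detections against ground truth; returns
# c(tp, fp, fn). A detection matches a truth event if their intervals
# (padded by `tol` seconds) intersect; each detection matches at most once.
match_events <- function(det, truth, tol = 0.25) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  if (nrow(truth) > 0) for (i in seq_len(nrow(truth))) {
    o <- truth$onset[i]; d <- truth$duration[i]
    j <- which(!used & det$onset < o + d + tol & det$onset + det$duration > o - tol)
    if (length(j) > 0) { used[j[1L]] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = nrow(det) - sum(used), fn = nrow(truth) - tp)
}

precision_of <- function(m) if (m[["tp"]] + m[["fp"]] == 0) NA_real_ else m[["tp"]] / (m[["tp"]] + m[["fp"]])
recall_of <- function(m) if (m[["tp"]] + m[["fn"]] == 0) NA_real_ else m[["tp"]] / (m[["tp"]] + m[["fn"]])

# independent brute-force mixed-ANOVA oracle built on stats::aov with an
# Error(subject) stratum; returns named list of F and SS per effect
aov_oracle <- function(d) {
  d$subject <- factor(d$subject)
  d$condition <- factor(d$condition)
  d$time <- factor(d$time, levels = levels(factor(d$time)))
  fit <- stats::aov(value ~ condition * time + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1L]]
  within <- s[["Error: Within"]][[1L]]
  list(
    F_condition = between["condition", "F value"],
    F_time = within["time", "F value"],
    F_interaction = within["condition:time", "F value"],
    ss_condition = between["condition", "Sum Sq"],
    ss_subjects = between["Residuals", "Sum Sq"],
    ss_time = within["time", "Sum Sq"],
    ss_interaction = within["condition:time", "Sum Sq"],
    ss_residual = within["Residuals", "Sum Sq"])
}

# random balanced mixed design for oracle-equivalence checks
random_design <- function(n_per_group, k = 3) {
  subj <- 0L
  rows <- list()
  for (cond in c("sham", "magnet")) for (s in seq_len(n_per_group)) {
    subj <- subj + 1L
    rows[[subj]] <- data.frame(subject = sprintf("s%02d", subj),
                               condition = cond,
                               time = paste0("t", seq_len(k)),
                               value = rnorm(k, mean = 2 * (cond == "magnet") +
                                               seq_len(k), sd = 1.5))
  }
  do.call(rbind, rows)
}

# simulation settings for detector-fidelity runs: constant event rates so
# every phase of the short recording carries events
fidelity_params <- function() {
  sim_params(fs = 1000,
             spikes = list(baseline_rate = 20, pilocarpine_rate = 20,
                           postdiazepam_rate_sham = 20,
                           postdiazepam_rate_magnet = 20,
                           magnet_prediazepam_scale = 1),
             ripples = list(baseline_rate = 240, pilocarpine_rate = 240,
                            postdiazepam_rate = 240))
}

# one short fidelity recording (11 min at 1 kHz)
fidelity_recording <- function(seed, condition = "sham") {
  simulate_recording(fidelity_params(), condition, duration = 660,
                     seed = seed, t0 = -300, tl = tl_tiny())
}
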