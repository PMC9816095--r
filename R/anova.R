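# Inferential layer: two-way mixed repeated-measures ANOVA (between-subject
# CONDITION, within-subject TIME) by the classical sums-of-squares
# decomposition with a subject-within-condition error stratum, the
# Greenhouse-Geisser sphericity correction estimated from the pooled
# within-subject covariance, and Tukey HSD multiple comparisons on the
# studentized-range distribution.

#' Validate and complete a measure table
#'
#' A measure table has one value per subject x time cell, with every subject
#' in exactly one condition. Subjects with missing or duplicated cells are
#' excluded listwise with a warning.
#'
#' @param table data.frame with columns `subject`, `condition`
#'   (sham/magnet or any two or more levels), `time`, `value`.
#' @return the completed table with factors in a canonical order.
#' @export
measure_table <- function(table) {
  need <- c("subject", "condition", "time", "value")
  if (!all(need %in% names(table)))
    abort_validation("measure table needs columns subject, condition, time, value")
  table <- table[, need]
  table$subject <- as.character(table$subject)
  table$condition <- as.character(table$condition)
  tlev <- if (all(unique(table$time) %in% phase_levels))
    intersect(phase_levels, unique(table$time)) else sort(unique(table$time))
  table$time <- factor(table$time, levels = tlev)
  k <- nlevels(table$time)
  keep <- vapply(split(table, table$subject), function(d)
    nrow(d) == k && !anyNA(d$value) && !anyDuplicated(d$time),
    logical(1))
  if (!all(keep)) {
    warning("excluding subjects with incomplete cells: ",
            paste(names(keep)[!keep], collapse = ", "), call. = FALSE)
    table <- table[table$subject %in% names(keep)[keep], ]
  }
  if (nrow(table) == 0) abort_validation("no complete subjects left")
  table[order(table$condition, table$subject, table$time), ]
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Two-way mixed ANOVA: CONDITION is between-subject (each animal received
#' either the magnet or the sham replica), TIME is within-subject (baseline,
#' prediazepam, postdiazepam). Sums of squares are decomposed into the
#' between-subject stratum (condition, tested against subjects within
#' condition) and the within-subject stratum (time and condition x time,
#' tested against the subject x time residual). The Greenhouse-Geisser
#' epsilon is estimated from the pooled within-group covariance of the
#' repeated measures and always reported; the corrected p-value `p_gg`
#' shrinks the within-effect degrees of freedom by epsilon. Following common
#' practice the `p_selected` column applies the correction when
#' epsilon < 0.75 and uses the uncorrected p otherwise.
#'
#' @param table a [measure_table()] (or raw data.frame with its columns).
#' @return object of class `ecosyn_rm_anova`: a list with `effects`
#'   (data.frame of F, dfs, epsilon and p-values per effect), `strata`
#'   (sums of squares), `epsilon`, and the design sizes.
#' @export
mixed_rm_anova <- function(table) {
  d <- measure_table(table)
  k <- nlevels(d$time)
  if (k < 2) abort_validation("need at least 2 time levels")
  subj <- unique(d$subject)
  N <- length(subj)
  cond_of <- vapply(subj, function(s) d$condition[d$subject == s][1L], character(1))
  g <- length(unique(cond_of))
  if (g < 2) abort_validation("need at least 2 conditions")
  if (any(table(cond_of) < 2))
    abort_validation("need at least 2 subjects per condition")

  grand <- mean(d$value)
  ys <- tapply(d$value, d$subject, mean)
  yc <- tapply(d$value, d$condition, mean)
  yt <- tapply(d$value, d$time, mean)
  yct <- tapply(d$value, list(d$condition, d$time), mean)
  nc <- table(cond_of)

  ss_total <- sum((d$value - grand)^2)
  ss_between_subj <- k * sum((ys - grand)^2)
  ss_cond <- k * sum(nc[names(yc)] * (yc - grand)^2)
  ss_subj <- ss_between_subj - ss_cond
  ss_time <- N * sum((yt - grand)^2)
  ss_int <- 0
  for (ci in names(yc)) for (ti in names(yt))
    ss_int <- ss_int + nc[[ci]] * (yct[ci, ti] - yc[[ci]] - yt[[ti]] + grand)^2
  ss_err_w <- ss_total - ss_between_subj - ss_time - ss_int

  df_cond <- g - 1; df_subj <- N - g
  df_time <- k - 1; df_int <- (g - 1) * (k - 1); df_err_w <- (N - g) * (k - 1)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_subj <- ms(ss_subj, df_subj); ms_err_w <- ms(ss_err_w, df_err_w)

  eps <- gg_epsilon(d, cond_of)

  eff <- data.frame(
    effect = c("condition", "time", "condition:time"),
    ss = c(ss_cond, ss_time, ss_int),
    df_num = c(df_cond, df_time, df_int),
    df_den = c(df_subj, df_err_w, df_err_w),
    ms_error = c(ms_subj, ms_err_w, ms_err_w))
  # a zero-SS effect is F = 0 by convention, even when the error MS is 0
  # (e.g. all values identical)
  eff$F <- ifelse(eff$ss == 0, 0, (eff$ss / eff$df_num) / eff$ms_error)
  eff$gg_epsilon <- c(NA, eps, eps)   # between-effect needs no sphericity
  eff$p_uncorrected <- pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$p_gg <- ifelse(is.na(eff$gg_epsilon), eff$p_uncorrected,
                     pf(eff$F, eff$df_num * eff$gg_epsilon,
                        eff$df_den * eff$gg_epsilon, lower.tail = FALSE))
  eff$p_selected <- ifelse(!is.na(eff$gg_epsilon) & eff$gg_epsilon < 0.75,
                           eff$p_gg, eff$p_uncorrected)

  structure(list(
    effects = eff,
    strata = data.frame(
      stratum = c("condition", "subjects_within_condition", "time",
                  "condition:time", "subjects:time_residual", "total"),
      ss = c(ss_cond, ss_subj, ss_time, ss_int, ss_err_w, ss_total),
      df = c(df_cond, df_subj, df_time, df_int, df_err_w, N * k - 1)),
    epsilon = eps, n_subjects = N, n_conditions = g, n_times = k,
    group_sizes = as.integer(nc), data = d),
    class = "ecosyn_rm_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k repeated measures: eps = tr(D)^2 / ((k-1) * sum(D^2)) with D the
# double-centered covariance. Bounded in [1/(k-1), 1].
gg_epsilon <- function(d, cond_of) {
  k <- nlevels(d$time)
  subj <- names(cond_of)
  M <- matrix(NA_real_, length(subj), k,
              dimnames = list(subj, levels(d$time)))
  for (i in seq_len(nrow(d)))
    M[d$subject[i], as.character(d$time[i])] <- d$value[i]
  Sp <- matrix(0, k, k)
  df <- 0
  for (ci in unique(cond_of)) {
    Mi <- M[cond_of == ci, , drop = FALSE]
    if (nrow(Mi) > 1) {
      Sp <- Sp + cov(Mi) * (nrow(Mi) - 1)
      df <- df + nrow(Mi) - 1
    }
  }
  Sp <- Sp / df
  D <- Sp - outer(rowMeans(Sp), rep(1, k)) - outer(rep(1, k), colMeans(Sp)) +
    mean(Sp)
  denom <- (k - 1) * sum(D^2)
  if (denom <= 0) return(1)           # degenerate (e.g. all values equal)
  min(1, max(1 / (k - 1), sum(diag(D))^2 / denom))
}

#' @export
print.ecosyn_rm_anova <- function(x, ...) {
  cat(sprintf("Mixed rm-ANOVA: %d subjects (%s), %d time levels; GG epsilon = %.3f\n",
              x$n_subjects, paste(x$group_sizes, collapse = "+"), x$n_times,
              x$epsilon))
  print(x$effects[, c("effect", "df_num", "df_den", "F", "gg_epsilon",
                      "p_uncorrected", "p_gg", "p_selected")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey HSD multiple comparisons for the mixed design
#'
#' Pairwise comparisons with the studentized-range distribution, using the
#' error stratum appropriate to the effect: the subject stratum for
#' condition means, the subject x time residual for time means, and for
#' condition comparisons at a fixed time (simple effects across groups,
#' e.g. magnet vs sham after diazepam) the pooled between + within stratum,
#' with the full set of condition x time cell means as the family.
#'
#' @param fit an [mixed_rm_anova()] result.
#' @param effect which family of means to compare.
#' @return data.frame of comparisons: group means, difference, standard
#'   error, q statistic and Tukey-adjusted p.
#' @export
tukey_posthoc <- function(fit, effect = c("condition", "time", "condition_at_time")) {
  stopifnot(inherits(fit, "ecosyn_rm_anova"))
  effect <- match.arg(effect)
  d <- fit$data
  k <- fit$n_times; N <- fit$n_subjects; g <- fit$n_conditions
  st <- fit$strata; ss <- st$ss; names(ss) <- st$stratum
  dfs <- st$df; names(dfs) <- st$stratum

  pairs_of <- function(means, ns, ms_err, df_err, nmeans) {
    nm <- names(means)
    cmb <- utils::combn(length(means), 2)
    out <- lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      se <- sqrt(ms_err / 2 * (1 / ns[a] + 1 / ns[b]))  # SE on the q scale
      q <- abs(means[a] - means[b]) / se
      data.frame(group1 = nm[a], group2 = nm[b],
                 mean1 = means[a], mean2 = means[b],
                 diff = means[a] - means[b],
                 se = se * sqrt(2), q = q,
                 p_adj = ptukey(q, nmeans, df_err, lower.tail = FALSE))
    })
    do.call(rbind, out)
  }

  if (effect == "time") {
    if (k < 2) abort_validation("need >= 2 time levels")
    means <- tapply(d$value, d$time, mean)
    ns <- rep(N, k)
    res <- pairs_of(means, ns, ss[["subjects:time_residual"]] /
                      dfs[["subjects:time_residual"]],
                    dfs[["subjects:time_residual"]], k)
  } else if (effect == "condition") {
    if (g < 2) abort_validation("need >= 2 conditions")
    means <- tapply(d$value, d$condition, mean)
    ns <- k * fit$group_sizes
    res <- pairs_of(means, ns, ss[["subjects_within_condition"]] /
                      dfs[["subjects_within_condition"]],
                    dfs[["subjects_within_condition"]], g)
  } else {
    # between-group simple effects at each time: pooled error stratum
    ms_pool <- (ss[["subjects_within_condition"]] + ss[["subjects:time_residual"]]) /
      (dfs[["subjects_within_condition"]] + dfs[["subjects:time_residual"]])
    df_pool <- dfs[["subjects_within_condition"]] + dfs[["subjects:time_residual"]]
    res <- NULL
    for (tl in levels(d$time)) {
      dt <- d[d$time == tl, ]
      means <- tapply(dt$value, dt$condition, mean)
      ns <- table(dt$condition)[names(means)]
      r <- pairs_of(means, as.numeric(ns), ms_pool, df_pool, g * k)
      r$time <- tl
      res <- rbind(res, r)
    }
  }
  rownames(res) <- NULL
  res
}
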