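# Mixed repeated-measures ANOVA, Greenhouse-Geisser epsilon, Tukey HSD.

test_that("a constant response gives F = 0 for every effect", {
  d <- expand.grid(subject = sprintf("s%d", 1:6),
                   time = c("baseline", "prediazepam", "postdiazepam"))
  d$condition <- ifelse(d$subject %in% c("s1", "s2", "s3"), "sham", "magnet")
  d$value <- 5
  fit <- mixed_rm_anova(d)
  expect_equal(fit$effects$F, c(0, 0, 0))
})

test_that("F and SS agree with the aov error-stratum oracle on random designs", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    k <- sample(2:4, 1)
    d <- random_design(n, k)
    fit <- mixed_rm_anova(d)
    orc <- aov_oracle(d)
    eff <- fit$effects
    expect_equal(eff$F[eff$effect == "condition"], orc$F_condition,
                 tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "time"], orc$F_time, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "condition:time"], orc$F_interaction,
                 tolerance = 1e-8)
    st <- fit$strata
    expect_equal(st$ss[st$stratum == "condition"], orc$ss_condition,
                 tolerance = 1e-8)
    expect_equal(st$ss[st$stratum == "subjects_within_condition"],
                 orc$ss_subjects, tolerance = 1e-8)
    expect_equal(st$ss[st$stratum == "subjects:time_residual"],
                 orc$ss_residual, tolerance = 1e-8)
  }
})

test_that("GG epsilon respects its bounds and is ~1 under compound symmetry", {
  set.seed(102)
  for (i in 1:20) {
    d <- random_design(sample(3:6, 1), k = 3)
    eps <- mixed_rm_anova(d)$epsilon
    expect_gte(eps, 0.5)
    expect_lte(eps, 1)
  }
  # compound symmetry: shared subject intercept + iid noise
  k <- 3
  rows <- list()
  for (cond in c("sham", "magnet")) for (s in 1:80) {
    id <- paste0(cond, s)
    rows[[id]] <- data.frame(subject = id, condition = cond,
                             time = paste0("t", 1:k),
                             value = rnorm(1, sd = 2) + rnorm(k))
  }
  eps_cs <- mixed_rm_anova(do.call(rbind, rows))$epsilon
  expect_gt(eps_cs, 0.9)
})

test_that("incomplete subjects are excluded listwise, degenerate designs error", {
  d <- random_design(3, 3)
  d <- d[!(d$subject == "s01" & d$time == "t2"), ]
  expect_warning(fit <- mixed_rm_anova(d), "s01")
  expect_identical(fit$n_subjects, 5L)

  one <- random_design(1, 3)
  expect_error(mixed_rm_anova(one), "2 subjects per condition")
  expect_error(measure_table(data.frame(subject = 1, value = 2)), "columns")
})

test_that("Tukey HSD behaves at the boundary cases", {
  set.seed(103)
  # identical condition groups (magnet values copied from sham):
  # difference 0, adjusted p ~1
  d2 <- random_design(6, 3)
  sham <- d2[d2$condition == "sham", ]
  mag <- d2[d2$condition == "magnet", ]
  mag$value <- sham$value
  fit <- mixed_rm_anova(rbind(sham, mag))
  tk <- tukey_posthoc(fit, "condition")
  expect_equal(tk$diff, 0)
  expect_gt(tk$p_adj, 0.999)

  # two groups separated by ~10 pooled SD: decisive rejection
  d3 <- random_design(6, 3)
  d3$value <- rnorm(nrow(d3), sd = 1) + 10 * (d3$condition == "magnet")
  fit3 <- mixed_rm_anova(d3)
  tk3 <- tukey_posthoc(fit3, "condition")
  expect_lt(tk3$p_adj, 1e-3)

  # three time levels -> 3 pairwise rows
  tk_t <- tukey_posthoc(fit3, "time")
  expect_identical(nrow(tk_t), 3L)

  # condition-at-time: one row per time level for 2 conditions
  tk_ct <- tukey_posthoc(fit3, "condition_at_time")
  expect_identical(nrow(tk_ct), 3L)
  expect_true(all(tk_ct$p_adj >= 0 & tk_ct$p_adj <= 1))
})

test_that("Tukey-adjusted p is never smaller than the unadjusted pairwise p", {
  set.seed(104)
  for (i in 1:10) {
    d <- random_design(5, 4)
    fit <- mixed_rm_anova(d)
    tk <- tukey_posthoc(fit, "time")
    p_unadj <- 2 * stats::pt(tk$q / sqrt(2),
                             df = fit$strata$df[fit$strata$stratum == "subjects:time_residual"],
                             lower.tail = FALSE)
    expect_true(all(tk$p_adj >= p_unadj - 1e-12))
  }
})
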