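balanced_profile <- function(effect = 0, noise = 0, reps = 3,
                             zts = c(1, 7, 13, 19), seed = 1) {
  set.seed(seed)
  df <- expand.grid(replicate = seq_len(reps), zt = zts,
                    condition = c("control", "TSR"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- 10 + effect * (df$condition == "TSR") +
    rnorm(nrow(df), sd = noise)
  df
}

test_that("two-way ANOVA handles degenerate and additive designs", {
  const <- balanced_profile(effect = 0, noise = 0)
  av <- two_way_anova(const)
  expect_equal(av$effects$F_stat, rep(0, 3))
  expect_equal(av$effects$p_value, rep(1, 3))

  shift <- balanced_profile(effect = 2, noise = 0)
  av2 <- two_way_anova(shift)
  eff <- setNames(av2$effects$p_value, av2$effects$effect)
  expect_equal(unname(eff["condition"]), 0)
  expect_equal(av2$effects$F_stat[av2$effects$effect == "interaction"], 0)
})

test_that("balanced ANOVA agrees with the sums-of-squares oracle", {
  prof <- balanced_profile(effect = 1, noise = 0.7, reps = 2,
                           zts = c(1, 13), seed = 12)
  av <- two_way_anova(prof)
  o <- anova_ss_oracle(prof)
  got <- setNames(av$effects$sum_sq, av$effects$effect)
  expect_equal(unname(got["condition"]), o$condition, tolerance = 1e-10)
  expect_equal(unname(got["time"]), o$time, tolerance = 1e-10)
  expect_equal(unname(got["interaction"]), o$interaction, tolerance = 1e-10)
  # total decomposition (balanced): SSA + SSB + SSint + SSres = SStot
  expect_equal(sum(got) + o$residual, o$total, tolerance = 1e-9)

  # larger balanced case
  prof2 <- balanced_profile(effect = 0.5, noise = 1, reps = 4, seed = 3)
  av2 <- two_way_anova(prof2)
  o2 <- anova_ss_oracle(prof2)
  expect_equal(sum(av2$effects$sum_sq) + o2$residual, o2$total,
               tolerance = 1e-9 * o2$total)
})

test_that("Bonferroni post-hoc contrasts are adjusted and bounded", {
  prof <- balanced_profile(effect = 1.5, noise = 0.5, seed = 8)
  av <- two_way_anova(prof)
  expect_equal(nrow(av$posthoc), 4)
  expect_true(all(av$posthoc$p_adj >= av$posthoc$p_value - 1e-15))
  expect_true(all(av$posthoc$p_adj <= 1))
  expect_equal(av$posthoc$p_adj,
               pmin(1, av$posthoc$p_value * 4), tolerance = 1e-12)

  bad <- prof[!(prof$condition == "TSR" & prof$zt == 13), ]
  expect_error(two_way_anova(bad), "empty design cell.*13")
})

test_that("profile peak phase recovers cosinor acrophases", {
  zts <- seq(0, 21, by = 3)
  prof <- data.frame(condition = "c", zt = rep(zts, each = 2),
                     value = rep(50 + 20 * cos(2 * pi * (zts - 12) / 24), each = 2))
  expect_equal(profile_peak_phase(prof, "c"), 12, tolerance = 1e-9)
  # invariant to adding a constant
  prof2 <- prof; prof2$value <- prof2$value + 100
  expect_equal(profile_peak_phase(prof2, "c"),
               profile_peak_phase(prof, "c"), tolerance = 1e-9)
  expect_error(profile_peak_phase(prof[prof$zt < 9, ], "c"), ">= 4 distinct")
  expect_error(profile_peak_phase(prof, "missing"), "not present")
})

test_that("AUC is trapezoidal, additive over partitions and linear", {
  rect <- tolerance_auc(c(0, 120), c(100, 100))
  expect_equal(rect$total_auc, 12000)
  expect_equal(rect$baseline_corrected_auc, 0)

  tri <- tolerance_auc(c(0, 60, 120), c(0, 100, 0))
  expect_equal(tri$total_auc, 6000)

  # splitting the interval anywhere leaves the total unchanged
  t_full <- c(0, 30, 60, 90, 120)
  set.seed(6)
  v <- 70 + runif(5, 0, 50)
  full <- tolerance_auc(t_full, v)$total_auc
  left <- tolerance_auc(t_full[1:3], v[1:3])$total_auc
  right <- sum(diff(t_full[3:5]) * (v[3:4] + v[4:5]) / 2)
  expect_equal(left + right, full, tolerance = 1e-12)

  # linearity in the measurements
  v2 <- 70 + runif(5, 0, 50)
  expect_equal(tolerance_auc(t_full, v + 2 * v2)$total_auc,
               tolerance_auc(t_full, v)$total_auc +
                 2 * tolerance_auc(t_full, v2)$total_auc,
               tolerance = 1e-10)

  expect_error(tolerance_auc(c(10, 20), c(1, 2)), "start at 0")
  expect_error(tolerance_auc(c(0, 20, 15), c(1, 2, 3)), "strictly increasing")
})

test_that("delta-delta-Ct quantitation follows the formulas", {
  ct <- data.frame(
    sample = rep(c("s1", "cal"), each = 2),
    gene = rep(c("target", "ref"), 2),
    ct = c(20, 15, 22, 15))
  res <- ddct_fold_change(ct, "ref", "cal")
  s1 <- res[res$sample == "s1", ]
  expect_equal(s1$delta_delta_ct, -2)
  expect_equal(s1$fold_change, 4)
  expect_equal(res$fold_change[res$sample == "cal"], 1)

  # reciprocity: calibrating on a then b multiplies to 1
  fa <- ddct_fold_change(ct, "ref", "s1")
  f_ab <- res$fold_change[res$sample == "s1"]
  f_ba <- fa$fold_change[fa$sample == "cal"]
  expect_equal(f_ab * f_ba, 1, tolerance = 1e-12)

  # replicate reference wells averaged on the Ct scale
  ct2 <- rbind(ct, data.frame(sample = "s1", gene = "ref", ct = 16))
  res2 <- ddct_fold_change(ct2, "ref", "cal")
  expect_equal(res2$delta_ct[res2$sample == "s1"], 20 - 15.5)

  expect_error(ddct_fold_change(ct[-2, ], "ref", "cal"), "missing Ct.*s1")
  expect_error(ddct_fold_change(ct, "ref", "nope"), "calibrator")
})
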