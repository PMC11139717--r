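# Reconstructions of the emulated study's reading sessions from its printed
# 2x2 counts: 16 positive / 48 negative cases; reader operating points are
# realized as nested prediction sets so the discordant counts are minimal.
study_truth <- c(rep(1L, 16), rep(0L, 48))

# reader predictions with the first `tp` positives called and the first
# `fp` negatives miscalled
mk_pred <- function(tp, fp) {
  c(rep(1L, tp), rep(0L, 16 - tp), rep(1L, fp), rep(0L, 48 - fp))
}

test_that("confusion metrics reproduce the printed first-session values", {
  r1 <- confusion_metrics(mk_pred(16, 29), study_truth)  # sens 1, spec 19/48
  expect_equal(unname(r1$percent["accuracy"]), 54.7)
  expect_equal(unname(r1$percent["npv"]), 100)
  expect_equal(unname(r1$percent["ppv"]), 35.6)
  expect_equal(r1$specificity, 19 / 48)
  # identity: accuracy * N = sens * N+ + spec * N-
  expect_equal(r1$accuracy * 64, r1$sensitivity * 16 + r1$specificity * 48)
  perfect <- confusion_metrics(study_truth, study_truth)
  expect_true(all(perfect$percent == 100))
  inverted <- confusion_metrics(1L - study_truth, study_truth)
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)
  none <- confusion_metrics(rep(0L, 64), study_truth)
  expect_true(is.na(none$ppv))
})

test_that("metric identity holds on random tables", {
  set.seed(14)
  for (i in 1:20) {
    truth <- c(rep(1L, sample(1:10, 1)), rep(0L, sample(1:10, 1)))
    pred <- rbinom(length(truth), 1, 0.5)
    m <- confusion_metrics(pred, truth)
    expect_equal(m$accuracy * length(truth),
                 m$sensitivity * sum(truth) + m$specificity * sum(1 - truth))
  }
})

test_that("McNemar handles no-discordance and the worked exact example", {
  pred <- mk_pred(16, 29)
  m0 <- mcnemar(pred, pred, study_truth)
  expect_equal(m0$p_value, 1)
  expect_true(m0$no_discordance)
  # b = 10, c = 2 -> exact two-sided p = 2 * P(X <= 2 | n = 12) = 158/4096
  truth <- rep(1L, 20)
  a <- c(rep(1L, 10), rep(0L, 2), rep(1L, 8))
  b <- c(rep(0L, 10), rep(1L, 2), rep(1L, 8))
  m <- mcnemar(a, b, truth, restrict = "positives")
  expect_equal(m$b, 10L)
  expect_equal(m$c, 2L)
  expect_equal(m$p_value, 158 / 4096)
  expect_identical(m$method, "exact")
  # symmetry in the two prediction sets
  m_swap <- mcnemar(b, a, truth, restrict = "positives")
  expect_equal(m_swap$p_value, m$p_value)
  # large discordance switches to continuity-corrected chi-square
  truth2 <- rep(1L, 40)
  a2 <- c(rep(1L, 20), rep(0L, 10), rep(1L, 10))
  b2 <- c(rep(0L, 20), rep(1L, 10), rep(1L, 10))
  m2 <- mcnemar(a2, b2, truth2, restrict = "positives")
  expect_identical(m2$method, "chi-square")
  expect_equal(m2$statistic, (abs(20 - 10) - 1)^2 / 30)
})

test_that("paired differences reproduce the printed specificity gain", {
  # R1 specificity 19/48 -> 29/48 between sessions: +20.8 points
  s1 <- mk_pred(16, 29)
  s2 <- mk_pred(16, 19)
  d <- paired_diff_ci(s1, s2, study_truth, "specificity")
  expect_equal(round(d$difference, 1), 20.8)
  expect_equal(round(d$value_a, 1), 39.6)
  expect_equal(round(d$value_b, 1), 60.4)
  expect_true(d$ci[1] < d$difference && d$difference < d$ci[2])
  dd <- paired_diff_ci(s1, s1, study_truth, "accuracy")
  expect_equal(dd$difference, 0)
  expect_true(dd$ci[1] <= 0 && dd$ci[2] >= 0)
})

test_that("paired AUC comparison matches the printed session AUCs", {
  # R2: session 1 (sens 15/16, spec 20/48), session 2 (sens 12/16, 43/48)
  s1 <- mk_pred(15, 28)
  s2 <- mk_pred(12, 5)
  cmp <- compare_auc_paired(s1, s2, study_truth)
  expect_equal(round(cmp$auc_a, 3), 0.677)
  expect_equal(round(cmp$auc_b, 3), 0.823)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
  same <- compare_auc_paired(s1, s1, study_truth)
  expect_equal(same$p_value, 1)
  # perfect vs random scores, n = 64 -> clearly different
  set.seed(3)
  perfect <- study_truth + 0
  random <- rnorm(64)
  cmp2 <- compare_auc_paired(perfect, random, study_truth)
  expect_lt(cmp2$p_value, 0.01)
})

test_that("evaluate_readers assembles the per-reader session summary", {
  tab <- reader_study_table(
    case_id = sprintf("c%02d", 1:64), truth = study_truth,
    r1_s1 = mk_pred(16, 29), r1_s2 = mk_pred(16, 19),
    r2_s1 = mk_pred(15, 28), r2_s2 = mk_pred(12, 5))
  ev <- evaluate_readers(tab)
  expect_equal(nrow(ev$metrics), 6L)
  expect_equal(nrow(ev$auc), 2L)
  r1_sens <- ev$metrics[ev$metrics$reader == "r1" &
                          ev$metrics$metric == "sensitivity", ]
  expect_equal(r1_sens$difference, 0)
  expect_equal(r1_sens$p_value, 1)
  expect_error(reader_study_table(case_id = 1:3, truth = c(1, 0, 1),
                                  r1_s1 = c(1, NA, 0)), "complete binary")
  expect_error(reader_study_table(case_id = 1:3, truth = c(1, 1, 1),
                                  r1_s1 = c(1, 0, 1)), "both classes")
})
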