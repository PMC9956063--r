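test_that("c-statistic matches closed forms on canonical inputs", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  # brute-force pair counting over all 6 case-control pairs gives 11/12
  expect_equal(roc_auc(c(0, 1, 1, 2, 3), c(0, 0, 1, 1, 1))$auc, 11 / 12)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "single class")
  expect_error(roc_auc(1:3, c(0, 1)), "length")
})

test_that("c-statistic equals the exhaustive pair-counting oracle", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    scores <- sample(0:6, n, replace = TRUE)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pair_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC, DeLong variance and test agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  labels <- rbinom(120, 1, 0.3)
  a <- labels + rnorm(120)
  b <- labels + rnorm(120)
  est <- roc_auc(a, labels)
  r <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  expect_equal(est$auc, as.numeric(pROC::auc(r)), tolerance = 1e-10)
  expect_equal(est$variance, as.numeric(pROC::var(r)), tolerance = 1e-10)
  dt <- delong_test(a, b, labels)
  pr <- pROC::roc.test(r, pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p, as.numeric(pr$p.value), tolerance = 1e-10)
})

test_that("DeLong variance tracks the jackknife on random instances", {
  set.seed(73)
  ok <- 0
  for (i in 1:20) {
    labels <- c(rep(1, 20), rep(0, 30))
    scores <- labels + rnorm(50)
    v_delong <- roc_auc(scores, labels)$variance
    v_jack <- auc_jackknife_var(scores, labels)
    if (abs(v_delong - v_jack) / v_jack < 0.10) ok <- ok + 1
  }
  expect_gte(ok, 18)  # agreement within 10% on nearly every instance
})

test_that("the paired DeLong test is antisymmetric and degenerate-safe", {
  set.seed(74)
  labels <- rbinom(60, 1, 0.4)
  a <- labels + rnorm(60)
  b <- labels + rnorm(60)
  self <- delong_test(a, a, labels)
  expect_identical(self$z, 0)
  expect_identical(self$p, 1)
  fwd <- delong_test(a, b, labels)
  rev <- delong_test(b, a, labels)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p, rev$p)
  expect_gt(fwd$p, 0)
  expect_lte(fwd$p, 1)
  expect_error(delong_test(a, b[-1], labels), "length")
})

test_that("a small-sample DeLong p agrees with a stratified bootstrap oracle", {
  # fixed printed fixture: 8 cases, 12 controls
  cases_a <- c(3, 2, 2, 3, 1, 2, 3, 2); controls_a <- c(1, 0, 2, 1, 0, 1, 2, 0, 1, 1, 0, 2)
  cases_b <- c(2, 1, 2, 2, 0, 1, 3, 1); controls_b <- c(1, 1, 2, 0, 0, 1, 2, 1, 1, 0, 0, 2)
  labels <- c(rep(1, 8), rep(0, 12))
  a <- c(cases_a, controls_a)
  b <- c(cases_b, controls_b)
  p_delong <- delong_test(a, b, labels)$p
  set.seed(75)
  diffs <- replicate(10000, {
    ic <- sample(1:8, replace = TRUE)
    in_ <- sample(9:20, replace = TRUE)
    idx <- c(ic, in_)
    auc_pair_oracle(a[idx], labels[idx]) - auc_pair_oracle(b[idx], labels[idx])
  })
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  expect_lt(abs(p_delong - min(p_boot, 1)), 0.02)
})

test_that("accuracy metrics reproduce 2x2 arithmetic and edge cases", {
  # tp 2, fn 1, fp 3, tn 4 at cutoff 1
  scores <- c(1, 1, 0, 1, 1, 1, 0, 0, 0, 0)
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  m <- accuracy_at_cutoff(scores, labels, 1)
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(2L, 3L, 1L, 4L))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 4 / 7)
  expect_equal(m$ppv, 2 / 5)
  expect_equal(m$npv, 4 / 5)
  # cutoff below the minimum score: everyone positive
  lo <- accuracy_at_cutoff(scores, labels, 0)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  expect_equal(lo$ppv, mean(labels))     # PPV -> prevalence
  expect_true(is.na(lo$npv))             # no test-negatives: NA, not 0
  hi <- accuracy_at_cutoff(scores, labels, 99)
  expect_true(is.na(hi$ppv))
})

test_that("Wilson intervals behave like proportion intervals", {
  m <- accuracy_at_cutoff(c(1, 1, 0, 0), c(1, 1, 0, 0), 1)
  expect_true(m$sensitivity_lo <= m$sensitivity &&
                m$sensitivity <= m$sensitivity_hi)
  expect_gte(m$sensitivity_lo, 0)
  expect_lte(m$sensitivity_hi, 1)
  # the exact method is available and wider than or equal to Wilson here
  ex <- accuracy_at_cutoff(c(1, 1, 0, 0), c(1, 1, 0, 0), 1,
                           ci_method = "exact")
  expect_lte(ex$sensitivity_lo, m$sensitivity_lo + 1e-9)
})

test_that("accuracy tables are monotone and satisfy the Bayes PPV identity", {
  co <- add_qsofa(complete_cohort(n = 800, seed = 76))
  lab <- label_cohort(co)$cohort
  for (sc in c("qsofa_pre", "qsofa_ed", "qsofa_combined")) {
    tab <- accuracy_table(lab, sc, "sepsis")
    m <- tab$metrics
    expect_identical(nrow(m), if (sc == "qsofa_combined") 6L else 3L)
    expect_true(all(diff(m$sensitivity) <= 1e-12))
    expect_true(all(diff(m$specificity) >= -1e-12))
    prev <- mean(lab$sepsis)
    bayes <- m$sensitivity * prev /
      (m$sensitivity * prev + (1 - m$specificity) * (1 - prev))
    expect_equal(m$ppv, bayes, tolerance = 1e-12)
    expect_true(all(m$tp + m$fp + m$fn + m$tn == nrow(lab)))
  }
  # empty cutoff list still carries the AUC
  none <- accuracy_table(lab, "qsofa_ed", "sepsis", cutoffs = integer(0))
  expect_identical(nrow(none$metrics), 0L)
  expect_true(none$auc$auc > 0 && none$auc$auc < 1)
  # the DeLong comparison column is attached against the ED reference
  cmp <- accuracy_table(lab, "qsofa_combined", "sepsis")
  expect_true(cmp$delong_p > 0 && cmp$delong_p <= 1)
  expect_true(is.na(accuracy_table(lab, "qsofa_ed", "sepsis")$delong_p))
})

test_that("transition table counts match a brute-force tally", {
  co <- add_qsofa(complete_cohort(n = 400, seed = 77))
  lab <- label_cohort(co)$cohort
  tt <- transition_table(lab, "sepsis")
  expect_identical(sum(tt$counts), 400L)
  for (p in 0:3) for (e in 0:3) for (o in c(FALSE, TRUE)) {
    brute <- sum(lab$qsofa_pre == p & lab$qsofa_ed == e & lab$sepsis == o)
    expect_identical(as.integer(tt$counts[p + 1, e + 1, o + 1]), brute)
  }
  # marginal over ED and outcome equals the prehospital distribution
  expect_identical(as.integer(apply(tt$counts, 1, sum)),
                   as.integer(table(factor(lab$qsofa_pre, levels = 0:3))))
  one <- lab[1, ]
  one$qsofa_pre <- 2L; one$qsofa_ed <- 1L; one$sepsis <- TRUE
  t1 <- transition_table(one, "sepsis")
  expect_identical(sum(t1$counts), 1L)
  expect_identical(as.integer(t1$counts[3, 2, 2]), 1L)
})

test_that("added capture counts combined-positive, ED-negative cases", {
  df <- data.frame(qsofa_pre = c(2, 0, 1), qsofa_ed = c(1, 2, 0),
                   qsofa_combined = c(3, 2, 1),
                   sepsis = c(TRUE, TRUE, TRUE))
  res <- added_capture(df, "sepsis", ed_cutoff = 2, combined_cutoff = 3)
  expect_identical(res$count, 1L)      # only the (pre 2, ED 1) patient
  expect_equal(res$fraction, 1 / 3)
  df$qsofa_combined <- c(2, 2, 1)      # nobody reaches combined >= 3
  expect_identical(added_capture(df, "sepsis")$count, 0L)
  df$sepsis <- FALSE
  expect_warning(res0 <- added_capture(df, "sepsis"), "undefined")
  expect_true(is.na(res0$fraction))
})
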