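test_that("confusion counts tally calls by true status", {
  truth <- rep(c(1, 0), each = 10)
  perfect <- ifelse(truth == 1, "high", "low")
  conf <- confusion_summary(perfect, truth)
  expect_identical(c(conf$tp, conf$tn, conf$fp, conf$fn), c(10L, 10L, 0L, 0L))

  all_cnc <- confusion_summary(rep("cnc", 20), truth)
  expect_identical(c(all_cnc$tp, all_cnc$tn, all_cnc$fp, all_cnc$fn),
                   rep(0L, 4))
  expect_identical(c(all_cnc$n_cnc_case, all_cnc$n_cnc_control), c(10L, 10L))

  expect_error(confusion_summary(c("high", "low"), c(1, 0, 1)), "same length")

  set.seed(40)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    calls <- sample(c("high", "low", "cnc"), n, replace = TRUE)
    truth <- rbinom(n, 1, 0.5)
    conf <- confusion_summary(calls, truth)
    # brute-force tally
    expect_identical(conf$tp, sum(calls == "high" & truth == 1))
    expect_identical(conf$fp, sum(calls == "high" & truth == 0))
    expect_identical(conf$tn, sum(calls == "low" & truth == 0))
    expect_identical(conf$fn, sum(calls == "low" & truth == 1))
    expect_identical(conf$n_cnc_case + conf$n_cnc_control, sum(calls == "cnc"))
    # class totals decompose exactly
    expect_identical(conf$tp + conf$fn + conf$n_cnc_case, sum(truth == 1))
    expect_identical(conf$tn + conf$fp + conf$n_cnc_control, sum(truth == 0))
  }
})

test_that("metrics use dual denominators when individuals are unclassifiable", {
  conf <- structure(list(tp = 51L, fp = 8L, tn = 33L, fn = 20L,
                         n_cnc_case = 16L, n_cnc_control = 13L),
                    class = "confusion_summary")
  m <- classification_metrics(conf)
  expect_equal(round(100 * m$classified$sensitivity, 1), 71.8)  # 51/71
  expect_equal(round(100 * m$all_tested$sensitivity, 1), 58.6)  # 51/87
  expect_equal(round(100 * m$classified$specificity, 1), 80.5)  # 33/41
  expect_equal(round(100 * m$all_tested$specificity, 1), 61.1)  # 33/54
  expect_equal(round(100 * m$classified$overall_correct, 1), 75.0)
  expect_equal(round(100 * m$all_tested$overall_correct, 1), 59.6)
  expect_equal(round(100 * m$cnc_rate, 1), 20.6)

  # consistency identity: overall correct decomposes over the two classes
  with(m$classified, expect_equal(
    overall_correct,
    (sensitivity * 71 + specificity * 41) / 112
  ))

  # equal true/false positives pin PPV at one half
  half <- confusion_summary(rep("high", 4), c(1, 1, 0, 0))
  expect_equal(classification_metrics(half)$classified$ppv, 0.5)

  # zero denominators surface as undefined, never as zero
  none_high <- classification_metrics(confusion_summary(rep("low", 4),
                                                        c(1, 1, 0, 0)))
  expect_true(is.na(none_high$classified$ppv))
  expect_identical(none_high$classified$specificity, 1)
})

test_that("prevalence adjustment follows Bayes' rule and its identities", {
  a <- adjust_predictive_values(0.851, 0.648, 0.055)
  expect_equal(round(100 * a$adjusted_ppv, 1), 12.3)
  expect_equal(round(100 * a$adjusted_npv, 1), 98.7)
  expect_equal(round(100 * adjust_predictive_values(0.839, 0.741, 0.15)$adjusted_ppv, 1),
               36.4)

  expect_error(adjust_predictive_values(0.8, 0.7, 0), "prevalence")
  expect_error(adjust_predictive_values(0.8, 0.7, 1), "prevalence")

  # at the sample case fraction, adjusted equals unadjusted (numerically)
  set.seed(41)
  for (i in 1:10) {
    truth <- c(0, 1, rbinom(48, 1, 0.4))
    p_call <- runif(50)
    calls <- ifelse(p_call > 0.5, "high", "low")
    conf <- confusion_summary(calls, truth)
    m <- classification_metrics(conf)$classified
    ok <- !anyNA(unlist(m)) &&
      m$sensitivity > 0 && m$sensitivity < 1 &&
      m$specificity > 0 && m$specificity < 1
    if (!ok) next
    a <- adjust_predictive_values(m$sensitivity, m$specificity, mean(truth))
    expect_equal(a$adjusted_ppv, m$ppv, tolerance = 1e-12)
    expect_equal(a$adjusted_npv, m$npv, tolerance = 1e-12)
  }

  # monotone in prevalence: PPV strictly increasing, NPV strictly decreasing
  grid <- seq(0.01, 0.99, by = 0.01)
  vals <- vapply(grid, function(pi) {
    unlist(adjust_predictive_values(0.8, 0.7, pi)[c("adjusted_ppv", "adjusted_npv")])
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("the Hardy-Weinberg chi-square test behaves at its landmarks", {
  exact <- hwe_test(c(25, 50, 25))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)

  # maximal disequilibrium at q = 0.5: statistic equals the sample size
  extreme <- hwe_test(c(50, 0, 50))
  expect_equal(extreme$statistic, 100)

  mono <- hwe_test(c(40, 0, 0))
  expect_true(is.na(mono$statistic) && is.na(mono$p_value))

  # type-I error near nominal for HWE genotypes
  set.seed(42)
  n <- 1000
  reps <- 1000
  rejections <- vapply(seq_len(reps), function(i) {
    g <- rbinom(n, 2, 0.3)
    hwe_test(tabulate(g + 1L, nbins = 3L))$p_value < 0.05
  }, logical(1))
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rejections) - 0.05), band)
})

test_that("metrics tables print percentages in the published layout", {
  conf_cnc <- structure(list(tp = 51L, fp = 8L, tn = 33L, fn = 20L,
                             n_cnc_case = 16L, n_cnc_control = 13L),
                        class = "confusion_summary")
  conf_plain <- confusion_summary(rep(c("high", "low"), c(6, 4)),
                                  c(rep(1, 5), 0, rep(0, 4)))
  tab <- metrics_table(list(mdr = classification_metrics(conf_cnc),
                            lr = classification_metrics(conf_plain)))
  expect_identical(tab["mdr", "Sensitivity"], "71.8 (58.6)")
  expect_identical(tab["mdr", "PPV"], "86.4")
  expect_false(grepl("\\(", tab["lr", "Sensitivity"]))
})
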