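test_that("confusion counts are exact", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)
  allpos <- confusion_counts(c(1, 0), c(1, 1))
  expect_equal(unclass(allpos)[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 1L, TN = 0L, FN = 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("metric suite reproduces external-benchmark confusion matrices", {
  # positively imbalanced external set: 30 blockers / 14 non-blockers
  m1 <- compute_classification_metrics(
    list(TP = 25, FN = 5, TN = 11, FP = 3))
  expect_equal(m1[["MCC"]], 0.599, tolerance = 1e-3)
  expect_equal(m1[["PPV"]], 0.893, tolerance = 1e-3)
  expect_equal(m1[["NPV"]], 0.688, tolerance = 1e-3)
  expect_equal(m1[["SEN"]], 0.833, tolerance = 1e-3)
  expect_equal(m1[["SPE"]], 0.786, tolerance = 1e-3)
  expect_equal(m1[["BACC"]], 0.810, tolerance = 1e-3)
  expect_equal(m1[["ACC"]], 36 / 44, tolerance = 1e-9)
  # negatively imbalanced external set: 11 blockers / 30 non-blockers
  m2 <- compute_classification_metrics(
    list(TP = 10, FN = 1, TN = 18, FP = 12))
  expect_equal(m2[["MCC"]], 0.452, tolerance = 1e-3)
  expect_equal(m2[["PPV"]], 0.455, tolerance = 1e-3)
  expect_equal(m2[["NPV"]], 0.947, tolerance = 1e-3)
})

test_that("zero denominators yield NA, never errors", {
  m <- compute_classification_metrics(list(TP = 0, FN = 1, TN = 1, FP = 0))
  expect_true(is.na(m[["PPV"]]))                    # nothing predicted positive
  expect_true(is.na(m[["MCC"]]))
  expect_false(is.na(m[["SEN"]]))
  m2 <- compute_classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(m2[["SEN"]]))
  expect_true(is.na(m2[["BACC"]]))
})

test_that("accuracy decomposes as prevalence-weighted SEN/SPE", {
  set.seed(9)
  for (i in 1:50) {
    cc <- list(TP = rpois(1, 8), FN = rpois(1, 5), TN = rpois(1, 9),
               FP = rpois(1, 4))
    m <- compute_classification_metrics(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    if (P > 0 && N > 0) {
      expect_equal(m[["ACC"]], (m[["SEN"]] * P + m[["SPE"]] * N) / (P + N),
                   tolerance = 1e-12)
    }
    if (!is.na(m[["MCC"]])) expect_true(abs(m[["MCC"]]) <= 1 + 1e-12)
  }
  expect_equal(compute_classification_metrics(
    list(TP = 5, FN = 0, TN = 7, FP = 0))[["MCC"]], 1)
  expect_equal(compute_classification_metrics(
    list(TP = 0, FN = 5, TN = 0, FP = 7))[["MCC"]], -1)
})

test_that("label swap maps SEN<->SPE, PPV<->NPV and fixes ACC, |MCC|", {
  set.seed(21)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    m <- compute_classification_metrics(confusion_counts(y, p))
    ms <- compute_classification_metrics(confusion_counts(1 - y, 1 - p))
    expect_equal(m[["SEN"]], ms[["SPE"]])
    expect_equal(m[["PPV"]], ms[["NPV"]])
    expect_equal(m[["ACC"]], ms[["ACC"]])
    if (!is.na(m[["MCC"]]) && !is.na(ms[["MCC"]]))
      expect_equal(abs(m[["MCC"]]), abs(ms[["MCC"]]))
  }
})

test_that("AUC equals the pair statistic on worked examples", {
  expect_equal(auc_roc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_roc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(auc_roc(c(1, 0, 1, 0), c(0.9, 0.4, 0.35, 0.8)), 0.5)
  expect_warning(v <- auc_roc(c(1, 1), c(0.2, 0.3)), "one class")
  expect_true(is.na(v))
  expect_error(auc_roc(c(1, 0), c(0.5)), "equal length")
})

test_that("rank-statistic AUC matches brute-force enumeration exhaustively", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    expect_equal(auc_roc(y, s), auc_bruteforce(y, s), tolerance = 1e-12)
  }
})

test_that("percent improvement matches direct arithmetic", {
  expect_equal(percent_improvement(0.7, 0.7), 0)
  expect_equal(percent_improvement(0.860, 0.840), 2.381, tolerance = 1e-3)
  expect_equal(percent_improvement(0.856, 0.868), -1.382, tolerance = 1e-3)
  expect_true(is.na(percent_improvement(0.5, 0)))
})

test_that("metric_report bundles thresholded metrics with AUC", {
  y <- c(1, 1, 0, 0, 1)
  p <- c(0.9, 0.5, 0.49, 0.1, 0.7)
  r <- metric_report(y, p)
  expect_named(r, c("SEN", "SPE", "NPV", "PPV", "ACC", "MCC", "BACC", "AUC"))
  expect_equal(r[["SEN"]], 1)          # 0.5 counts as a blocker call
  expect_equal(r[["SPE"]], 1)
  expect_equal(r[["AUC"]], 1)
})
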