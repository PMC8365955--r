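# The cross-validated meta-validation grid reported for the original
# framework: 31 combinations x 7 metrics (MCC, NPV, ACC, PPV, SPE, SEN,
# AUC), used here as a fixed input to the selection rule.
published_grid <- function() {
  txt <- "
id size members MCC NPV ACC PPV SPE SEN AUC
M1-1 1 DESC 0.676 0.829 0.838 0.862 0.868 0.819 0.909
M1-2 1 MGF 0.599 0.784 0.799 0.815 0.792 0.806 0.878
M1-3 1 MFP 0.682 0.829 0.840 0.853 0.838 0.843 0.909
M1-4 1 FPeV 0.636 0.820 0.817 0.819 0.795 0.839 0.897
M1-5 1 SeV 0.621 0.806 0.809 0.816 0.791 0.828 0.880
M2-1 2 MGF+MFP 0.691 0.826 0.846 0.864 0.850 0.842 0.919
M2-2 2 MGF+DESC 0.683 0.818 0.842 0.865 0.848 0.835 0.914
M2-3 2 MGF+SeV 0.685 0.837 0.842 0.848 0.830 0.854 0.916
M2-4 2 MGF+FPeV 0.682 0.828 0.841 0.854 0.833 0.848 0.916
M2-5 2 MFP+DESC 0.710 0.843 0.855 0.866 0.855 0.855 0.928
M2-6 2 MFP+SeV 0.698 0.838 0.849 0.861 0.844 0.853 0.921
M2-7 2 MFP+FPeV 0.690 0.831 0.845 0.859 0.840 0.850 0.920
M2-8 2 DESC+SeV 0.707 0.847 0.853 0.860 0.846 0.861 0.926
M2-9 2 DESC+FPeV 0.715 0.848 0.857 0.867 0.859 0.856 0.929
M2-10 2 SeV+FPeV 0.680 0.828 0.840 0.853 0.835 0.845 0.918
M3-1 3 MGF+MFP+DESC 0.707 0.851 0.853 0.857 0.841 0.866 0.924
M3-2 3 MGF+MFP+SeV 0.711 0.855 0.855 0.857 0.835 0.874 0.927
M3-3 3 MGF+MFP+FPeV 0.701 0.849 0.850 0.853 0.833 0.867 0.921
M3-4 3 MGF+DESC+SeV 0.710 0.847 0.855 0.864 0.849 0.861 0.926
M3-5 3 MGF+DESC+FPeV 0.706 0.853 0.852 0.855 0.831 0.874 0.928
M3-6 3 MGF+SeV+FPeV 0.697 0.844 0.849 0.854 0.838 0.859 0.925
M3-7 3 MFP+DESC+SeV 0.718 0.854 0.859 0.865 0.850 0.868 0.930
M3-8 3 MFP+DESC+FPeV 0.710 0.850 0.855 0.861 0.846 0.864 0.926
M3-9 3 MFP+SeV+FPeV 0.699 0.837 0.849 0.862 0.848 0.851 0.925
M3-10 3 DESC+SeV+FPeV 0.712 0.846 0.856 0.866 0.854 0.858 0.928
M4-1 4 MGF+MFP+DESC+SeV 0.711 0.850 0.855 0.861 0.841 0.869 0.927
M4-2 4 MGF+MFP+DESC+FPeV 0.719 0.851 0.860 0.869 0.853 0.867 0.929
M4-3 4 MGF+MFP+SeV+FPeV 0.705 0.846 0.852 0.859 0.846 0.859 0.921
M4-4 4 MGF+DESC+SeV+FPeV 0.707 0.849 0.853 0.859 0.841 0.865 0.926
M4-5 4 MFP+DESC+SeV+FPeV 0.720 0.849 0.860 0.871 0.856 0.864 0.930
M5-1 5 MGF+DESC+SeV+FPeV+MFP 0.717 0.853 0.858 0.864 0.850 0.867 0.925"
  df <- read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
  df$members <- strsplit(df$members, "+", fixed = TRUE)
  df
}

test_that("meta features concatenate in canonical column order", {
  probs <- list(DESC = runif(100), MGF = runif(100), MFP = runif(100),
                SeV = runif(100), FPeV = runif(100))
  M <- assemble_meta_features(probs, names(probs))
  expect_equal(dim(M), c(100L, 5L))
  expect_equal(colnames(M), c("DESC", "MGF", "MFP", "SeV", "FPeV"))
  M1 <- assemble_meta_features(probs, "MFP")
  expect_equal(dim(M1), c(100L, 1L))
  # order requested does not matter; canonical order wins
  M2 <- assemble_meta_features(probs, c("SeV", "DESC"))
  expect_equal(colnames(M2), c("DESC", "SeV"))
  expect_true(all(M >= 0 & M <= 1))
  probs$DESC <- runif(50)
  expect_error(assemble_meta_features(probs), "length")
  expect_error(assemble_meta_features(list(DESC = runif(5)), "XXX"), "unknown")
})

test_that("combination enumeration yields 31 unique subsets in groups", {
  combos <- enumerate_feature_combinations()
  expect_equal(nrow(combos), 31L)
  expect_equal(as.vector(table(combos$size)), c(5L, 10L, 10L, 5L, 1L))
  keys <- vapply(combos$members, function(m) paste(sort(m), collapse = "|"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(combos$id[1], "M1-1")
  expect_equal(combos$id[31], "M5-1")
})

test_that("selection maximizes improved-metric count with MCC tie-break", {
  grid <- data.frame(id = c("M1-1", "M1-2", "M2-1", "M2-2"),
                     size = c(1, 1, 2, 2),
                     MCC = c(0.60, 0.55, 0.72, 0.70),
                     NPV = c(0.80, 0.78, 0.85, 0.85),
                     ACC = c(0.82, 0.80, 0.86, 0.86),
                     PPV = c(0.84, 0.80, 0.88, 0.88),
                     SPE = c(0.86, 0.80, 0.84, 0.84),
                     SEN = c(0.80, 0.81, 0.87, 0.87),
                     AUC = c(0.90, 0.88, 0.93, 0.93))
  grid$members <- list("DESC", "MGF", c("DESC", "MGF"), c("DESC", "SeV"))
  w <- select_best_combination(grid)
  expect_equal(w$id, "M2-1")                         # tie on 6/7, higher MCC
  expect_equal(attr(w, "n_improved"), 6L)
  expect_error(select_best_combination(grid[0, ]), "empty")
})

test_that("selection on the published grid recovers the reported winner", {
  w <- select_best_combination(published_grid())
  expect_equal(w$id, "M4-5")
  expect_setequal(w$members[[1]], c("MFP", "DESC", "SeV", "FPeV"))
})

test_that("percent-improvement grid reproduces the reported arithmetic", {
  imp <- combination_improvement(published_grid())
  m45 <- imp[imp$id == "M4-5", ]
  # improvements over per-metric best single-feature rows
  expect_equal(m45$ACC_pct, 100 * (0.860 - 0.840) / 0.840, tolerance = 1e-6)
  expect_equal(m45$SPE_pct, 100 * (0.856 - 0.868) / 0.868, tolerance = 1e-6)
  expect_equal(round(m45$ACC_pct, 1), 2.4)
  expect_equal(round(m45$SPE_pct, 1), -1.4)
  expect_true(m45$MCC_pct > 5 && m45$MCC_pct < 6)
})

test_that("threshold rule declares blockers at exactly 0.5", {
  expect_equal(classify_threshold(c(0.5, 0.49, 1.0, 0)), c(1L, 0L, 1L, 0L))
  expect_error(classify_threshold(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(classify_threshold(c(-0.1)), "\\[0, 1\\]")
})

test_that("meta model learns a perfect feature and ignores pure noise", {
  set.seed(10)
  y <- rbinom(200, 1, 0.5)
  perfect <- cbind(DESC = 0.98 * y + 0.01, MGF = runif(200))
  m <- train_meta_model(perfect[1:120, ], y[1:120],
                        cfg = train_config(1e-2, epochs = 40, seed = 2))
  p <- predict_probabilities(m, perfect[121:200, ])
  expect_gt(suppressWarnings(auc_roc(y[121:200], p)), 0.99)
  noise <- cbind(DESC = runif(200), MGF = runif(200))
  m2 <- train_meta_model(noise[1:120, ], y[1:120],
                         cfg = train_config(1e-2, epochs = 40, seed = 2))
  p2 <- predict_probabilities(m2, noise[121:200, ])
  expect_equal(suppressWarnings(auc_roc(y[121:200], p2)), 0.5,
               tolerance = 0.15)
  # seeded rerun reproduces the training trajectory
  m3 <- train_meta_model(perfect[1:120, ], y[1:120],
                         cfg = train_config(1e-2, epochs = 40, seed = 2))
  expect_identical(m$history, m3$history)
})
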