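test_that("standardization canonicalizes, strips salts and is idempotent", {
  expect_equal(standardize_molecule("OCC"), standardize_molecule("CCO"))
  expect_equal(standardize_molecule("C1=CC=CC=C1"),
               standardize_molecule("c1ccccc1"))
  s <- standardize_molecule("CC(=O)[O-].[Na+]")
  expect_equal(s, standardize_molecule("CC(=O)O"))   # salt stripped, neutral
  cans <- standardize_molecule(c("CCO", "c1ccccc1O", "CC(C)CO"))
  expect_equal(standardize_molecule(cans), cans)      # idempotent
  expect_error(standardize_molecule("C1CC"), "unparseable")
})

test_that("read_dataset_csv loads, standardizes, and skips bad rows", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCO", "OCC", "c1ccccc1"),
                       label = c(1, 0, 1)), path, row.names = FALSE)
  ds <- read_dataset_csv(path)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(length(ds), 3L)
  expect_equal(attr(ds, "n_skipped"), 0L)

  write.csv(data.frame(smiles = c("CCO", "C1CC", "CCN", "CCC", "CCCC"),
                       label = c(1, 1, 0, 0, 1)), path, row.names = FALSE)
  expect_message(ds2 <- read_dataset_csv(path), "skipped 1")
  expect_equal(length(ds2), 4L)
  expect_equal(attr(ds2, "n_skipped"), 1L)

  expect_error(read_dataset_csv(path, smiles_column = "smi"), "column")
  write.csv(data.frame(smiles = character(0), label = integer(0)), path,
            row.names = FALSE)
  expect_error(read_dataset_csv(path), "empty")
  expect_error(read_dataset_csv(tempfile()), "not found")
})

test_that("reconcile_labels collapses duplicates and removes conflicts", {
  ds <- labeled_dataset(c("A", "A", "B"), c(1, 1, 0))
  r <- reconcile_labels(ds)
  expect_equal(r$records$smiles, c("A", "B"))
  expect_equal(r$records$label, c(1L, 0L))

  ds2 <- labeled_dataset(c("A", "A"), c(1, 0))
  expect_message(r2 <- reconcile_labels(ds2), "1 molecule")
  expect_equal(length(r2), 0L)
  expect_equal(attr(r2, "n_conflict"), 1L)

  expect_equal(length(reconcile_labels(labeled_dataset(character(0),
                                                       integer(0)))), 0L)
})

test_that("reconcile_labels is idempotent and order-independent", {
  set.seed(4)
  smi <- sample(sprintf("M%02d", 1:40), 120, replace = TRUE)
  lab <- rbinom(120, 1, 0.5)
  ds <- labeled_dataset(smi, lab)
  r1 <- suppressMessages(reconcile_labels(ds))
  r11 <- suppressMessages(reconcile_labels(r1))
  expect_equal(r1$records[order(r1$records$smiles), c("smiles", "label")],
               r11$records[order(r11$records$smiles), c("smiles", "label")],
               ignore_attr = TRUE)
  perm <- sample(120)
  r2 <- suppressMessages(reconcile_labels(labeled_dataset(smi[perm], lab[perm])))
  expect_equal(r1$records[order(r1$records$smiles), c("smiles", "label")],
               r2$records[order(r2$records$smiles), c("smiles", "label")],
               ignore_attr = TRUE)
})

test_that("stepwise_split cuts seeded 70/10/10/10 partitions", {
  ds <- labeled_dataset(sprintf("M%03d", 1:100), rep(c(0, 1), 50))
  sp <- stepwise_split(ds, seed = 7)
  expect_equal(vapply(sp[c("base_train", "base_valid", "meta_train",
                           "meta_valid")], length, integer(1)),
               c(base_train = 70L, base_valid = 10L, meta_train = 10L,
                 meta_valid = 10L))
  ds10 <- labeled_dataset(sprintf("M%02d", 1:10), rep(0:1, 5))
  sp10 <- stepwise_split(ds10, seed = 7)
  expect_equal(unname(vapply(sp10[1:4], length, integer(1))),
               c(7L, 1L, 1L, 1L))
  sp2 <- stepwise_split(ds, seed = 7)
  expect_identical(lapply(sp[1:4], function(d) d$records),
                   lapply(sp2[1:4], function(d) d$records))
  expect_error(stepwise_split(ds, fractions = c(0.7, 0.1, 0.1, 0.2)),
               "sum to 1")
})

test_that("split partitions are disjoint covers on random datasets", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    ds <- labeled_dataset(sprintf("M%04d", sample(1e4, n)), rbinom(n, 1, 0.4))
    sp <- stepwise_split(ds, seed = rep)
    parts <- lapply(sp[1:4], function(d) d$records$smiles)
    expect_equal(sum(lengths(parts)), n)
    expect_equal(sort(unname(unlist(parts))), sort(ds$records$smiles))
    for (a in 1:3) for (b in (a + 1):4)
      expect_length(intersect(parts[[a]], parts[[b]]), 0)
  }
})

test_that("consecutive CV folds rotate the four roles over k parts", {
  ds <- labeled_dataset(sprintf("M%03d", 1:100), rbinom(100, 1, 0.5))
  plan <- consecutive_cv_folds(ds, k = 10)
  expect_length(plan$folds, 10L)
  for (f in plan$folds) {
    expect_equal(lengths(f),
                 c(base_train = 70L, base_valid = 10L, meta_train = 10L,
                   meta_valid = 10L))
    expect_equal(sort(unname(unlist(f))), 1:100)   # union is the full dataset
  }
  # hand-enumerated rotation at k = 4, n = 8 (parts {1,2}{3,4}{5,6}{7,8}):
  # fold 1 holds parts 1/2/3 for valid/meta-train/meta-valid, part 4 trains
  ds8 <- labeled_dataset(sprintf("M%d", 1:8), rep(0:1, 4))
  p4 <- consecutive_cv_folds(ds8, k = 4)
  expect_equal(p4$folds[[1]],
               list(base_train = 7:8, base_valid = 1:2,
                    meta_train = 3:4, meta_valid = 5:6))
  expect_equal(p4$folds[[4]],
               list(base_train = 5:6, base_valid = 7:8,
                    meta_train = 1:2, meta_valid = 3:4))
  expect_error(consecutive_cv_folds(ds, k = 3), "k must be")
})

test_that("each part serves each non-training role once under rotation", {
  ds <- labeled_dataset(sprintf("M%03d", 1:50), rbinom(50, 1, 0.5))
  plan <- consecutive_cv_folds(ds, k = 5)
  for (role in c("base_valid", "meta_train", "meta_valid")) {
    served <- lapply(plan$folds, `[[`, role)
    expect_equal(sort(unname(unlist(served))), 1:50)  # every part appears once
  }
})
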