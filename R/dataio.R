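#' Labeled SMILES datasets
#'
#' A `labeled_dataset` is an ordered collection of molecule records: a
#' canonical SMILES string, a binary activity label (1 = hERG blocker,
#' 0 = non-blocker) and a free-text provenance tag.
#'
#' @param smiles Character vector of SMILES strings.
#' @param label Integer/numeric vector of 0/1 labels.
#' @param source Provenance tag(s), recycled.
#' @param name Dataset identifier.
#' @return An object of class `labeled_dataset` wrapping a data.frame with
#'   columns `smiles`, `label`, `source`.
#' @export
labeled_dataset <- function(smiles, label, source = "unknown", name = "dataset") {
  stopifnot(length(smiles) == length(label))
  label <- as.integer(label)
  if (length(label) > 0 && !all(label %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  records <- data.frame(smiles = as.character(smiles), label = label,
                        source = rep_len(as.character(source), length(smiles)),
                        stringsAsFactors = FALSE)
  structure(list(records = records, name = name), class = "labeled_dataset")
}

#' @method print labeled_dataset
#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset '", x$name, "': ", nrow(x$records), " records (",
      sum(x$records$label == 1L), " blockers / ",
      sum(x$records$label == 0L), " non-blockers)\n", sep = "")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) nrow(x$records)

#' Read a labeled SMILES dataset from CSV
#'
#' Reads a CSV with a header row, standardizes every SMILES
#' (see [standardize_molecule()]), and skips rows whose SMILES cannot be
#' parsed, reporting the skip count. Column names are configurable so the
#' deposited hERG benchmark files (columns `smiles`, `ACTIVITY`) and plain
#' `smiles,label` exports both load.
#'
#' @param path CSV file path.
#' @param smiles_column,label_column Column names (defaults `"smiles"`,
#'   `"label"`).
#' @param standardize Standardize/canonicalize SMILES on read (default TRUE).
#' @param name Dataset identifier; defaults to the file name.
#' @return A [labeled_dataset()] with attribute `n_skipped` (rows dropped for
#'   unparseable SMILES).
#' @export
read_dataset_csv <- function(path, smiles_column = "smiles",
                             label_column = "label",
                             standardize = TRUE, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path, call. = FALSE)
  for (col in c(smiles_column, label_column)) {
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  }
  smi <- as.character(df[[smiles_column]])
  lab <- as.integer(df[[label_column]])
  if (standardize) {
    can <- standardize_molecule(smi)
  } else {
    can <- smi
    can[!vapply(smi, function(s)
      !inherits(tryCatch(parse_smiles(s), error = identity), "error"),
      logical(1))] <- NA_character_
  }
  keep <- !is.na(can) & !is.na(lab)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("read_dataset_csv: skipped ", n_skipped,
            " row(s) with unparseable SMILES or missing label")
  ds <- labeled_dataset(can[keep], lab[keep], source = basename(path),
                        name = name %||% basename(path))
  attr(ds, "n_skipped") <- n_skipped
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a labeled dataset to CSV
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output CSV path.
#' @param role Optional role column value(s) (used for split manifests).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, role = NULL) {
  df <- dataset$records
  if (!is.null(role)) df$role <- rep_len(role, nrow(df))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Collapse duplicates and remove inconsistently labeled molecules
#'
#' Records sharing a canonical SMILES and label collapse to one record
#' (first occurrence kept); canonical SMILES that appear with both labels
#' are removed entirely. The number of molecules removed for label conflict
#' is reported via a message and the `n_conflict` attribute.
#'
#' @param dataset A [labeled_dataset()] whose records carry canonical SMILES.
#' @return A deduplicated, conflict-free [labeled_dataset()].
#' @export
reconcile_labels <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0L) {
    out <- dataset
    attr(out, "n_conflict") <- 0L
    return(out)
  }
  lab_per_smiles <- tapply(rec$label, rec$smiles, function(x) length(unique(x)))
  conflicted <- names(lab_per_smiles)[lab_per_smiles > 1L]
  keep <- !(rec$smiles %in% conflicted)
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[!duplicated(rec$smiles), , drop = FALSE]
  rownames(rec) <- NULL
  if (length(conflicted) > 0L)
    message("reconcile_labels: removed ", length(conflicted),
            " molecule(s) with conflicting labels")
  out <- structure(list(records = rec, name = dataset$name),
                   class = "labeled_dataset")
  attr(out, "n_conflict") <- length(conflicted)
  out
}

#' Four-way step-wise split
#'
#' Shuffles the dataset with a seeded permutation and cuts it contiguously
#' into the four step-wise-training roles: base-model training, base-model
#' validation, meta-model training and meta-model validation (default
#' fractions 0.7/0.1/0.1/0.1). No class stratification is applied.
#'
#' @param dataset A [labeled_dataset()].
#' @param fractions Numeric length-4 vector summing to 1.
#' @param seed Integer seed for the shuffle (default 42).
#' @return An object of class `stepwise_split`: list with elements
#'   `base_train`, `base_valid`, `meta_train`, `meta_valid`
#'   (each a [labeled_dataset()]) plus `seed` and `fractions`.
#' @export
stepwise_split <- function(dataset, fractions = c(0.7, 0.1, 0.1, 0.1),
                           seed = 42L) {
  stopifnot(inherits(dataset, "labeled_dataset"), length(fractions) == 4L)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  n <- nrow(dataset$records)
  if (n == 0L) stop("cannot split an empty dataset", call. = FALSE)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  cuts <- round(cumsum(fractions) * n + 1e-9)
  cuts[4] <- n
  starts <- c(0L, cuts[-4]) + 1L
  roles <- c("base_train", "base_valid", "meta_train", "meta_valid")
  parts <- lapply(seq_along(roles), function(k) {
    idx <- if (starts[k] > cuts[k]) integer(0) else ord[starts[k]:cuts[k]]
    rec <- dataset$records[idx, , drop = FALSE]
    rownames(rec) <- NULL
    structure(list(records = rec,
                   name = paste0(dataset$name, ":", roles[k])),
              class = "labeled_dataset")
  })
  names(parts) <- roles
  structure(c(parts, list(seed = as.integer(seed), fractions = fractions)),
            class = "stepwise_split")
}

#' Consecutive-splitting cross-validation fold plan
#'
#' Cuts the dataset (in its current order, or after a seeded shuffle) into
#' `k` consecutive parts and rotates the four step-wise roles over the
#' parts: in fold `i`, part `i` is the base-validation part, part
#' `i+1 (mod k)` the meta-training part, part `i+2 (mod k)` the
#' meta-validation part, and the remaining `k-3` parts form the
#' base-training set.
#'
#' @param dataset A [labeled_dataset()].
#' @param k Number of parts/folds (>= 4); default 10.
#' @param seed Optional integer; when non-`NULL` the dataset is shuffled
#'   with this seed before the consecutive cut.
#' @return An object of class `cv_fold_plan`: list with `k`, `part`
#'   (integer part id per record, in dataset order), and `folds`, a list of
#'   `k` lists each holding integer record indices for the four roles.
#' @export
consecutive_cv_folds <- function(dataset, k = 10L, seed = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  k <- as.integer(k)
  if (k < 4L) stop("k must be >= 4 so all four roles can be filled", call. = FALSE)
  n <- nrow(dataset$records)
  if (n < k) stop("dataset smaller than k", call. = FALSE)
  ord <- seq_len(n)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    ord <- sample.int(n)
  }
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  part_of_pos <- rep(seq_len(k), times = sizes)
  part <- integer(n)
  part[ord] <- part_of_pos
  folds <- lapply(seq_len(k), function(i) {
    bv <- i
    mt <- (i %% k) + 1L
    mv <- ((i + 1L) %% k) + 1L
    bt <- setdiff(seq_len(k), c(bv, mt, mv))
    list(base_train = which(part %in% bt),
         base_valid = which(part == bv),
         meta_train = which(part == mt),
         meta_valid = which(part == mv))
  })
  structure(list(k = k, part = part, folds = folds, seed = seed),
            class = "cv_fold_plan")
}

#' Extract one role of a fold as a labeled_dataset
#'
#' @param dataset The [labeled_dataset()] the plan was built from.
#' @param plan A [consecutive_cv_folds()] plan.
#' @param fold Fold index in `1..k`.
#' @param role One of `"base_train"`, `"base_valid"`, `"meta_train"`,
#'   `"meta_valid"`.
#' @return A [labeled_dataset()].
#' @export
fold_subset <- function(dataset, plan, fold, role) {
  stopifnot(inherits(plan, "cv_fold_plan"),
            role %in% c("base_train", "base_valid", "meta_train", "meta_valid"))
  idx <- plan$folds[[fold]][[role]]
  rec <- dataset$records[idx, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 name = paste0(dataset$name, ":fold", fold, ":", role)),
            class = "labeled_dataset")
}
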