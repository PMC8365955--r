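# Canonical order of the five base-feature views. All combination
# enumeration and meta-feature column ordering follows this order.
BASE_FEATURE_NAMES <- c("DESC", "MGF", "MFP", "SeV", "FPeV")

#' Assemble base-model probabilities into a meta-feature matrix
#'
#' Concatenates the output probabilities of the chosen base models
#' column-wise; columns follow the canonical base order
#' (DESC, MGF, MFP, SeV, FPeV) restricted to `members`.
#'
#' @param base_probs Named list of probability vectors (names from
#'   `BASE_FEATURE_NAMES`), all the same length.
#' @param members Character subset of `BASE_FEATURE_NAMES` to include.
#' @return Numeric matrix `n x length(members)` with column names, entries
#'   in `[0, 1]`.
#' @export
assemble_meta_features <- function(base_probs, members = names(base_probs)) {
  stopifnot(length(members) > 0, !anyDuplicated(members))
  if (!all(members %in% names(base_probs)))
    stop("unknown member(s): ",
         paste(setdiff(members, names(base_probs)), collapse = ", "),
         call. = FALSE)
  members <- BASE_FEATURE_NAMES[BASE_FEATURE_NAMES %in% members]
  lens <- vapply(base_probs[members], length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("probability vectors differ in length", call. = FALSE)
  M <- do.call(cbind, base_probs[members])
  colnames(M) <- members
  if (any(M < 0 | M > 1))
    stop("base probabilities must lie in [0, 1]", call. = FALSE)
  M
}

#' Train the meta-ensemble network
#'
#' A small fully connected network (default hidden widths 32-16, a
#' reconstruction of the original figure-only architecture) over the
#' meta-feature matrix, trained with Adam at learning rate 1e-3 for 300
#' epochs with batch size 32 by default.
#'
#' @param meta Meta-feature matrix from [assemble_meta_features()].
#' @param labels Binary 0/1 labels (rows of `meta`).
#' @param cfg A [train_config()]; defaults to the meta-stage settings.
#' @param hidden Hidden widths (default `c(32, 16)`).
#' @param valid_meta,valid_labels Optional validation matrix/labels for
#'   best-epoch selection.
#' @return Object of class `meta_model`.
#' @export
train_meta_model <- function(meta, labels, cfg = NULL, hidden = c(32L, 16L),
                             valid_meta = NULL, valid_labels = NULL) {
  meta <- as.matrix(meta)
  if (is.null(cfg)) cfg <- train_config(learning_rate = 1e-3, epochs = 300L)
  if (nrow(meta) != length(labels))
    stop("labels length does not match meta-feature rows", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  layers <- c(lapply(hidden, function(h) nn_dense(h, "relu")),
              list(nn_dense(1L, "linear")))
  res <- .train_network(layers, ncol(meta), dense_features(meta), labels,
                        if (!is.null(valid_meta)) dense_features(as.matrix(valid_meta)),
                        valid_labels, cfg)
  structure(list(net = res$net, history = res$history, k = ncol(meta),
                 members = colnames(meta), hidden = hidden, trained = TRUE),
            class = "meta_model")
}

#' @method print meta_model
#' @export
print.meta_model <- function(x, ...) {
  cat("meta_model over {", paste(x$members, collapse = ", "), "}\n")
  invisible(x)
}

#' Enumerate all base-feature combinations
#'
#' All 31 nonempty subsets of the five base-feature views, grouped by size
#' (M1..M5) and deterministically ordered within each group by the
#' canonical base order.
#'
#' @param base_set Character vector of 5 distinct base-feature names
#'   (default `BASE_FEATURE_NAMES`).
#' @return data.frame with columns `id` (e.g. `"M2-3"`), `size`, and
#'   `members` (list column of character vectors).
#' @export
enumerate_feature_combinations <- function(base_set = BASE_FEATURE_NAMES) {
  stopifnot(length(base_set) == 5L, !anyDuplicated(base_set))
  rows <- list()
  for (m in 1:5) {
    combos <- utils::combn(base_set, m, simplify = FALSE)
    for (i in seq_along(combos)) {
      rows[[length(rows) + 1L]] <-
        data.frame(id = sprintf("M%d-%d", m, i), size = m)
      rows[[length(rows)]]$members <- list(combos[[i]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best meta-feature combination
#'
#' Winner = combination (size >= 2) maximizing the number of metrics
#' improved over the per-metric best M1 (single-feature) baseline; ties
#' are broken by higher MCC, then by smaller combination size. Improvement
#' is strict (`>`), mirroring the count-of-metrics-improved analysis over
#' the seven threshold metrics plus AUC reported for meta-feature grids.
#'
#' @param results data.frame with one row per combination: columns `id`,
#'   `size`, `members` (list), and the metric columns in `metrics`.
#' @param metrics Metric columns to compare (default
#'   `MCC, NPV, ACC, PPV, SPE, SEN, AUC` — the seven reported columns).
#' @return One-row data.frame (the winning combination) with attribute
#'   `n_improved` and `baseline` (named per-metric best-M1 vector).
#' @export
select_best_combination <- function(results,
                                    metrics = c("MCC", "NPV", "ACC", "PPV",
                                                "SPE", "SEN", "AUC")) {
  if (is.null(results) || nrow(results) == 0L)
    stop("empty combination results", call. = FALSE)
  metrics <- intersect(metrics, colnames(results))
  m1 <- results[results$size == 1L, , drop = FALSE]
  if (nrow(m1) == 0L) stop("results lack the M1 baseline group", call. = FALSE)
  baseline <- vapply(metrics, function(mm) suppressWarnings(max(m1[[mm]], na.rm = TRUE)),
                     numeric(1))
  cand <- results[results$size >= 2L, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- results
  n_improved <- vapply(seq_len(nrow(cand)), function(i) {
    sum(vapply(metrics, function(mm) {
      v <- cand[[mm]][i]
      !is.na(v) && v > baseline[[mm]]
    }, logical(1)))
  }, integer(1))
  ord <- order(-n_improved, -cand$MCC, cand$size)
  winner <- cand[ord[1], , drop = FALSE]
  attr(winner, "n_improved") <- n_improved[ord[1]]
  attr(winner, "baseline") <- baseline
  winner
}

#' Threshold probabilities into class labels
#'
#' A molecule is declared a hERG blocker (label 1) iff its predicted
#' probability is greater than or equal to the threshold (default 0.5).
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 vector.
#' @export
classify_threshold <- function(probabilities, threshold = 0.5) {
  if (any(is.na(probabilities)) ||
      any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  as.integer(probabilities >= threshold)
}

#' Percent-improvement grid over the best single-feature baseline
#'
#' For every combination of size >= 2, the percent improvement of each
#' metric over the per-metric best M1 row.
#'
#' @inheritParams select_best_combination
#' @return data.frame: `id`, `size`, then one `<metric>_pct` column per
#'   metric.
#' @export
combination_improvement <- function(results,
                                    metrics = c("MCC", "NPV", "ACC", "PPV",
                                                "SPE", "SEN", "AUC")) {
  metrics <- intersect(metrics, colnames(results))
  m1 <- results[results$size == 1L, , drop = FALSE]
  baseline <- vapply(metrics, function(mm) suppressWarnings(max(m1[[mm]], na.rm = TRUE)),
                     numeric(1))
  cand <- results[results$size >= 2L, , drop = FALSE]
  out <- cand[, c("id", "size"), drop = FALSE]
  for (mm in metrics)
    out[[paste0(mm, "_pct")]] <- percent_improvement(cand[[mm]], baseline[[mm]])
  out
}
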