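#' Confusion counts for binary predictions
#'
#' Positive class (1) is the hERG blocker, negative (0) the non-blocker.
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return Object of class `confusion_counts`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_counts")
}

#' @method print confusion_counts
#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion: TP", x$TP, "FN", x$FN, "TN", x$TN, "FP", x$FP, "\n")
  invisible(x)
}

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metric suite from confusion counts
#'
#' Computes sensitivity `SEN = TP/(TP+FN)`, specificity `SPE = TN/(TN+FP)`,
#' negative predictive value `NPV = TN/(TN+FN)`, positive predictive value
#' `PPV = TP/(TP+FP)`, raw accuracy `ACC = (TP+TN)/total`, the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' and balanced accuracy `BACC = (SEN+SPE)/2`. Any metric with a zero
#' denominator is reported as `NA` (the reporting convention of the hERG
#' benchmark literature) rather than 0; no error is raised.
#'
#' @param counts A [confusion_counts()] object, or a named list with
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector with elements `SEN`, `SPE`, `NPV`, `PPV`,
#'   `ACC`, `MCC`, `BACC` (NA-capable).
#' @export
compute_classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  sen <- .safe_ratio(TP, TP + FN)
  spe <- .safe_ratio(TN, TN + FP)
  npv <- .safe_ratio(TN, TN + FN)
  ppv <- .safe_ratio(TP, TP + FP)
  acc <- .safe_ratio(TP + TN, TP + TN + FP + FN)
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  bacc <- if (is.na(sen) || is.na(spe)) NA_real_ else (sen + spe) / 2
  c(SEN = sen, SPE = spe, NPV = npv, PPV = ppv, ACC = acc, MCC = mcc,
    BACC = bacc)
}

#' ROC AUC via the tie-corrected rank statistic
#'
#' Equals the probability that a uniformly drawn positive outscores a
#' uniformly drawn negative, with ties counted one half (the
#' Wilcoxon-Mann-Whitney statistic), which is the area under the ROC curve
#' of TPR against FPR over all thresholds.
#'
#' @param y_true Binary 0/1 vector.
#' @param scores Real-valued scores, higher = more blocker-like.
#' @return AUC in `[0, 1]`; `NA` with a warning when only one class is
#'   present.
#' @export
auc_roc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length", call. = FALSE)
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1L); nneg <- sum(y_true == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Metric report for one evaluation
#'
#' Bundles the threshold-based metric suite with AUC for one (model,
#' dataset) evaluation: probabilities are thresholded (label 1 iff
#' `p >= threshold`), counted, and scored.
#'
#' @param y_true Binary 0/1 vector.
#' @param probabilities Predicted blocker probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5; `p >= threshold`
#'   declares a blocker).
#' @return Named numeric vector `SEN, SPE, NPV, PPV, ACC, MCC, BACC, AUC`.
#' @export
metric_report <- function(y_true, probabilities, threshold = 0.5) {
  pred <- classify_threshold(probabilities, threshold)
  m <- compute_classification_metrics(confusion_counts(y_true, pred))
  auc <- suppressWarnings(auc_roc(y_true, probabilities))
  c(m, AUC = auc)
}

#' Percent improvement of a candidate metric over a baseline
#'
#' `100 * (candidate - baseline) / baseline`; `NA` for a zero baseline.
#' Used for the improvement analysis of meta-feature combinations over the
#' best single-feature baseline.
#'
#' @param candidate,baseline Real scalars (vectorized).
#' @return Percent improvement (negative = deterioration).
#' @export
percent_improvement <- function(candidate, baseline) {
  n <- max(length(candidate), length(baseline))
  candidate <- rep_len(candidate, n)
  baseline <- rep_len(baseline, n)
  out <- 100 * (candidate - baseline) / baseline
  out[baseline == 0] <- NA_real_
  out
}
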