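#' Grouped stratified k-fold assignment
#'
#' Splits slides into k folds such that every patient's slides fall in
#' exactly one fold (no patient straddles train and test) while keeping
#' per-fold class counts as close to the global proportions as the
#' grouping allows.  Patients are shuffled under `seed`, ordered by
#' decreasing slide count, and greedily assigned to the fold whose class
#' counts deviate least from its proportional target after the
#' assignment.
#'
#' @param slides data.frame with columns `slide_id`, `patient_id`,
#'   `label` (+1/-1).
#' @param k number of folds (>= 2).
#' @param seed integer seed for the patient shuffle.
#' @return integer vector of fold ids (1..k) aligned with `slides` rows.
#' @export
grouped_stratified_kfold <- function(slides, k = 5L, seed = 1L) {
  if (k < 2) .duv_invalid("k must be >= 2")
  req <- c("slide_id", "patient_id", "label")
  if (!all(req %in% names(slides))) .duv_invalid("slides needs columns ", paste(req, collapse = ", "))
  patients <- unique(slides$patient_id)
  if (length(patients) < k)
    .duv_stop("fewer patients (", length(patients), ") than folds (", k, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # per-patient class composition
  pos <- vapply(patients, function(p) sum(slides$label[slides$patient_id == p] == 1), 0)
  tot <- vapply(patients, function(p) sum(slides$patient_id == p), 0)
  ord <- sample.int(length(patients))
  ord <- ord[order(-tot[ord])]          # big patients first, random ties
  n_pos <- sum(slides$label == 1); n_neg <- sum(slides$label == -1)
  target_pos <- n_pos / k; target_neg <- n_neg / k
  fold_pos <- numeric(k); fold_neg <- numeric(k)
  fold_of_patient <- setNames(integer(length(patients)), patients)
  for (i in ord) {
    # change in the global imbalance objective if patient i joins fold f
    cost <- vapply(seq_len(k), function(f) {
      (fold_pos[f] + pos[i] - target_pos)^2 - (fold_pos[f] - target_pos)^2 +
        (fold_neg[f] + (tot[i] - pos[i]) - target_neg)^2 -
        (fold_neg[f] - target_neg)^2 +
        1e-3 * (fold_pos[f] + fold_neg[f])  # tie-break toward emptier folds
    }, 0)
    f <- which.min(cost)
    fold_pos[f] <- fold_pos[f] + pos[i]
    fold_neg[f] <- fold_neg[f] + tot[i] - pos[i]
    fold_of_patient[patients[i]] <- f
  }
  folds <- as.integer(fold_of_patient[slides$patient_id])
  # hard guarantee of the grouping contract
  stopifnot(all(tapply(folds, slides$patient_id, function(x) length(unique(x))) == 1L))
  folds
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Percentages computed as `100 (TP + TN) / (TP + TN + FP + FN)`,
#' `100 TP / (TP + FN)` and `100 TN / (TN + FP)`.  A zero denominator
#' yields `NA` for that rate plus an entry in the `undefined` field --
#' never a silent zero.
#'
#' @param TP,TN,FP,FN non-negative confusion counts (positive =
#'   malignant).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent)
#'   and `undefined` (character vector of rates with zero denominators).
#' @export
performance_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts))) .duv_invalid("counts must be non-negative integers")
  undefined <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    100 * num / den
  }
  list(accuracy = rate(TP + TN, TP + TN + FP + FN, "accuracy"),
       sensitivity = rate(TP, TP + FN, "sensitivity"),
       specificity = rate(TN, TN + FP, "specificity"),
       undefined = undefined)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold across the slide scores (predict +1 when
#' `score >= t`), traces the (FPR, TPR) curve and integrates it with the
#' trapezoidal rule.  For the fused pipeline the natural slide score is
#' `H_i / M_i`.
#'
#' @param scores numeric slide scores (higher = more malignant).
#' @param labels slide labels in `{+1, -1}`; both classes must be present.
#' @return list with `roc_points` (data.frame `fpr`, `tpr`, ordered) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) .duv_invalid("scores/labels length mismatch")
  if (!all(labels %in% c(-1, 1))) .duv_invalid("labels must be +1 or -1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) .duv_stop("ROC requires both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == -1) / n_neg, 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) { fpr <- c(fpr, 1); tpr <- c(tpr, 1) }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Assemble an evaluation report
#'
#' @param truth slide labels (+1/-1).
#' @param predicted fused slide labels (+1/-1).
#' @param scores slide scores for the ROC (e.g. `H_i / M_i`).
#' @param folds optional fold ids for a per-fold breakdown.
#' @return object of class `duv_eval_report`: confusion counts, the three
#'   rates (percent, 1-decimal reporting), `roc_points`, `auc` and
#'   `per_fold`.
#' @export
eval_report <- function(truth, predicted, scores = NULL, folds = NULL) {
  if (length(truth) != length(predicted)) .duv_invalid("length mismatch")
  TP <- sum(truth == 1 & predicted == 1); TN <- sum(truth == -1 & predicted == -1)
  FP <- sum(truth == -1 & predicted == 1); FN <- sum(truth == 1 & predicted == -1)
  m <- performance_metrics(TP, TN, FP, FN)
  roc <- if (!is.null(scores) && length(unique(truth)) == 2) roc_auc(scores, truth) else NULL
  per_fold <- NULL
  if (!is.null(folds)) {
    per_fold <- do.call(rbind, lapply(sort(unique(folds)), function(f) {
      i <- folds == f
      data.frame(fold = f, n = sum(i),
                 correct = sum(truth[i] == predicted[i]),
                 accuracy = 100 * mean(truth[i] == predicted[i]))
    }))
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, undefined = m$undefined,
                 roc_points = if (is.null(roc)) NULL else roc$roc_points,
                 auc = if (is.null(roc)) NA_real_ else roc$auc,
                 per_fold = per_fold),
            class = "duv_eval_report")
}

#' @export
print.duv_eval_report <- function(x, ...) {
  cat("Slide-level evaluation (", x$TP + x$TN + x$FP + x$FN, " slides)\n", sep = "")
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  accuracy    %.1f%%\n", x$accuracy))
  cat(sprintf("  sensitivity %.1f%%\n", x$sensitivity))
  cat(sprintf("  specificity %.1f%%\n", x$specificity))
  if (!is.na(x$auc)) cat(sprintf("  AUC         %.3f\n", x$auc))
  invisible(x)
}
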