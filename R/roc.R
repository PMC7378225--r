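# Empirical ROC curve, trapezoidal AUC and Youden-optimal cutoff.

#' Empirical ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score threshold (a case is called positive when
#' its score strictly exceeds the threshold), records sensitivity and
#' specificity at each, and integrates the ROC by the trapezoidal rule.
#' Ties contribute half, so the AUC equals the tie-corrected Mann-Whitney
#' statistic. The curve runs from (sensitivity, specificity) = (1, 0) at
#' threshold -Inf to (0, 1) at +Inf; internal thresholds are midpoints
#' between consecutive distinct scores.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels: logical, 0/1 numeric, or a two-level
#'   factor/character vector whose *second* sorted level is positive.
#'   `"expansion"`/`"non_expansion"` are recognised explicitly.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`, plus the original scores and
#'   binary labels.
#' @examples
#' roc_result(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc
#' @export
roc_result <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(scores) != length(y))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build a ROC curve", call. = FALSE)

  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  sens <- vapply(thr, function(t) sum(scores > t & y == 1L) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & y == 0L) / n_neg, numeric(1))

  # trapezoid over (FPR, TPR), points ordered by decreasing FPR
  fpr <- 1 - spec; tpr <- sens
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)

  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = y),
            class = "roc_result")
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  lab <- as.character(labels)
  if (all(lab %in% c("expansion", "non_expansion")))
    return(as.integer(lab == "expansion"))
  lv <- sort(unique(lab))
  if (length(lv) > 2L) stop("labels must be binary", call. = FALSE)
  as.integer(lab == lv[length(lv)])
}

#' @export
print.roc_result <- function(x, digits = 4, ...) {
  cat(sprintf("ROC: %d positives, %d negatives, AUC = %.*f\n",
              x$n_pos, x$n_neg, digits, x$auc))
  if (!is.null(x$cutoff))
    cat(sprintf("  cutoff %.*f: sens %.*f, spec %.*f, PPV %.*f, NPV %.*f, acc %.*f\n",
                digits, x$cutoff, digits, x$metrics["sensitivity"],
                digits, x$metrics["specificity"], digits, x$metrics["ppv"],
                digits, x$metrics["npv"], digits, x$metrics["accuracy"]))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,fn,tn counts of true positives, false positives, false
#'   negatives and true negatives.
#' @return Named vector: sensitivity, specificity, ppv, npv, accuracy.
#'   Undefined ratios (empty denominator) are `NaN`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    accuracy = (tp + tn) / (tp + fp + fn + tn))
}

#' Youden-optimal cutoff and at-cutoff metrics
#'
#' Selects the threshold maximizing Youden's J = sensitivity +
#' specificity - 1 by exhaustive sweep over the ROC's thresholds; ties are
#' broken toward higher specificity (the larger threshold). When the
#' optimum is an open interval between two observed scores the reported
#' cutoff is the interval midpoint.
#'
#' @param roc a [roc_result()].
#' @return The `roc_result` augmented with `cutoff`, `youden` and
#'   `metrics` (sensitivity, specificity, ppv, npv, accuracy at the
#'   cutoff).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  J <- roc$sensitivity + roc$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  pick <- best[length(best)]            # ties -> larger threshold/higher spec
  cut <- roc$thresholds[pick]
  pred <- roc$scores > cut
  tp <- sum(pred & roc$labels == 1L); fp <- sum(pred & roc$labels == 0L)
  fn <- sum(!pred & roc$labels == 1L); tn <- sum(!pred & roc$labels == 0L)
  roc$cutoff <- cut
  roc$youden <- J[pick]
  roc$metrics <- confusion_metrics(tp, fp, fn, tn)
  roc
}
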