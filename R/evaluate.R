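# Repeated-split evaluation of a feature set: stratified 70:15:15 splits,
# network trained on the training partition with early stopping on the
# validation partition, scored on the test partition, per-repeat ROC
# metrics averaged across repeats.

#' Evaluate a feature set under repeated stratified splits
#'
#' For each of `n_repeats` stratified 70:15:15 partitions: z-score the
#' features with training-set statistics, train the backpropagation
#' network with early stopping on the validation partition, score the
#' test partition, and compute per-repeat AUC plus Youden-cutoff
#' confusion metrics from the test ROC. The headline aggregate is the
#' mean of per-repeat metrics; a pooled-score ROC over all repeats'
#' test predictions is also computed.
#'
#' @param features data frame or matrix of predictor columns (rows =
#'   patients, aligned with `labels`).
#' @param labels binary outcome per patient.
#' @param n_repeats number of random splits (default 100).
#' @param seed seed controlling both the splits and the per-repeat
#'   network initialisations.
#' @param hidden hidden-layer width(s) passed to [mlp_net()].
#' @param ratios train/validation/test proportions.
#' @param ... further arguments to [mlp_net()] (`epochs`, `lr`,
#'   `patience`).
#' @return Object of class `repeat_eval`: `per_repeat` data frame (auc,
#'   cutoff, sensitivity, specificity, ppv, npv, accuracy per repeat),
#'   `summary` (mean and sd of each, NaN-repeats dropped per metric),
#'   and `pooled` (a [roc_result()] over the concatenated test scores).
#' @export
evaluate_feature_set <- function(features, labels, n_repeats = 100L,
                                 seed = 1L, hidden = 10L,
                                 ratios = c(0.70, 0.15, 0.15), ...) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as_binary_label(labels)
  stopifnot(nrow(X) == length(y))
  splits <- make_splits(y, n_repeats = n_repeats, ratios = ratios, seed = seed)

  metric_names <- c("auc", "cutoff", "sensitivity", "specificity",
                    "ppv", "npv", "accuracy")
  per <- matrix(NA_real_, n_repeats, length(metric_names),
                dimnames = list(NULL, metric_names))
  pooled_scores <- numeric(0); pooled_labels <- integer(0)

  for (r in seq_len(n_repeats)) {
    sp <- splits[[r]]
    fit <- mlp_net(X[sp$train, , drop = FALSE], y[sp$train], hidden = hidden,
                   validation = list(x = X[sp$validation, , drop = FALSE],
                                     y = y[sp$validation]),
                   seed = seed + 7919L * r, ...)
    sc <- predict(fit, X[sp$test, , drop = FALSE])
    roc <- optimal_cutoff(roc_result(sc, y[sp$test]))
    per[r, ] <- c(roc$auc, roc$cutoff, roc$metrics)
    pooled_scores <- c(pooled_scores, sc)
    pooled_labels <- c(pooled_labels, y[sp$test])
  }

  per <- as.data.frame(per)
  per$repeat_index <- seq_len(n_repeats)
  smry <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(per[[m]][is.finite(per[[m]])]),
                  numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(per[[m]][is.finite(per[[m]])]),
                numeric(1)),
    row.names = NULL)
  structure(list(per_repeat = per, summary = smry,
                 pooled = roc_result(pooled_scores, pooled_labels),
                 n_repeats = n_repeats, seed = seed),
            class = "repeat_eval")
}

#' @export
print.repeat_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated-split evaluation (%d repeats, 70:15:15 stratified)\n",
              x$n_repeats))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  mean %-12s %.*f (sd %.*f)\n", s$metric[i],
                digits, s$mean[i], digits, s$sd[i]))
  cat(sprintf("  pooled-score AUC     %.*f\n", digits, x$pooled$auc))
  invisible(x)
}

#' Mean test AUC of a repeated-split evaluation
#' @param x a [evaluate_feature_set()] result.
#' @return Mean per-repeat test AUC.
#' @export
mean_auc <- function(x) {
  stopifnot(inherits(x, "repeat_eval"))
  x$summary$mean[x$summary$metric == "auc"]
}
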