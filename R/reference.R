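# Volume-change reference standard and the type-I endoleak exclusion.

#' Label a cohort by relative volume change
#'
#' Applies the expansion reference standard: a patient is labeled
#' `expansion` iff the relative volume change `(V2 - V1) / V1` strictly
#' exceeds `threshold` (default 2%); otherwise `non_expansion` (stable or
#' shrunken sac). The comparison is strict: a change of exactly 2% is
#' non-expansion. No rounding is applied before the comparison, and the
#' label is invariant to rescaling both volumes by any positive constant.
#'
#' @param cohort data frame with numeric `V1` and `V2` columns (volumes in
#'   cc; `V1` must be positive).
#' @param threshold relative-change threshold as a fraction (default 0.02).
#' @return The cohort with a `label` column (`"expansion"` /
#'   `"non_expansion"`) and a `rel_change` column.
#' @examples
#' apply_reference_standard(data.frame(V1 = 100, V2 = c(103, 102, 90)))
#' @export
apply_reference_standard <- function(cohort, threshold = 0.02) {
  stopifnot(is.data.frame(cohort), all(c("V1", "V2") %in% names(cohort)))
  if (any(!is.finite(cohort$V1)) || any(cohort$V1 <= 0))
    stop("V1 must be positive for every patient", call. = FALSE)
  if (any(!is.finite(cohort$V2)) || any(cohort$V2 < 0))
    stop("V2 must be non-negative for every patient", call. = FALSE)
  rel <- (cohort$V2 - cohort$V1) / cohort$V1
  cohort$rel_change <- rel
  cohort$label <- ifelse(rel > threshold, "expansion", "non_expansion")
  cohort
}

#' Exclude type-I endoleak patients from a labeled cohort
#'
#' Type-I (attachment-site) endoleaks are a strong independent driver of
#' sac expansion and are excluded before texture analysis so the texture
#' signal is not confounded by them. Idempotent.
#'
#' @param cohort labeled data frame with an `endoleak` column
#'   (`"type_I"`, `"type_II"`, `"none"`).
#' @param label_col column holding the expansion label for the per-group
#'   bookkeeping (default `"label"`; fall back to `"group"` if absent).
#' @return A list of class `exclusion_report`: `cohort` (filtered data
#'   frame), `removed_ids`, `before` and `after` per-group counts.
#' @export
exclude_type1 <- function(cohort, label_col = NULL) {
  stopifnot(is.data.frame(cohort), "endoleak" %in% names(cohort))
  if (is.null(label_col))
    label_col <- if ("label" %in% names(cohort)) "label" else "group"
  if (!label_col %in% names(cohort))
    stop(sprintf("label column '%s' not found", label_col), call. = FALSE)
  drop <- cohort$endoleak == "type_I"
  kept <- cohort[!drop, , drop = FALSE]
  if (nrow(kept) == 0L)
    warning("all patients excluded: cohort consisted only of type-I endoleaks")
  out <- list(cohort = kept,
              removed_ids = if ("id" %in% names(cohort)) cohort$id[drop]
                            else which(drop),
              before = table(factor(cohort[[label_col]])),
              after = table(factor(kept[[label_col]],
                                   levels = levels(factor(cohort[[label_col]])))))
  class(out) <- "exclusion_report"
  out
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Type-I endoleak exclusion: %d patient(s) removed\n",
              length(x$removed_ids)))
  tab <- rbind(before = as.integer(x$before), after = as.integer(x$after))
  colnames(tab) <- names(x$before)
  print(tab)
  invisible(x)
}
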