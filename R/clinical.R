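# Comparison arms: univariable screening of clinical/imaging variables,
# binary logistic regression, and ROC on the model's predicted
# probabilities.

#' Univariable screening of clinical and imaging variables
#'
#' Continuous variables are checked for normality (Lilliefors-corrected
#' Kolmogorov-Smirnov; approximate, a failure only logs a warning since
#' the group comparison proceeds by t test regardless) and compared
#' between expansion groups with a two-sample t test (Welch by default).
#' Categorical variables are compared with a chi-square test, switching
#' to Fisher's exact test when any expected cell is below 5. A variable
#' is selected when P < `select_p` or when it is on the `force` list
#' (clinical-importance forcing).
#'
#' @param cohort labeled data frame.
#' @param variables character vector of column names to screen.
#' @param label_col outcome column (default `"label"`).
#' @param select_p selection threshold on the univariable P value
#'   (default 0.1).
#' @param force variables always selected regardless of P (default
#'   endoleak and the maximal diameter).
#' @param pooled_t use the pooled-variance t test instead of Welch.
#' @return Data frame of class `screening_result`: variable, type, test,
#'   group summaries, p_value, selected, forced. Zero-variance variables
#'   are flagged (`test = "none"`, P `NA`), never an error.
#' @export
screen_univariable <- function(cohort, variables, label_col = "label",
                               select_p = 0.1,
                               force = c("endoleak", "max_diameter"),
                               pooled_t = FALSE) {
  stopifnot(is.data.frame(cohort), label_col %in% names(cohort))
  y <- factor(as_binary_label(cohort[[label_col]]), levels = c(0, 1))
  rows <- lapply(variables, function(v) {
    if (!v %in% names(cohort)) stop(sprintf("variable '%s' not found", v),
                                    call. = FALSE)
    x <- cohort[[v]]
    ok <- !is.na(x)
    xs <- x[ok]; ys <- y[ok]
    is_cont <- is.numeric(xs) && length(unique(xs)) > 5L
    summarize <- function(sel) {
      if (is_cont) sprintf("%.1f +/- %.1f", mean(xs[sel]), stats::sd(xs[sel]))
      else paste(sprintf("%s: %d", names(table(xs[sel])), table(xs[sel])),
                 collapse = "; ")
    }
    if (length(unique(xs)) < 2L) {
      return(data.frame(variable = v, type = if (is_cont) "continuous" else "categorical",
                        test = "none", group0 = summarize(ys == 0),
                        group1 = summarize(ys == 1), p_value = NA_real_,
                        note = "zero variance", stringsAsFactors = FALSE))
    }
    if (is_cont) {
      norm_p <- tryCatch(nortest::lillie.test(xs)$p.value,
                         error = function(e) NA_real_)
      if (is.finite(norm_p) && norm_p < 0.05)
        warning(sprintf(
          "'%s' deviates from normality (Lilliefors P = %.3g); t test applied regardless",
          v, norm_p), call. = FALSE)
      p <- stats::t.test(xs ~ ys, var.equal = pooled_t)$p.value
      test <- if (pooled_t) "t (pooled)" else "t (Welch)"
    } else {
      tab <- table(factor(xs), ys)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "Fisher exact"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chi-square"
      }
    }
    data.frame(variable = v, type = if (is_cont) "continuous" else "categorical",
               test = test, group0 = summarize(ys == 0),
               group1 = summarize(ys == 1), p_value = p, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$forced <- out$variable %in% force
  out$selected <- (is.finite(out$p_value) & out$p_value < select_p) | out$forced
  class(out) <- c("screening_result", class(out))
  out
}

#' @export
print.screening_result <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, digits)
  print(df[, c("variable", "test", "group0", "group1", "p_value", "selected")],
        row.names = FALSE)
  invisible(x)
}

#' Binary logistic regression on selected variables
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of the
#' expansion label on the selected variables. The endoleak column, when
#' present, is dummy-coded with "none" as the reference level (odds ratio
#' 1 for no endoleak). Complete separation and non-convergence raise an
#' explicit diagnostic rather than returning a silently unusable fit.
#'
#' @param cohort labeled data frame.
#' @param variables predictor column names.
#' @param label_col outcome column (default `"label"`).
#' @return Object of class `sac_logistic`: the `glm` fit, `odds_ratios`
#'   (with Wald P values), and `probabilities` (per-patient predicted
#'   expansion probability).
#' @export
fit_logistic <- function(cohort, variables, label_col = "label") {
  stopifnot(is.data.frame(cohort), label_col %in% names(cohort))
  y <- as_binary_label(cohort[[label_col]])
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: all patients share one label", call. = FALSE)
  dat <- cohort[, variables, drop = FALSE]
  if ("endoleak" %in% names(dat))
    dat$endoleak <- stats::relevel(factor(dat$endoleak), ref = "none")
  for (v in names(dat))
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  dat$.y <- y

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    warning("logistic regression did not converge; estimates unreliable",
            call. = FALSE)
  if (sep_warn || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
    warning(paste("possible (quasi-)separation: fitted probabilities at 0/1",
                  "or extreme coefficients; odds ratios unreliable"),
            call. = FALSE)

  cf <- summary(fit)$coefficients
  or <- data.frame(term = rownames(cf)[-1],
                   odds_ratio = exp(cf[-1, 1]),
                   p_value = cf[-1, 4], row.names = NULL)
  structure(list(fit = fit, odds_ratios = or,
                 probabilities = stats::fitted(fit)),
            class = "sac_logistic")
}

#' @export
print.sac_logistic <- function(x, digits = 4, ...) {
  cat("Binary logistic regression for aneurysm expansion\n")
  or <- x$odds_ratios
  or$odds_ratio <- signif(or$odds_ratio, digits)
  or$p_value <- signif(or$p_value, 3)
  print(or, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sac_logistic <- function(object, ...) stats::coef(object$fit)

#' @export
predict.sac_logistic <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$probabilities)
  if ("endoleak" %in% names(newdata))
    newdata$endoleak <- stats::relevel(factor(newdata$endoleak), ref = "none")
  stats::predict(object$fit, newdata = newdata, type = "response")
}

#' ROC of logistic prediction probabilities per comparison arm
#'
#' Fits one logistic model per named variable set (e.g. conventional
#' imaging, clinical risk factors, and their combination) and feeds each
#' arm's in-sample predicted probabilities into the ROC machinery.
#'
#' @param cohort labeled data frame.
#' @param arms named list of character vectors of predictor columns.
#' @param label_col outcome column (default `"label"`).
#' @return Named list with, per arm, the fitted `sac_logistic` and its
#'   `roc_result` (with Youden cutoff metrics); plus an `auc` summary
#'   data frame.
#' @export
model_probability_roc <- function(cohort, arms, label_col = "label") {
  stopifnot(is.list(arms), !is.null(names(arms)))
  res <- lapply(arms, function(vars) {
    m <- fit_logistic(cohort, vars, label_col = label_col)
    roc <- optimal_cutoff(roc_result(m$probabilities,
                                     as_binary_label(cohort[[label_col]])))
    list(model = m, roc = roc)
  })
  res$auc <- data.frame(arm = names(arms),
                        auc = vapply(res[names(arms)],
                                     function(a) a$roc$auc, numeric(1)),
                        row.names = NULL)
  res
}
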