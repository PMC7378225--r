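test_that("a variable identical in both groups is flagged, not selected", {
  ch <- data.frame(label = rep(c("expansion", "non_expansion"), each = 20),
                   flat = rep(5, 40))
  sc <- screen_univariable(ch, "flat", force = character(0))
  expect_identical(sc$test, "none")
  expect_true(is.na(sc$p_value))
  expect_false(sc$selected)
})

test_that("a 3-SD group shift is selected with near-certain power", {
  set.seed(61)
  ch <- data.frame(label = rep(c("expansion", "non_expansion"), each = 50),
                   x = c(rnorm(50, 3, 1), rnorm(50, 0, 1)))
  sc <- suppressWarnings(screen_univariable(ch, "x", force = character(0)))
  expect_lt(sc$p_value, 0.001)
  expect_true(sc$selected)
})

test_that("screening P values are invariant to affine rescaling", {
  set.seed(62)
  ch <- data.frame(label = rep(c("expansion", "non_expansion"), each = 30),
                   x = rnorm(60, 10, 2))
  p1 <- suppressWarnings(screen_univariable(ch, "x", force = character(0)))$p_value
  ch$x <- ch$x * 13 - 250
  p2 <- suppressWarnings(screen_univariable(ch, "x", force = character(0)))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the published endoleak table screens below the 0.1 threshold", {
  ch <- apply_reference_standard(published_counts_cohort())
  sc <- screen_univariable(ch, "endoleak", force = character(0))
  expect_lt(sc$p_value, 0.1)
  expect_true(sc$selected)
  expect_match(sc$test, "Fisher|chi-square")
})

test_that("clinical-importance forcing selects regardless of P", {
  set.seed(63)
  ch <- data.frame(label = rep(c("expansion", "non_expansion"), each = 30),
                   max_diameter = rnorm(60, 50, 10))
  sc <- suppressWarnings(screen_univariable(ch, "max_diameter"))
  expect_true(sc$selected)
  expect_true(sc$forced)
})

test_that("univariable logistic OR on a 2x2 table equals the cross-product ratio", {
  # expansion: 6 type II / 26 none; non-expansion: 6 type II / 54 none
  ch <- data.frame(
    label = rep(c("expansion", "non_expansion"), c(32, 60)),
    endoleak = c(rep(c("type_II", "none"), c(6, 26)),
                 rep(c("type_II", "none"), c(6, 54))))
  fit <- fit_logistic(ch, "endoleak")
  expect_equal(fit$odds_ratios$odds_ratio, (6 * 54) / (6 * 26),
               tolerance = 1e-6)
  expect_equal(fit$odds_ratios$term, "endoleaktype_II")  # "none" is reference
})

test_that("a label-independent predictor recovers a null odds ratio", {
  set.seed(64)
  n <- 500
  ch <- data.frame(label = rbinom(n, 1, 0.4), x = rbinom(n, 1, 0.5))
  fit <- fit_logistic(ch, "x")
  expect_gt(fit$odds_ratios$odds_ratio, 0.8)
  expect_lt(fit$odds_ratios$odds_ratio, 1.25)
})

test_that("degenerate outcomes and separation raise explicit diagnostics", {
  ch <- data.frame(label = rep("expansion", 20), x = rnorm(20))
  expect_error(fit_logistic(ch, "x"), "degenerate outcome")
  sep <- data.frame(label = rep(c(1, 0), each = 20),
                    x = rep(c(1, 0), each = 20))
  expect_warning(fit_logistic(sep, "x"), "separation")
})

test_that("model-probability ROC behaves per arm", {
  set.seed(65)
  n <- 500
  ch <- data.frame(label = rbinom(n, 1, 0.4))
  ch$oracle <- ch$label
  ch$junk1 <- rnorm(n); ch$junk2 <- rbinom(n, 1, 0.3)
  res <- suppressWarnings(model_probability_roc(
    ch, arms = list(oracle = "oracle", noise = c("junk1", "junk2"))))
  expect_equal(res$oracle$roc$auc, 1.0)
  expect_gt(res$noise$roc$auc, 0.44)
  expect_lt(res$noise$roc$auc, 0.56)

  # nested in-sample models: the larger arm's likelihood cannot be worse,
  # and its in-sample AUC tracks it up to optimizer-free slack
  ch$signal <- ch$label + rnorm(n)
  res2 <- model_probability_roc(
    ch, arms = list(imaging = "signal", combined = c("signal", "junk1")))
  expect_lte(deviance(res2$combined$model$fit),
             deviance(res2$imaging$model$fit) + 1e-8)
  expect_gte(res2$combined$roc$auc, res2$imaging$roc$auc - 0.005)
})
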