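test_that("co-occurrence matrix matches exhaustive pair enumeration", {
  # 2x2 checkerboard: two horizontal pairs, both orders
  q <- quantize(matrix(c(0, 1, 1, 0), 2, 2), matrix(TRUE, 2, 2), G = 2)
  P <- glcm_matrix(q, d = 1, theta = 0)
  expect_equal(unclass(P)[1:2, 1:2],
               matrix(c(0, 0.5, 0.5, 0), 2, 2), tolerance = 1e-12)

  # constant ROI: all mass at (1, 1)
  qc <- quantize(matrix(5, 3, 3), matrix(TRUE, 3, 3), G = 4)
  Pc <- glcm_matrix(qc, 1, 90)
  expect_equal(unclass(Pc)[1, 1], 1)
  expect_equal(sum(Pc), 1)

  # masking one corner changes pair counts exactly as brute force says
  img <- matrix(c(0, 1, 2, 1, 0, 2, 2, 1, 0), 3, 3)
  mask <- matrix(TRUE, 3, 3); mask[3, 3] <- FALSE
  qm <- quantize(img, mask, G = 3)
  for (th in c(0, 45, 90, 135))
    expect_equal(unclass(glcm_matrix(qm, 1, th))[1:3, 1:3],
                 bf_glcm(qm$levels, mask, 1, th, G = 3), tolerance = 1e-12)
})

test_that("matrices are symmetric, normalized, and error when no pair exists", {
  set.seed(7)
  roi <- random_masked_roi(6, 6, 4)
  for (th in c(0, 45, 90, 135)) {
    P <- glcm_matrix(roi, 1, th)
    expect_equal(sum(P), 1, tolerance = 1e-9)
    expect_identical(unclass(P), t(unclass(P)))
  }
  # single-pixel mask: nonempty but no pair in any direction
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  q1 <- suppressWarnings(quantize(matrix(1:9, 3, 3), m, G = 2))
  expect_error(glcm_matrix(q1, 1, 0), "no in-mask pixel pair")
})

test_that("checkerboard features match hand evaluation", {
  q <- quantize(matrix(c(0, 1, 1, 0), 2, 2), matrix(TRUE, 2, 2), G = 2)
  f <- glcm_features(q, thetas = 0)
  expect_equal(unname(f["glcm_contrast"]), 1.0)
  expect_equal(unname(f["glcm_energy"]), 0.5)
})

test_that("constant ROI hits the degenerate single-cell limits", {
  qc <- quantize(matrix(7, 4, 4), matrix(TRUE, 4, 4), G = 16)
  f <- glcm_features(qc)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_inverse_difference_moment"]), 1)
  expect_equal(unname(f["glcm_correlation"]), 0)  # zero-variance convention
})

test_that("feature vector has the 13 documented names", {
  roi <- quantize(matrix(runif(36), 6, 6), matrix(TRUE, 6, 6), G = 4)
  f <- glcm_features(roi)
  expect_length(f, 13)
  expect_named(f, paste0("glcm_", c(
    "energy", "contrast", "correlation", "entropy",
    "inverse_difference_moment", "sum_average", "sum_variance",
    "sum_entropy", "difference_average", "difference_variance",
    "difference_entropy", "imc1", "imc2")))
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  rotate90 <- function(m) t(apply(m, 2, rev))
  set.seed(11)
  for (rep in 1:5) {
    img <- matrix(sample.int(100, 49, replace = TRUE), 7, 7)
    mask <- matrix(runif(49) < 0.9, 7, 7)
    roi <- quantize(img, mask, G = 5)
    roi_rot <- quantize(rotate90(img), rotate90(mask), G = 5)
    expect_equal(glcm_features(roi), glcm_features(roi_rot), tolerance = 1e-9)
    expect_equal(glrlm_features(roi), glrlm_features(roi_rot), tolerance = 1e-9)
  }
})

test_that("matrix-averaging mode agrees with features mode on symmetric input", {
  # both averaging conventions exist; on a constant ROI they coincide
  qc <- quantize(matrix(3, 5, 5), matrix(TRUE, 5, 5), G = 8)
  expect_equal(glcm_features(qc, average = "features"),
               glcm_features(qc, average = "matrices"))
  # and on general input both return finite 13-vectors
  roi <- random_masked_roi(6, 6, 4)
  expect_true(all(is.finite(glcm_features(roi, average = "matrices"))))
})
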