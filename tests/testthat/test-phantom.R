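test_that("noise-free homogeneous sac is exactly the thrombus mean", {
  p <- small_phantom(thrombus_sd = 0, n_pockets = 0)
  ph <- render_sac_image(p, expander = FALSE)
  expect_true(all(ph$image[ph$mask] == p$thrombus_mean))
  expect_true(any(ph$mask))
})

test_that("rendering is bit-identical under a fixed seed", {
  p <- small_phantom(seed = 42)
  a <- render_sac_image(p, expander = TRUE)
  b <- render_sac_image(p, expander = TRUE)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("contrast pockets raise in-mask variance; zero amplitude is a no-op", {
  p <- small_phantom(seed = 9, n_pockets = 5, pocket_amplitude = 150)
  exp_img <- render_sac_image(p, expander = TRUE)
  stab_img <- render_sac_image(p, expander = FALSE)
  expect_gt(var(exp_img$image[exp_img$mask]), var(stab_img$image[stab_img$mask]))

  p0 <- small_phantom(seed = 9, pocket_amplitude = 0)
  expect_identical(render_sac_image(p0, TRUE)$image,
                   render_sac_image(p0, FALSE)$image)
})

test_that("degenerate geometry is rejected with the offending parameter named", {
  expect_error(phantom_params(sac_radius_px = 60, image_size = 96),
               "sac_radius_px")
  expect_error(phantom_params(lumen_radius_frac = 1.2), "lumen_radius_frac")
})

test_that("cohort generation writes a self-consistent manifest", {
  out <- withr::local_tempdir()
  cp <- cohort_params(n_total = 8, n_expanders = 3, seed = 2)
  man <- generate_cohort(cp, small_phantom(), out)
  expect_equal(nrow(man), 8)
  expect_equal(sum(man$group == "expansion"), 3)
  expect_true(all(file.exists(file.path(out, man$image))))
  expect_true(all(file.exists(file.path(out, man$mask))))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "params.json")))

  # round-trip via the manifest reader
  man2 <- read_manifest(out)
  expect_equal(man2$id, man$id)
  expect_equal(man2$V1, man$V1, tolerance = 1e-8)

  # written rasters reproduce the rendered scene (up to 16-bit scaling)
  ph <- read_gray_image(file.path(out, man$image[1]))
  mk <- read_mask(file.path(out, man$mask[1]))
  expect_identical(dim(ph), c(64L, 64L))
  expect_true(is.logical(mk) && any(mk))
})

test_that("cohort generation is reproducible and zero-variance deltas are exact", {
  cp <- cohort_params(n_total = 10, n_expanders = 4, seed = 7,
                      delta_exp_sd = 0, delta_non_sd = 0)
  m1 <- generate_cohort(cp, write_images = FALSE)
  m2 <- generate_cohort(cp, write_images = FALSE)
  expect_identical(m1$V1, m2$V1)
  expect_identical(m1$endoleak, m2$endoleak)
  rel <- (m1$V2 - m1$V1) / m1$V1
  expect_equal(rel[m1$group == "expansion"], rep(0.098, 4), tolerance = 1e-12)
  expect_equal(rel[m1$group == "non_expansion"], rep(-0.087, 6), tolerance = 1e-12)

  # with zero-variance deltas the 2% rule recovers the generating group
  lab <- apply_reference_standard(m1)
  expect_identical(lab$label, m1$group)
})

test_that("large-sample volume moments match the configured log-normal", {
  cp <- cohort_params(n_total = 4000, n_expanders = 1000, seed = 11)
  man <- generate_cohort(cp, write_images = FALSE)
  expect_equal(mean(man$V1), 156.9, tolerance = 0.1)   # |z| < 3 at n = 4000
  expect_equal(sd(man$V1), 133.6, tolerance = 0.15)
  expect_true(all(man$V1 > 0))
})

test_that("impossible cohort sizes are rejected", {
  expect_error(cohort_params(n_total = 5, n_expanders = 9), "n_expanders")
  expect_error(cohort_params(n_total = 0), "n_total")
})
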