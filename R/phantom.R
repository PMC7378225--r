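# Synthetic aneurysm-sac phantom: a bright stent lumen surrounded by a
# thrombus annulus. Expansion-prone sacs carry spatially heterogeneous
# contrast pockets (uneven contrast-agent distribution); stable sacs are
# statistically homogeneous.

#' Parameters of the aneurysm-sac phantom image
#'
#' @param image_size pixels per side of the square image.
#' @param lumen_radius_frac fraction of the sac radius occupied by the
#'   stent lumen; must lie in (0, 1).
#' @param sac_radius_px outer sac radius in pixels; must be smaller than
#'   half the image size.
#' @param thrombus_mean baseline sac intensity (arbitrary HU-like units).
#' @param thrombus_sd pixel noise standard deviation before smoothing.
#' @param n_pockets number of contrast pockets added to expansion-prone
#'   sacs; 0 disables the pocket machinery entirely.
#' @param pocket_amplitude peak added intensity per pocket.
#' @param pocket_sigma_px Gaussian spatial scale of a pocket, in pixels.
#' @param smoothing_sigma_px Gaussian blur scale applied to the pixel
#'   noise, giving spatially correlated thrombus texture; 0 = white noise.
#' @param seed integer RNG seed; identical parameters and seed reproduce
#'   the image bit-exactly.
#' @return An object of class `phantom_params` (validated list).
#' @export
phantom_params <- function(image_size = 96L, lumen_radius_frac = 0.35,
                           sac_radius_px = 40, thrombus_mean = 60,
                           thrombus_sd = 12, n_pockets = 5L,
                           pocket_amplitude = 150, pocket_sigma_px = 4,
                           smoothing_sigma_px = 1.5, seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            lumen_radius_frac = lumen_radius_frac,
            sac_radius_px = sac_radius_px, thrombus_mean = thrombus_mean,
            thrombus_sd = thrombus_sd, n_pockets = as.integer(n_pockets),
            pocket_amplitude = pocket_amplitude,
            pocket_sigma_px = pocket_sigma_px,
            smoothing_sigma_px = smoothing_sigma_px, seed = as.integer(seed))
  stopifnot_scalar_number(p$image_size, "image_size", positive = TRUE)
  if (p$lumen_radius_frac <= 0 || p$lumen_radius_frac >= 1)
    stop("`lumen_radius_frac` must lie strictly in (0, 1)", call. = FALSE)
  stopifnot_scalar_number(p$sac_radius_px, "sac_radius_px", positive = TRUE)
  if (p$sac_radius_px >= p$image_size / 2)
    stop("`sac_radius_px` must be smaller than image_size/2", call. = FALSE)
  if (p$thrombus_sd < 0) stop("`thrombus_sd` must be >= 0", call. = FALSE)
  if (p$n_pockets < 0) stop("`n_pockets` must be >= 0", call. = FALSE)
  if (p$pocket_sigma_px <= 0) stop("`pocket_sigma_px` must be > 0", call. = FALSE)
  if (p$smoothing_sigma_px < 0) stop("`smoothing_sigma_px` must be >= 0", call. = FALSE)
  class(p) <- "phantom_params"
  p
}

# intensity of the stent lumen (contrast-filled graft) and the background;
# fixed scene constants, outside the analysed ROI in any case
LUMEN_VALUE <- 300
BACKGROUND_VALUE <- 30
INTENSITY_MAX <- 65535   # representable range of the 16-bit container

# Gaussian blur with boundary renormalization (kernel rows re-sum to 1 at
# the edges), implemented as two banded-matrix products.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smooth_1d <- function(n) {
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  smooth_1d(nrow(m)) %*% m %*% t(smooth_1d(ncol(m)))
}

#' Render one synthetic aneurysm-sac image and its annulus mask
#'
#' Draws a square image containing a bright circular stent lumen inside a
#' thrombus-filled sac annulus. The analysed ROI is the annulus between
#' the lumen and the outer sac contour. Thrombus texture is Gaussian
#' pixel noise, optionally blurred into spatially correlated texture. For
#' an expansion-prone sac (`expander = TRUE`), `n_pockets` isotropic
#' Gaussian contrast pockets are added at uniformly random in-mask
#' centres. Pixel values are clipped to the representable 16-bit range.
#'
#' @param params a [phantom_params()] object.
#' @param expander logical; add contrast pockets?
#' @return A list with `image` (numeric matrix) and `mask` (logical
#'   annulus matrix).
#' @examples
#' ph <- render_sac_image(phantom_params(seed = 7), expander = TRUE)
#' mean(ph$image[ph$mask])
#' @export
render_sac_image <- function(params, expander = FALSE) {
  stopifnot(inherits(params, "phantom_params"))
  s <- params$image_size
  ctr <- (s + 1) / 2
  rr <- matrix(seq_len(s), s, s) - ctr
  cc <- t(rr)
  rad <- sqrt(rr^2 + cc^2)
  lumen_r <- params$lumen_radius_frac * params$sac_radius_px
  mask <- rad <= params$sac_radius_px & rad > lumen_r
  if (!any(mask))
    stop(paste0("degenerate geometry: annulus mask is empty ",
                "(check sac_radius_px / lumen_radius_frac)"), call. = FALSE)

  with_seed(params$seed, {
    img <- matrix(BACKGROUND_VALUE, s, s)
    img[rad <= lumen_r] <- LUMEN_VALUE
    noise <- matrix(stats::rnorm(s * s, 0, params$thrombus_sd), s, s)
    noise <- gauss_blur(noise, params$smoothing_sigma_px)
    img[mask] <- params$thrombus_mean + noise[mask]
    if (expander && params$n_pockets > 0L) {
      idx <- which(mask)
      centres <- idx[sample.int(length(idx), params$n_pockets, replace = TRUE)]
      r0 <- ((centres - 1L) %% s) + 1L
      c0 <- ((centres - 1L) %/% s) + 1L
      rows <- matrix(seq_len(s), s, s); cols <- t(rows)
      for (k in seq_len(params$n_pockets)) {
        d2 <- (rows - r0[k])^2 + (cols - c0[k])^2
        img <- img + params$pocket_amplitude *
          exp(-d2 / (2 * params$pocket_sigma_px^2))
      }
    }
    img <- pmin(pmax(img, 0), INTENSITY_MAX)
    list(image = img, mask = mask)
  })
}

#' Parameters of the synthetic phantom cohort
#'
#' Defaults reproduce the study conditions of the cohort the pipeline was
#' designed for: 99 patients of whom 38 expanded; first-interval sac
#' volumes 156.9 +/- 133.6 cc; relative volume change 9.8% +/- 9.9% in the
#' expansion group and -8.7% +/- 10.7% in the non-expansion group; and the
#' observed endoleak mix per group (expansion: 6 type I, 6 type II of 38;
#' non-expansion: 1 type I, 6 type II of 61).
#'
#' @param n_total number of patients.
#' @param n_expanders number of expansion-group patients (<= `n_total`).
#' @param v1_mean,v1_sd mean/SD (cc) of the first-interval volume; drawn
#'   log-normal with moments matched, since the SD is of the order of the
#'   mean and volumes must be positive.
#' @param delta_exp_mean,delta_exp_sd relative volume change distribution
#'   (fractions) for expanders, drawn normal.
#' @param delta_non_mean,delta_non_sd same for non-expanders.
#' @param endoleak_rates 2 x 3 numeric matrix of per-group probabilities,
#'   rows `expansion`/`non_expansion`, columns `type_I`/`type_II`/`none`;
#'   each row must sum to 1 (within tolerance).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_total = 99L, n_expanders = 38L,
                          v1_mean = 156.9, v1_sd = 133.6,
                          delta_exp_mean = 0.098, delta_exp_sd = 0.099,
                          delta_non_mean = -0.087, delta_non_sd = 0.107,
                          endoleak_rates = NULL, seed = 1L) {
  if (is.null(endoleak_rates)) {
    endoleak_rates <- rbind(expansion = c(6, 6, 26) / 38,
                            non_expansion = c(1, 6, 54) / 61)
    colnames(endoleak_rates) <- c("type_I", "type_II", "none")
  }
  p <- list(n_total = as.integer(n_total), n_expanders = as.integer(n_expanders),
            v1_mean = v1_mean, v1_sd = v1_sd,
            delta_exp_mean = delta_exp_mean, delta_exp_sd = delta_exp_sd,
            delta_non_mean = delta_non_mean, delta_non_sd = delta_non_sd,
            endoleak_rates = endoleak_rates, seed = as.integer(seed))
  if (p$n_total < 1L) stop("`n_total` must be >= 1", call. = FALSE)
  if (p$n_expanders < 0L || p$n_expanders > p$n_total)
    stop("`n_expanders` must lie in [0, n_total]", call. = FALSE)
  if (p$v1_mean <= 0 || p$v1_sd < 0)
    stop("`v1_mean` must be > 0 and `v1_sd` >= 0", call. = FALSE)
  if (p$delta_exp_sd < 0 || p$delta_non_sd < 0)
    stop("delta SDs must be >= 0", call. = FALSE)
  er <- p$endoleak_rates
  if (!is.matrix(er) || !all(dim(er) == c(2, 3)) || any(er < 0) ||
      any(abs(rowSums(er) - 1) > 1e-8))
    stop("`endoleak_rates` must be a 2 x 3 matrix of probabilities with rows summing to 1",
         call. = FALSE)
  class(p) <- "cohort_params"
  p
}

# Log-normal draw with the requested arithmetic mean and SD (moment fit).
rlnorm_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Clinical covariates, drawn independently of the expansion group from
# distributions matching the published cohort summaries (no clinical
# variable discriminated the groups there, so phantom covariates carry no
# label signal by construction).
draw_covariates <- function(n) {
  trunc0 <- function(x) pmax(x, 0)
  data.frame(
    age = round(stats::rnorm(n, 68.5, 8.3), 1),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(87, 12) / 99),
    max_diameter = round(trunc0(stats::rnorm(n, 50.9, 14.8)), 1),
    hypertension = stats::rbinom(n, 1, 60 / 96),
    hypertension_duration = round(trunc0(stats::rnorm(n, 9.7, 13.7)), 1),
    systolic_pressure = round(stats::rnorm(n, 146.3, 26.4), 1),
    diastolic_pressure = round(stats::rnorm(n, 83.6, 16.1), 1),
    heart_disease = stats::rbinom(n, 1, 33 / 99),
    diabetes = stats::rbinom(n, 1, 14 / 98),
    smoking_history = stats::rbinom(n, 1, 61 / 98),
    current_smoking = stats::rbinom(n, 1, 31 / 95),
    smoking_duration = round(trunc0(stats::rnorm(n, 21.6, 20.4)), 1),
    alcohol_history = stats::rbinom(n, 1, 31 / 97),
    current_alcohol = stats::rbinom(n, 1, 19 / 97),
    total_cholesterol = round(stats::rnorm(n, 4.2, 1.0), 2),
    triglyceride = round(trunc0(stats::rnorm(n, 1.6, 0.9)), 2),
    hdl_c = round(trunc0(stats::rnorm(n, 1.0, 0.3)), 2),
    ldl_c = round(trunc0(stats::rnorm(n, 2.5, 1.0)), 2),
    stringsAsFactors = FALSE)
}

clinical_covariate_names <- function() {
  c("age", "sex", "max_diameter", "hypertension", "hypertension_duration",
    "systolic_pressure", "diastolic_pressure", "heart_disease", "diabetes",
    "smoking_history", "current_smoking", "smoking_duration",
    "alcohol_history", "current_alcohol", "total_cholesterol",
    "triglyceride", "hdl_c", "ldl_c")
}

#' Generate a synthetic phantom cohort
#'
#' Writes one sac image and annulus mask per patient (16-bit grey TIFF and
#' 8-bit PNG respectively) under `out_dir`, together with `manifest.csv`
#' and a JSON sidecar recording every parameter and seed. Expansion-group
#' patients get heterogeneous (pocketed) sacs; volumes, endoleak types and
#' clinical covariates are drawn per [cohort_params()].
#'
#' @param cparams a [cohort_params()] object.
#' @param pparams a [phantom_params()] object; per-patient image seeds are
#'   derived from `pparams$seed`.
#' @param out_dir output directory, created if needed. May be `NULL` when
#'   `write_images = FALSE`.
#' @param write_images logical; set `FALSE` to generate volumes, labels
#'   and covariates only (no raster output), e.g. for large calibration
#'   cohorts.
#' @return The manifest as a data frame (invisibly written to
#'   `out_dir/manifest.csv` when images are written), with attribute
#'   `"dir"` set to `out_dir`. Columns: `id`, `group`, `image`, `mask`
#'   (relative paths or `NA`), `V1`, `V2`, `endoleak`, then the clinical
#'   covariates.
#' @export
generate_cohort <- function(cparams, pparams = phantom_params(),
                            out_dir = NULL, write_images = TRUE) {
  stopifnot(inherits(cparams, "cohort_params"),
            inherits(pparams, "phantom_params"))
  n <- cparams$n_total
  n_exp <- cparams$n_expanders
  if (write_images) {
    if (is.null(out_dir)) stop("`out_dir` is required when writing images",
                               call. = FALSE)
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("could not create `out_dir`", call. = FALSE)
  }

  man <- with_seed(cparams$seed, {
    group <- rep(c("expansion", "non_expansion"), c(n_exp, n - n_exp))
    V1 <- rlnorm_moments(n, cparams$v1_mean, cparams$v1_sd)
    delta <- ifelse(group == "expansion",
                    stats::rnorm(n, cparams$delta_exp_mean, cparams$delta_exp_sd),
                    stats::rnorm(n, cparams$delta_non_mean, cparams$delta_non_sd))
    V2 <- pmax(V1 * (1 + delta), 0)
    leak_levels <- colnames(cparams$endoleak_rates)
    endoleak <- vapply(group, function(g) {
      sample(leak_levels, 1L, prob = cparams$endoleak_rates[g, ])
    }, character(1), USE.NAMES = FALSE)
    cbind(data.frame(id = sprintf("P%03d", seq_len(n)), group = group,
                     image = NA_character_, mask = NA_character_,
                     V1 = V1, V2 = V2, endoleak = endoleak,
                     stringsAsFactors = FALSE),
          draw_covariates(n))
  })

  if (write_images) {
    for (i in seq_len(n)) {
      pp <- pparams
      pp$seed <- (pparams$seed + i) %% .Machine$integer.max
      ph <- render_sac_image(pp, expander = man$group[i] == "expansion")
      man$image[i] <- file.path("images", sprintf("%s.tif", man$id[i]))
      man$mask[i] <- file.path("masks", sprintf("%s.png", man$id[i]))
      write_gray_tiff(ph$image, file.path(out_dir, man$image[i]))
      write_mask_png(ph$mask, file.path(out_dir, man$mask[i]))
    }
    utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    sidecar <- list(cohort_params = unclass(cparams),
                    phantom_params = unclass(pparams),
                    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(sidecar, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(man, "dir") <- if (write_images) out_dir else NA_character_
  man
}
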