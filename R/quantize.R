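#' Quantize a masked region of interest to G grey levels
#'
#' Reduces the in-mask intensity range to `G` equal-width bins, the standard
#' preprocessing step before grey-level matrix texture analysis. Bin edges
#' span the minimum and maximum of the *in-mask* intensities (per-ROI
#' min--max binning), which makes all downstream texture features invariant
#' to affine rescaling of the input intensities (scanner offset/gain).
#'
#' The in-mask maximum maps to level `G`; a constant ROI maps entirely to
#' level 1. Pixels outside the mask carry `NA` and never enter any texture
#' statistic.
#'
#' @param image numeric matrix of intensities.
#' @param mask logical (or 0/1 numeric) matrix of the same dimensions;
#'   `TRUE` marks region-of-interest pixels.
#' @param G integer number of grey levels (>= 2). Default 16, the level
#'   count conventionally used to suppress noise in CT texture work.
#' @return An object of class `quantized_roi`: a list with `levels`
#'   (integer matrix, values in `1:G` inside the mask, `NA` outside),
#'   `mask` (logical matrix), `G`, and `source_range` (in-mask min/max of
#'   the raw intensities).
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' q <- quantize(img, matrix(TRUE, 8, 8), G = 4)
#' table(q$levels)
#' @export
quantize <- function(image, mask, G = 16L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  mask <- as_mask(mask)
  if (!identical(dim(image), dim(mask)))
    stop("`image` and `mask` must have identical dimensions", call. = FALSE)
  G <- as.integer(G)
  if (is.na(G) || G < 2L) stop("`G` must be an integer >= 2", call. = FALSE)
  n_in <- sum(mask)
  if (n_in == 0L) stop("mask is empty: no in-mask pixels to quantize", call. = FALSE)
  if (n_in < G)
    warning(sprintf("ROI has %d in-mask pixels, fewer than G = %d levels", n_in, G))
  vals <- image[mask]
  if (any(!is.finite(vals)))
    stop("non-finite intensities inside the mask", call. = FALSE)
  lo <- min(vals); hi <- max(vals)
  levels <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    levels[mask] <- 1L
  } else {
    levels[mask] <- pmin.int(G, as.integer(floor((vals - lo) / (hi - lo) * G)) + 1L)
  }
  structure(
    list(levels = levels, mask = mask, G = G, source_range = c(lo, hi)),
    class = "quantized_roi"
  )
}

as_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical or 0/1 numeric matrix", call. = FALSE)
  mask[is.na(mask)] <- FALSE
  mask
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("Quantized ROI: %d x %d image, %d in-mask pixels, G = %d levels\n",
              nrow(x$levels), ncol(x$levels), sum(x$mask), x$G))
  cat(sprintf("  source intensity range: [%g, %g]\n",
              x$source_range[1], x$source_range[2]))
  invisible(x)
}

#' Volume of a binary mask in cubic centimetres
#'
#' Voxel-counting volume: the number of set voxels times the voxel volume
#' implied by the axis spacings. This replaces workstation-based volumetry
#' when a delineated 3D mask is available.
#'
#' @param mask 3D logical/0-1 array (a 2D matrix is accepted and treated as
#'   a single slice).
#' @param spacing numeric vector of per-axis voxel spacing in millimetres;
#'   recycled to the array rank if length 1.
#' @return Volume in cc (1 cc = 1000 mm^3).
#' @examples
#' volume_from_mask(array(1, c(10, 10, 10)), spacing = c(1, 1, 1))  # 1 cc
#' @export
volume_from_mask <- function(mask, spacing) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  if (!(is.array(mask) && length(dim(mask)) == 3L))
    stop("`mask` must be a 3D array (or a 2D matrix)", call. = FALSE)
  nd <- length(dim(mask))
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(spacing) != nd)
    stop("`spacing` must have one entry per mask axis", call. = FALSE)
  if (!is.numeric(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive on all axes", call. = FALSE)
  storage.mode(mask) <- "double"
  sum(mask != 0) * prod(spacing) / 1000
}
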