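# Raster and manifest I/O. Images travel as 16-bit single-channel TIFF,
# masks as 8-bit {0, 255} PNG; 3D masks may come as NIfTI. Texture
# features are invariant to the container's intensity scaling because
# quantization rebins per-ROI min--max.

write_gray_tiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img / INTENSITY_MAX, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a grey-scale raster image as a numeric matrix
#'
#' Reads PNG or TIFF by extension. Multi-channel input is reduced to its
#' first channel. Values are returned on the scale the reader provides
#' (0..1 for both formats); downstream quantization is scale-invariant.
#'
#' @param path file path (.png, .tif/.tiff).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported raster extension '.%s'", ext),
                     call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read a binary mask (2D raster or 3D NIfTI)
#'
#' PNG/TIFF masks become logical matrices (non-zero = in-mask); `.nii` /
#' `.nii.gz` masks become logical 3D arrays suitable for
#' [volume_from_mask()].
#'
#' @param path file path.
#' @return Logical matrix or 3D array.
#' @export
read_mask <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    return(arr != 0)
  }
  read_gray_image(path) != 0
}

#' Read a cohort manifest
#'
#' @param path path to a `manifest.csv` or to a cohort directory
#'   containing one.
#' @return Data frame with attribute `"dir"` pointing at the directory
#'   the image/mask paths are relative to.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path),
                               call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(man, "dir") <- dirname(path)
  man
}

#' Extract the 25 texture features for every patient in a manifest
#'
#' Reads each patient's image and mask, quantizes the masked ROI to `G`
#' levels and computes the 13 + 7 + 5 direction-averaged texture features.
#'
#' @param manifest data frame as returned by [generate_cohort()] or
#'   [read_manifest()], with `image` and `mask` path columns.
#' @param dir directory the paths are relative to; defaults to the
#'   manifest's `"dir"` attribute.
#' @param G grey levels for quantization (default 16).
#' @param d inter-pixel distance (default 1).
#' @return Data frame: `id` plus 25 feature columns (`glcm_*`, `glrlm_*`,
#'   `gldm_*`).
#' @export
extract_cohort_features <- function(manifest, dir = attr(manifest, "dir"),
                                    G = 16L, d = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("id", "image", "mask") %in% names(manifest)))
  if (is.null(dir) || is.na(dir))
    stop("no base directory: pass `dir` or use a manifest with images on disk",
         call. = FALSE)
  feats <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_gray_image(file.path(dir, manifest$image[i]))
    msk <- read_mask(file.path(dir, manifest$mask[i]))
    roi <- quantize(img, msk, G = G)
    texture_features(roi, d = d)
  })
  out <- as.data.frame(do.call(rbind, feats))
  cbind(data.frame(id = manifest$id, stringsAsFactors = FALSE), out)
}
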