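# Grey-level difference method: first-order statistics of absolute
# grey-level differences at a fixed displacement (Weszka's five features).

#' Grey-level difference histogram for one displacement
#'
#' For every in-mask pixel whose delta-neighbour is also in-mask,
#' accumulates the absolute grey-level difference |level(x) - level(x +
#' delta)| and normalizes to a probability vector over k = 0..G-1.
#'
#' @param roi a [quantize()]d ROI.
#' @param delta integer displacement `c(drow, dcol)` in pixels.
#' @return A `gldm` object: named probability vector `pdelta` over
#'   differences `0:(G-1)`, with attributes `delta` and `n_pairs`.
#' @examples
#' q <- quantize(matrix(c(0, 1, 1, 0), 2, 2), matrix(TRUE, 2, 2), G = 2)
#' gldm_histogram(q, delta = c(0, 1))
#' @export
gldm_histogram <- function(roi, delta = c(0L, 1L)) {
  stopifnot(inherits(roi, "quantized_roi"))
  if (length(delta) != 2L || any(delta != as.integer(delta)))
    stop("`delta` must be an integer displacement c(drow, dcol)", call. = FALSE)
  if (sum(roi$mask) == 0L) stop("mask is empty", call. = FALSE)
  pr <- level_pairs(roi$levels, as.integer(delta[1]), as.integer(delta[2]))
  if (length(pr$a) == 0L)
    stop(sprintf("no in-mask pixel pair at displacement (%d, %d)",
                 delta[1], delta[2]), call. = FALSE)
  G <- roi$G
  k <- abs(pr$a - pr$b)                    # 0 .. G-1
  counts <- tabulate(k + 1L, nbins = G)
  p <- counts / sum(counts)
  names(p) <- 0:(G - 1)
  structure(p, class = "gldm", delta = as.integer(delta), n_pairs = length(k))
}

#' @export
print.gldm <- function(x, ...) {
  cat(sprintf("GLDM difference histogram (delta = (%d, %d), %d pairs)\n",
              attr(x, "delta")[1], attr(x, "delta")[2], attr(x, "n_pairs")))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

gldm_feature_names <- c("contrast", "asm", "entropy", "mean",
                        "inverse_difference_moment")

weszka5 <- function(p) {
  k <- as.numeric(names(p))
  c(contrast = sum(k^2 * p),
    asm      = sum(p^2),
    entropy  = -sum(p * xlog2(p)),
    mean     = sum(k * p),
    idm      = sum(p / (k^2 + 1)))
}

#' The 5 GLDM texture features
#'
#' Per displacement delta in (0,d), (d,0), (d,d), (d,-d) computes contrast,
#' angular second moment, entropy, mean and inverse difference moment of
#' the grey-level difference histogram, then averages each over the four
#' displacements under the isotropic-texture assumption. The inverse
#' difference moment uses the k^2 + 1 denominator so the zero-difference
#' bin is well defined.
#'
#' @param roi a [quantize()]d ROI.
#' @param d displacement magnitude in pixels (default 1, shared with the
#'   co-occurrence features).
#' @param deltas optional list of integer displacements overriding the
#'   default four (e.g. `list(c(0, 1))` for a single direction).
#' @return Named numeric vector of length 5, names prefixed `gldm_`.
#' @export
gldm_features <- function(roi, d = 1L, deltas = NULL) {
  d <- as.integer(d)
  if (is.null(deltas)) deltas <- list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
  per_dir <- vapply(deltas, function(dl) weszka5(gldm_histogram(roi, dl)),
                    numeric(5))
  out <- rowMeans(per_dir)
  names(out) <- paste0("gldm_", gldm_feature_names)
  out
}

#' All 25 grey-level texture features of a masked ROI
#'
#' Convenience wrapper computing the 13 co-occurrence (GLCM), 7 run-length
#' (GLRLM) and 5 grey-level difference (GLDM) features of one quantized
#' ROI, each direction-averaged.
#'
#' @param roi a [quantize()]d ROI.
#' @param d inter-pixel distance / displacement magnitude (default 1).
#' @return Named numeric vector of length 25.
#' @export
texture_features <- function(roi, d = 1L) {
  c(glcm_features(roi, d = d), glrlm_features(roi), gldm_features(roi, d = d))
}
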