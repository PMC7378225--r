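# Grey-level co-occurrence matrix and the 13 classic Haralick features.
#
# Direction conventions (row, col displacement for angle theta, distance d):
#   0 deg  -> (0,  d)   horizontal
#   45 deg -> (-d, d)   up-right anti-diagonal
#   90 deg -> (-d, 0)   vertical
#   135deg -> (-d,-d)   up-left diagonal
# Pairs are counted symmetrically (both orders), so the sign of the
# displacement is immaterial.

glcm_offsets <- c(`0` = 0, `45` = 45, `90` = 90, `135` = 135)

theta_to_disp <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("`theta` must be one of 0, 45, 90, 135 (degrees)", call. = FALSE))
}

# Extract the aligned level pairs (a, b) at displacement (dr, dc), keeping
# only pairs with both pixels in-mask. Shared by GLCM and GLDM.
level_pairs <- function(levels, dr, dc) {
  n <- nrow(levels); m <- ncol(levels)
  r <- seq.int(max(1L, 1L - dr), min(n, n - dr))
  c <- seq.int(max(1L, 1L - dc), min(m, m - dc))
  if (length(r) == 0L || length(c) == 0L)
    return(list(a = integer(0), b = integer(0)))
  a <- levels[r, c, drop = FALSE]
  b <- levels[r + dr, c + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Estimates the second-order joint probability of observing grey levels
#' (i, j) in two in-mask pixels separated by distance `d` along direction
#' `theta`. Pairs are counted in both orders (symmetric matrix); pairs with
#' either pixel outside the mask are skipped; the count matrix is
#' normalized to sum to 1.
#'
#' @param roi a [quantize()]d ROI.
#' @param d inter-pixel distance in pixels (>= 1).
#' @param theta direction angle in degrees: 0, 45, 90 or 135.
#' @return A `glcm` object: the G x G probability matrix `P` with
#'   attributes `d`, `theta` and `n_pairs` (ordered pair count).
#' @examples
#' q <- quantize(matrix(c(0, 1, 1, 0), 2, 2), matrix(TRUE, 2, 2), G = 2)
#' glcm_matrix(q, d = 1, theta = 0)
#' @export
glcm_matrix <- function(roi, d = 1L, theta = 0) {
  stopifnot(inherits(roi, "quantized_roi"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("`d` must be an integer >= 1", call. = FALSE)
  if (sum(roi$mask) == 0L) stop("mask is empty", call. = FALSE)
  disp <- theta_to_disp(theta, d)
  pr <- level_pairs(roi$levels, disp[1], disp[2])
  if (length(pr$a) == 0L)
    stop(sprintf("no in-mask pixel pair at d = %d, theta = %s degrees", d, theta),
         call. = FALSE)
  G <- roi$G
  counts <- tabulate((pr$a - 1L) * G + pr$b, nbins = G * G)
  C <- matrix(counts, G, G, byrow = TRUE)   # row = first pixel level
  C <- C + t(C)                             # both orders
  P <- C / sum(C)
  structure(P, class = c("glcm", "matrix"), d = d, theta = theta,
            n_pairs = sum(C))
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM (G = %d, d = %d, theta = %g deg, %d ordered pairs)\n",
              nrow(x), attr(x, "d"), attr(x, "theta"), attr(x, "n_pairs")))
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))], ...)
  invisible(x)
}

glcm_feature_names <- c(
  "energy", "contrast", "correlation", "entropy", "inverse_difference_moment",
  "sum_average", "sum_variance", "sum_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "imc1", "imc2")

# The 13 Haralick (1973) features of a single normalized co-occurrence
# matrix. Logs are base 2; 0*log(0) = 0; correlation of a zero-variance
# marginal is defined as 0; IMC2's radicand is clipped at 0.
haralick13 <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)          # row index (first level)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sdx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  # distributions of i+j (2..2G) and |i-j| (0..G-1)
  psum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), numeric(1))
  pdif <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * G); kd <- 0:(G - 1)

  energy   <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  corr     <- if (sdx > 0 && sdy > 0) (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  entropy  <- -sum(P * xlog2(P))
  idm      <- sum(P / (1 + (i - j)^2))
  sum_avg  <- sum(ks * psum)
  sum_var  <- sum((ks - sum_avg)^2 * psum)
  sum_ent  <- -sum(psum * xlog2(psum))
  dif_avg  <- sum(kd * pdif)
  dif_var  <- sum((kd - dif_avg)^2 * pdif)
  dif_ent  <- -sum(pdif * xlog2(pdif))

  hx <- -sum(px * xlog2(px)); hy <- -sum(py * xlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(energy, contrast, corr, entropy, idm, sum_avg, sum_var, sum_ent,
    dif_avg, dif_var, dif_ent, imc1, imc2)
}

#' The 13 GLCM (Haralick) texture features
#'
#' Computes, for each of the four directions (0, 45, 90, 135 degrees), the
#' classic 13-feature Haralick set -- energy (angular second moment),
#' contrast (inertia), correlation, entropy, inverse difference moment, sum
#' average/variance/entropy, difference average/variance/entropy and the two
#' information measures of correlation -- and averages each feature over the
#' directions under the isotropic-texture assumption.
#'
#' @param roi a [quantize()]d ROI.
#' @param d inter-pixel distance (default 1).
#' @param average `"features"` (default): compute the 13 features per
#'   direction, then average each across directions. `"matrices"`: average
#'   the four co-occurrence matrices first and compute the features once.
#' @param thetas directions in degrees; default all four.
#' @return Named numeric vector of length 13, names prefixed `glcm_`.
#' @export
glcm_features <- function(roi, d = 1L, average = c("features", "matrices"),
                          thetas = c(0, 45, 90, 135)) {
  average <- match.arg(average)
  mats <- lapply(thetas, function(th) glcm_matrix(roi, d = d, theta = th))
  if (average == "features") {
    per_dir <- vapply(mats, haralick13, numeric(13))
    out <- rowMeans(per_dir)
  } else {
    Pbar <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
    out <- haralick13(Pbar)
  }
  names(out) <- paste0("glcm_", glcm_feature_names)
  out
}
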