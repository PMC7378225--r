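# Grey-level run-length matrix and the 7 Galloway/Chu features.
#
# A run is a maximal sequence of collinear in-mask pixels sharing one grey
# level; masked-out pixels break runs. Every in-mask pixel belongs to
# exactly one run per direction, so sum_ij j * R(i, j) = Np.

# Concatenate the image lines along direction `theta` into one vector with
# NA separators between lines; NA also marks out-of-mask pixels, so a
# single rle() pass yields all runs with mask breaks applied.
direction_lines <- function(levels, theta) {
  switch(as.character(theta),
         "0"   = as.vector(rbind(t(levels), NA_integer_)),         # rows
         "90"  = as.vector(rbind(levels, NA_integer_)),            # columns
         "45"  = {                                                 # anti-diagonals
           grp <- row(levels) + col(levels)
           unlist(lapply(split(levels, grp), function(v) c(v, NA_integer_)),
                  use.names = FALSE)
         },
         "135" = {                                                 # diagonals
           grp <- col(levels) - row(levels)
           unlist(lapply(split(levels, grp), function(v) c(v, NA_integer_)),
                  use.names = FALSE)
         },
         stop("`theta` must be one of 0, 45, 90, 135 (degrees)", call. = FALSE))
}

#' Grey-level run-length matrix for one direction
#'
#' Counts maximal runs of equal grey level along direction `theta`. Runs
#' are broken by the mask boundary: masked-out pixels never join two
#' in-mask segments.
#'
#' @param roi a [quantize()]d ROI.
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @return A `glrlm` object: G x Lmax matrix `R` of run counts (rows =
#'   grey level, columns = run length) with attributes `theta`, `Nr`
#'   (total runs) and `Np` (in-mask pixels).
#' @examples
#' q <- quantize(matrix(c(10, 10, 20, 20, 20), 1, 5), matrix(TRUE, 1, 5), G = 2)
#' glrlm_matrix(q, theta = 0)
#' @export
glrlm_matrix <- function(roi, theta = 0) {
  stopifnot(inherits(roi, "quantized_roi"))
  Np <- sum(roi$mask)
  if (Np == 0L) stop("mask is empty", call. = FALSE)
  v <- direction_lines(roi$levels, theta)
  r <- rle(ifelse(is.na(v), -1L, v))
  keep <- r$values > 0L
  lev <- r$values[keep]; len <- r$lengths[keep]
  G <- roi$G
  Lmax <- max(len)
  R <- matrix(0, G, Lmax)
  for (k in seq_along(lev)) R[lev[k], len[k]] <- R[lev[k], len[k]] + 1
  structure(R, class = c("glrlm", "matrix"), theta = theta,
            Nr = sum(R), Np = Np)
}

#' @export
print.glrlm <- function(x, ...) {
  cat(sprintf("GLRLM (G = %d, Lmax = %d, theta = %g deg, Nr = %d runs, Np = %d px)\n",
              nrow(x), ncol(x), attr(x, "theta"), attr(x, "Nr"), attr(x, "Np")))
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x)), drop = FALSE], ...)
  invisible(x)
}

glrlm_feature_names <- c("sre", "lre", "gln", "rln", "rp", "lglre", "hglre")

galloway7 <- function(R, Np) {
  Nr <- sum(R)
  i2 <- matrix(seq_len(nrow(R))^2, nrow(R), ncol(R))
  j2 <- matrix(rep(seq_len(ncol(R))^2, each = nrow(R)), nrow(R), ncol(R))
  c(sre   = sum(R / j2) / Nr,
    lre   = sum(R * j2) / Nr,
    gln   = sum(rowSums(R)^2) / Nr,
    rln   = sum(colSums(R)^2) / Nr,
    rp    = Nr / Np,
    lglre = sum(R / i2) / Nr,
    hglre = sum(R * i2) / Nr)
}

#' The 7 GLRLM run-length texture features
#'
#' Per direction computes short-run emphasis (SRE), long-run emphasis
#' (LRE), grey-level nonuniformity (GLN), run-length nonuniformity (RLN),
#' run percentage (RP), low grey-level run emphasis (LGLRE) and high
#' grey-level run emphasis (HGLRE) -- the classical Galloway/Chu set --
#' then averages each over the four directions.
#'
#' @param roi a [quantize()]d ROI.
#' @param thetas directions in degrees; default all four.
#' @return Named numeric vector of length 7, names prefixed `glrlm_`.
#' @export
glrlm_features <- function(roi, thetas = c(0, 45, 90, 135)) {
  per_dir <- vapply(thetas, function(th) {
    R <- glrlm_matrix(roi, theta = th)
    galloway7(unclass(R), attr(R, "Np"))
  }, numeric(7))
  out <- rowMeans(per_dir)
  names(out) <- paste0("glrlm_", glrlm_feature_names)
  out
}
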