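# Independent brute-force oracles for the grey-level texture statistics.
# Deliberately naive: explicit loops over pixel pairs / line scans, direct
# formula evaluation, no code shared with the package internals.

bf_disp <- function(theta, d = 1L) {
  switch(as.character(theta),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

# symmetric co-occurrence probabilities by looping over every pixel twice
bf_glcm <- function(levels, mask, d, theta, G = max(levels[mask])) {
  dd <- bf_disp(theta, d)
  C <- matrix(0, G, G)
  n <- nrow(levels); m <- ncol(levels)
  for (r in seq_len(n)) for (c in seq_len(m)) {
    if (!mask[r, c]) next
    for (s in c(1, -1)) {
      r2 <- r + s * dd[1]; c2 <- c + s * dd[2]
      if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m && mask[r2, c2])
        C[levels[r, c], levels[r2, c2]] <- C[levels[r, c], levels[r2, c2]] + 1
    }
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

log2z <- function(p) if (p > 0) log2(p) else 0

# direct Haralick formula evaluation with scalar loops
bf_haralick <- function(P) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sdx <- sqrt(sum(((1:G) - mux)^2 * px)); sdy <- sqrt(sum(((1:G) - muy)^2 * py))
  energy <- 0; contrast <- 0; entropy <- 0; idm <- 0; cross <- 0
  psum <- numeric(2 * G); pdif <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    entropy <- entropy - p * log2z(p)
    idm <- idm + p / (1 + (i - j)^2)
    cross <- cross + i * j * p
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  corr <- if (sdx > 0 && sdy > 0) (cross - mux * muy) / (sdx * sdy) else 0
  sum_avg <- 0; for (k in 2:(2 * G)) sum_avg <- sum_avg + k * psum[k]
  sum_var <- 0; for (k in 2:(2 * G)) sum_var <- sum_var + (k - sum_avg)^2 * psum[k]
  sum_ent <- 0; for (k in 2:(2 * G)) sum_ent <- sum_ent - psum[k] * log2z(psum[k])
  dif_avg <- 0; for (k in 0:(G - 1)) dif_avg <- dif_avg + k * pdif[k + 1]
  dif_var <- 0; for (k in 0:(G - 1)) dif_var <- dif_var + (k - dif_avg)^2 * pdif[k + 1]
  dif_ent <- 0; for (k in 0:(G - 1)) dif_ent <- dif_ent - pdif[k + 1] * log2z(pdif[k + 1])
  hx <- 0; for (i in 1:G) hx <- hx - px[i] * log2z(px[i])
  hy <- 0; for (j in 1:G) hy <- hy - py[j] * log2z(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    hxy1 <- hxy1 - P[i, j] * log2z(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * log2z(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(energy, contrast, corr, entropy, idm, sum_avg, sum_var, sum_ent,
    dif_avg, dif_var, dif_ent, imc1, imc2)
}

# run-length counts by walking each line pixel-by-pixel
bf_glrlm <- function(levels, mask, theta, G = max(levels[mask])) {
  n <- nrow(levels); m <- ncol(levels)
  lines <- list()
  if (theta == 0) {
    for (r in seq_len(n)) lines[[length(lines) + 1]] <- cbind(r, seq_len(m))
  } else if (theta == 90) {
    for (c in seq_len(m)) lines[[length(lines) + 1]] <- cbind(seq_len(n), c)
  } else if (theta == 45) {   # up-right: start at bottom/left border, step (-1,+1)
    for (s in 2:(n + m)) {
      rs <- seq(min(n, s - 1), max(1, s - m))
      lines[[length(lines) + 1]] <- cbind(rs, s - rs)
    }
  } else if (theta == 135) {  # down-right: step (+1,+1)
    for (k in (-(n - 1)):(m - 1)) {
      rs <- seq(max(1, 1 - k), min(n, m - k))
      lines[[length(lines) + 1]] <- cbind(rs, rs + k)
    }
  }
  runs <- list()
  for (ln in lines) {
    cur_lev <- NA; cur_len <- 0
    for (q in seq_len(nrow(ln))) {
      r <- ln[q, 1]; c <- ln[q, 2]
      lv <- if (mask[r, c]) levels[r, c] else NA
      if (!is.na(lv) && !is.na(cur_lev) && lv == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- lv; cur_len <- if (is.na(lv)) 0 else 1
      }
    }
    if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (length(runs) == 0) return(NULL)
  lens <- vapply(runs, `[`, numeric(1), 2)
  R <- matrix(0, G, max(lens))
  for (rn in runs) R[rn[1], rn[2]] <- R[rn[1], rn[2]] + 1
  R
}

bf_glrlm_features <- function(R, Np) {
  Nr <- sum(R)
  sre <- lre <- gln <- rln <- lglre <- hglre <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    sre <- sre + R[i, j] / j^2
    lre <- lre + R[i, j] * j^2
    lglre <- lglre + R[i, j] / i^2
    hglre <- hglre + R[i, j] * i^2
  }
  for (i in seq_len(nrow(R))) gln <- gln + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) rln <- rln + sum(R[, j])^2
  c(sre, lre, gln, rln, Nr / Np, lglre, hglre) / c(Nr, Nr, Nr, Nr, 1, Nr, Nr)
}

# grey-level difference histogram: one direction only, pixel -> pixel+delta
bf_gldm <- function(levels, mask, delta, G = max(levels[mask])) {
  n <- nrow(levels); m <- ncol(levels)
  counts <- numeric(G)   # differences 0..G-1
  for (r in seq_len(n)) for (c in seq_len(m)) {
    if (!mask[r, c]) next
    r2 <- r + delta[1]; c2 <- c + delta[2]
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m && mask[r2, c2]) {
      k <- abs(levels[r, c] - levels[r2, c2])
      counts[k + 1] <- counts[k + 1] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

bf_gldm_features <- function(p) {
  ks <- seq_along(p) - 1
  contrast <- 0; asm <- 0; ent <- 0; mu <- 0; idm <- 0
  for (q in seq_along(p)) {
    contrast <- contrast + ks[q]^2 * p[q]
    asm <- asm + p[q]^2
    ent <- ent - p[q] * log2z(p[q])
    mu <- mu + ks[q] * p[q]
    idm <- idm + p[q] / (ks[q]^2 + 1)
  }
  c(contrast, asm, ent, mu, idm)
}

# Random masked quantized test images. Density kept high enough that every
# direction has at least one valid pair.
random_masked_roi <- function(nr, nc, G) {
  img <- matrix(sample.int(100, nr * nc, replace = TRUE), nr, nc)
  repeat {
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (sum(mask) >= max(4, G)) {
      roi <- quantize(img, mask, G = G)
      ok <- all(vapply(c(0, 45, 90, 135), function(th) {
        !is.null(bf_glcm(roi$levels, mask, 1, th))
      }, logical(1)))
      if (ok) return(roi)
    }
  }
}
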