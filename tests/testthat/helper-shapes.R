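# Shape rasterizers and independent brute-force oracles used across tests.
# All fixtures are generated in code; nothing is read from disk.

# supersampled rasterization of a star-convex polar shape r(theta) centred at
# ctr = c(row, col) on an n x n grid; returns per-pixel coverage in [0, 1]
raster_polar <- function(rfun, n, ctr, S = 4L) {
  sub <- rep(seq_len(n), each = S) - 0.5 + (rep(seq_len(S), n) - 0.5) / S
  dy <- matrix(sub - ctr[1], n * S, n * S)
  dx <- matrix(sub - ctr[2], n * S, n * S, byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  inside <- rho <= matrix(rfun(as.numeric(th)), n * S, n * S)
  ri <- rep(seq_len(n), each = S)
  t(rowsum(t(rowsum(inside + 0, ri)), ri)) / S^2
}

polar_disk <- function(r) function(t) rep(r, length(t))

polar_ellipse <- function(a, b, phi = 0) {
  function(t) a * b / sqrt((b * cos(t - phi))^2 + (a * sin(t - phi))^2)
}

raster_disk <- function(r, n = NULL, S = 4L) {
  n <- n %||% (2L * ceiling(r) + 21L)
  raster_polar(polar_disk(r), n, c((n + 1) / 2, (n + 1) / 2), S)
}

# analytic contour of a polar shape, sampled densely (no rasterization)
polar_contour <- function(rfun, m = 2048L, ctr = c(100, 100)) {
  th <- seq(0, 2 * pi, length.out = m + 1L)[seq_len(m)]
  r <- rfun(th)
  as_contour(row = ctr[1] + r * sin(th), col = ctr[2] + r * cos(th))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- brute-force oracles ----------------------------------------------------

# gift-wrapping convex hull of integer points (independent of grDevices::chull)
giftwrap_hull <- function(pts) {
  n <- nrow(pts)
  start <- which.min(pts[, 1] + pts[, 2] / (max(pts[, 2]) + 1))
  start <- order(pts[, 1], pts[, 2])[1]
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- 1L
    for (q in seq_len(n)) {
      if (q == p) next
      cr <- (pts[cand, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
            (pts[cand, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      d_cand <- (pts[cand, 1] - pts[p, 1])^2 + (pts[cand, 2] - pts[p, 2])^2
      d_q <- (pts[q, 1] - pts[p, 1])^2 + (pts[q, 2] - pts[p, 2])^2
      if (cand == p || cr < 0 || (cr == 0 && d_q > d_cand)) cand <- q
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  pts[hull, , drop = FALSE]
}

# exhaustive solidity: hull membership tested pixel by pixel with exact
# integer cross products against the gift-wrapped hull
oracle_solidity <- function(mask) {
  idx <- which(mask >= 0.5, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  A <- nrow(pts)
  v <- giftwrap_hull(pts)
  if (nrow(v) <= 2L) return(1)
  # orient CCW
  x <- c(v[, 1], v[1, 1]); y <- c(v[, 2], v[1, 2])
  if (sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)]) < 0)
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  H <- 0L
  for (px in min(pts[, 1]):max(pts[, 1])) {
    for (py in min(pts[, 2]):max(pts[, 2])) {
      ok <- TRUE
      for (i in seq_len(nrow(v))) {
        j <- if (i == nrow(v)) 1L else i + 1L
        cr <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) -
              (v[j, 2] - v[i, 2]) * (px - v[i, 1])
        if (cr < 0) { ok <- FALSE; break }
      }
      if (ok) H <- H + 1L
    }
  }
  A / H
}

# exhaustive point asymmetry by explicit per-pixel reflection lookup
oracle_point_asymmetry <- function(mask) {
  bin <- mask >= 0.5
  idx <- which(bin, arr.ind = TRUE)
  ctr <- colMeans(idx)
  bad <- 0L
  for (i in seq_len(nrow(idx))) {
    rr <- round(2 * ctr[1] - idx[i, 1])
    cc <- round(2 * ctr[2] - idx[i, 2])
    inside <- rr >= 1 && rr <= nrow(bin) && cc >= 1 && cc <= ncol(bin) &&
      bin[rr, cc]
    if (!inside) bad <- bad + 1L
  }
  list(count = bad, fraction = bad / nrow(idx))
}

# random connected blob mask (thresholded smoothed noise, largest component)
random_blob <- function(seed, n = 48L) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  z <- nucleoshape:::ebi_mat(EBImage::gblur(z, sigma = 4))
  m <- z > stats::quantile(z, 0.72)
  lab <- nucleoshape:::label8(m)
  if (max(lab) == 0L) return(random_blob(seed + 1000L, n))
  sz <- tabulate(lab[lab > 0])
  out <- lab == which.max(sz)
  if (sum(out) < 12L) return(random_blob(seed + 1000L, n))
  out
}

# default scene sizes used in detector tests (smaller than the acceptance
# suite; same study conditions otherwise)
mn_scene_spec <- function(n = 50L)
  scene_spec(width = 1500L, height = 1320L, n_nuclei = n,
             micronucleus_prob = 0.2)

inv_scene_spec <- function(n = 50L)
  scene_spec(width = 1200L, height = 1050L, n_nuclei = n,
             invag_count_range = c(0, 5))

bleb_scene_spec <- function(n = 50L)
  scene_spec(width = 1200L, height = 1050L, n_nuclei = n, bleb_prob = 0.3)
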