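# Low-level helpers shared across modules. Pixel convention throughout the
# package: matrices are indexed [row, col], 1-based in R, origin top-left.
# Geometric computations use the plane x = col, y = row.

#' Otsu threshold on raw intensity values
#'
#' Histogram-based Otsu threshold computed directly on the supplied values, in
#' their native units (images are never rescaled on load).
#'
#' @param v numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, nbins)
  sb[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  # plateau between well-separated modes: take the middle of the argmax run
  best <- which(sb >= max(sb) * (1 - 1e-12))
  mids[best[ceiling(length(best) / 2)]]
}

# disc structuring element of integer radius r (3x3 cross-ish disc for r = 1)
disc_brush <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

ebi_mat <- function(x) {
  # strip EBImage class back to a plain matrix
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Euclidean-disc erosion/dilation of radius n (single structuring element,
# not an iterated 3x3 cross: iterating the cross gives a Manhattan ball whose
# diagonal reach is n/sqrt(2), which under-erodes diagonal boundaries)
erode_n <- function(m, n) {
  if (n <= 0) return(m)
  ebi_mat(EBImage::erode(m, disc_brush(as.integer(n))))
}

dilate_n <- function(m, n) {
  if (n <= 0) return(m)
  ebi_mat(EBImage::dilate(m, disc_brush(as.integer(n))))
}

# Opening as n erosions followed by n dilations with the radius-1 disc
# (equivalent to opening by the n-fold composite element).
open_n <- function(m, n) dilate_n(erode_n(m, n), n)

# bounding box of a logical/numeric mask, padded, clipped to the image
mask_bbox <- function(m, pad = 0L) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(m), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(m), max(idx[, 2]) + pad)
  c(r0, r1, c0, c1)
}

# relabel a label mask to consecutive 1..count, ordered by first (raster) pixel
relabel_consecutive <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0L) {
    out <- lab; storage.mode(out) <- "integer"
    return(list(labels = out, count = 0L))
  }
  v <- lab[idx]
  u <- v[!duplicated(v)]  # first-appearance (raster) order
  map <- integer(max(v))
  map[u] <- seq_along(u)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[idx] <- map[v]
  list(labels = out, count = length(u))
}

# 8-connected component labelling (objects 8-connected, background
# 4-connected): EBImage's 4-connected labelling plus union-find merging of
# diagonally adjacent labels; labels consecutive in raster order.
label8 <- function(m) {
  lab <- ebi_mat(EBImage::bwlabel(matrix(as.numeric(m > 0), nrow(m), ncol(m))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]  # down-left diagonal neighbours
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
      x
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[rb] <- ra
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel_consecutive(lab)$labels
}

# bounding boxes of all labels in one pass; matrix with rows r0,r1,c0,c1
label_bboxes <- function(lab) {
  n <- max(lab)
  out <- matrix(NA_integer_, 4, n)
  idx <- which(lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  k <- lab[lab > 0]
  g <- sort(unique(k))
  out[1, g] <- vapply(split(idx[, 1], k), min, numeric(1))
  out[2, g] <- vapply(split(idx[, 1], k), max, numeric(1))
  out[3, g] <- vapply(split(idx[, 2], k), min, numeric(1))
  out[4, g] <- vapply(split(idx[, 2], k), max, numeric(1))
  out
}

label_areas <- function(lab) {
  u <- seq_len(max(lab))
  if (max(lab) == 0) return(integer(0))
  tabulate(lab[lab > 0], nbins = max(lab))
}

label_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(lab > 0, arr.ind = TRUE)
  k <- lab[lab > 0]
  cbind(row = as.numeric(rowsum(idx[, 1], k) / tabulate(k, n)),
        col = as.numeric(rowsum(idx[, 2], k) / tabulate(k, n)))
}

# intersection-over-union of two pixel index sets
iou_sets <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0) return(0)
  i / (length(a) + length(b) - i)
}

equivalent_diameter <- function(area) sqrt(4 * area / pi)

`%||%` <- function(a, b) if (is.null(a)) b else a
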