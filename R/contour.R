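# Sub-pixel contour tracing and boundary-curvature analysis.
#
# Contours live in the plane x = col, y = row and are stored closed
# (first point repeated last), oriented so the signed (shoelace) area is
# positive; with that orientation the signed curvature is positive on convex
# arcs and negative where the boundary indents toward the nuclear interior.

#' Construct a contour object from boundary points
#'
#' @param row,col numeric vectors of boundary coordinates (need not be
#'   closed; the constructor closes and orients them).
#' @param resampled logical; whether the points are uniform in arc length.
#' @return an object of class `nuc_contour`.
#' @export
as_contour <- function(row, col, resampled = FALSE) {
  stopifnot(length(row) == length(col), length(row) >= 8L)
  if (row[1] != row[length(row)] || col[1] != col[length(col)]) {
    row <- c(row, row[1]); col <- c(col, col[1])
  }
  # orient: positive signed area in (x=col, y=row)
  x <- col; y <- row
  a2 <- sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])
  if (a2 < 0) { row <- rev(row); col <- rev(col) }
  structure(list(row = row, col = col, resampled = resampled,
                 n = length(row) - 1L),
            class = "nuc_contour")
}

#' @export
print.nuc_contour <- function(x, ...) {
  cat(sprintf("<nuc_contour> %d points, closed, %s\n", x$n,
              if (x$resampled) "arc-length resampled" else "raw"))
  invisible(x)
}

#' Trace the sub-pixel outer contour of a single object
#'
#' Extracts the 0.5-level iso-contour between foreground and background.
#' Works on binary masks and on graded coverage images (values in `[0, 1]`);
#' holes are filled before tracing so the outer boundary is returned.
#'
#' @param mask numeric matrix; foreground where `>= 0.5`. Must contain
#'   exactly one connected component.
#' @return a [as_contour()] object, ordered, closed, positively oriented.
#' @export
trace_contour <- function(mask) {
  bin <- matrix(as.numeric(mask >= 0.5), nrow(mask), ncol(mask))
  if (sum(bin) == 0) stop("empty mask: nothing to trace")
  lab <- label8(bin)
  if (max(lab) > 1L) stop("mask contains ", max(lab),
                          " connected components; expected exactly one")
  filled <- ebi_mat(EBImage::fillHull(bin))
  # keep graded edge values; force interior holes to foreground
  z <- pmin(pmax(matrix(as.numeric(mask), nrow(mask), ncol(mask)), 0), 1)
  z[filled > 0 & bin == 0] <- 1
  # pad with background so border-touching objects still close
  zp <- matrix(0, nrow(z) + 2L, ncol(z) + 2L)
  zp[2:(nrow(z) + 1L), 2:(ncol(z) + 1L)] <- z
  cl <- grDevices::contourLines(x = 0:(nrow(zp) - 1L), y = 0:(ncol(zp) - 1L),
                                z = zp, levels = 0.5)
  if (length(cl) == 0L) stop("no iso-contour found")
  len <- vapply(cl, function(p) length(p$x), numeric(1))
  p <- cl[[which.max(len)]]
  if (length(p$x) < 8L) stop("object too small: fewer than 8 boundary points")
  as_contour(row = p$x, col = p$y)
}

#' Resample a contour to uniform arc length
#'
#' @param ct a [as_contour()] object.
#' @param m number of sample points (the closing point is added on top).
#' @return a resampled `nuc_contour`.
#' @export
contour_resample <- function(ct, m = 256L) {
  x <- ct$col; y <- ct$row
  d <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, d > 0)  # drop duplicated vertices
  x <- x[keep]; y <- y[keep]
  d <- d[d > 0]
  t <- c(0, cumsum(d))
  L <- t[length(t)]
  s <- seq(0, L, length.out = m + 1L)[seq_len(m)]
  xs <- stats::approx(t, x, xout = s)$y
  ys <- stats::approx(t, y, xout = s)$y
  as_contour(row = c(ys, ys[1]), col = c(xs, xs[1]), resampled = TRUE)
}

# periodic Gaussian smoothing of a closed coordinate sequence (open form,
# length n without the closing point); sigma in sample units
smooth_periodic <- function(v, sigma) {
  n <- length(v)
  if (sigma <= 0) return(v)
  k <- min(n, ceiling(4 * sigma))
  w <- stats::dnorm(seq(-k, k), sd = sigma)
  w <- w / sum(w)
  vv <- c(v[(n - k + 1):n], v, v[1:k])
  as.numeric(stats::filter(vv, w, sides = 2))[(k + 1):(k + n)]
}

#' Smooth a contour along its arc length
#'
#' Periodic Gaussian smoothing of the (resampled) contour coordinates;
#' `sigma_px` is expressed in pixels of arc length. Used to remove the
#' stair-step noise binary rasters impose on the boundary before measuring
#' perimeter or curvature.
#'
#' @param ct a resampled [as_contour()].
#' @param sigma_px smoothing scale in pixels of arc length.
#' @return smoothed `nuc_contour`.
#' @export
contour_smooth <- function(ct, sigma_px) {
  if (sigma_px <= 0) return(ct)
  n <- ct$n
  L <- contour_perimeter(ct)
  sigma_s <- sigma_px * n / L
  xs <- smooth_periodic(ct$col[seq_len(n)], sigma_s)
  ys <- smooth_periodic(ct$row[seq_len(n)], sigma_s)
  as_contour(row = c(ys, ys[1]), col = c(xs, xs[1]), resampled = ct$resampled)
}

#' Polygon perimeter of a contour
#' @param ct a [as_contour()] object.
#' @return total arc length.
#' @export
contour_perimeter <- function(ct) {
  sum(sqrt(diff(ct$col)^2 + diff(ct$row)^2))
}

#' Shoelace area enclosed by a contour
#' @param ct a [as_contour()] object.
#' @return enclosed polygon area (positive).
#' @export
contour_area <- function(ct) {
  x <- ct$col; y <- ct$row
  abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
}

#' Mean negative boundary curvature
#'
#' Signed curvature along the arc-length-resampled, periodically smoothed
#' contour, from first and second derivatives (central differences). With the
#' package's positive orientation convention, curvature is negative exactly
#' where the boundary is concave (indents toward the interior). Returns the
#' mean of the curvature over the concave set, or 0 when the contour is
#' convex everywhere. Units: 1/pixel.
#'
#' @param ct a [as_contour()] object (resampled internally if needed).
#' @param sigma_frac smoothing scale as a fraction of the contour length
#'   (default 0.02); raw raster contours need this to suppress stair-step
#'   curvature noise.
#' @param n_points resampling count (default 256; at least 32 required).
#' @return mean curvature over concave arcs (`<= 0`).
#' @export
mean_negative_curvature <- function(ct, sigma_frac = 0.02, n_points = 256L) {
  if (ct$n < 32L) stop("contour has fewer than 32 points")
  rs <- contour_resample(ct, n_points)
  L <- contour_perimeter(rs)
  sigma_s <- sigma_frac * n_points  # fraction of length = fraction of samples
  n <- rs$n
  x <- smooth_periodic(rs$col[seq_len(n)], sigma_s)
  y <- smooth_periodic(rs$row[seq_len(n)], sigma_s)
  h <- L / n
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  xp <- (x[ip] - x[im]) / (2 * h); yp <- (y[ip] - y[im]) / (2 * h)
  xpp <- (x[ip] - 2 * x + x[im]) / h^2; ypp <- (y[ip] - 2 * y + y[im]) / h^2
  kappa <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  neg <- kappa[kappa < 0]
  if (length(neg) == 0L) 0 else mean(neg)
}
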