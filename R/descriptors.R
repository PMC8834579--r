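# Per-nucleus 2D shape descriptors: form factor, moment-based eccentricity,
# solidity, radial and point asymmetry, and elliptic Fourier descriptors.

#' Form factor (circularity) from area and perimeter
#'
#' `4 * pi * A / P^2`: 1 for a perfect circle, smaller for convoluted shapes
#' (blebs, lobulations). Values above 1, which can only arise from
#' perimeter-estimator bias, are clipped to 1; overshoots beyond 0.1%
#' additionally raise a warning.
#'
#' @param A area (px^2), `> 0`.
#' @param P perimeter (px), `> 0`.
#' @return form factor in `(0, 1]`.
#' @export
form_factor <- function(A, P) {
  if (any(A <= 0) || any(P <= 0)) stop("area and perimeter must be positive")
  ff <- 4 * pi * A / P^2
  if (any(ff > 1 + 1e-3)) {
    warning("form factor > 1 clipped (perimeter-estimator bias)")
  }
  pmin(ff, 1)
}

#' Eccentricity and axis ratio from second central moments
#'
#' Principal second moments of the moment-equivalent ellipse:
#' `e = sqrt(1 - (b/a)^2)` with `a >= b` the semi-axes; 0 for a circle,
#' approaching 1 for elongated shapes. `axis_ratio = a/b` is the nuclear
#' length-to-width ratio.
#'
#' @param mu20,mu02,mu11 second central moments.
#' @return list with `eccentricity`, `axis_ratio` and `degenerate` flag
#'   (TRUE when the minor moment vanishes, e.g. collinear pixels).
#' @export
eccentricity_from_moments <- function(mu20, mu02, mu11) {
  tr <- mu20 + mu02
  d <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + d) / 2
  l2 <- (tr - d) / 2
  if (l2 <= .Machine$double.eps * max(l1, 1)) {
    return(list(eccentricity = 1, axis_ratio = Inf, degenerate = TRUE))
  }
  list(eccentricity = sqrt(1 - l2 / l1),
       axis_ratio = sqrt(l1 / l2),
       degenerate = FALSE)
}

mask_moments <- function(mask) {
  idx <- which(mask >= 0.5, arr.ind = TRUE)
  w <- 1
  r <- idx[, 1]; cc <- idx[, 2]
  n <- length(r)
  mr <- mean(r); mc <- mean(cc)
  list(n = n, centroid = c(row = mr, col = mc),
       mu20 = sum((r - mr)^2) / n,
       mu02 = sum((cc - mc)^2) / n,
       mu11 = sum((r - mr) * (cc - mc)) / n)
}

#' Eccentricity and axis ratio of one object
#'
#' @param mask binary (or coverage) matrix of a single object, area `>= 4` px.
#' @return list with `eccentricity` in `[0,1)` (1 for degenerate collinear
#'   objects, with `degenerate = TRUE`), `axis_ratio >= 1`, `degenerate`.
#' @export
eccentricity_and_axes <- function(mask) {
  mm <- mask_moments(mask)
  if (mm$n < 4L) stop("object area must be >= 4 px")
  eccentricity_from_moments(mm$mu20, mm$mu02, mm$mu11)
}

# convex hull of pixel centres, returned as CCW integer vertex matrix (row,col)
pixel_hull <- function(mask) {
  idx <- which(mask >= 0.5, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])  # x=col, y=row
  h <- grDevices::chull(pts[, 1], pts[, 2])
  v <- pts[h, , drop = FALSE]
  # orient CCW (positive signed area)
  x <- c(v[, 1], v[1, 1]); y <- c(v[, 2], v[1, 2])
  if (sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)]) < 0)
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

#' Solidity of one object
#'
#' Object area divided by the area of its convex hull, both counted on the
#' same pixel-centre convention: the hull area is the number of pixel centres
#' inside or on the convex hull of the object's pixel centres (exact integer
#' arithmetic). Sensitive to lobulation; 1 for convex shapes.
#'
#' @param mask binary (or coverage) matrix of a single object, area `>= 4` px.
#' @return solidity in `(0, 1]`.
#' @export
solidity <- function(mask) {
  bin <- mask >= 0.5
  A <- sum(bin)
  if (A < 4L) stop("object area must be >= 4 px")
  v <- pixel_hull(bin)
  if (nrow(v) <= 2L) return(1)  # collinear: hull has no interior beyond pixels
  bb <- mask_bbox(bin)
  rows <- bb[1]:bb[2]; cols <- bb[3]:bb[4]
  px <- as.vector(outer(rep(1, length(rows)), cols))      # x = col
  py <- as.vector(outer(rows, rep(1, length(cols))))      # y = row
  inside <- rep(TRUE, length(px))
  nv <- nrow(v)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]; ey <- v[j, 2] - v[i, 2]
    cr <- ex * (py - v[i, 2]) - ey * (px - v[i, 1])
    inside <- inside & cr >= 0
    if (!any(inside)) break
  }
  H <- sum(inside)
  A / H
}

#' Radial asymmetry of one object
#'
#' Counts the object pixels outside the largest inscribed circle. The circle
#' centre is the maximum of the Euclidean distance transform (ties broken by
#' the lexicographically smallest (row, col)) and its radius is that maximum
#' distance.
#'
#' @param mask binary (or coverage) matrix of a single object, area `>= 4` px.
#' @return list with `count` (pixels outside the circle), `fraction`
#'   (`count / area`), `center` and `radius` of the inscribed circle.
#' @export
radial_asymmetry <- function(mask) {
  bin <- matrix(as.numeric(mask >= 0.5), nrow(mask), ncol(mask))
  A <- sum(bin)
  if (A < 4L) stop("object area must be >= 4 px")
  dm <- ebi_mat(EBImage::distmap(bin))
  rmax <- max(dm)
  cand <- which(dm == rmax, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  ctr <- cand[1, ]
  idx <- which(bin > 0, arr.ind = TRUE)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  count <- sum(d2 > rmax^2)
  list(count = count, fraction = count / A,
       center = c(row = ctr[[1]], col = ctr[[2]]), radius = rmax)
}

#' Point asymmetry of one object
#'
#' Counts the object pixels whose reflection through the object centroid
#' (rounded to the nearest pixel) is not itself an object pixel; 0 for a
#' centrally symmetric shape up to rounding.
#'
#' @param mask binary (or coverage) matrix of a single object, area `>= 4` px.
#' @return list with `count` and `fraction` (`count / area`).
#' @export
point_asymmetry <- function(mask) {
  bin <- mask >= 0.5
  idx <- which(bin, arr.ind = TRUE)
  A <- nrow(idx)
  if (A < 4L) stop("object area must be >= 4 px")
  ctr <- colMeans(idx)
  rr <- round(2 * ctr[1] - idx[, 1])
  cc <- round(2 * ctr[2] - idx[, 2])
  ok <- rr >= 1 & rr <= nrow(bin) & cc >= 1 & cc <= ncol(bin)
  partner <- rep(FALSE, A)
  partner[ok] <- bin[cbind(rr[ok], cc[ok])]
  count <- sum(!partner)
  list(count = count, fraction = count / A)
}

#' Elliptic Fourier coefficients of a closed contour
#'
#' Closed-form coefficients for a piecewise-linear closed contour
#' (Kuhl-Giardina): the shape is approximated as a sum of harmonic ellipses.
#'
#' @param ct a [as_contour()] object.
#' @param n_harm number of harmonics.
#' @return list with `A0`, `C0` (locus) and an `n_harm x 4` matrix `coef`
#'   with columns `a, b, c, d` (x-cos, x-sin, y-cos, y-sin), plus the total
#'   arc length `T`.
#' @export
efd_coefficients <- function(ct, n_harm = 20L) {
  x <- ct$col; y <- ct$row
  dx <- diff(x); dy <- diff(y)
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  xs <- cumsum(c(x[1], dx)); ys <- cumsum(c(y[1], dy))
  A0 <- sum((xs[-1] + xs[-length(xs)]) / 2 * dt) / T
  C0 <- sum((ys[-1] + ys[-length(ys)]) / 2 * dt) / T
  coef <- matrix(0, n_harm, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harm)) {
    w <- 2 * pi * n / T
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    k <- T / (2 * n^2 * pi^2)
    coef[n, "a"] <- k * sum(dx / dt * dcos)
    coef[n, "b"] <- k * sum(dx / dt * dsin)
    coef[n, "c"] <- k * sum(dy / dt * dcos)
    coef[n, "d"] <- k * sum(dy / dt * dsin)
  }
  list(A0 = A0, C0 = C0, coef = coef, T = T)
}

#' Reconstruct contour points from elliptic Fourier coefficients
#'
#' @param ef output of [efd_coefficients()].
#' @param n_harm harmonics to use (`<=` rows of `ef$coef`).
#' @param t arc-length positions at which to evaluate (default: 256 uniform).
#' @return matrix with columns `row`, `col`.
#' @export
efd_reconstruct <- function(ef, n_harm, t = NULL) {
  if (is.null(t)) t <- seq(0, ef$T, length.out = 257L)[1:256]
  x <- rep(ef$A0, length(t)); y <- rep(ef$C0, length(t))
  for (n in seq_len(n_harm)) {
    w <- 2 * pi * n / ef$T
    x <- x + ef$coef[n, "a"] * cos(w * t) + ef$coef[n, "b"] * sin(w * t)
    y <- y + ef$coef[n, "c"] * cos(w * t) + ef$coef[n, "d"] * sin(w * t)
  }
  cbind(row = y, col = x)
}

#' Elliptic Fourier shape summaries
#'
#' Two summaries of the harmonic-ellipse expansion of the nuclear contour:
#' \describe{
#'   \item{harmonics_needed}{the smallest number of harmonics whose
#'     reconstruction deviates from the contour by at most
#'     `(1 - fidelity) * equivalent radius`. Deviation is geometric (mean
#'     distance from each contour point to the nearest reconstructed point),
#'     so a pure reparametrisation of the same curve costs nothing.}
#'   \item{coefficient_ratio}{high-harmonic to first-harmonic energy ratio
#'     `sum(E_n, n = 2..n_fixed) / E_1` with `E_n = a^2 + b^2 + c^2 + d^2`;
#'     rotation and phase invariant, near 0 for a perfect ellipse, growing
#'     with shape deformation.}
#' }
#'
#' @param ct a closed [as_contour()] with at least 64 points.
#' @param mode `"harmonics_needed"` or `"coefficient_ratio"`.
#' @param n_fixed harmonics for the ratio mode (default 20).
#' @param fidelity reconstruction fidelity for the harmonics mode
#'   (default 0.95).
#' @param n_max search cap for harmonics_needed (default 40).
#' @return a single number (integer count or energy ratio).
#' @export
elliptic_fourier <- function(ct, mode = c("harmonics_needed", "coefficient_ratio"),
                             n_fixed = 20L, fidelity = 0.95, n_max = 40L) {
  mode <- match.arg(mode)
  if (ct$n < 64L) stop("contour must have at least 64 points")
  rs <- contour_resample(ct, max(256L, ct$n))
  if (mode == "coefficient_ratio") {
    ef <- efd_coefficients(rs, n_harm = n_fixed)
    en <- rowSums(ef$coef^2)
    return(sum(en[-1]) / en[1])
  }
  ef <- efd_coefficients(rs, n_harm = n_max)
  r_eq <- sqrt(contour_area(rs) / pi)
  tol <- (1 - fidelity) * r_eq
  m <- rs$n
  px <- rs$col[seq_len(m)]; py <- rs$row[seq_len(m)]
  tdense <- seq(0, ef$T, length.out = 1025L)[1:1024]
  for (N in seq_len(n_max)) {
    rec <- efd_reconstruct(ef, N, t = tdense)
    # geometric deviation: distance from each contour point to the nearest
    # point of the (densely sampled) reconstruction
    d2 <- outer(px, rec[, "col"], `-`)^2 + outer(py, rec[, "row"], `-`)^2
    dev <- mean(sqrt(apply(d2, 1, min)))
    if (dev <= tol) return(N)
  }
  n_max
}

#' All shape descriptors for one object mask
#'
#' Computes the full descriptor record for a single nucleus mask: area,
#' perimeter (sub-pixel contour with stair-step smoothing), equivalent
#' diameter, centroid, form factor, eccentricity, axis ratio, solidity, mean
#' negative curvature, elliptic Fourier summaries (both modes) and the two
#' asymmetry measures (raw count and fraction).
#'
#' @param mask binary (or coverage) matrix of a single object.
#' @param cfg a [nuc_config()].
#' @return one-row data.frame.
#' @export
shape_descriptors <- function(mask, cfg = nuc_config()) {
  bin <- mask >= 0.5
  A <- sum(bin)
  ct <- trace_contour(mask)
  rs <- contour_resample(ct, cfg$contour_points)
  sm <- contour_smooth(rs, cfg$contour_smooth_px)
  P <- contour_perimeter(sm)
  ecc <- eccentricity_and_axes(mask)
  ra <- radial_asymmetry(mask)
  pa <- point_asymmetry(mask)
  mm <- mask_moments(mask)
  data.frame(
    area_px = A,
    perimeter_px = P,
    equivalent_diameter = equivalent_diameter(A),
    centroid_row = mm$centroid[["row"]],
    centroid_col = mm$centroid[["col"]],
    form_factor = form_factor(A, P),
    eccentricity = ecc$eccentricity,
    axis_ratio = ecc$axis_ratio,
    solidity = solidity(mask),
    mean_negative_curvature = mean_negative_curvature(
      sm, sigma_frac = cfg$curvature_sigma_frac, n_points = cfg$contour_points),
    efd_harmonics_needed = elliptic_fourier(
      sm, "harmonics_needed", fidelity = cfg$efd_fidelity),
    efd_coefficient_ratio = elliptic_fourier(
      sm, "coefficient_ratio", n_fixed = cfg$efd_n_fixed),
    radial_asymmetry_count = ra$count,
    radial_asymmetry_frac = ra$fraction,
    point_asymmetry_count = pa$count,
    point_asymmetry_frac = pa$fraction
  )
}

#' Shape descriptors for every retained nucleus in a label mask
#'
#' @param mask integer label mask (see [segment_nuclei()]).
#' @param cfg a [nuc_config()].
#' @param labels which labels to measure (default all).
#' @return data.frame with one row per nucleus, `label` first.
#' @export
nucleus_descriptors <- function(mask, cfg = nuc_config(),
                                labels = NULL) {
  labs <- labels %||% sort(unique(mask[mask > 0]))
  rows <- lapply(labs, function(k) {
    bb <- mask_bbox(mask == k, pad = 2L)
    sub <- mask[bb[1]:bb[2], bb[3]:bb[4]] == k
    d <- shape_descriptors(sub, cfg)
    d$centroid_row <- d$centroid_row + bb[1] - 1
    d$centroid_col <- d$centroid_col + bb[3] - 1
    cbind(label = k, d)
  })
  if (length(rows) == 0L) {
    cols <- c("label", "area_px", "perimeter_px", "equivalent_diameter",
              "centroid_row", "centroid_col", "form_factor", "eccentricity",
              "axis_ratio", "solidity", "mean_negative_curvature",
              "efd_harmonics_needed", "efd_coefficient_ratio",
              "radial_asymmetry_count", "radial_asymmetry_frac",
              "point_asymmetry_count", "point_asymmetry_frac")
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    return(df)
  }
  do.call(rbind, rows)
}
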