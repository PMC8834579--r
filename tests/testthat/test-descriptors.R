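# Shape descriptors against closed forms and brute-force oracles.

test_that("form factor hits its analytic anchors and clips estimator bias", {
  r <- c(1, 10, 50, 200)
  expect_equal(form_factor(pi * r^2, 2 * pi * r), rep(1, 4), tolerance = 1e-12)
  s <- c(2, 10)
  expect_equal(form_factor(s^2, 4 * s), rep(pi / 4, 2), tolerance = 1e-12)
  expect_error(form_factor(0, 1), "positive")
  expect_warning(ff <- form_factor(pi * 100, 2 * pi * 10 * 0.999), "clipped")
  expect_equal(ff, 1)
})

test_that("rasterized disk measures as a circle on every descriptor", {
  cov <- raster_disk(50, 121)
  d <- suppressWarnings(shape_descriptors(cov))
  expect_gte(d$form_factor, 0.98)
  expect_lte(d$eccentricity, 0.05)
  expect_gte(d$solidity, 0.98)
  expect_equal(d$mean_negative_curvature, 0)
  expect_equal(d$efd_harmonics_needed, 1)
  expect_lt(d$efd_coefficient_ratio, 1e-4)
  expect_lt(d$radial_asymmetry_frac, 0.05)
  expect_lt(d$point_asymmetry_frac, 0.02)
})

test_that("moment eccentricity matches the closed form and is rotation invariant", {
  true_e <- sqrt(3) / 2  # 2:1 ellipse: sqrt(1 - (b/a)^2)
  e1 <- eccentricity_and_axes(raster_polar(polar_ellipse(60, 30), 141, c(71, 71)))
  e2 <- eccentricity_and_axes(raster_polar(polar_ellipse(60, 30, 37 * pi / 180),
                                           141, c(71, 71)))
  expect_lt(abs(e1$eccentricity - true_e), 0.02)
  expect_lt(abs(e2$eccentricity - true_e), 0.02)
  expect_lt(abs(e1$axis_ratio - 2), 0.05)
  # analytic moments of a circle: equal second moments, zero cross moment
  ecirc <- eccentricity_from_moments(pi * 50^4 / 4, pi * 50^4 / 4, 0)
  expect_equal(ecirc$eccentricity, 0)
  expect_false(ecirc$degenerate)
  # collinear pixels are degenerate
  m <- matrix(0, 20, 20); m[10, 3:18] <- 1
  ed <- eccentricity_and_axes(m)
  expect_true(ed$degenerate)
  expect_equal(ed$eccentricity, 1)
})

test_that("solidity matches analytic values and the brute-force oracle", {
  expect_gte(solidity(raster_disk(30, 81)), 0.98)
  # plus sign from two crossing 10x50 bars: hull is the octagon cutting the
  # 20x20 corners, area 900 px over ~1700 px hull
  plus <- matrix(0, 60, 60)
  plus[26:35, 6:55] <- 1
  plus[6:55, 26:35] <- 1
  s <- solidity(plus)
  expect_lt(abs(s - 900 / 1700), 0.03)
  expect_equal(s, oracle_solidity(plus))
  # removing a deep wedge strictly lowers solidity
  disk <- raster_disk(25, 71) >= 0.5
  xy <- expand.grid(r = 1:71, c = 1:71)
  wedge <- abs(atan2(xy$r - 36, xy$c - 36)) < pi / 7 & xy$c > 36
  notched <- disk & !matrix(wedge, 71, 71)
  expect_lt(solidity(notched), solidity(disk))
})

test_that("solidity and point asymmetry match exhaustive oracles on random blobs", {
  for (seed in 1:20) {
    m <- random_blob(seed)
    expect_identical(solidity(m), oracle_solidity(m))
    pa <- point_asymmetry(m)
    opa <- oracle_point_asymmetry(m)
    expect_identical(pa$count, opa$count)
    expect_identical(pa$fraction, opa$fraction)
  }
})

test_that("radial asymmetry matches the analytic bar value and its bounds", {
  bar <- matrix(0, 20, 110)
  bar[6:15, 6:105] <- 1
  ra <- radial_asymmetry(bar)
  expect_lt(abs(ra$fraction - (1 - pi * 25 / 1000)), 0.05)
  expect_true(ra$fraction >= 0 && ra$fraction <= 1)
  expect_lt(radial_asymmetry(raster_disk(30, 81))$fraction, 0.05)
  for (seed in 1:5) {
    f <- radial_asymmetry(random_blob(seed))$fraction
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("point asymmetry separates symmetric from asymmetric shapes", {
  rect <- matrix(0, 40, 40); rect[11:30, 6:35] <- 1
  expect_lte(point_asymmetry(rect)$fraction, 0.02)
  tri <- matrix(0, 60, 60)
  for (i in 1:50) tri[i + 5, 6:(5 + i)] <- 1
  pa <- point_asymmetry(tri)
  expect_gt(pa$fraction, 0.2)
  expect_identical(pa$count, oracle_point_asymmetry(tri)$count)
  expect_lte(pa$count, sum(tri))
})

test_that("mean negative curvature matches the closed-form polar oracle", {
  # peanut r = 50 (1 + 0.4 cos 2t): kappa from the polar curvature formula
  th <- seq(0, 2 * pi, length.out = 4097)[1:4096]
  r <- 50 * (1 + 0.4 * cos(2 * th))
  rp <- -40 * sin(2 * th)
  rpp <- -80 * cos(2 * th)
  kap <- (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
  ds <- sqrt(r^2 + rp^2)
  neg <- kap < 0
  oracle <- sum(kap[neg] * ds[neg]) / sum(ds[neg])
  ct <- polar_contour(function(t) 50 * (1 + 0.4 * cos(2 * t)), m = 2048)
  mnc <- mean_negative_curvature(ct, sigma_frac = 0.002, n_points = 1024)
  expect_lt(abs(mnc - oracle) / abs(oracle), 0.05)
  # convex disk: no concave arcs
  expect_equal(mean_negative_curvature(polar_contour(polar_disk(50))), 0)
  # bi-lobed strictly more negative than a convex shape of the same area
  ell <- polar_contour(polar_ellipse(50 * 1.2, 50 / 1.2))
  expect_lt(mnc, mean_negative_curvature(ell, sigma_frac = 0.002,
                                         n_points = 1024))
})

test_that("elliptic Fourier summaries behave on ellipses and match the DFT oracle", {
  ell <- polar_contour(polar_ellipse(50, 25), m = 1024)
  expect_equal(elliptic_fourier(ell, "harmonics_needed"), 1)
  # under the arc-length parametrisation an ellipse carries a little energy
  # above the first harmonic; it must stay far below a lobulated shape
  expect_lt(elliptic_fourier(ell, "coefficient_ratio"), 0.01)
  circ <- polar_contour(polar_disk(40), m = 1024)
  expect_lt(elliptic_fourier(circ, "coefficient_ratio"), 1e-10)
  # 4-fold star: energy ratio against trapezoid Fourier integrals of the
  # arc-length parametrised contour
  th <- seq(0, 2 * pi, length.out = 2049)[1:2048]
  r4 <- 50 * (1 + 0.2 * cos(4 * th))
  x <- 100 + r4 * cos(th); y <- 100 + r4 * sin(th)
  d <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  tt <- c(0, cumsum(d)); T <- tt[length(tt)]
  s <- seq(0, T, length.out = 4097)[1:4096]
  xs <- approx(tt, c(x, x[1]), xout = s)$y
  ys <- approx(tt, c(y, y[1]), xout = s)$y
  E <- sapply(1:20, function(n) {
    a <- 2 * mean(xs * cos(2 * pi * n * s / T))
    b <- 2 * mean(xs * sin(2 * pi * n * s / T))
    cc <- 2 * mean(ys * cos(2 * pi * n * s / T))
    dd <- 2 * mean(ys * sin(2 * pi * n * s / T))
    a^2 + b^2 + cc^2 + dd^2
  })
  oracle_ratio <- sum(E[-1]) / E[1]
  star <- as_contour(row = y, col = x)
  cr <- elliptic_fourier(star, "coefficient_ratio")
  expect_lt(abs(cr - oracle_ratio) / oracle_ratio, 0.10)
  expect_gt(elliptic_fourier(star, "harmonics_needed"), 1)
  # open/short contours are rejected
  expect_error(elliptic_fourier(contour_resample(ell, 40), "harmonics_needed"),
               "64")
})

test_that("descriptors are scale and rotation invariant within 2%", {
  # genuinely elongated lobed shape with a single inscribed-circle basin:
  # near-round shapes make eccentricity a ratio of near-equal moments and
  # multi-lobed ones make the inscribed-circle centre jump between ties
  ebase <- polar_ellipse(48, 34)
  rfun <- function(t) ebase(t) * (1 + 0.08 * cos(3 * t))
  base <- raster_polar(rfun, 121, c(61, 61))
  twice <- raster_polar(function(t) 2 * rfun(t), 241, c(121, 121))
  rot <- raster_polar(function(t) rfun(t - 0.6), 121, c(61, 61))
  d0 <- shape_descriptors(base)
  d2 <- shape_descriptors(twice)
  dr <- shape_descriptors(rot)
  rel <- function(a, b) abs(a - b) / abs(a)
  for (v in c("form_factor", "eccentricity", "solidity",
              "radial_asymmetry_frac", "efd_coefficient_ratio")) {
    expect_lt(rel(d0[[v]], d2[[v]]), 0.02)
    expect_lt(rel(d0[[v]], dr[[v]]), 0.02)
  }
  expect_identical(d0$efd_harmonics_needed, d2$efd_harmonics_needed)
  # area scales as s^2, perimeter as s
  expect_lt(rel(4 * d0$area_px, d2$area_px), 0.02)
  expect_lt(rel(2 * d0$perimeter_px, d2$perimeter_px), 0.02)
})

test_that("the descriptor panel orders canonical shapes correctly", {
  shapes <- list(
    circle = raster_disk(40, 111),
    ellipse = raster_polar(polar_ellipse(56, 28), 141, c(71, 71)),
    bilobed = raster_polar(function(t) 40 * (1 + 0.35 * cos(2 * t)),
                           131, c(66, 66)),
    lobulated = raster_polar(function(t) 40 * (1 + 0.12 * cos(3 * t) +
                                               0.12 * cos(5 * t) +
                                               0.10 * cos(7 * t)),
                             131, c(66, 66)))
  d <- do.call(rbind, lapply(shapes, function(m)
    suppressWarnings(shape_descriptors(m))))
  # the deeply lobulated shape is the extreme on solidity and form factor
  expect_equal(which.min(d$solidity), 4L)
  expect_equal(which.min(d$form_factor), 4L)
  # elongation is caught by eccentricity, not solidity
  expect_gt(d$eccentricity[2], d$eccentricity[1])
  # bi-lobed has strictly more negative curvature than the single-lobed blobs
  expect_lt(d$mean_negative_curvature[3], d$mean_negative_curvature[1])
})

test_that("nucleus_descriptors reports one consistent row per label", {
  spec <- scene_spec(width = 400, height = 400, n_nuclei = 4, lobe_amp = 0)
  sc <- render_scene(spec, seed = 4)
  seg <- segment_nuclei(sc$channels$dna)
  d <- nucleus_descriptors(seg$labels)
  expect_equal(nrow(d), seg$count)
  # stored form factor is recomputable from stored area and perimeter
  expect_equal(d$form_factor,
               pmin(1, 4 * pi * d$area_px / d$perimeter_px^2),
               tolerance = 1e-9)
  expect_true(all(d$solidity <= 1 & d$solidity > 0))
  expect_true(all(d$form_factor <= 1))
  expect_true(all(d$radial_asymmetry_frac >= 0 & d$radial_asymmetry_frac <= 1))
  expect_true(all(d$point_asymmetry_frac >= 0 & d$point_asymmetry_frac <= 1))
  expect_true(all(d$mean_negative_curvature <= 0))
})
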