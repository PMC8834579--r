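# Bleb detection: lamin-gap subtraction, morphological cut-off, enrichment
# and frequency.

test_that("an intact lamin ring yields no lamin-gap blebs", {
  spec <- scene_spec(width = 400, height = 400, n_nuclei = 4, bleb_prob = 0)
  sc <- render_scene(spec, seed = 6)
  bl <- detect_blebs_lamin_gap(sc$channels$dna, sc$channels$laminB)
  expect_equal(nrow(bl), 0L)
  expect_error(detect_blebs_lamin_gap(sc$channels$dna, NULL),
               "morphological")
})

test_that("a planted chromatin bleb is recovered with its area and geometry", {
  spec <- scene_spec(width = 400, height = 400, n_nuclei = 1, bleb_prob = 1,
                     bleb_radius_range = c(14, 14))
  sc <- render_scene(spec, seed = 2)
  bl <- detect_blebs_lamin_gap(sc$channels$dna, sc$channels$laminB,
                               laminAC = sc$channels$laminAC)
  expect_equal(nrow(bl), 1L)
  truth_area <- length(sc$masks[[which(sc$truth$kind == "bleb")]])
  expect_lt(abs(bl$area_px - truth_area) / truth_area, 0.2)
  expect_true(bl$relative_area > 0 && bl$relative_area < 1)
  # by construction no detected lamin pixel is inside the bleb
  lam_px <- attr(bl, "lamin_filled")[[bl$nucleus_label]]
  expect_length(intersect(attr(bl, "masks")[[1]], lam_px), 0)
})

test_that("membrane-only blebs are invisible to the subtraction method", {
  spec <- scene_spec(width = 400, height = 400, n_nuclei = 1, bleb_prob = 1,
                     bleb_chromatin = FALSE)
  sc <- render_scene(spec, seed = 2)
  bl <- detect_blebs_lamin_gap(sc$channels$dna, sc$channels$laminB)
  expect_equal(nrow(bl), 0L)
})

test_that("enrichment is exact on flat regions and ~1.5 on planted blebs", {
  ch <- channel_image(matrix(100, 64, 64), "laminAC")
  b <- matrix(0, 64, 64); b[5:14, 5:14] <- 1
  l <- matrix(0, 64, 64); l[30:59, 30:59] <- 1
  expect_equal(bleb_enrichment(b, ch, l), 1)
  ch2 <- channel_image(matrix(100, 64, 64) + 100 * b, "laminAC")
  expect_equal(bleb_enrichment(b, ch2, l), 2)
  expect_warning(e <- bleb_enrichment(matrix(0, 64, 64), ch, l), "empty")
  expect_true(is.na(e))
  # planted 1.5x raw enrichment, Poisson + Gaussian noise, bleb >= 200 px
  spec <- scene_spec(width = 400, height = 400, n_nuclei = 1, bleb_prob = 1,
                     bleb_radius_range = c(16, 16), poisson = TRUE)
  sc <- render_scene(spec, seed = 9)
  bleb_mask <- matrix(0, 400, 400)
  bleb_mask[sc$masks[[which(sc$truth$kind == "bleb")]]] <- 1
  body_mask <- matrix(0, 400, 400)
  body_mask[sc$masks[[which(sc$truth$kind == "nucleus")]]] <- 1
  expect_gte(sum(bleb_mask), 200)
  enr <- bleb_enrichment(bleb_mask, sc$channels$laminAC, body_mask)
  expect_lt(abs(enr - 1.5) / 1.5, 0.05)
})

test_that("the morphological method keeps protrusions and routes detached objects", {
  n <- 201
  xy <- expand.grid(r = 1:n, c = 1:n)
  disk <- (xy$r - 100)^2 + (xy$c - 90)^2 <= 40^2
  bump <- (xy$r - 100)^2 + (xy$c - 130)^2 <= 8^2   # hemispherical protrusion
  stain <- channel_image(matrix(10 + 90 * as.numeric(disk | bump), n, n),
                         "dna")
  # the opening must be strictly wider than the protrusion to cut it off
  bl <- detect_blebs_morphological(stain, nuc_config(bleb_max_iter = 10L))
  expect_equal(nrow(bl), 1L)
  expect_identical(bl$method, "morphological")
  expect_true(bl$touches_nucleus)
  # a clean disk produces no residual
  plain <- channel_image(matrix(10 + 90 * as.numeric(disk), n, n), "dna")
  expect_equal(nrow(detect_blebs_morphological(plain)), 0L)
  # a detached round object 20 px away is not a bleb (micronucleus path)
  mn <- (xy$r - 100)^2 + (xy$c - 180)^2 <= 7^2
  both <- channel_image(matrix(10 + 90 * as.numeric(disk | mn), n, n), "dna")
  bl2 <- detect_blebs_morphological(both, nuc_config(bleb_max_iter = 10L))
  expect_equal(nrow(bl2), 0L)
  expect_true("object_vanished" %in% attr(bl2, "rejected")$reason)
})

test_that("the touching rule accepts 8-adjacent residuals and rejects a 1-px gap", {
  # constructed boundary case on a square core with a square satellite:
  # diagonal contact passes, one pixel of separation fails
  n <- 161
  base <- matrix(0, n, n)
  base[40:120, 40:120] <- 1           # core survives opening radius 8
  touch <- base
  touch[121:135, 121:135] <- 1        # corner-touches the core diagonally
  gap <- base
  gap[122:136, 122:136] <- 1          # 1-px diagonal gap
  mk <- function(m) channel_image(10 + 90 * m, "dna")
  bl_touch <- detect_blebs_morphological(mk(touch))
  bl_gap <- detect_blebs_morphological(mk(gap))
  expect_equal(nrow(bl_touch), 1L)
  expect_equal(nrow(bl_gap), 0L)
  expect_true("not_touching" %in% attr(bl_gap, "rejected")$reason ||
              "object_vanished" %in% attr(bl_gap, "rejected")$reason)
})

test_that("bleb frequency counts nuclei once and pools sizes", {
  expect_equal(bleb_frequency(20L, NULL)$frequency_percent, 0)
  recs <- data.frame(nucleus_label = c(1L, 1L, 2L, 3L, 4L, 5L),
                     area_px = c(50, 60, 40, 70, 80, 90),
                     relative_area = rep(0.02, 6))
  bf <- bleb_frequency(20L, recs)
  expect_equal(bf$frequency_percent, 25)
  expect_equal(bf$mean_area_px, mean(recs$area_px))
  expect_error(bleb_frequency(0L, recs), "zero nuclei")
})

test_that("both methods agree on blebbed-nucleus calls on planted scenes", {
  spec <- bleb_scene_spec(50)
  sc <- render_scene(spec, seed = 5)
  blA <- detect_blebs_lamin_gap(sc$channels$dna, sc$channels$laminB)
  blB <- detect_blebs_morphological(sc$channels$dna)
  tr <- sc$truth
  mapA <- match_nuclei(tr, attr(blA, "nuclei"))
  mapB <- match_nuclei(tr, attr(blB, "nuclei"))
  callA <- names(mapA)[mapA %in% blA$nucleus_label]
  callB <- names(mapB)[mapB %in% blB$nucleus_label]
  ids <- as.character(1:50)
  expect_gte(mean((ids %in% callA) == (ids %in% callB)), 0.9)
  expect_true(all(blA$relative_area < 1))
  expect_true(all(blB$relative_area < 1))
})

test_that("adding a bleb strictly decreases form factor and solidity", {
  spec <- scene_spec(width = 400, height = 400, n_nuclei = 1, bleb_prob = 1,
                     noise_sd = 0)
  sc <- render_scene(spec, seed = 3)
  nuc <- matrix(0, 400, 400)
  nuc[sc$masks[[which(sc$truth$kind == "nucleus")]]] <- 1
  withb <- nuc
  withb[sc$masks[[which(sc$truth$kind == "bleb")]]] <- 1
  d0 <- suppressWarnings(shape_descriptors(nuc))
  d1 <- suppressWarnings(shape_descriptors(withb))
  expect_lt(d1$form_factor, d0$form_factor)
  expect_lt(d1$solidity, d0$solidity)
})
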