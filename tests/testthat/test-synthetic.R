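# Synthetic scene generator: construction guarantees, determinism,
# closed-form truth, and detection scoring.

test_that("spec validation catches impossible parameters", {
  expect_error(scene_spec(micronucleus_prob = 1.4), "invalid scene spec")
  expect_error(scene_spec(lobe_amp = 0.5), "invalid scene spec")
  expect_error(scene_spec(radius_range = c(40, 30)), "invalid scene spec")
  expect_error(render_scene(scene_spec(width = 200, height = 200,
                                       n_nuclei = 30), 1),
               "infeasible packing")
})

test_that("construction guarantees hold: one nucleus, blebs as specified", {
  spec <- scene_spec(width = 300, height = 300, n_nuclei = 1, noise_sd = 0,
                     lobe_amp = 0)
  sc <- render_scene(spec, seed = 1)
  lab <- nucleoshape:::label8(sc$channels$dna$pixels > 50)
  expect_equal(max(lab), 1L)
  # lamin ring encloses the nucleus: DNA mask sits inside the filled ring
  ring <- sc$channels$laminB$pixels > 60
  filled <- nucleoshape:::ebi_mat(EBImage::fillHull(ring + 0))
  expect_true(all(filled[sc$masks[[1]]] > 0))
  spec2 <- scene_spec(width = 800, height = 600, n_nuclei = 10, bleb_prob = 1)
  sc2 <- render_scene(spec2, seed = 4)
  expect_equal(sum(sc2$truth$kind == "bleb"), 10L)
  expect_equal(sum(sc2$truth$kind == "nucleus"), 10L)
})

test_that("identical spec and seed render bit-identical scenes", {
  spec <- scene_spec(width = 500, height = 500, n_nuclei = 4,
                     micronucleus_prob = 0.5, bleb_prob = 0.5,
                     invag_count_range = c(0, 3), poisson = TRUE)
  a <- render_scene(spec, seed = 123)
  b <- render_scene(spec, seed = 123)
  expect_identical(a$channels$dna$pixels, b$channels$dna$pixels)
  expect_identical(a$channels$laminB$pixels, b$channels$laminB$pixels)
  expect_identical(a$channels$laminAC$pixels, b$channels$laminAC$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$masks, b$masks)
  d <- render_scene(spec, seed = 124)
  expect_false(identical(a$channels$dna$pixels, d$channels$dna$pixels))
})

test_that("planted pure ellipses carry their closed-form descriptor truth", {
  spec <- scene_spec(width = 700, height = 550, n_nuclei = 6, lobe_amp = 0,
                     aspect_range = c(1.6, 2.2))
  sc <- render_scene(spec, seed = 10)
  nuc <- sc$truth[sc$truth$kind == "nucleus", ]
  expect_true(all(is.finite(nuc$analytic_eccentricity)))
  seg <- segment_nuclei(sc$channels$dna)
  map <- match_nuclei(sc$truth, seg$labels)
  d <- nucleus_descriptors(seg$labels)
  for (i in seq_len(nrow(nuc))) {
    row <- d[d$label == map[as.character(nuc$nucleus_id[i])], ]
    expect_lt(abs(row$eccentricity - nuc$analytic_eccentricity[i]), 0.02)
    expect_lt(abs(row$area_px - nuc$analytic_area[i]) / nuc$analytic_area[i],
              0.05)
  }
})

test_that("scoring is exact on identity, empty and fragmented detections", {
  t1 <- list(1:100, 201:260, 400:420)
  s <- score_detections(t1, t1, iou_min = 0.3)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$fdr, 0)
  s0 <- score_detections(t1, list(), iou_min = 0.3)
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$fn, 3L)
  # one truth object split into two detected fragments: one-to-one matching
  # credits at most one true positive (verified against the optimal matching
  # on this tiny instance, which also pairs each truth at most once)
  t2 <- list(1:100)
  frag <- list(1:50, 51:100)
  s2 <- score_detections(t2, frag, iou_min = 0.3)
  expect_equal(s2$tp, 1L)
  expect_equal(s2$fp, 1L)
  # greedy picks the highest-IoU pair first
  t3 <- list(1:100, 90:200)
  d3 <- list(95:200)
  s3 <- score_detections(t3, d3, iou_min = 0.3)
  expect_equal(unname(s3$matches[, "truth"]), 2L)
})

test_that("detector sensitivity is non-increasing in noise", {
  sens <- vapply(c(10, 30, 60), function(sd) {
    spec <- scene_spec(width = 1500, height = 1320, n_nuclei = 25,
                       micronucleus_prob = 0.4, noise_sd = sd)
    sc <- render_scene(spec, seed = 42)
    res <- suppressWarnings(detect_micronuclei(sc$channels$dna))
    tm <- sc$masks[sc$truth$kind == "micronucleus"]
    mnrec <- res$records[res$records$status == "micronucleus", ]
    dm <- lapply(mnrec$label, function(j) which(res$candidates == j))
    score_detections(tm, dm, 0.3)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})
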