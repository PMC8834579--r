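# Micronucleus pipeline: cleanup, cell territories, size-rule classification
# and frequency.

test_that("cleanup is the identity at 0 iterations and removes spurs at 3", {
  n <- 81
  xy <- expand.grid(r = 1:n, c = 1:n)
  disk <- (xy$r - 41)^2 + (xy$c - 41)^2 <= 20^2
  spur <- abs(xy$r - 41) <= 1 & xy$c >= 41 & xy$c <= 75   # 2 px wide
  lab <- matrix(0L, n, n)
  lab[disk | spur] <- 1L
  expect_identical(cleanup_nuclei(lab, 0L), lab)
  cl <- cleanup_nuclei(lab, 3L)
  # spur removed ...
  expect_equal(sum(cl[, 67:75]), 0)
  # ... while the disk survives within 5% of its area
  expect_lt(abs(sum(cl > 0) - sum(disk)) / sum(disk), 0.05)
  # tiny objects vanish entirely and their labels are dropped
  lab2 <- lab
  lab2[5:6, 5:6] <- 2L
  cl2 <- cleanup_nuclei(lab2, 3L)
  expect_false(any(cl2 == 2L))
  expect_true(any(cl2 == 1L))  # survivor keeps its label
})

test_that("cell territories extend nuclei and partition along the midline", {
  n <- 141
  xy <- expand.grid(r = 1:n, c = 1:n)
  lab <- matrix(0L, n, n)
  lab[(xy$r - 71)^2 + (xy$c - 40)^2 <= 12^2] <- 1L
  lab[(xy$r - 71)^2 + (xy$c - 102)^2 <= 12^2] <- 2L
  cells <- approximate_cells(lab, dilation_px = 25L)
  # every region contains its nucleus
  expect_true(all(cells[lab == 1L] == 1L))
  expect_true(all(cells[lab == 2L] == 2L))
  # single-nucleus case: a disk of radius r + d (within rasterization)
  single <- matrix(0L, 101, 101)
  xy2 <- expand.grid(r = 1:101, c = 1:101)
  single[(xy2$r - 51)^2 + (xy2$c - 51)^2 <= 15^2] <- 1L
  cs <- approximate_cells(single, dilation_px = 10L)
  expect_lt(abs(sum(cs > 0) - pi * 25^2) / (pi * 25^2), 0.05)
  # collision resolved by the equidistant line: nearest-centroid brute force
  mid <- (40 + 102) / 2
  own <- cells[71, ]
  expect_true(all(own[cells[71, ] > 0 & seq_len(n) < mid - 1] == 1L))
  expect_true(all(own[cells[71, ] > 0 & seq_len(n) > mid + 1] == 2L))
  expect_error(approximate_cells(matrix(0L, 50, 50)), "empty")
})

test_that("the 1/3 diameter rule accepts at the threshold and rejects one px over", {
  n <- 201
  nuclei <- matrix(0L, n, n)
  nuclei[50:79, 50:79] <- 1L          # area 900, equivalent diameter d
  cells <- approximate_cells(nuclei, dilation_px = 60L)
  at <- matrix(0L, n, n); at[100:109, 50:59] <- 1L         # area 100: d/3
  over <- matrix(0L, n, n); over[100:109, 50:59] <- 1L
  over[110, 50] <- 1L                                      # area 101
  r_at <- classify_micronuclei(at, nuclei, cells, max_ratio = 1 / 3)
  r_over <- classify_micronuclei(over, nuclei, cells, max_ratio = 1 / 3)
  expect_identical(r_at$status, "micronucleus")
  expect_equal(r_at$diameter_ratio, 1 / 3, tolerance = 1e-12)
  expect_identical(r_over$status, "unclassified")
  # spec's worked sizes: nucleus d = 30, object d = 9 accepted, d = 12 not
  expect_lte(9 / 30, 1 / 3); expect_gt(12 / 30, 1 / 3)
  # centroid outside every cell region: discarded entirely
  far <- matrix(0L, n, n); far[190:199, 190:199] <- 1L
  expect_equal(nrow(classify_micronuclei(far, nuclei, cells)), 0L)
})

test_that("raising max_ratio never decreases the number of micronuclei", {
  spec <- mn_scene_spec(16)
  sc <- render_scene(spec, seed = 2)
  cfg <- nuc_config()
  res <- detect_micronuclei(sc$channels$dna, cfg)
  counts <- vapply(c(0.15, 0.25, 1 / 3, 0.5), function(r) {
    rec <- classify_micronuclei(res$candidates, res$nuclei, res$cells,
                                max_ratio = r)
    sum(rec$status == "micronucleus")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("micronuclear frequency counts nuclei once regardless of multiplicity", {
  expect_equal(micronucleus_frequency(10L, NULL), 0)
  two_one_parent <- data.frame(parent_nucleus_label = c(4L, 4L),
                               status = c("micronucleus", "micronucleus"))
  expect_equal(micronucleus_frequency(10L, two_one_parent), 10)
  expect_error(micronucleus_frequency(0L, NULL), "zero nuclei")
  # unclassified records never count
  uncl <- data.frame(parent_nucleus_label = 1L, status = "unclassified")
  expect_equal(micronucleus_frequency(10L, uncl), 0)
})

test_that("planted micronuclei are recovered with high sensitivity and low FDR", {
  spec <- mn_scene_spec(50)
  sc <- render_scene(spec, seed = 11)
  res <- detect_micronuclei(sc$channels$dna)
  expect_equal(max(res$nuclei), 50L)
  tm <- sc$masks[sc$truth$kind == "micronucleus"]
  mnrec <- res$records[res$records$status == "micronucleus", ]
  dm <- lapply(mnrec$label, function(j) which(res$candidates == j))
  s <- score_detections(tm, dm, iou_min = 0.3)
  expect_gte(s$sensitivity, 0.95)
  expect_lte(s$fdr, 0.05)
  # frequency is intensity-scale invariant
  scaled <- channel_image(sc$channels$dna$pixels * 3.7, "dna")
  res2 <- detect_micronuclei(scaled)
  expect_equal(res2$frequency, res$frequency)
})
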