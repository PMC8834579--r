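# Micronucleus detection: nucleus cleanup, cell-territory approximation, and
# size-ratio classification of small extranuclear chromatin bodies.

#' Nucleus cleanup by sequential erosion and dilation
#'
#' Erodes and then dilates each label with a Euclidean disc of radius
#' `n_iter` (a morphological opening whose strength grows with the iteration
#' count), clearing small attached objects and spurs. Objects eroded to
#' nothing are dropped; surviving labels keep their numbers. `n_iter = 0` is
#' the identity.
#'
#' @param mask integer label mask.
#' @param n_iter non-negative number of erosion/dilation passes.
#' @return cleaned integer label mask.
#' @export
cleanup_nuclei <- function(mask, n_iter) {
  stopifnot(n_iter >= 0)
  if (n_iter == 0L) return(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (k in sort(unique(mask[mask > 0]))) {
    bb <- mask_bbox(mask == k, pad = as.integer(n_iter) + 1L)
    sub <- matrix(as.numeric(mask[bb[1]:bb[2], bb[3]:bb[4]] == k),
                  bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L)
    op <- open_n(sub, n_iter)
    if (sum(op) == 0) next  # object vanished entirely
    tgt <- out[bb[1]:bb[2], bb[3]:bb[4]]
    tgt[op > 0] <- k        # opening is anti-extensive: no leak across labels
    out[bb[1]:bb[2], bb[3]:bb[4]] <- tgt
  }
  out
}

#' Approximate cell territories around nuclei
#'
#' Without a whole-cell stain, each nucleus is dilated by `dilation_px` and
#' collisions are resolved by assigning every territory pixel to the nearest
#' nucleus (Voronoi-style propagation from the nucleus masks). With a
#' whole-cell channel, its thresholded foreground (union with the nuclei) is
#' partitioned the same way. Every cell region contains its nucleus and
#' regions are disjoint.
#'
#' @param nuclei integer label mask of nuclei.
#' @param dilation_px dilation distance in px (default 25).
#' @param whole_cell optional [channel_image()] of a whole-cell stain.
#' @return integer label mask of cell territories (same labels as nuclei).
#' @export
approximate_cells <- function(nuclei, dilation_px = 25L, whole_cell = NULL) {
  if (max(nuclei) == 0L) stop("empty nucleus mask")
  nucbin <- matrix(as.numeric(nuclei > 0), nrow(nuclei), ncol(nuclei))
  territory <- if (is.null(whole_cell)) {
    stopifnot(dilation_px >= 1)
    d_out <- ebi_mat(EBImage::distmap(1 - nucbin))  # distance to nearest nucleus
    d_out <= dilation_px
  } else {
    th <- otsu_threshold(whole_cell$pixels)
    (whole_cell$pixels > th) | (nucbin > 0)
  }
  pr <- EBImage::propagate(EBImage::Image(matrix(0, nrow(nuclei), ncol(nuclei))),
                           seeds = nuclei, mask = territory)
  cells <- ebi_mat(pr)
  storage.mode(cells) <- "integer"
  cells
}

#' Classify candidate objects as micronuclei by comparative size
#'
#' A candidate object becomes a micronucleus of nucleus `k` when its centroid
#' falls inside the cell region of `k` and its equivalent-circle diameter
#' `sqrt(4A/pi)` is at most `max_ratio` times the equivalent diameter of
#' nucleus `k` (default ratio 1/3). Candidates failing the ratio test are
#' reported as unclassified; candidates whose centroid lies outside every
#' cell region are discarded.
#'
#' @param objects integer label mask of candidate small objects.
#' @param nuclei integer label mask of nuclei.
#' @param cells cell-territory mask from [approximate_cells()].
#' @param max_ratio maximum diameter ratio in (0,1); default 1/3.
#' @param channels optional named list of [channel_image()]s; per-candidate
#'   mean intensities are added as `mean_<role>` columns.
#' @return data.frame of micronucleus records: `label`,
#'   `parent_nucleus_label`, `area_px`, `equivalent_diameter`,
#'   `centroid_row`, `centroid_col`, `diameter_ratio`, `status`
#'   (`"micronucleus"` or `"unclassified"`), plus intensity columns.
#' @export
classify_micronuclei <- function(objects, nuclei, cells, max_ratio = 1 / 3,
                                 channels = NULL) {
  stopifnot(max_ratio > 0, max_ratio < 1)
  empty <- data.frame(label = integer(0), parent_nucleus_label = integer(0),
                      area_px = numeric(0), equivalent_diameter = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      diameter_ratio = numeric(0), status = character(0))
  if (max(objects) == 0L) return(empty)
  nuc_area <- label_areas(nuclei)
  nuc_diam <- equivalent_diameter(nuc_area)
  obj_area <- label_areas(objects)
  ctr <- label_centroids(objects)
  rows <- lapply(seq_len(max(objects)), function(j) {
    if (obj_area[j] == 0) return(NULL)
    ri <- round(ctr[j, "row"]); ci <- round(ctr[j, "col"])
    parent <- cells[ri, ci]
    if (parent == 0L) return(NULL)  # outside all cell regions: discarded
    dj <- equivalent_diameter(obj_area[j])
    ratio <- dj / nuc_diam[parent]
    data.frame(label = j, parent_nucleus_label = parent,
               area_px = obj_area[j], equivalent_diameter = dj,
               centroid_row = ctr[j, "row"], centroid_col = ctr[j, "col"],
               diameter_ratio = ratio,
               status = if (ratio <= max_ratio + 1e-9) "micronucleus"
                        else "unclassified")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  if (!is.null(channels)) {
    for (nm in names(channels)) {
      px <- channels[[nm]]$pixels
      out[[paste0("mean_", nm)]] <- vapply(out$label, function(j)
        mean(px[objects == j]), numeric(1))
    }
  }
  out
}

#' Micronuclear frequency
#'
#' Percentage of nuclei with one or more associated micronuclei; a nucleus
#' with several micronuclei counts once.
#'
#' @param nuclei integer label mask of nuclei, or the nucleus count.
#' @param micronuclei record data.frame from [classify_micronuclei()]
#'   (only rows with `status == "micronucleus"` count).
#' @return percentage in `[0, 100]`.
#' @export
micronucleus_frequency <- function(nuclei, micronuclei) {
  n <- if (is.matrix(nuclei)) max(nuclei) else as.integer(nuclei)
  if (n < 1L) stop("zero nuclei: frequency undefined")
  if (is.null(micronuclei) || nrow(micronuclei) == 0L) return(0)
  mn <- micronuclei[micronuclei$status == "micronucleus", , drop = FALSE]
  100 * length(unique(mn$parent_nucleus_label)) / n
}

#' Full micronucleus detection pipeline on one image
#'
#' Segments the DNA (or other nuclear) channel with a dual-threshold pass:
#' the primary global threshold yields nucleus candidates (area at least
#' `min_nucleus_area`, cleaned with [cleanup_nuclei()]), and a second, lower
#' threshold (`mn_low_thresh_scale` times the primary) recovers dim
#' micronucleus candidates. Cell territories are approximated by dilation
#' (or a whole-cell stain) and candidates are classified by comparative size
#' within their cell.
#'
#' @param dna [channel_image()] used for detection (DNA, NE, lamina or
#'   nucleoplasm stain all work).
#' @param cfg a [nuc_config()].
#' @param whole_cell optional whole-cell stain for territory definition.
#' @param channels optional named list of channels for intensity readouts.
#' @return list with `nuclei` (label mask), `cells`, `candidates` (label
#'   mask), `records` (classification data.frame), `frequency` (percent),
#'   and `qc` from segmentation.
#' @export
detect_micronuclei <- function(dna, cfg = nuc_config(), whole_cell = NULL,
                               channels = NULL) {
  seg_cfg <- cfg
  seg_cfg$seg_min_area <- cfg$mn_min_area
  seg <- segment_nuclei(dna, seg_cfg)
  lab <- seg$labels
  areas <- label_areas(lab)
  big <- which(areas >= cfg$min_nucleus_area)
  nuclei <- lab
  nuclei[!(nuclei %in% big)] <- 0L
  nuclei <- cleanup_nuclei(nuclei, cfg$cleanup_iter)
  nuclei <- relabel_consecutive(nuclei)$labels
  if (max(nuclei) == 0L) {
    warning("no nuclei found")
    return(list(nuclei = nuclei, cells = nuclei, candidates = nuclei,
                records = classify_micronuclei(nuclei, nuclei, nuclei),
                frequency = NA_real_, qc = seg$qc))
  }
  small <- which(areas < cfg$min_nucleus_area & areas >= cfg$mn_min_area)
  cand <- matrix(0L, nrow(lab), ncol(lab))
  cand[lab %in% small] <- 1L
  # second, lower threshold pass for dim micronuclei missed by the primary
  img <- dna$pixels
  th1 <- if (identical(cfg$seg_threshold, "otsu")) otsu_threshold(img)
         else if (identical(cfg$seg_threshold, "quantile"))
           stats::quantile(img, cfg$seg_threshold_quantile, names = FALSE)
         else cfg$seg_threshold
  low <- img > th1 * cfg$mn_low_thresh_scale
  claimed <- ebi_mat(EBImage::dilate(matrix(as.numeric(lab > 0), nrow(lab),
                                            ncol(lab)),
                                     EBImage::makeBrush(3L, "box"))) > 0
  extra <- label8(matrix(as.numeric(low & !claimed), nrow(lab), ncol(lab)))
  ex_areas <- label_areas(extra)
  for (k in which(ex_areas >= cfg$mn_min_area & ex_areas < cfg$min_nucleus_area))
    cand[extra == k] <- 1L
  cand <- label8(cand)
  cells <- approximate_cells(nuclei, cfg$cell_dilation_px, whole_cell)
  recs <- classify_micronuclei(cand, nuclei, cells,
                               max_ratio = cfg$mn_max_ratio,
                               channels = channels)
  list(nuclei = nuclei, cells = cells, candidates = cand, records = recs,
       frequency = micronucleus_frequency(nuclei, recs), qc = seg$qc)
}
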