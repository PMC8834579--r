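# Nuclear-envelope bleb detection, two pipelines:
#  (A) lamin-deficiency subtraction: chromatin object minus the filled
#      lamin-B object leaves chromatin that lacks lamin B (the bleb);
#  (B) morphological: a maximal nucleus-cleanup opening cuts blebs off the
#      main nuclear shape; residuals must touch the nucleus, and small round
#      residuals are rejected as micronuclei.

bleb_record_template <- function() {
  data.frame(nucleus_label = integer(0), method = character(0),
             area_px = numeric(0), relative_area = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             touches_nucleus = logical(0), enrichment = numeric(0))
}

#' Detect blebs by lamin-B deficiency (subtraction method)
#'
#' Per cell territory, a chromatin object is segmented from the DNA channel
#' with a deliberately permissive threshold (blebs often contain less DNA:
#' per-cell Otsu scaled by `bleb_dna_scale`, or a fixed in-cell quantile),
#' and the lamin-B object is built by thresholding the lamin signal, closing
#' the ring (bridging the gap at the bleb neck) and filling its interior.
#' Chromatin outside the (dilated) lamin-B object, within the configured
#' area band and adjacent to the lamin-B object, is a bleb. Only
#' chromatin-containing blebs can be found by this method.
#'
#' @param dna DNA [channel_image()].
#' @param laminB lamin-B [channel_image()]; an informative error points to
#'   [detect_blebs_morphological()] when absent.
#' @param cfg a [nuc_config()].
#' @param laminAC optional lamin-A/C (or other) channel; per-bleb enrichment
#'   `mean(channel in bleb) / mean(channel in lamin-B object)` is reported.
#' @return data.frame of bleb records (`nucleus_label`, `method`,
#'   `area_px`, `relative_area`, centroid, `touches_nucleus`, `enrichment`);
#'   attributes: `"masks"` (per-record pixel indices), `"nuclei"` (label
#'   mask), `"lamin_filled"` (list of per-nucleus lamin-object pixel
#'   indices), `"n_nuclei"`.
#' @export
detect_blebs_lamin_gap <- function(dna, laminB = NULL, cfg = nuc_config(),
                                   laminAC = NULL) {
  if (is.null(laminB))
    stop("missing lamin-B channel: the subtraction method needs it; ",
         "use detect_blebs_morphological() on a single NE/nucleoplasm stain")
  stopifnot(inherits(laminB, "channel_image"), laminB$role == "laminB")
  seg <- segment_nuclei(dna, cfg)
  nuclei <- seg$labels
  if (max(nuclei) == 0L) {
    out <- bleb_record_template()
    attr(out, "masks") <- list(); attr(out, "nuclei") <- nuclei
    attr(out, "lamin_filled") <- list(); attr(out, "n_nuclei") <- 0L
    return(out)
  }
  cells <- approximate_cells(nuclei, cfg$cell_dilation_px)
  nuc_area <- label_areas(nuclei)
  H <- nrow(nuclei)
  recs <- list(); masks <- list(); lamfill <- vector("list", max(nuclei))
  for (k in seq_len(max(nuclei))) {
    cellk <- cells == k
    if (!any(cellk)) next
    bb <- mask_bbox(cellk, pad = 2L)
    rows <- bb[1]:bb[2]; colsr <- bb[3]:bb[4]
    inc <- cellk[rows, colsr]
    dnak <- dna$pixels[rows, colsr]
    lamk <- laminB$pixels[rows, colsr]
    nuck <- nuclei[rows, colsr] == k
    # chromatin object: permissive threshold, component overlapping nucleus
    th_d <- if (!is.null(cfg$bleb_dna_quantile))
      stats::quantile(dnak[inc], cfg$bleb_dna_quantile, names = FALSE)
    else otsu_threshold(dnak[inc]) * cfg$bleb_dna_scale
    chrom <- matrix(as.numeric(inc & dnak > th_d), nrow(inc), ncol(inc))
    cc <- label8(chrom)
    hit <- unique(cc[cc > 0 & nuck])
    chrom <- matrix(as.numeric(cc %in% hit), nrow(inc), ncol(inc))
    chrom <- ebi_mat(EBImage::fillHull(chrom))
    # lamin-B object: threshold, close the ring gap, fill the interior
    th_l <- otsu_threshold(lamk[inc])
    lam <- matrix(as.numeric(inc & lamk > th_l), nrow(inc), ncol(inc))
    # drop isolated noise specks before building the object: a few bright
    # pixels inside the bleb would otherwise punch dilated holes into it
    ll <- label8(lam)
    lam <- matrix(as.numeric(ll %in% which(label_areas(ll) >= 9)),
                  nrow(inc), ncol(inc))
    lam_cl <- erode_n(dilate_n(lam, cfg$bleb_close_px), cfg$bleb_close_px)
    lam_fill <- ebi_mat(EBImage::fillHull(lam_cl))
    lf <- label8(lam_fill)
    hit <- unique(lf[lf > 0 & nuck])
    lam_fill <- matrix(as.numeric(lf %in% hit | lam > 0), nrow(inc), ncol(inc))
    idxlf <- which(lam_fill > 0, arr.ind = TRUE)
    lamfill[[k]] <- (colsr[1] - 1L + idxlf[, 2] - 1L) * H +
      (rows[1] - 1L + idxlf[, 1])
    # subtraction: chromatin lacking lamin B
    lam_dil <- dilate_n(lam_fill, cfg$bleb_lamin_dilate)
    cand <- matrix(as.numeric(chrom > 0 & lam_dil == 0), nrow(inc), ncol(inc))
    cl <- label8(cand)
    if (max(cl) == 0) next
    sz <- label_areas(cl)
    for (j in which(sz >= cfg$min_bleb_area &
                    sz <= cfg$max_bleb_frac * nuc_area[k])) {
      comp <- cl == j
      # adjacency to the lamin-B object: the candidate was carved out by the
      # dilated object, so touching is tested against that dilated mask
      touching <- any(ebi_mat(EBImage::dilate(
        matrix(as.numeric(comp), nrow(inc), ncol(inc)),
        EBImage::makeBrush(3L, "box"))) > 0 & lam_dil > 0)
      if (!touching) next
      idx <- which(comp, arr.ind = TRUE)
      enr <- if (!is.null(laminAC)) {
        ack <- laminAC$pixels[rows, colsr]
        mean(ack[comp]) / mean(ack[lam_fill > 0])
      } else NA_real_
      recs[[length(recs) + 1L]] <- data.frame(
        nucleus_label = k, method = "lamin_gap", area_px = sz[j],
        relative_area = sz[j] / nuc_area[k],
        centroid_row = mean(idx[, 1]) + rows[1] - 1,
        centroid_col = mean(idx[, 2]) + colsr[1] - 1,
        touches_nucleus = TRUE, enrichment = enr)
      masks[[length(masks) + 1L]] <-
        (colsr[1] - 1L + idx[, 2] - 1L) * H + (rows[1] - 1L + idx[, 1])
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else bleb_record_template()
  attr(out, "masks") <- masks
  attr(out, "nuclei") <- nuclei
  attr(out, "lamin_filled") <- lamfill
  attr(out, "n_nuclei") <- max(nuclei)
  out
}

#' Protein enrichment in a bleb
#'
#' Ratio of the mean channel intensity over the bleb pixels to the mean over
#' the lamin-B object pixels.
#'
#' @param bleb_mask logical/binary matrix of the bleb.
#' @param channel a [channel_image()] aligned with the masks.
#' @param laminB_object_mask logical/binary matrix of the lamin-B object.
#' @return enrichment ratio, or `NA` with a warning if either region is empty.
#' @export
bleb_enrichment <- function(bleb_mask, channel, laminB_object_mask) {
  bsel <- bleb_mask > 0; lsel <- laminB_object_mask > 0
  if (!any(bsel) || !any(lsel)) {
    warning("empty region: enrichment undefined")
    return(NA_real_)
  }
  mean(channel$pixels[bsel]) / mean(channel$pixels[lsel])
}

#' Detect blebs morphologically from a single NE/nucleoplasm stain
#'
#' The micronucleus algorithm with different constraints: the nucleus
#' cleanup (opening) is run at its maximum iteration count so that blebs are
#' cut off from the main nuclear shape; residual components must touch the
#' nuclear core (8-adjacency), and residuals that look like micronuclei
#' (small AND round: area below `mn_reject_area` and form factor above
#' `mn_reject_circ`) are rejected.
#'
#' @param stain a [channel_image()] of a NE or nucleoplasm stain (LAP2,
#'   lamin, or DNA all work); segmented permissively so blebs are included
#'   in the nuclear objects.
#' @param cfg a [nuc_config()].
#' @return data.frame of bleb records (`method = "morphological"`);
#'   attributes `"masks"`, `"nuclei"`, `"n_nuclei"`, and `"rejected"`
#'   (data.frame of residuals routed away with a `reason`).
#' @export
detect_blebs_morphological <- function(stain, cfg = nuc_config()) {
  img <- stain$pixels
  th <- otsu_threshold(img) * cfg$stain_thresh_scale
  seg_cfg <- cfg
  seg_cfg$seg_threshold <- th
  dna_like <- channel_image(img, "dna", stain$pixel_size_um, stain$bit_depth)
  seg <- segment_nuclei(dna_like, seg_cfg)
  nuclei <- seg$labels
  H <- nrow(nuclei)
  recs <- list(); masks <- list(); rej <- list()
  for (k in seq_len(max(nuclei))) {
    sel <- nuclei == k
    bb <- mask_bbox(sel, pad = 2L)
    rows <- bb[1]:bb[2]; colsr <- bb[3]:bb[4]
    sub <- matrix(as.numeric(sel[rows, colsr]), length(rows), length(colsr))
    core <- open_n(sub, cfg$bleb_max_iter)
    if (sum(core) == 0) {
      rej[[length(rej) + 1L]] <- data.frame(nucleus_label = k,
                                            reason = "object_vanished")
      next
    }
    resid <- matrix(as.numeric(sub > 0 & core == 0), nrow(sub), ncol(sub))
    cl <- label8(resid)
    if (max(cl) == 0) next
    sz <- label_areas(cl)
    core_area <- sum(core)
    for (j in which(sz >= cfg$min_bleb_area)) {
      comp <- cl == j
      compm <- matrix(as.numeric(comp), nrow(sub), ncol(sub))
      touching <- any(ebi_mat(EBImage::dilate(
        compm, EBImage::makeBrush(3L, "box"))) > 0 & core > 0)
      if (!touching) {
        rej[[length(rej) + 1L]] <- data.frame(nucleus_label = k,
                                              reason = "not_touching")
        next
      }
      circ <- residual_circularity(compm, cfg)
      if (sz[j] < cfg$mn_reject_area && circ > cfg$mn_reject_circ) {
        rej[[length(rej) + 1L]] <- data.frame(nucleus_label = k,
                                              reason = "micronucleus_like")
        next
      }
      idx <- which(comp, arr.ind = TRUE)
      recs[[length(recs) + 1L]] <- data.frame(
        nucleus_label = k, method = "morphological", area_px = sz[j],
        relative_area = sz[j] / sum(sub),
        centroid_row = mean(idx[, 1]) + rows[1] - 1,
        centroid_col = mean(idx[, 2]) + colsr[1] - 1,
        touches_nucleus = TRUE, enrichment = NA_real_)
      masks[[length(masks) + 1L]] <-
        (colsr[1] - 1L + idx[, 2] - 1L) * H + (rows[1] - 1L + idx[, 1])
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else bleb_record_template()
  attr(out, "masks") <- masks
  attr(out, "nuclei") <- nuclei
  attr(out, "n_nuclei") <- max(nuclei)
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(nucleus_label = integer(0), reason = character(0))
  out
}

# form factor of a residual component; falls back to the pixel-perimeter
# estimate for components too small to trace
residual_circularity <- function(compm, cfg) {
  out <- tryCatch({
    ct <- trace_contour(compm)
    rs <- contour_resample(ct, 128L)
    sm <- contour_smooth(rs, cfg$contour_smooth_px)
    min(1, 4 * pi * sum(compm > 0) / contour_perimeter(sm)^2)
  }, error = function(e) NA_real_)
  if (is.na(out)) 1 else out  # untraceably small: treat as round
}

#' Bleb frequency and mean size
#'
#' Percentage of nuclei with at least one bleb, plus the mean bleb area.
#'
#' @param nuclei integer label mask of nuclei, or the nucleus count.
#' @param blebs bleb record data.frame.
#' @return list with `frequency_percent`, `mean_area_px`,
#'   `mean_relative_area`.
#' @export
bleb_frequency <- function(nuclei, blebs) {
  n <- if (is.matrix(nuclei)) max(nuclei) else as.integer(nuclei)
  if (n < 1L) stop("zero nuclei: frequency undefined")
  if (is.null(blebs) || nrow(blebs) == 0L)
    return(list(frequency_percent = 0, mean_area_px = NA_real_,
                mean_relative_area = NA_real_))
  list(frequency_percent = 100 * length(unique(blebs$nucleus_label)) / n,
       mean_area_px = mean(blebs$area_px),
       mean_relative_area = mean(blebs$relative_area))
}
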