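# Nucleus segmentation from the DNA channel, with QC flags for
# border-touching and mitotic nuclei.

#' Segment nuclei from a DNA-stain channel
#'
#' Foreground is taken above a global threshold (Otsu on the raw intensities
#' by default, or a fixed value / quantile from the configuration), after
#' optional Gaussian pre-smoothing. Touching nuclei are split by a
#' distance-transform watershed, objects below the minimum area are removed,
#' and labels are renumbered 1..count in raster order. Segmentation is fully
#' deterministic for a fixed configuration.
#'
#' A blank image (no foreground) yields an empty mask with a warning, not an
#' error.
#'
#' @param dna a [channel_image()] with role `"dna"`.
#' @param cfg a [nuc_config()].
#' @return list with `labels` (integer matrix), `count`, and `qc`
#'   data.frame (`label`, `touches_border`, `mitotic`, `smoothed`).
#' @export
segment_nuclei <- function(dna, cfg = nuc_config()) {
  stopifnot(inherits(dna, "channel_image"))
  if (dna$role != "dna") stop("segment_nuclei expects the dna channel")
  img <- dna$pixels
  smoothed <- cfg$seg_smooth_sigma > 0
  if (smoothed)
    img <- ebi_mat(EBImage::gblur(img, sigma = cfg$seg_smooth_sigma))
  th <- if (identical(cfg$seg_threshold, "otsu")) {
    otsu_threshold(img)
  } else if (identical(cfg$seg_threshold, "quantile")) {
    stats::quantile(img, cfg$seg_threshold_quantile, names = FALSE)
  } else cfg$seg_threshold
  fg <- matrix(as.numeric(img > th), nrow(img), ncol(img))
  fg <- ebi_mat(EBImage::fillHull(fg))  # noise holes corrupt every descriptor
  if (sum(fg) == 0) {
    warning("blank image: no foreground above threshold")
    return(list(labels = matrix(0L, nrow(img), ncol(img)), count = 0L,
                qc = data.frame(label = integer(0),
                                touches_border = logical(0),
                                mitotic = logical(0),
                                smoothed = logical(0))))
  }
  lab <- label8(fg)
  if (isTRUE(cfg$seg_watershed) && max(lab) > 0L) {
    # watershed per connected component (basins cannot cross components, so
    # this equals a whole-image watershed but runs on small bounding boxes)
    out <- matrix(0L, nrow(fg), ncol(fg))
    nxt <- 0L
    bbs <- label_bboxes(lab)
    for (k in seq_len(max(lab))) {
      bb <- c(max(1L, bbs[1, k] - 1L), min(nrow(fg), bbs[2, k] + 1L),
              max(1L, bbs[3, k] - 1L), min(ncol(fg), bbs[4, k] + 1L))
      sub <- matrix(as.numeric(lab[bb[1]:bb[2], bb[3]:bb[4]] == k),
                    bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L)
      ws <- ebi_mat(EBImage::watershed(EBImage::distmap(sub),
                                       tolerance = cfg$seg_watershed_tol,
                                       ext = 1))
      storage.mode(ws) <- "integer"
      tgt <- out[bb[1]:bb[2], bb[3]:bb[4]]
      tgt[ws > 0L] <- ws[ws > 0L] + nxt
      out[bb[1]:bb[2], bb[3]:bb[4]] <- tgt
      nxt <- nxt + max(ws)
    }
    lab <- out
  }
  storage.mode(lab) <- "integer"
  areas <- label_areas(lab)
  drop <- which(areas < cfg$seg_min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  rl <- relabel_consecutive(lab)
  lab <- rl$labels
  qc <- data.frame(
    label = seq_len(rl$count),
    touches_border = vapply(seq_len(rl$count), function(k)
      touches_border(lab, k), logical(1)),
    mitotic = flag_mitotic(lab, dna, k_mad = cfg$mitotic_k_mad),
    smoothed = rep(smoothed, rl$count)
  )
  list(labels = lab, count = rl$count, qc = qc)
}

touches_border <- function(lab, k) {
  any(lab[1, ] == k) || any(lab[nrow(lab), ] == k) ||
    any(lab[, 1] == k) || any(lab[, ncol(lab)] == k)
}

#' Flag mitotic nuclei by integrated DNA intensity
#'
#' Mitotic chromatin is condensed, so mitotic nuclei stand out by their
#' total (integrated, not mean) DNA staining intensity. A nucleus is flagged
#' when its integrated intensity exceeds `median + k_mad * MAD` over all
#' nuclei in the image (MAD with the usual 1.4826 normal-consistency
#' constant). With fewer than 4 nuclei the robust statistics are undefined:
#' no flags are raised and a warning is issued.
#'
#' @param mask integer label mask.
#' @param dna the DNA [channel_image()], same shape.
#' @param k_mad robustness multiplier (default 3).
#' @return logical vector, one flag per label 1..count.
#' @export
flag_mitotic <- function(mask, dna, k_mad = 3) {
  stopifnot(all(dim(mask) == dim(dna$pixels)))
  n <- max(mask)
  if (n == 0L) return(logical(0))
  tot <- as.numeric(rowsum(dna$pixels[mask > 0], mask[mask > 0]))
  # rowsum orders by sorted unique label == 1..n since labels consecutive
  if (n < 4L) {
    warning("fewer than 4 nuclei: mitotic flagging skipped ",
            "(robust statistics undefined)")
    return(rep(FALSE, n))
  }
  med <- stats::median(tot)
  madv <- stats::mad(tot)
  tot > med + k_mad * madv
}
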