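#' Run configuration for all analysis modules
#'
#' Collects every tunable parameter of the segmentation, shape-descriptor,
#' micronucleus, invagination and bleb modules, each with a documented default
#' and a declared legal range. The object serialises to a plain-text YAML file
#' with [write_config()] and round-trips identically through [read_config()].
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @section Parameters:
#' \describe{
#'   \item{seg_smooth_sigma}{Gaussian pre-smoothing sigma in px for nucleus
#'     segmentation. Default 0 (off): smoothing removes the very contour
#'     irregularities under study, so it is opt-in and recorded in QC.}
#'   \item{seg_threshold}{`"otsu"`, or a fixed numeric threshold in raw units,
#'     or `"quantile"` (then `seg_threshold_quantile` applies).}
#'   \item{seg_threshold_quantile}{quantile in (0,1) used when
#'     `seg_threshold = "quantile"`. Default 0.5.}
#'   \item{seg_min_area}{minimum object area in px^2 kept by segmentation.
#'     Default 100.}
#'   \item{seg_watershed}{split touching nuclei by distance-transform
#'     watershed. Default TRUE.}
#'   \item{seg_watershed_tol}{watershed tolerance (min depth between basins).
#'     Default 10 (deep enough not to split lobulated single nuclei).}
#'   \item{mitotic_k_mad}{a nucleus is flagged mitotic when its integrated DNA
#'     intensity exceeds median + k * MAD over all nuclei. Default 3.}
#'   \item{contour_points}{uniform arc-length resampling count for contour
#'     measurements. Default 256.}
#'   \item{contour_smooth_px}{Gaussian smoothing (in px of arc length) of the
#'     traced contour before perimeter/curvature measurement; corrects the
#'     stair-step bias of binary rasters. Default 1.5.}
#'   \item{curvature_sigma_frac}{curvature smoothing scale as a fraction of
#'     contour length. Default 0.02.}
#'   \item{efd_n_fixed}{number of harmonics for the EFD coefficient-ratio
#'     mode. Default 20.}
#'   \item{efd_fidelity}{reconstruction fidelity for the harmonics-needed
#'     mode: mean deviation must be below (1 - fidelity) * equivalent radius.
#'     Default 0.95.}
#'   \item{mn_max_ratio}{maximum micronucleus/nucleus equivalent-diameter
#'     ratio. Default 1/3.}
#'   \item{mn_min_area}{minimum candidate micronucleus area, px^2. Default 50.}
#'   \item{min_nucleus_area}{objects at least this large are nucleus
#'     candidates; smaller ones are micronucleus candidates. Default 1000.}
#'   \item{mn_low_thresh_scale}{second, lower threshold pass for dim
#'     micronuclei, as a fraction of the primary threshold. Default 0.6.}
#'   \item{cleanup_iter}{nucleus cleanup strength: opening radius in px
#'     (erosion then dilation with a disc of this radius). Default 2.}
#'   \item{cell_dilation_px}{nuclear mask dilation approximating the cell
#'     territory when no whole-cell stain is given. Default 25.}
#'   \item{inv_threshold_quantile}{per-nucleus lamin-B threshold quantile in
#'     (0,1), or NULL (default) for a per-nucleus Otsu threshold.}
#'   \item{inv_min_size}{minimum intranuclear lamin object size, px^2.
#'     Default 12.}
#'   \item{shrink_px}{nucleus erosion separating NE from intranuclear lamin.
#'     Default 4 (for ~0.1 um/px imagery; must exceed segmentation jitter plus
#'     the lamin ring width).}
#'   \item{inv_open_px}{radius of the morphological opening applied to the
#'     clipped intranuclear lamin mask; removes 1-px NE leaks. Default 1.}
#'   \item{bleb_dna_scale}{permissive chromatin threshold = per-cell Otsu on
#'     the DNA channel times this factor (blebs contain less DNA). Default 0.5.}
#'   \item{bleb_dna_quantile}{alternative: chromatin threshold as a quantile
#'     of in-cell DNA intensities; NULL (default) uses the scaled Otsu.}
#'   \item{bleb_close_px}{closing radius bridging the lamin-ring gap before
#'     filling the lamin-B object. Default 3.}
#'   \item{bleb_lamin_dilate}{dilation of the lamin-B object before
#'     subtraction, suppressing 1-2 px boundary slivers. Default 2.}
#'   \item{min_bleb_area}{minimum bleb candidate area, px^2. Default 30.}
#'   \item{max_bleb_frac}{maximum bleb area as a fraction of the nucleus
#'     area. Default 0.5.}
#'   \item{bleb_max_iter}{cleanup iterations for the morphological bleb
#'     method (the "maximum" cleanup that cuts blebs off). Default 8.}
#'   \item{mn_reject_area}{morphological method: candidates smaller than this
#'     AND rounder than `mn_reject_circ` are rejected as micronuclei.
#'     Default 150.}
#'   \item{mn_reject_circ}{form-factor cutoff for micronucleus rejection.
#'     Default 0.85.}
#'   \item{stain_thresh_scale}{permissive threshold scale for segmenting the
#'     single NE/nucleoplasm stain in the morphological bleb method.
#'     Default 0.5.}
#'   \item{iou_min}{IoU at which a detection matches a planted object when
#'     scoring. Default 0.3.}
#'   \item{seed}{integer seed for any stochastic step. Default 1.}
#' }
#' @return an object of class `nuc_config` (a validated named list).
#' @export
nuc_config <- function(...) {
  defaults <- list(
    seg_smooth_sigma = 0,
    seg_threshold = "otsu",
    seg_threshold_quantile = 0.5,
    seg_min_area = 100,
    seg_watershed = TRUE,
    seg_watershed_tol = 10,
    mitotic_k_mad = 3,
    contour_points = 256L,
    contour_smooth_px = 1.5,
    curvature_sigma_frac = 0.02,
    efd_n_fixed = 20L,
    efd_fidelity = 0.95,
    mn_max_ratio = 1 / 3,
    mn_min_area = 50,
    min_nucleus_area = 1000,
    mn_low_thresh_scale = 0.6,
    cleanup_iter = 2L,
    cell_dilation_px = 25L,
    inv_threshold_quantile = NULL,
    inv_min_size = 12,
    shrink_px = 4L,
    inv_open_px = 1L,
    bleb_dna_scale = 0.5,
    bleb_dna_quantile = NULL,
    bleb_close_px = 3L,
    bleb_lamin_dilate = 2L,
    min_bleb_area = 30,
    max_bleb_frac = 0.5,
    bleb_max_iter = 8L,
    mn_reject_area = 150,
    mn_reject_circ = 0.85,
    stain_thresh_scale = 0.5,
    iou_min = 0.3,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "nuc_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$seg_smooth_sigma >= 0, "seg_smooth_sigma must be >= 0")
  chk(identical(cfg$seg_threshold, "otsu") ||
        identical(cfg$seg_threshold, "quantile") ||
        (is.numeric(cfg$seg_threshold) && length(cfg$seg_threshold) == 1L),
      "seg_threshold must be \"otsu\", \"quantile\" or a number")
  chk(cfg$seg_threshold_quantile > 0 && cfg$seg_threshold_quantile < 1,
      "seg_threshold_quantile must be in (0,1)")
  chk(cfg$seg_min_area >= 0, "seg_min_area must be >= 0")
  chk(cfg$mitotic_k_mad > 0, "mitotic_k_mad must be > 0")
  chk(cfg$contour_points >= 32, "contour_points must be >= 32")
  chk(cfg$contour_smooth_px >= 0, "contour_smooth_px must be >= 0")
  chk(cfg$curvature_sigma_frac >= 0, "curvature_sigma_frac must be >= 0")
  chk(cfg$efd_n_fixed >= 1, "efd_n_fixed must be >= 1")
  chk(cfg$efd_fidelity > 0 && cfg$efd_fidelity < 1,
      "efd_fidelity must be in (0,1)")
  chk(cfg$mn_max_ratio > 0 && cfg$mn_max_ratio < 1,
      "mn_max_ratio must be in (0,1)")
  chk(cfg$mn_min_area >= 0 && cfg$min_nucleus_area > cfg$mn_min_area,
      "need 0 <= mn_min_area < min_nucleus_area")
  chk(cfg$mn_low_thresh_scale > 0 && cfg$mn_low_thresh_scale <= 1,
      "mn_low_thresh_scale must be in (0,1]")
  chk(cfg$cleanup_iter >= 0, "cleanup_iter must be >= 0")
  chk(cfg$cell_dilation_px >= 1, "cell_dilation_px must be >= 1")
  chk(is.null(cfg$inv_threshold_quantile) ||
        (cfg$inv_threshold_quantile > 0 && cfg$inv_threshold_quantile < 1),
      "inv_threshold_quantile must be NULL or in (0,1)")
  chk(cfg$shrink_px >= 1, "shrink_px must be >= 1")
  chk(cfg$inv_open_px >= 0, "inv_open_px must be >= 0")
  chk(is.null(cfg$bleb_dna_quantile) ||
        (cfg$bleb_dna_quantile > 0 && cfg$bleb_dna_quantile < 1),
      "bleb_dna_quantile must be NULL or in (0,1)")
  chk(cfg$bleb_dna_scale > 0 && cfg$bleb_dna_scale <= 1,
      "bleb_dna_scale must be in (0,1]")
  chk(cfg$max_bleb_frac > 0 && cfg$max_bleb_frac < 1,
      "max_bleb_frac must be in (0,1)")
  chk(cfg$bleb_max_iter >= 1, "bleb_max_iter must be >= 1")
  chk(cfg$mn_reject_circ > 0 && cfg$mn_reject_circ <= 1,
      "mn_reject_circ must be in (0,1]")
  chk(cfg$iou_min > 0 && cfg$iou_min <= 1, "iou_min must be in (0,1]")
  invisible(cfg)
}

#' @export
print.nuc_config <- function(x, ...) {
  cat("<nuc_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Serialise a configuration to a YAML file
#' @param cfg a [nuc_config()] object.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "nuc_config"))
  lst <- unclass(cfg)
  # encode NULLs explicitly so the round trip preserves them
  for (nm in names(lst)) if (is.null(lst[[nm]])) lst[[nm]] <- "NULL"
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path YAML path.
#' @return a [nuc_config()] object.
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  for (nm in names(lst)) if (identical(lst[[nm]], "NULL")) lst[nm] <- list(NULL)
  int_fields <- c("contour_points", "efd_n_fixed", "cleanup_iter",
                  "cell_dilation_px", "shrink_px", "inv_open_px",
                  "bleb_close_px", "bleb_lamin_dilate", "bleb_max_iter", "seed")
  for (nm in int_fields)
    if (!is.null(lst[[nm]])) lst[[nm]] <- as.integer(lst[[nm]])
  do.call(nuc_config, lst)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialisation; recorded in run summaries for
#' provenance.
#' @param cfg a [nuc_config()] object.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(cfg, f)
  unname(tools::md5sum(f))
}
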