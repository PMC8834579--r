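# End-to-end orchestration: segment -> descriptors -> detectors -> summaries,
# with per-object CSVs and a JSON run summary.

#' Run the full analysis pipeline over a set of images
#'
#' Each image is a named list of [channel_image()]s (at least `dna`;
#' optionally `laminB`, `laminAC`, `wholeCell`), or a directory containing
#' files named `<image>_<role>.tif`/`.png`. Nuclei flagged border-touching
#' or mitotic are excluded from shape statistics but listed in the QC table.
#' Detectors whose required channels are missing are skipped with a warning
#' (an error under `strict = TRUE`).
#'
#' Reruns with identical inputs and configuration produce identical CSVs.
#'
#' @param images named list of images (each a named list of channels), or a
#'   directory path.
#' @param cfg a [nuc_config()].
#' @param which subset of `c("shape", "micronuclei", "invaginations",
#'   "blebs")`.
#' @param out_dir optional output directory for CSVs and the JSON summary.
#' @param strict error (instead of warn) on missing channels.
#' @return object of class `nuc_run` with `summary` (per-image and pooled
#'   statistics), `nuclei`, `micronuclei`, `invaginations`, `blebs`, `qc`
#'   data.frames.
#' @export
run_pipeline <- function(images, cfg = nuc_config(),
                         which = c("shape", "micronuclei", "invaginations",
                                   "blebs"),
                         out_dir = NULL, strict = FALSE) {
  which <- match.arg(which, several.ok = TRUE)
  if (is.character(images) && length(images) == 1L) {
    images <- load_image_dir(images)
  }
  if (length(images) == 0L) stop("no images found")
  if (is.null(names(images)))
    names(images) <- sprintf("image%03d", seq_along(images))
  complain <- function(msg) if (strict) stop(msg) else warning(msg)
  all_nuc <- list(); all_mn <- list(); all_inv <- list(); all_bleb <- list()
  all_qc <- list(); per_image <- list()
  for (nm in names(images)) {
    ch <- images[[nm]]
    if (is.null(ch$dna)) { complain(paste0(nm, ": no dna channel")); next }
    seg <- segment_nuclei(ch$dna, cfg)
    excluded <- seg$qc$label[seg$qc$touches_border | seg$qc$mitotic]
    # nucleus statistics cover nucleus-scale objects only; micronucleus-size
    # objects are handled by their own detector
    areas <- label_areas(seg$labels)
    retained <- setdiff(which(areas >= cfg$min_nucleus_area), excluded)
    qc <- cbind(image = nm, seg$qc)
    all_qc[[nm]] <- qc
    img_sum <- list(image = nm, nucleus_count = length(retained))
    if ("shape" %in% which && length(retained)) {
      nd <- nucleus_descriptors(seg$labels, cfg, labels = retained)
      all_nuc[[nm]] <- cbind(image = nm, nd)
      for (v in c("form_factor", "eccentricity", "solidity",
                  "mean_negative_curvature")) {
        img_sum[[paste0("mean_", v)]] <- mean(nd[[v]])
        img_sum[[paste0("median_", v)]] <- stats::median(nd[[v]])
      }
    }
    if ("micronuclei" %in% which) {
      mn <- detect_micronuclei(ch$dna, cfg, whole_cell = ch$wholeCell,
                               channels = ch[!vapply(ch, is.null, TRUE)])
      if (nrow(mn$records))
        all_mn[[nm]] <- cbind(image = nm, mn$records)
      img_sum$micronucleus_frequency_percent <- mn$frequency
    }
    if ("invaginations" %in% which) {
      if (is.null(ch$laminB)) {
        complain(paste0(nm, ": no laminB channel; skipping invaginations"))
      } else {
        inv <- detect_invaginations(ch$dna, ch$laminB, cfg)
        if (nrow(inv$results))
          all_inv[[nm]] <- cbind(image = nm, inv$results)
        img_sum$mean_invagination_count <-
          if (nrow(inv$results)) mean(inv$results$intranuclear_object_count)
          else NA_real_
        img_sum$mean_intranuclear_area_fraction <-
          if (nrow(inv$results)) mean(inv$results$intranuclear_area_fraction)
          else NA_real_
      }
    }
    if ("blebs" %in% which) {
      if (is.null(ch$laminB)) {
        complain(paste0(nm, ": no laminB channel; skipping lamin-gap blebs"))
      } else {
        bl <- detect_blebs_lamin_gap(ch$dna, ch$laminB, cfg,
                                     laminAC = ch$laminAC)
        if (nrow(bl)) all_bleb[[nm]] <- cbind(image = nm, as.data.frame(bl))
        bf <- bleb_frequency(attr(bl, "n_nuclei"), bl)
        img_sum$bleb_frequency_percent <- bf$frequency_percent
        img_sum$mean_bleb_area_px <- bf$mean_area_px
      }
    }
    per_image[[nm]] <- img_sum
  }
  bindf <- function(l) if (length(l)) do.call(rbind, l) else NULL
  res <- list(
    summary = list(per_image = per_image,
                   pooled = pool_summaries(per_image),
                   config_hash = config_hash(cfg),
                   software_version = as.character(
                     utils::packageVersion("nucleoshape")),
                   timestamp = format(Sys.time(), tz = "UTC")),
    nuclei = bindf(all_nuc), micronuclei = bindf(all_mn),
    invaginations = bindf(all_inv), blebs = bindf(all_bleb),
    qc = bindf(all_qc), cfg = cfg)
  class(res) <- "nuc_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

pool_summaries <- function(per_image) {
  if (!length(per_image)) return(list())
  nums <- unique(unlist(lapply(per_image, function(s)
    names(s)[vapply(s, is.numeric, TRUE)])))
  out <- list()
  for (v in nums) {
    vals <- unlist(lapply(per_image, function(s) s[[v]]))
    out[[v]] <- if (v == "nucleus_count") sum(vals, na.rm = TRUE)
                else mean(vals, na.rm = TRUE)
  }
  out
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("nuclei", "micronuclei", "invaginations", "blebs", "qc")) {
    if (!is.null(res[[nm]]))
      write_records(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

load_image_dir <- function(path) {
  if (!dir.exists(path)) stop("no images found: ", path, " is not a directory")
  files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  if (!length(files)) stop("no images found in ", path)
  roles <- c(dna = "dna", laminb = "laminB", laminac = "laminAC",
             wholecell = "wholeCell", ne = "nuclearEnvelope")
  m <- regmatches(files, regexec("^(.*)_([A-Za-z]+)\\.(tif|tiff|png)$", files))
  images <- list()
  for (i in seq_along(files)) {
    if (length(m[[i]]) == 0L) next
    base <- m[[i]][2]; tag <- tolower(m[[i]][3])
    if (!tag %in% names(roles)) next
    images[[base]] <- images[[base]] %||% list()
    images[[base]][[roles[[tag]]]] <-
      read_image(file.path(path, files[i]), roles[[tag]])
  }
  if (!length(images)) stop("no images found: no files match <name>_<role>.<ext>")
  images
}

#' @export
print.nuc_run <- function(x, ...) {
  p <- x$summary$pooled
  cat("<nuc_run>\n")
  cat(sprintf("  images: %d   nuclei retained: %d\n",
              length(x$summary$per_image), p$nucleus_count %||% 0))
  if (!is.null(p$mean_form_factor))
    cat(sprintf("  mean form factor %.3f  eccentricity %.3f  solidity %.3f\n",
                p$mean_form_factor, p$mean_eccentricity, p$mean_solidity))
  if (!is.null(p$micronucleus_frequency_percent))
    cat(sprintf("  micronucleus frequency: %.1f%%\n",
                p$micronucleus_frequency_percent))
  if (!is.null(p$mean_invagination_count))
    cat(sprintf("  mean invagination count: %.2f\n",
                p$mean_invagination_count))
  if (!is.null(p$bleb_frequency_percent))
    cat(sprintf("  bleb frequency: %.1f%%\n", p$bleb_frequency_percent))
  cat(sprintf("  config %s\n", x$summary$config_hash))
  invisible(x)
}
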