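#' Single-channel fluorescence image with a declared biological role
#'
#' A `channel_image` wraps one 2D non-negative intensity matrix together with
#' the biological role of the channel (what was stained), the pixel size if
#' known, and the bit depth of the source file. Intensities are kept in raw
#' units; the package never rescales on load, so thresholds stated in raw
#' units or as quantiles remain meaningful.
#'
#' @param pixels numeric matrix of intensities, `[row, col]`, all `>= 0`,
#'   both dimensions `>= 16`.
#' @param role one of `"dna"`, `"laminB"`, `"laminAC"`, `"nuclearEnvelope"`,
#'   `"wholeCell"`.
#' @param pixel_size_um physical pixel size in micrometres, or `NA` if unknown.
#' @param bit_depth `8`, `16` or `"float"`.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, role, pixel_size_um = NA_real_,
                          bit_depth = "float") {
  roles <- c("dna", "laminB", "laminAC", "nuclearEnvelope", "wholeCell")
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(dim(pixels) < 16L))
    stop("image too small: both dimensions must be >= 16")
  if (anyNA(pixels) || min(pixels) < 0)
    stop("intensities must be finite and non-negative")
  role <- match.arg(role, roles)
  if (!is.na(pixel_size_um) && pixel_size_um <= 0)
    stop("pixel_size_um must be positive or NA")
  if (!(identical(bit_depth, "float") || bit_depth %in% c(8, 16)))
    stop("bit_depth must be 8, 16 or \"float\"")
  structure(list(pixels = pixels, role = role,
                 pixel_size_um = pixel_size_um, bit_depth = bit_depth),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> role=%s  %d x %d px  bit_depth=%s  range [%g, %g]\n",
              x$role, nrow(x$pixels), ncol(x$pixels), as.character(x$bit_depth),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Read a single-plane TIFF or PNG as a channel image
#'
#' Pixels are loaded unscaled (integer sample values for TIFF/PNG) and the
#' source bit depth is recorded. Multi-page TIFFs require an explicit `page`;
#' RGB images require an explicit `channel` index.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param role channel role, see [channel_image()].
#' @param page page index for multi-page TIFF (1-based).
#' @param channel channel index for RGB images (1-based).
#' @param pixel_size_um physical pixel size, if known.
#' @return a [channel_image()].
#' @export
read_image <- function(path, role, page = NULL, channel = NULL,
                       pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) > 1L && is.null(page))
      stop("ambiguous plane: multi-page TIFF (", length(pages),
           " pages) needs an explicit page index")
    img <- pages[[page %||% 1L]]
    # sample depth: readTIFF(as.is=TRUE) returns integers at native depth
    depth <- if (max(img) > 255) 16 else 8
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    img <- img * (2^depth - 1)  # readPNG rescales to [0,1]; undo
  } else stop("unsupported format: ", ext, " (expected TIFF or PNG)")
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("RGB image without channel selector: pass channel = 1, 2 or 3")
    img <- img[, , channel]
  }
  channel_image(matrix(as.numeric(img), nrow(img), ncol(img)),
                role = role, pixel_size_um = pixel_size_um, bit_depth = depth)
}

#' Write a label mask as a 16-bit TIFF
#'
#' Labels are stored as raw 16-bit sample values so that reading back with
#' [read_mask()] is bit-exact.
#'
#' @param mask integer label matrix (0 = background).
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#' @param path path to a 16-bit TIFF label mask.
#' @return integer label matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write a table of per-object records to CSV
#'
#' One row per record, stable column order, header row, floats at full
#' (17 significant digit) precision so that a write/read round trip is
#' value-identical well below 1e-12 relative tolerance.
#'
#' @param records data.frame of records sharing one schema.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  rec <- records
  for (j in seq_along(rec)) {
    if (is.double(rec[[j]])) rec[[j]] <- sprintf("%.17g", rec[[j]])
  }
  utils::write.csv(rec, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a record CSV written by [write_records()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
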