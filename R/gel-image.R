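#' Multi-channel gel image
#'
#' Container for a digitised fluorescence gel: one 2-D intensity raster per
#' emission channel (e.g. the 700 nm sample channel and the 800 nm
#' molecular-weight-marker channel), in arbitrary linear fluorescence units.
#' Row index increases downward, i.e. in the direction of electrophoretic
#' migration; indices are 1-based as usual in R.
#'
#' @param pixels a list of numeric matrices, one per channel, identical
#'   dimensions, all values finite and >= 0.
#' @param channels character vector of channel labels (e.g.
#'   `c("700nm", "800nm")`), same length as `pixels`.
#' @param bit_depth integer, nominal bit depth of the source scan.
#' @param meta named list of free-form provenance (gel id, date, instrument).
#' @return an object of class `gel_image`.
#' @export
gel_image <- function(pixels, channels, bit_depth = 16L, meta = list()) {
  if (!is.list(pixels) || length(pixels) < 1L)
    stop("at least one channel required")
  if (length(channels) != length(pixels))
    stop("page/label count mismatch: ", length(pixels), " channel(s), ",
         length(channels), " label(s)")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  dims <- dim(pixels[[1L]])
  for (i in seq_along(pixels)) {
    p <- pixels[[i]]
    if (!is.matrix(p) || !is.numeric(p))
      stop("channel ", channels[i], " is not a numeric matrix")
    if (!identical(dim(p), dims))
      stop("all channels must share identical dimensions")
    if (!all(is.finite(p)) || any(p < 0))
      stop("intensities must be finite and >= 0")
    storage.mode(pixels[[i]]) <- "double"
  }
  names(pixels) <- channels
  structure(list(pixels = pixels, channels = channels,
                 bit_depth = as.integer(bit_depth), meta = meta),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  d <- dim(x$pixels[[1L]])
  cat("gel_image: ", d[1L], " x ", d[2L], " px, ",
      length(x$channels), " channel(s) [",
      paste(x$channels, collapse = ", "), "], ",
      x$bit_depth, "-bit\n", sep = "")
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$pixels[[1L]])

#' Extract one channel as a matrix
#' @param img a `gel_image`.
#' @param channel channel label.
#' @return numeric matrix.
#' @export
gel_channel <- function(img, channel) {
  if (!channel %in% img$channels)
    stop("unknown channel '", channel, "' (have: ",
         paste(img$channels, collapse = ", "), ")")
  img$pixels[[channel]]
}

#' Read a gel scan from disk
#'
#' Reads a single- or multi-page grayscale TIFF (8/16-bit), or a set of
#' per-channel grayscale PNG files, into a [gel_image]. TIFF intensities are
#' preserved bit-exactly; PNG values are rescaled to the integer range of the
#' stated bit depth.
#'
#' @param path one TIFF path, or a character vector of PNG paths (one per
#'   channel).
#' @param channels channel labels, in page/file order.
#' @param meta optional provenance list.
#' @return a [gel_image].
#' @export
read_gel <- function(path, channels, meta = list()) {
  if (length(path) < 1L || !all(file.exists(path)))
    stop("unreadable file: ", paste(path[!file.exists(path)], collapse = ", "))
  ext <- tolower(tools::file_ext(path[1L]))
  if (length(path) == 1L && ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bd <- 16L
  } else if (all(tolower(tools::file_ext(path)) == "png")) {
    pages <- lapply(path, function(p) {
      m <- png::readPNG(p)
      round(m * 65535)
    })
    bd <- 16L
  } else {
    stop("unsupported image format: ", path[1L])
  }
  if (length(pages) != length(channels))
    stop("page/label count mismatch: ", length(pages), " page(s), ",
         length(channels), " label(s)")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] == 1L) p <- p[, , 1L]
      else stop("non-grayscale page (", dim(p)[3L], " samples per pixel)")
    }
    p
  })
  gel_image(pages, channels, bit_depth = bd, meta = meta)
}

#' Write a gel image to a multi-page 16-bit TIFF
#'
#' @param img a [gel_image]; intensities must fit in the 16-bit range.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gel <- function(img, path) {
  mx <- 65535
  pages <- lapply(img$pixels, function(p) {
    if (max(p) > mx) stop("intensity exceeds 16-bit range")
    round(p) / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
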