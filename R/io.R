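#' Read a grayscale TIFF image as an intensity matrix
#'
#' Integer TIFFs are returned on their native scale (e.g. 0..65535 for
#' 16-bit); floating-point TIFFs as stored.
#'
#' @param path TIFF file path.
#' @param page Page (directory) to read for multi-page files.
#' @return Numeric matrix (rows y, columns x).
#' @export
read_image_tiff <- function(path, page = 1L) {
  if (!file.exists(path)) abort_invalid(sprintf("image file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (page < 1L || page > length(pages)) {
    abort_invalid(sprintf("%s has %d page(s); page %d requested", path,
                          length(pages), page))
  }
  img <- pages[[page]]
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse grayscale-as-RGB
  storage.mode(img) <- "double"
  img
}

#' Write an intensity matrix as an unsigned 16-bit grayscale TIFF
#'
#' Intensities are stored as `round(img / max_value * 65535)`; pass the
#' native `max_value = 65535` to write values through unchanged.
#'
#' @param img Numeric matrix with values in `[0, max_value]`.
#' @param path Output path.
#' @param max_value Intensity mapped to full scale (default 65535).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, max_value = 65535) {
  img <- as_intensity_matrix(img)
  if (!is_number(max_value) || max_value <= 0) {
    abort_invalid("`max_value` must be positive")
  }
  if (min(img) < 0 || max(img) > max_value) {
    abort_invalid("image intensities must lie in [0, max_value]")
  }
  tiff::writeTIFF(img / max_value, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary mask from a TIFF file
#'
#' Any strictly positive pixel is `TRUE`.
#'
#' @param path TIFF file path.
#' @return Logical matrix.
#' @export
read_mask_tiff <- function(path) {
  read_image_tiff(path) > 0
}

## Write any list as pretty JSON (scalars unboxed).
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
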