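#' Pearson's correlation coefficient between two channels
#'
#' Standard product-moment correlation of pixel intensities over the masked
#' region (whole image when `mask` is `NULL`). Invariant under affine
#' rescaling with positive slope of either channel.
#'
#' @param a,b Numeric matrices of the same dimensions.
#' @param mask Optional logical matrix selecting the pixels to analyze.
#' @return Correlation in \[-1, 1\]. A constant channel within the mask
#'   raises a degenerate-input condition.
#' @export
pearson_coefficient <- function(a, b, mask = NULL) {
  a <- as_intensity_matrix(a); b <- as_intensity_matrix(b)
  if (!all(dim(a) == dim(b))) abort_invalid("channels must have identical dimensions")
  if (is.null(mask)) {
    va <- as.vector(a); vb <- as.vector(b)
  } else {
    stopifnot(is.matrix(mask), is.logical(mask))
    if (!all(dim(mask) == dim(a))) abort_invalid("mask must match the image dimensions")
    va <- a[mask]; vb <- b[mask]
  }
  if (length(va) < 2L) abort_invalid("need at least 2 pixels to correlate")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort_degenerate("zero variance in a channel: correlation undefined")
  }
  stats::cor(va, vb)
}

#' Manders overlap coefficients M1 and M2
#'
#' Thresholded Manders coefficients in the JaCOP convention:
#' `M1 = sum of A over pixels supra-threshold in both channels / sum of A
#' over pixels with A > thrA`, and M2 with the channels swapped. Both are in
#' \[0, 1\] by construction (never clamped post hoc) and reduce to the
#' classic coefficients at `thrA = thrB = 0` for nonnegative images. M1/M2
#' are invariant under positive rescaling of the non-denominator channel
#' only; rescaling the denominator channel moves its threshold cut.
#'
#' @param a,b Numeric matrices of the same dimensions.
#' @param thrA,thrB Per-channel intensity thresholds (foreground strictly
#'   above).
#' @return Named numeric vector `c(m1, m2)`. Zero supra-threshold signal in
#'   a denominator channel raises a degenerate-input condition.
#' @export
manders_coefficients <- function(a, b, thrA = 0, thrB = 0) {
  a <- as_intensity_matrix(a); b <- as_intensity_matrix(b)
  if (!all(dim(a) == dim(b))) abort_invalid("channels must have identical dimensions")
  fa <- a > thrA; fb <- b > thrB
  denom1 <- sum(a[fa]); denom2 <- sum(b[fb])
  if (denom1 <= 0 || denom2 <= 0) {
    abort_degenerate("no supra-threshold signal in a denominator channel")
  }
  c(m1 = sum(a[fa & fb]) / denom1, m2 = sum(b[fa & fb]) / denom2)
}

#' Colocalization pipeline: threshold, Pearson and Manders
#'
#' Applies per-channel maximum-entropy thresholds (when `auto_threshold`),
#' then computes Pearson's r and the thresholded Manders coefficients. By
#' default r is computed on the raw intensities over the union of the two
#' supra-threshold masks; `pcc_mode = "whole_image"` uses every pixel
#' instead (both conventions exist in practice and the choice is recorded in
#' the result).
#'
#' @param a,b Numeric matrices (two channels of one field).
#' @param auto_threshold Use [kapur_threshold()] per channel (default). When
#'   `FALSE`, `thrA`/`thrB` are used as given.
#' @param thrA,thrB Manual thresholds (ignored under `auto_threshold`).
#' @param pcc_mode `"union_mask"` (default) or `"whole_image"`.
#' @return An object of class `"coloc_result"`: `pearson_r`, `m1`, `m2`,
#'   `thrA`, `thrB`, `n_pixels`, `pcc_mode`.
#' @examples
#' syn <- synth_two_channel_puncta(30, coloc_fraction = 1, seed = 1)
#' coloc_pipeline(syn$channel_a, syn$channel_b)
#' @export
coloc_pipeline <- function(a, b, auto_threshold = TRUE, thrA = 0, thrB = 0,
                           pcc_mode = c("union_mask", "whole_image")) {
  pcc_mode <- match.arg(pcc_mode)
  if (!is_flag(auto_threshold)) abort_invalid("`auto_threshold` must be TRUE or FALSE")
  if (auto_threshold) {
    thrA <- kapur_threshold(a)
    thrB <- kapur_threshold(b)
  }
  m <- manders_coefficients(a, b, thrA, thrB)
  mask <- if (pcc_mode == "union_mask") (a > thrA) | (b > thrB) else NULL
  r <- pearson_coefficient(a, b, mask)
  structure(
    list(pearson_r = r, m1 = unname(m["m1"]), m2 = unname(m["m2"]),
         thrA = thrA, thrB = thrB,
         n_pixels = if (is.null(mask)) length(a) else sum(mask),
         pcc_mode = pcc_mode),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result: r = %.3f, M1 = %.3f, M2 = %.3f (thr %.3g/%.3g, %d px, %s)>\n",
    x$pearson_r, x$m1, x$m2, x$thrA, x$thrB, x$n_pixels, x$pcc_mode))
  invisible(x)
}
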