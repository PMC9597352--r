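#' Corrected total cell fluorescence (CTCF)
#'
#' `CTCF = integrated_density - cell_area * background_mean`: the summed
#' intensity of the cell region corrected by the expected background
#' contribution over the same area. Units follow the ImageJ "Measure"
#' convention: `cell_area` in pixels with `background_mean` per pixel (any
#' consistent pair of units works). Negative values are possible when the
#' background region is brighter than the cell and are reported with a
#' warning, never clamped.
#'
#' @param integrated_density Summed intensity over the cell region (>= 0).
#' @param cell_area Region area (> 0), same unit system as
#'   `background_mean`.
#' @param background_mean Mean intensity of a background region.
#' @return The CTCF value.
#' @examples
#' ctcf(1000, 10, 5)  # 950
#' @export
ctcf <- function(integrated_density, cell_area, background_mean) {
  if (!is_number(integrated_density) || integrated_density < 0) {
    abort_invalid("`integrated_density` must be a nonnegative number")
  }
  if (!is_number(cell_area) || cell_area <= 0) {
    abort_invalid("`cell_area` must be positive")
  }
  if (!is_number(background_mean)) abort_invalid("`background_mean` must be a number")
  out <- integrated_density - cell_area * background_mean
  if (out < 0) warning("negative CTCF: background region brighter than the cell")
  out
}

#' CTCF measured from an image and region masks
#'
#' Derives the three CTCF operands from pixel data: integrated density and
#' area (in pixels) over `cell_mask`, mean background over
#' `background_mask`, then applies [ctcf()].
#'
#' @param img Numeric intensity matrix.
#' @param cell_mask,background_mask Logical matrices matching `img`;
#'   non-empty and disjoint regions.
#' @return The CTCF value, with the operands attached as attribute
#'   `"operands"`.
#' @export
ctcf_from_image <- function(img, cell_mask, background_mask) {
  img <- as_intensity_matrix(img)
  stopifnot(is.matrix(cell_mask), is.logical(cell_mask),
            is.matrix(background_mask), is.logical(background_mask))
  if (!all(dim(cell_mask) == dim(img)) || !all(dim(background_mask) == dim(img))) {
    abort_invalid("masks must match the image dimensions")
  }
  if (!any(cell_mask)) abort_invalid("empty cell mask")
  if (!any(background_mask)) abort_invalid("empty background mask")
  if (any(cell_mask & background_mask)) {
    abort_invalid("cell and background masks must be disjoint")
  }
  intden <- sum(img[cell_mask])
  area <- sum(cell_mask)
  bg <- mean(img[background_mask])
  out <- ctcf(intden, area, bg)
  attr(out, "operands") <- c(integrated_density = intden, cell_area = area,
                             background_mean = bg)
  out
}

#' Residual fractions of a degradation time course
#'
#' Normalizes the mean intensity at each chase time to the time-0 pulse
#' intensity: `fraction(t) = intensity(t) / intensity(0)`, so the pulse
#' itself is 1. Scale-invariant: multiplying the whole course by a positive
#' constant leaves the fractions unchanged.
#'
#' @param tc Data frame with columns `t_min` (strictly increasing, first
#'   value 0) and `mean_intensity` (>= 0).
#' @return Data frame `t_min`, `fraction`.
#' @examples
#' tc <- synth_decay_timecourse(100, half_life_min = 30)
#' degradation_fractions(tc)
#' @export
degradation_fractions <- function(tc) {
  stopifnot(is.data.frame(tc))
  if (!all(c("t_min", "mean_intensity") %in% names(tc))) {
    abort_invalid("time course needs columns `t_min` and `mean_intensity`")
  }
  if (nrow(tc) < 1L || tc$t_min[1L] != 0 || any(diff(tc$t_min) <= 0)) {
    abort_invalid("`t_min` must start at 0 (the pulse) and be strictly increasing")
  }
  if (any(tc$mean_intensity < 0)) abort_invalid("intensities must be >= 0")
  pulse <- tc$mean_intensity[1L]
  if (pulse <= 0) abort_degenerate("zero pulse intensity: fractions undefined")
  data.frame(t_min = tc$t_min, fraction = tc$mean_intensity / pulse)
}

#' Fold change of a treated mean over a control mean
#'
#' @param treated_mean Mean intensity of the treated group (>= 0).
#' @param control_mean Mean intensity of the control group (> 0).
#' @return `treated_mean / control_mean`.
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (!is_number(treated_mean) || treated_mean < 0) {
    abort_invalid("`treated_mean` must be a nonnegative number")
  }
  if (!is_number(control_mean)) abort_invalid("`control_mean` must be a number")
  if (control_mean <= 0) abort_degenerate("zero or negative control mean: fold change undefined")
  treated_mean / control_mean
}

#' Fit a ratiometric pH calibration line
#'
#' Ordinary least-squares fit of the 340/380 nm excitation ratio on buffer
#' pH. The dye response is locally linear over the narrow acidic range
#' (pH 4-6) where lysosomal measurements are made; the fitted line is used
#' to extrapolate sample pH from measured ratios via [ph_from_ratio()].
#'
#' @param readings Data frame with columns `ph` and `ratio_340_380`,
#'   containing at least 2 distinct pH values.
#' @return An object of class `"ph_calibration"`: `slope`, `intercept`,
#'   `sigma` (residual standard error, `NA` with < 3 points), `n`,
#'   `ph_range`.
#' @examples
#' cal <- synth_calibration_readings(-0.3, 2.5, seq(4, 6, by = 0.5))
#' fit_ph_calibration(cal)
#' @export
fit_ph_calibration <- function(readings) {
  stopifnot(is.data.frame(readings))
  if (!all(c("ph", "ratio_340_380") %in% names(readings))) {
    abort_invalid("readings need columns `ph` and `ratio_340_380`")
  }
  if (length(unique(readings$ph)) < 2L) {
    abort_invalid("need at least 2 distinct pH values to fit a line")
  }
  fit <- stats::lm(ratio_340_380 ~ ph, data = readings)
  df <- nrow(readings) - 2L
  s <- if (df > 0) sqrt(sum(stats::residuals(fit)^2) / df) else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         sigma = s,
         n = nrow(readings),
         ph_range = range(readings$ph)),
    class = "ph_calibration"
  )
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf(
    "<ph_calibration: ratio = %.4f * pH + %.4f (n = %d, pH %.2f-%.2f, sigma %.4g)>\n",
    x$slope, x$intercept, x$n, x$ph_range[1L], x$ph_range[2L], x$sigma))
  invisible(x)
}

#' @export
coef.ph_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted ratio at given pH values
#' @param object A `"ph_calibration"`.
#' @param newdata Optional data frame with a `ph` column (or a numeric
#'   vector of pH values).
#' @param ... Ignored.
#' @return Predicted 340/380 ratios.
#' @export
predict.ph_calibration <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) {
    abort_invalid("supply `newdata` with the pH values to predict at")
  } else if (is.data.frame(newdata)) newdata$ph else newdata
  object$slope * ph + object$intercept
}

#' Invert a pH calibration: pH from a measured ratio
#'
#' `pH = (ratio - intercept) / slope`. Results outside the calibrated pH
#' range are returned with attribute `out_of_range = TRUE` (extrapolation
#' beyond the buffer series is flagged, not suppressed).
#'
#' @param curve A `"ph_calibration"` from [fit_ph_calibration()].
#' @param ratio Measured 340/380 ratio(s).
#' @return pH value(s) with attribute `out_of_range`.
#' @export
ph_from_ratio <- function(curve, ratio) {
  stopifnot(inherits(curve, "ph_calibration"))
  if (!is.numeric(ratio) || !all(is.finite(ratio))) {
    abort_invalid("`ratio` must be finite numeric")
  }
  if (!is.finite(curve$slope) || curve$slope == 0) {
    abort_degenerate("zero calibration slope: pH is not identified by the ratio")
  }
  ph <- (ratio - curve$intercept) / curve$slope
  eps <- 1e-8 * max(1, abs(curve$ph_range))  # don't flag boundary round-off
  attr(ph, "out_of_range") <-
    ph < curve$ph_range[1L] - eps | ph > curve$ph_range[2L] + eps
  ph
}
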