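#' Synthesize a two-channel punctate image pair with known colocalization
#'
#' Places `n_puncta` disk-shaped puncta per channel on a uniform background.
#' A `coloc_fraction` share of channel-B puncta share centers with
#' channel-A puncta; the remaining B puncta are placed disjointly (no pixel
#' overlap with any A punctum). Optional i.i.d. Gaussian noise is added per
#' pixel. The ground truth carries every center and the colocalization
#' flags, so downstream Manders estimates can be checked against the known
#' fraction.
#'
#' @param n_puncta Puncta per channel (>= 1).
#' @param coloc_fraction Fraction in \[0, 1\] of B puncta that colocalize
#'   with A puncta (rounded to a whole count).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param puncta_radius_px Disk radius in pixels.
#' @param intensity Peak intensity added inside a punctum.
#' @param background Background intensity.
#' @param noise_sd Gaussian noise sd per pixel (0 for none).
#' @param seed Integer seed or `NULL`.
#' @param max_tries Placement retries before giving up.
#' @return A list: `channel_a`, `channel_b` (numeric matrices),
#'   `ground_truth` (list with `centers_a`, `centers_b` as n x 2 matrices of
#'   0-based `(x, y)` pixel positions, `coloc` logical per B punctum,
#'   `radius_px`, `n_coloc`).
#' @examples
#' syn <- synth_two_channel_puncta(50, coloc_fraction = 0.5, seed = 2)
#' sum(syn$ground_truth$coloc)
#' @export
synth_two_channel_puncta <- function(n_puncta, coloc_fraction,
                                     image_shape = c(256L, 256L),
                                     puncta_radius_px = 3L,
                                     intensity = 200, background = 10,
                                     noise_sd = 0, seed = NULL,
                                     max_tries = 10000L) {
  if (!is_count(n_puncta, min = 1L)) abort_invalid("`n_puncta` must be an integer >= 1")
  if (!is_number(coloc_fraction) || coloc_fraction < 0 || coloc_fraction > 1) {
    abort_invalid("`coloc_fraction` must lie in [0, 1]")
  }
  nr <- image_shape[1L]; nc <- image_shape[2L]
  r <- puncta_radius_px
  if (2 * r + 2 >= min(nr, nc)) abort_invalid("puncta do not fit inside the image")
  with_seed(seed, {
    n_coloc <- round(coloc_fraction * n_puncta)
    n_total <- 2L * n_puncta - n_coloc   # distinct disk sites needed
    centers <- place_disjoint_centers(n_total, nr, nc, r, max_tries)
    centers_a <- centers[seq_len(n_puncta), , drop = FALSE]
    centers_b <- rbind(
      centers_a[seq_len(n_coloc), , drop = FALSE],
      centers[seq_len(n_puncta - n_coloc) + n_puncta, , drop = FALSE])
    a <- draw_puncta(nr, nc, centers_a, r, intensity, background)
    b <- draw_puncta(nr, nc, centers_b, r, intensity, background)
    if (noise_sd > 0) {
      a <- pmax(a + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
      b <- pmax(b + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    }
    list(channel_a = a, channel_b = b,
         ground_truth = list(
           centers_a = centers_a, centers_b = centers_b,
           coloc = seq_len(n_puncta) <= n_coloc,
           radius_px = r, n_coloc = n_coloc))
  })
}

## Rejection-sample n centers with pairwise separation > 2r + 1 px so no two
## disks share a pixel. 0-based (x, y).
place_disjoint_centers <- function(n, nr, nc, r, max_tries) {
  centers <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x", "y")))
  min_sep2 <- (2 * r + 2)^2
  k <- 0L
  for (try in seq_len(max_tries)) {
    cx <- stats::runif(1, r + 1, nc - r - 2)
    cy <- stats::runif(1, r + 1, nr - r - 2)
    if (k > 0L) {
      d2 <- (centers[seq_len(k), 1L] - cx)^2 + (centers[seq_len(k), 2L] - cy)^2
      if (min(d2) <= min_sep2) next
    }
    k <- k + 1L
    centers[k, ] <- c(cx, cy)
    if (k == n) return(centers)
  }
  abort_degenerate(sprintf(
    "could not place %d disjoint puncta in a %dx%d image after %d tries",
    n, nr, nc, max_tries))
}

draw_puncta <- function(nr, nc, centers, r, intensity, background) {
  img <- matrix(background, nr, nc)
  xs <- seq_len(nc) - 1L; ys <- seq_len(nr) - 1L
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1L]; cy <- centers[i, 2L]
    rows <- which(abs(ys - cy) <= r)
    cols <- which(abs(xs - cx) <= r)
    for (rw in rows) for (cl in cols) {
      if ((ys[rw] - cy)^2 + (xs[cl] - cx)^2 <= r^2) {
        img[rw, cl] <- background + intensity
      }
    }
  }
  img
}

#' Synthesize a radially structured cell image
#'
#' Distributes a total intensity across concentric rings around `center` in
#' the requested proportions: every pixel of ring i receives
#' `total_intensity * ring_weights[i] / n_pixels_in_ring_i`, so the
#' integrated radial profile of the output equals `ring_weights` up to
#' discretization. Pixels outside the outer radius are zero.
#'
#' @param ring_weights Nonnegative weights, one per ring; normalized to sum
#'   to 1.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param center `c(x, y)` in µm; defaults to the image center.
#' @param outer_radius Disk radius in µm; defaults to the largest inscribed
#'   radius.
#' @param pixel_size µm per pixel.
#' @param total_intensity Total intensity to distribute.
#' @param noise_sd Optional Gaussian noise sd per pixel.
#' @param seed Integer seed or `NULL` (only used when `noise_sd > 0`).
#' @return A list: `image` (matrix) and `ground_truth` (list with
#'   normalized `weights`, `center`, `outer_radius`, `edges`).
#' @export
synth_radial_cell <- function(ring_weights, image_shape = c(128L, 128L),
                              center = NULL, outer_radius = NULL,
                              pixel_size = 1, total_intensity = 1e4,
                              noise_sd = 0, seed = NULL) {
  if (!is.numeric(ring_weights) || length(ring_weights) < 1L ||
      any(ring_weights < 0) || sum(ring_weights) <= 0) {
    abort_invalid("`ring_weights` must be nonnegative with a positive sum")
  }
  w <- ring_weights / sum(ring_weights)
  nr <- image_shape[1L]; nc <- image_shape[2L]
  if (is.null(center)) {
    center <- c((nc - 1) / 2, (nr - 1) / 2) * pixel_size
  }
  if (is.null(outer_radius)) {
    outer_radius <- min(center[1L], center[2L],
                        (nc - 1) * pixel_size - center[1L],
                        (nr - 1) * pixel_size - center[2L])
  }
  n_rings <- length(w)
  edges <- seq(0, outer_radius, length.out = n_rings + 1L)
  d <- pixel_center_distances(c(nr, nc), center, pixel_size)
  ring <- findInterval(d, edges, left.open = FALSE)
  ring[d >= outer_radius] <- 0L
  img <- matrix(0, nr, nc)
  for (k in seq_len(n_rings)) {
    idx <- which(ring == k)
    if (length(idx) == 0L) {
      if (w[k] > 0) abort_invalid(sprintf(
        "ring %d contains no pixels but has weight %g; refine the grid", k, w[k]))
      next
    }
    img[idx] <- total_intensity * w[k] / length(idx)
  }
  if (noise_sd > 0) {
    img <- with_seed(seed,
      pmax(img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0))
  }
  list(image = img,
       ground_truth = list(weights = w, center = center,
                           outer_radius = outer_radius, edges = edges))
}

#' Synthesize ratiometric pH calibration readings
#'
#' Generates `(pH, ratio)` pairs on the line
#' `ratio = slope * pH + intercept` with additive Gaussian noise — the form
#' of a dual-excitation (340/380 nm) lysosomal pH calibration series
#' acquired in pH-clamped buffers.
#'
#' @param slope,intercept Line parameters.
#' @param ph_values pH values of the calibration buffers.
#' @param noise_sd Gaussian noise sd on the ratio (0 for exact points).
#' @param seed Integer seed or `NULL`.
#' @return Data frame with columns `ph`, `ratio_340_380`.
#' @export
synth_calibration_readings <- function(slope, intercept, ph_values,
                                       noise_sd = 0, seed = NULL) {
  if (!is_number(slope) || !is_number(intercept)) {
    abort_invalid("`slope` and `intercept` must be numbers")
  }
  if (!is.numeric(ph_values) || length(ph_values) < 1L) {
    abort_invalid("`ph_values` must be a numeric vector")
  }
  with_seed(seed, {
    ratio <- slope * ph_values + intercept +
      if (noise_sd > 0) stats::rnorm(length(ph_values), 0, noise_sd) else 0
    data.frame(ph = ph_values, ratio_340_380 = ratio)
  })
}

#' Synthesize an exponential-decay intensity time course
#'
#' Mean intensity decaying with the given half-life, sampled at the
#' requested chase times (time 0 is the pulse) — the shape of a
#' receptor-degradation chase experiment.
#'
#' @param pulse_intensity Intensity at time 0 (> 0).
#' @param half_life_min Half-life in minutes (> 0).
#' @param times_min Strictly increasing sampling times in minutes, starting
#'   at 0.
#' @param noise_sd Gaussian noise sd on intensities.
#' @param seed Integer seed or `NULL`.
#' @return Data frame with columns `t_min`, `mean_intensity`.
#' @export
synth_decay_timecourse <- function(pulse_intensity, half_life_min,
                                   times_min = c(0, 15, 30, 45, 60),
                                   noise_sd = 0, seed = NULL) {
  if (!is_number(pulse_intensity) || pulse_intensity <= 0) {
    abort_invalid("`pulse_intensity` must be > 0")
  }
  if (!is_number(half_life_min) || half_life_min <= 0) {
    abort_invalid("`half_life_min` must be > 0")
  }
  if (times_min[1L] != 0 || any(diff(times_min) <= 0)) {
    abort_invalid("`times_min` must start at 0 and be strictly increasing")
  }
  with_seed(seed, {
    y <- pulse_intensity * 2^(-times_min / half_life_min)
    if (noise_sd > 0) y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 0)
    data.frame(t_min = times_min, mean_intensity = y)
  })
}
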