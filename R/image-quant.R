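#' Maximum-entropy (Kapur) threshold of an intensity image
#'
#' Builds an `n_bins` equal-width histogram over the observed min-max range
#' (the ImageJ convention for non-8-bit data) and returns the bin boundary
#' that maximizes the summed Shannon entropies of the background and
#' foreground partitions. Ties are broken toward the lowest threshold.
#' Pixels strictly above the returned value are foreground.
#'
#' @param img Numeric matrix of nonnegative intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold intensity (upper edge of the last background bin).
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' kapur_threshold(img)  # strictly between the two modes
#' @export
kapur_threshold <- function(img, n_bins = 256L) {
  img <- as_intensity_matrix(img)
  if (!is_count(n_bins, min = 2L)) abort_invalid("`n_bins` must be an integer >= 2")
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) abort_degenerate("constant image: no threshold exists")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  ## findInterval puts v == hi into bin n_bins (half-open bins, top closed)
  bin <- pmin(findInterval(v, breaks, left.open = FALSE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(v)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)            # background mass up to bin t
  S <- cumsum(plogp)        # cumulative sum of p log p
  St <- S[n_bins]
  obj <- rep(-Inf, n_bins - 1L)
  for (t in seq_len(n_bins - 1L)) {
    Pb <- P[t]; Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) next
    Hb <- -S[t] / Pb + log(Pb)
    Hf <- -(St - S[t]) / Pf + log(Pf)
    obj[t] <- Hb + Hf
  }
  if (!any(is.finite(obj))) abort_degenerate("degenerate histogram: no admissible threshold")
  t_star <- which.max(obj)  # which.max takes the first (lowest) maximizer
  breaks[t_star + 1L]
}

## Coerce to a finite nonnegative numeric matrix.
as_intensity_matrix <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort_invalid("image must be a numeric matrix")
  }
  if (!all(is.finite(img))) abort_invalid("image intensities must be finite")
  img
}

## Connected-component labeling of a logical mask by breadth-first search.
## Written here because no installed labeling routine offers 8-connectivity
## (the ImageJ Analyze Particles default). Returns an integer matrix with
## labels 1..L, 0 = background.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4L, 8L)) abort_invalid("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  doff <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L), c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  fg <- which(mask)
  queue <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1L] <- start; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      idx <- queue[qh]; qh <- qh + 1L
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      for (d in seq_len(nrow(doff))) {
        rr <- r + doff[d, 1L]; ccn <- cc + doff[d, 2L]
        if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
        nidx <- (ccn - 1L) * nr + rr
        if (mask[nidx] && labels[nidx] == 0L) {
          labels[nidx] <- lab
          qt <- qt + 1L
          if (qt > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qt] <- nidx
        }
      }
    }
  }
  labels
}

#' Segment particles above a threshold
#'
#' Binarizes the image at `threshold` (foreground = strictly above), labels
#' connected components, discards components smaller than `min_area_px`
#' pixels, and reports per-particle morphometry. Pixel coordinates are
#' 0-based with pixel centers at integer positions; rows index y and columns
#' index x; areas are pixel counts times `pixel_size^2`.
#'
#' @param img Numeric intensity matrix.
#' @param threshold Intensity threshold (see [kapur_threshold()]).
#' @param pixel_size Pixel edge length in µm (default 1).
#' @param connectivity 4- or 8-neighbour connectivity (default 8, the ImageJ
#'   Analyze Particles convention).
#' @param min_area_px Minimum component size in pixels (default 1).
#' @return A list with
#'   \item{mask}{integer label matrix (0 background, labels consecutive
#'     1..L) with attributes `threshold` and `connectivity`;}
#'   \item{particles}{data frame `label`, `area_um2`, `centroid_x_um`,
#'     `centroid_y_um`, `mean_intensity`.}
#' @examples
#' img <- matrix(0, 32, 32); img[10:14, 10:14] <- 100
#' seg <- segment_particles(img, threshold = 50, pixel_size = 0.1)
#' seg$particles
#' @export
segment_particles <- function(img, threshold, pixel_size = 1,
                              connectivity = 8L, min_area_px = 1L) {
  img <- as_intensity_matrix(img)
  if (!is_number(threshold)) abort_invalid("`threshold` must be a number")
  if (!is_number(pixel_size) || pixel_size <= 0) {
    abort_invalid("`pixel_size` must be a positive number (um/pixel)")
  }
  labels <- label_components(img > threshold, as.integer(connectivity))
  L <- max(labels)
  if (L > 0L && min_area_px > 1L) {
    sizes <- tabulate(labels[labels > 0L], nbins = L)
    keep <- which(sizes >= min_area_px)
    remap <- integer(L)
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    L <- length(keep)
  }
  if (L == 0L) {
    particles <- data.frame(label = integer(), area_um2 = numeric(),
                            centroid_x_um = numeric(), centroid_y_um = numeric(),
                            mean_intensity = numeric())
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    nr <- nrow(img)
    row0 <- ((idx - 1L) %% nr)        # 0-based y
    col0 <- ((idx - 1L) %/% nr)       # 0-based x
    npx <- tabulate(lab, nbins = L)
    particles <- data.frame(
      label = seq_len(L),
      area_um2 = npx * pixel_size^2,
      centroid_x_um = as.vector(tapply(col0, lab, mean)) * pixel_size,
      centroid_y_um = as.vector(tapply(row0, lab, mean)) * pixel_size,
      mean_intensity = as.vector(tapply(img[idx], lab, mean))
    )
  }
  attr(labels, "threshold") <- threshold
  attr(labels, "connectivity") <- as.integer(connectivity)
  list(mask = labels, particles = particles)
}

#' Mean particle area, optionally within a cell region
#'
#' Arithmetic mean of `area_um2` over the particles whose centroid lies in
#' `cell_mask` (the whole image when absent) — the per-cell average organelle
#' area of standard lysosome morphometry.
#'
#' @param particles Particle table from [segment_particles()].
#' @param cell_mask Optional logical matrix; a particle is kept when the
#'   pixel containing its centroid is `TRUE`.
#' @param pixel_size Pixel size in µm, needed to map centroids back to
#'   pixels when `cell_mask` is given.
#' @return Mean area in µm². Raises a degenerate-input condition when no
#'   particle qualifies (an explicit signal, never a silent 0).
#' @export
mean_particle_area <- function(particles, cell_mask = NULL, pixel_size = 1) {
  stopifnot(is.data.frame(particles))
  keep <- particles
  if (!is.null(cell_mask)) {
    stopifnot(is.matrix(cell_mask), is.logical(cell_mask))
    r <- round(particles$centroid_y_um / pixel_size) + 1L
    cc <- round(particles$centroid_x_um / pixel_size) + 1L
    inside <- r >= 1 & r <= nrow(cell_mask) & cc >= 1 & cc <= ncol(cell_mask)
    inside[inside] <- cell_mask[cbind(r[inside], cc[inside])]
    keep <- particles[inside, , drop = FALSE]
  }
  if (nrow(keep) == 0L) abort_degenerate("no particles in the analysis region")
  mean(keep$area_um2)
}
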