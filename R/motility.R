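#' Configuration for track filtering, classification and phase segmentation
#'
#' Holds the thresholds of the motility analysis. The defaults are the
#' operational definitions used throughout: tracks of at least 25 frames are
#' analyzed; the anomalous diffusion exponent alpha (slope of log MSD vs log
#' lag) classifies a track as processive when alpha > 1.45, diffusive when
#' 1 <= alpha <= 1.45, and non-processive when alpha < 1.
#'
#' @param alpha_processive_gt Exponent above which a track is processive
#'   (strict inequality). Default 1.45.
#' @param alpha_diffusive_min Lower bound of the diffusive band (inclusive).
#'   Default 1.0.
#' @param min_frames Minimum track length in frames for analysis
#'   (inclusive). Default 25.
#' @param max_lag_fraction Fraction of `n_frames - 1` used as the largest MSD
#'   lag in the power-law fit. Long lags average few displacement pairs and
#'   are noisy, so the fit is restricted to the first quarter by default.
#' @param phase_window Rolling-window width in frames for active/passive
#'   phase segmentation. Default 10.
#' @param phase_alpha_active Local-exponent threshold above which a window
#'   votes "active"; defaults to `alpha_processive_gt`.
#' @param min_phase_frames Runs shorter than this many frames are absorbed
#'   into their neighbours during phase merging. Default 3.
#' @param phase_straightness_min Minimum net/path displacement ratio for a
#'   candidate active phase to be accepted (directed runs are nearly
#'   straight; random-walk excursions are not). Default 0.8.
#'
#' @return An object of class `"classifier_config"`.
#' @export
classifier_config <- function(alpha_processive_gt = 1.45,
                              alpha_diffusive_min = 1.0,
                              min_frames = 25L,
                              max_lag_fraction = 0.25,
                              phase_window = 10L,
                              phase_alpha_active = alpha_processive_gt,
                              min_phase_frames = 3L,
                              phase_straightness_min = 0.8) {
  if (!is_number(alpha_processive_gt) || !is_number(alpha_diffusive_min) ||
      alpha_processive_gt <= alpha_diffusive_min) {
    abort_invalid("`alpha_processive_gt` must exceed `alpha_diffusive_min`")
  }
  if (!is_count(min_frames, min = 2L)) abort_invalid("`min_frames` must be an integer >= 2")
  if (!is_number(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction > 1) {
    abort_invalid("`max_lag_fraction` must be in (0, 1]")
  }
  if (!is_count(phase_window, min = 4L)) abort_invalid("`phase_window` must be an integer >= 4")
  structure(
    list(alpha_processive_gt = alpha_processive_gt,
         alpha_diffusive_min = alpha_diffusive_min,
         min_frames = as.integer(min_frames),
         max_lag_fraction = max_lag_fraction,
         phase_window = as.integer(phase_window),
         phase_alpha_active = phase_alpha_active,
         min_phase_frames = as.integer(min_phase_frames),
         phase_straightness_min = phase_straightness_min),
    class = "classifier_config"
  )
}

#' Filter tracks by minimum length
#'
#' Keeps exactly the tracks with at least `config$min_frames` points
#' (boundary inclusive: a 25-frame track passes the default filter, a
#' 24-frame track does not). Order is preserved.
#'
#' @param tracks List of [trajectory()] objects.
#' @param config A [classifier_config()].
#' @return The retained sublist.
#' @export
filter_tracks <- function(tracks, config = classifier_config()) {
  stopifnot(is.list(tracks), inherits(config, "classifier_config"))
  tracks[vapply(tracks, n_frames, integer(1)) >= config$min_frames]
}

#' Time-averaged mean squared displacement of a track
#'
#' For each integer lag k in `1..floor(max_lag_fraction * (n - 1))`, the MSD
#' is the mean over all overlapping ordered pairs (i, i + k) of the squared
#' Euclidean displacement. The overlapping (all-pairs) estimator maximizes
#' the number of displacement pairs per lag.
#'
#' @param traj A [trajectory()].
#' @param max_lag_fraction Largest lag as a fraction of `n - 1`; must yield
#'   at least one lag.
#' @return An object of class `"msd_curve"`: list with `lags` (seconds),
#'   `values` (µm²), `n_pairs`, `dt`.
#' @examples
#' tr <- trajectory(x = 0:9, y = rep(0, 10), dt = 1)  # 1 µm/s ballistic
#' compute_msd(tr, max_lag_fraction = 0.5)$values     # (k * dt)^2
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is_number(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction > 1) {
    abort_invalid("`max_lag_fraction` must be in (0, 1]")
  }
  n <- n_frames(traj)
  kmax <- floor(max_lag_fraction * (n - 1L))
  if (kmax < 1L) {
    abort_invalid(sprintf(
      "max_lag_fraction = %g yields no usable lag for a %d-frame track",
      max_lag_fraction, n))
  }
  vals <- numeric(kmax); np <- integer(kmax)
  x <- traj$x; y <- traj$y
  for (k in seq_len(kmax)) {
    dx <- x[(1L + k):n] - x[1L:(n - k)]
    dy <- y[(1L + k):n] - y[1L:(n - k)]
    vals[k] <- mean(dx * dx + dy * dy)
    np[k] <- n - k
  }
  structure(list(lags = seq_len(kmax) * traj$dt, values = vals,
                 n_pairs = np, dt = traj$dt),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve: %d lags, dt = %g s, MSD(dt) = %.4g um^2>\n",
              length(x$lags), x$dt, x$values[1L]))
  invisible(x)
}

#' Fit the MSD power law log MSD = alpha * log(lag) + C
#'
#' Unweighted ordinary least squares of `log(MSD)` on `log(lag)` (natural
#' logarithms). The slope is the anomalous diffusion exponent alpha; the
#' intercept C is reported in the natural-log convention. Lags with zero MSD
#' carry no information about the exponent and are dropped before fitting;
#' if fewer than two positive-MSD lags remain (e.g. a motionless particle)
#' the fit is flagged degenerate and downstream classification maps it to
#' non-processive.
#'
#' @param msd An `"msd_curve"` from [compute_msd()].
#' @return An object of class `"power_law_fit"`: `alpha`, `intercept`
#'   (natural log), `r_squared`, `n_lags_used`, `degenerate`.
#' @examples
#' tr <- trajectory(x = 0:19, y = rep(0, 20), dt = 1)
#' fit_power_law(compute_msd(tr, 0.5))  # alpha = 2 for ballistic motion
#' @export
fit_power_law <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  keep <- msd$values > 0
  if (sum(keep) < 2L) {
    return(structure(list(alpha = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_lags_used = sum(keep),
                          degenerate = TRUE),
                     class = "power_law_fit"))
  }
  lx <- log(msd$lags[keep]); ly <- log(msd$values[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(alpha = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r_squared = min(max(r2, 0), 1),
                 n_lags_used = sum(keep),
                 degenerate = FALSE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<power_law_fit: degenerate (fewer than 2 positive-MSD lags)>\n")
  } else {
    cat(sprintf("<power_law_fit: alpha = %.4f, C = %.4f (ln), R^2 = %.3f, %d lags>\n",
                x$alpha, x$intercept, x$r_squared, x$n_lags_used))
  }
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(alpha = object$alpha, intercept = object$intercept)
}

#' Classify a track from its fitted MSD exponent
#'
#' Thresholds as printed in the operational definition: alpha > 1.45
#' processive; 1 <= alpha <= 1.45 diffusive (both boundaries land in the
#' diffusive class); alpha < 1 non-processive. A degenerate fit (motionless
#' particle) is the limiting non-processive case.
#'
#' @param fit A `"power_law_fit"`.
#' @param config A [classifier_config()].
#' @return One of `"processive"`, `"diffusive"`, `"non_processive"`.
#' @export
classify_track <- function(fit, config = classifier_config()) {
  stopifnot(inherits(fit, "power_law_fit"), inherits(config, "classifier_config"))
  if (isTRUE(fit$degenerate) || !is.finite(fit$alpha)) return("non_processive")
  if (fit$alpha > config$alpha_processive_gt) return("processive")
  if (fit$alpha >= config$alpha_diffusive_min) return("diffusive")
  "non_processive"
}
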