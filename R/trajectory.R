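#' Single-particle trajectory
#'
#' Container for one particle's ordered 2D positions over frames at a fixed
#' frame interval. Positions are in micrometres, the frame interval in
#' seconds. Frames must be consecutive integers: tracking gaps are rejected
#' rather than interpolated, because the MSD lag structure assumes equal
#' spacing.
#'
#' @param x,y Numeric vectors of positions (µm), equal length >= 2.
#' @param dt Frame interval in seconds (> 0).
#' @param track_id Identifier (coerced to character).
#' @param frame Integer frame indices; defaults to `0:(n-1)`. Must be
#'   strictly increasing with unit steps.
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `track_id`, `dt`, `frame`, `x`, `y`.
#' @examples
#' tr <- trajectory(x = c(0, 1, 2), y = c(0, 0, 0), dt = 0.5)
#' n_frames(tr)
#' @export
trajectory <- function(x, y, dt, track_id = "track", frame = NULL) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort_invalid("`x` and `y` must be numeric vectors of equal length")
  }
  n <- length(x)
  if (n < 2L) abort_invalid("a trajectory needs at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_invalid("trajectory coordinates must be finite")
  }
  if (!is_number(dt) || dt <= 0) abort_invalid("`dt` must be a positive number")
  if (is.null(frame)) frame <- seq_len(n) - 1L
  frame <- as.integer(frame)
  if (length(frame) != n || anyNA(frame)) {
    abort_invalid("`frame` must be an integer vector matching the positions")
  }
  if (any(diff(frame) != 1L)) {
    abort_invalid("frame indices must be consecutive (gapped tracks are rejected)")
  }
  structure(
    list(track_id = as.character(track_id)[1L], dt = as.numeric(dt),
         frame = frame, x = as.numeric(x), y = as.numeric(y)),
    class = "trajectory"
  )
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer point count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  length(traj$x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames, dt = %g s, span %.3g s>\n",
              x$track_id, n_frames(x), x$dt, (n_frames(x) - 1L) * x$dt))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(track_id = x$track_id, frame = x$frame,
             t_sec = x$frame * x$dt, x_um = x$x, y_um = x$y,
             stringsAsFactors = FALSE)
}

#' Read trajectories from a tracks CSV
#'
#' Expects the header `track_id,frame,t_sec,x_um,y_um`. The frame interval is
#' inferred per track from the `t_sec` column (it must be consistent with the
#' frame spacing).
#'
#' @param path CSV file path.
#' @return A list of [trajectory()] objects, in order of first appearance.
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("tracks file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_sec", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    abort_invalid(sprintf("tracks CSV %s must have columns %s",
                          path, paste(need, collapse = ",")))
  }
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    dts <- diff(sub$t_sec) / diff(sub$frame)
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > 1e-6 * max(dt, 1))) {
      abort_invalid(sprintf("track '%s' in %s has a non-constant frame interval", id, path))
    }
    trajectory(sub$x_um, sub$y_um, dt = dt, track_id = id, frame = sub$frame)
  })
}

#' Write trajectories to a tracks CSV
#'
#' @param tracks A list of [trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(is.list(tracks))
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
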