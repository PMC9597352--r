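## Local exponent of a short track segment: MSD over lags 1..floor((w-1)/2),
## power-law fit. Returns NA for a degenerate (motionless) window.
segment_alpha <- function(traj, from, to) {
  sub <- trajectory(traj$x[from:to], traj$y[from:to], dt = traj$dt,
                    track_id = traj$track_id)
  fit <- fit_power_law(compute_msd(sub, max_lag_fraction = 0.5))
  if (fit$degenerate) NA_real_ else fit$alpha
}

## Profile Gaussian log-likelihood of a run of steps under its state model:
## active steps ~ N(mean step vector, sigma^2 I), passive ~ N(0, sigma^2 I).
## The per-segment variance is floored at `vfloor` so short collinear
## segments cannot claim unbounded likelihood.
step_score <- function(ux, uy, active_seg, vfloor) {
  if (length(ux) == 0L) return(0)
  rss <- if (active_seg) sum((ux - mean(ux))^2 + (uy - mean(uy))^2)
         else sum(ux * ux + uy * uy)
  m <- 2 * length(ux)
  -m * log(max(rss / m, vfloor))
}

## Split active runs that bridge a short passive gap: accept the best
## active|passive|active split when it beats the single-run model by a
## BIC-style margin.
split_bridged_gaps <- function(x, y, active, w, pen_mult, vfloor) {
  dx <- diff(x); dy <- diff(y)
  repeat {
    r <- rle(active)
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
    improved <- FALSE
    for (b in which(r$values)) {
      s <- starts[b]; e <- ends[b]
      if (e - s + 1L < 11L) next
      steps <- s:(e - 1L)
      base <- step_score(dx[steps], dy[steps], TRUE, vfloor)
      best <- -Inf; bg <- NULL
      for (g1 in (s + 4L):(e - 6L)) {
        for (g2 in g1:min(g1 + w - 1L, e - 5L)) {
          sc <- step_score(dx[s:(g1 - 1L)], dy[s:(g1 - 1L)], TRUE, vfloor) +
                step_score(dx[g1:g2], dy[g1:g2], FALSE, vfloor) +
                step_score(dx[(g2 + 1L):(e - 1L)], dy[(g2 + 1L):(e - 1L)], TRUE, vfloor)
          if (sc > best) { best <- sc; bg <- c(g1, g2) }
        }
      }
      if (best - base > pen_mult * log(2 * length(steps))) {
        active[bg[1L]:bg[2L]] <- FALSE
        improved <- TRUE
      }
    }
    if (!improved) return(active)
  }
}

## Relocate each active/passive boundary to the maximum-likelihood
## changepoint within +/- one window of the voted position.
refine_boundaries <- function(x, y, active, w, vfloor) {
  r <- rle(active)
  if (length(r$lengths) < 2L) return(active)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  dx <- diff(x); dy <- diff(y)
  for (b in seq_len(length(r$lengths) - 1L)) {
    lo <- max(starts[b] + 2L, ends[b] - (w - 1L))
    hi <- min(ends[b + 1L] - 1L, ends[b] + w)
    if (lo > hi) next
    best <- -Inf; bestc <- ends[b] + 1L
    for (cc in lo:hi) {
      li <- starts[b]:(cc - 1L)
      ri <- if (cc <= ends[b + 1L] - 1L) cc:(ends[b + 1L] - 1L) else integer(0)
      sc <- step_score(dx[li], dy[li], r$values[b], vfloor) +
            step_score(dx[ri], dy[ri], r$values[b + 1L], vfloor)
      if (sc > best) { best <- sc; bestc <- cc }
    }
    active[starts[b]:(bestc - 1L)] <- r$values[b]
    active[bestc:ends[b + 1L]] <- r$values[b + 1L]
  }
  active
}

## Demote active runs that do not look like transport when examined on
## their own: the run must be long enough to fit (>= 5 frames), have a
## local exponent above the active threshold, and be nearly straight
## (net/path displacement ratio), which random-walk excursions rarely are.
validate_active_runs <- function(traj, active, alpha_thr, min_straight) {
  r <- rle(active)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (b in which(r$values)) {
    s <- starts[b]; e <- ends[b]
    ok <- FALSE
    if (r$lengths[b] >= 5L) {
      a <- segment_alpha(traj, s, e)
      path <- sum(sqrt(diff(traj$x[s:e])^2 + diff(traj$y[s:e])^2))
      net <- sqrt((traj$x[e] - traj$x[s])^2 + (traj$y[e] - traj$y[s])^2)
      straight <- if (path > 0) net / path else 0
      ok <- is.finite(a) && a > alpha_thr && straight >= min_straight
    }
    if (!ok) active[s:e] <- FALSE
  }
  active
}

#' Segment a trajectory into active and passive phases
#'
#' Partitions a track into alternating active (directed transport) and
#' passive (pause/diffusion) phases. The segmentation proceeds in four
#' passes:
#' \enumerate{
#'   \item every rolling window of `phase_window` frames is fitted for its
#'     local MSD exponent and votes "active" when it exceeds
#'     `phase_alpha_active`; each frame takes the majority vote of the
#'     windows covering it, and runs shorter than `min_phase_frames` are
#'     absorbed into their neighbours;
#'   \item active runs bridging a brief pause are split where an
#'     active/passive/active changepoint model beats the single-run model
#'     by a BIC-style margin;
#'   \item each phase boundary is relocated to the maximum-likelihood step
#'     changepoint within one window of the voted position (window votes
#'     alone blur boundaries by several frames);
#'   \item each active run is re-examined on its own: it must sustain a
#'     local exponent above the threshold and a near-straight path
#'     (net/path ratio >= `phase_straightness_min`), which discards the
#'     occasional random-walk excursion that mimics a short run.
#' }
#' Tracks shorter than the window collapse to a single phase whose state
#' follows the whole-track classification (processive tracks are active,
#' all others passive).
#'
#' @param traj A [trajectory()].
#' @param config A [classifier_config()].
#' @return A data frame with columns `state` ("active"/"passive"),
#'   `start_frame`, `end_frame` (inclusive frame indices of `traj`). Phases
#'   are ordered, non-overlapping, tile the track and alternate states.
#' @examples
#' sim <- simulate_trajectory(motion_model("ballistic", speed = 1), 40, 1, seed = 1)
#' segment_phases(sim$trajectory)  # one active phase spanning the track
#' @export
segment_phases <- function(traj, config = classifier_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(config, "classifier_config"))
  n <- n_frames(traj)
  w <- config$phase_window
  thr <- config$phase_alpha_active
  if (n < w) {
    cls <- classify_track(fit_power_law(compute_msd(traj, 0.5)), config)
    state <- if (cls == "processive") "active" else "passive"
    return(data.frame(state = state, start_frame = traj$frame[1L],
                      end_frame = traj$frame[n], stringsAsFactors = FALSE))
  }
  n_win <- n - w + 1L
  win_active <- logical(n_win)
  for (s in seq_len(n_win)) {
    a <- segment_alpha(traj, s, s + w - 1L)
    win_active[s] <- is.finite(a) && a > thr
  }
  votes_active <- integer(n); votes_total <- integer(n)
  for (s in seq_len(n_win)) {
    idx <- s:(s + w - 1L)
    votes_total[idx] <- votes_total[idx] + 1L
    if (win_active[s]) votes_active[idx] <- votes_active[idx] + 1L
  }
  active <- votes_active * 2L > votes_total   # ties are passive
  active <- absorb_short_runs(active, config$min_phase_frames)
  dx <- diff(traj$x); dy <- diff(traj$y)
  vfloor <- 0.05 * mean(dx * dx + dy * dy)    # variance floor for changepoints
  if (vfloor > 0) {
    active <- split_bridged_gaps(traj$x, traj$y, active, w,
                                 pen_mult = 10, vfloor = vfloor)
    active <- refine_boundaries(traj$x, traj$y, active, w, vfloor)
  }
  active <- validate_active_runs(traj, active, thr,
                                 config$phase_straightness_min)
  runs_to_phases(active, traj$frame)
}

## Flip runs shorter than min_len into the neighbouring state (shortest run
## first) until none remain or only one run is left.
absorb_short_runs <- function(active, min_len) {
  repeat {
    r <- rle(active)
    if (length(r$lengths) <= 1L) return(active)
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) return(active)
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    active <- inverse.rle(r)
  }
}

runs_to_phases <- function(active, frames) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(state = ifelse(r$values, "active", "passive"),
             start_frame = frames[starts], end_frame = frames[ends],
             stringsAsFactors = FALSE)
}

#' Run lengths of the active phases of a track
#'
#' One record per active phase: the run length is the net Euclidean
#' displacement between the phase's first and last positions (transport
#' distance, not path length — path length is inflated by localization
#' noise).
#'
#' @param traj A [trajectory()].
#' @param phases Phase table from [segment_phases()] for the same track.
#' @param measure `"net"` (default) for net displacement or `"path"` for
#'   summed step lengths within the phase.
#' @return Numeric vector of run lengths in µm (empty if no active phase).
#' @examples
#' tr <- trajectory(x = 0.5 * (0:10), y = rep(0, 11), dt = 1)
#' ph <- data.frame(state = "active", start_frame = 0, end_frame = 10)
#' compute_run_lengths(tr, ph)  # 5 um: 0.5 um/s for 10 s
#' @export
compute_run_lengths <- function(traj, phases, measure = c("net", "path")) {
  stopifnot(inherits(traj, "trajectory"), is.data.frame(phases))
  measure <- match.arg(measure)
  act <- phases[phases$state == "active", , drop = FALSE]
  if (nrow(act) == 0L) return(numeric(0))
  vapply(seq_len(nrow(act)), function(i) {
    i0 <- match(act$start_frame[i], traj$frame)
    i1 <- match(act$end_frame[i], traj$frame)
    if (is.na(i0) || is.na(i1) || i1 < i0) {
      abort_invalid("phase bounds do not match the trajectory's frames")
    }
    if (measure == "net") {
      sqrt((traj$x[i1] - traj$x[i0])^2 + (traj$y[i1] - traj$y[i0])^2)
    } else {
      sum(sqrt(diff(traj$x[i0:i1])^2 + diff(traj$y[i0:i1])^2))
    }
  }, numeric(1))
}
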