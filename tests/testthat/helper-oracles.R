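## Independent brute-force oracles used to validate the fast implementations.
## These are deliberately written in the most literal way possible and share
## no code with the package internals.

# All-pairs MSD by an explicit double loop over ordered index pairs.
brute_force_msd <- function(x, y, dt, kmax) {
  n <- length(x)
  vals <- numeric(kmax)
  for (k in seq_len(kmax)) {
    acc <- 0; cnt <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      cnt <- cnt + 1
    }
    vals[k] <- acc / cnt
  }
  list(lags = seq_len(kmax) * dt, values = vals)
}

# Kapur objective for a given histogram and candidate threshold bin t
# (background = bins 1..t), evaluated from first principles.
kapur_objective <- function(p, t) {
  pb <- p[1:t]; pf <- p[(t + 1):length(p)]
  Pb <- sum(pb); Pf <- sum(pf)
  if (Pb <= 0 || Pf <= 0) return(-Inf)
  hb <- pb[pb > 0] / Pb
  hf <- pf[pf > 0] / Pf
  -sum(hb * log(hb)) - sum(hf * log(hf))
}

# Exhaustive argmax of the Kapur objective over all candidate thresholds of
# a histogram of counts; returns the lowest maximizing bin index.
brute_force_kapur_bin <- function(counts) {
  p <- counts / sum(counts)
  obj <- vapply(seq_len(length(p) - 1L), function(t) kapur_objective(p, t),
                numeric(1))
  which.max(obj)
}

# Ground-truth active runs of a simulated switching track, as 1-based index
# ranges into the trajectory.
truth_active_runs <- function(ground_truth) {
  r <- rle(ground_truth$state == "active")
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(start = starts, end = ends)[r$values, , drop = FALSE]
}

# Net displacement of the noise-free path over an index range.
truth_net_displacement <- function(ground_truth, start, end) {
  sqrt((ground_truth$x_true[end] - ground_truth$x_true[start])^2 +
       (ground_truth$y_true[end] - ground_truth$y_true[start])^2)
}

# Default switching-motion conditions used across phase/run-length tests:
# a cargo alternating ~1 um/s directed runs (mean dwell 40 s) with slow
# diffusion, observed with 10 nm localization error.
switching_test_model <- function() {
  motion_model("switching", speed = 1, diffusion_coeff = 0.02,
               p_active_to_passive = 1 / 40, p_passive_to_active = 1 / 40,
               localization_noise_sd = 0.01)
}

# Share of recovered active phases whose run length is within `tol` of the
# ground-truth net displacement of the overlapping true run.
run_length_recovery_rate <- function(n_tracks, n_frames = 160L, seed = 1L,
                                     tol = 0.10) {
  ok <- logical(0)
  withr_seed <- function(s, code) { set.seed(s); code }
  withr_seed(seed, {
    for (i in seq_len(n_tracks)) {
      sim <- simulate_trajectory(switching_test_model(), n_frames, dt = 1)
      tr <- sim$trajectory
      runs <- truth_active_runs(sim$ground_truth)
      ph <- segment_phases(tr)
      act <- ph[ph$state == "active", , drop = FALSE]
      if (nrow(act) == 0L) next
      rl <- compute_run_lengths(tr, ph)
      for (j in seq_len(nrow(act))) {
        s1 <- act$start_frame[j] + 1L; e1 <- act$end_frame[j] + 1L
        if (nrow(runs) == 0L) { ok <- c(ok, FALSE); next }
        ov <- pmin(runs$end, e1) - pmax(runs$start, s1) + 1L
        if (max(ov) <= 0L) { ok <- c(ok, FALSE); next }
        k <- which.max(ov)
        gtd <- truth_net_displacement(sim$ground_truth, runs$start[k], runs$end[k])
        ok <- c(ok, abs(rl[j] - gtd) <= tol * gtd)
      }
    }
  })
  mean(ok)
}

# Random short trajectory for property tests.
random_trajectory <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:50, 1)
  trajectory(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), dt = runif(1, 0.1, 2))
}

# MSD curve lying exactly on MSD = A * lag^alpha.
power_law_msd <- function(alpha, A = 1, lags = 1:10, dt = 1) {
  structure(list(lags = lags * dt, values = A * (lags * dt)^alpha,
                 n_pairs = rep(10L, length(lags)), dt = dt),
            class = "msd_curve")
}
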