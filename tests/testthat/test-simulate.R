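test_that("simulation is deterministic under a seed and leaves the RNG alone", {
  m <- motion_model("brownian", diffusion_coeff = 0.1,
                    localization_noise_sd = 0.02)
  s1 <- simulate_trajectory(m, 50, 1, seed = 42)
  set.seed(7); before <- runif(1)
  set.seed(7)
  s2 <- simulate_trajectory(m, 50, 1, seed = 42)
  after <- runif(1)
  expect_identical(s1, s2)
  expect_identical(before, after)  # caller's RNG stream untouched

  mix <- list(list(model = m, weight = 1),
              list(model = motion_model("ballistic", speed = 1), weight = 2))
  p1 <- simulate_population(mix, 10, 30, 0.5, seed = 9)
  p2 <- simulate_population(mix, 10, 30, 0.5, seed = 9)
  expect_identical(
    do.call(rbind, lapply(p1$tracks, as.data.frame)),
    do.call(rbind, lapply(p2$tracks, as.data.frame)))
})

test_that("degenerate and ballistic motions obey their closed forms", {
  st <- simulate_trajectory(motion_model("stationary"), 20, 1, seed = 1)
  expect_true(all(st$trajectory$x == st$trajectory$x[1]))
  expect_true(all(compute_msd(st$trajectory, 0.5)$values == 0))

  b <- simulate_trajectory(motion_model("ballistic", speed = 1), 50, 1, seed = 2)
  net <- sqrt((b$trajectory$x[50] - b$trajectory$x[1])^2 +
              (b$trajectory$y[50] - b$trajectory$y[1])^2)
  expect_equal(net, 49, tolerance = 1e-12)  # speed * (n_frames - 1) * dt

  msd <- compute_msd(b$trajectory, 0.25)
  expect_equal(msd$values, msd$lags^2, tolerance = 1e-12)  # (v * lag)^2
})

test_that("Brownian ensemble MSD converges to 4*D*lag", {
  set.seed(123)
  D <- 0.1; n_tracks <- 1000; n_frames <- 100
  m <- motion_model("brownian", diffusion_coeff = D)
  acc <- NULL
  for (i in seq_len(n_tracks)) {
    sim <- simulate_trajectory(m, n_frames, 1)
    v <- compute_msd(sim$trajectory, 0.25)$values
    acc <- if (is.null(acc)) v else acc + v
  }
  ens <- acc / n_tracks
  lags <- seq_along(ens)
  expect_lt(max(abs(ens - 4 * D * lags) / (4 * D * lags)), 0.05)
})

test_that("confined tracks stay within the confinement radius", {
  m <- motion_model("confined", diffusion_coeff = 0.5, confinement_radius = 0.3)
  sim <- simulate_trajectory(m, 200, 1, seed = 5)
  r <- sqrt(sim$ground_truth$x_true^2 + sim$ground_truth$y_true^2)
  expect_true(all(r <= 0.3 + 1e-12))
})

test_that("population assignment follows the mixture and honours edge cases", {
  mix <- list(list(model = motion_model("ballistic", speed = 1), weight = 1),
              list(model = motion_model("brownian", diffusion_coeff = 0.1),
                   weight = 0))
  pop <- simulate_population(mix, 25, 30, 1, seed = 3)
  expect_length(pop$tracks, 25)
  expect_true(all(vapply(pop$ground_truth, `[[`, "", "kind") == "ballistic"))

  expect_identical(simulate_population(mix, 0, 30, 1, seed = 1)$tracks, list())
  expect_error(simulate_population(list(), 5, 30, 1, seed = 1),
               class = "vesiquant_invalid")
  expect_error(simulate_trajectory(motion_model("brownian"), 1, 1),
               class = "vesiquant_invalid")
  expect_error(simulate_trajectory(motion_model("brownian"), 10, 0),
               class = "vesiquant_invalid")
  expect_error(motion_model("confined", diffusion_coeff = 1),
               class = "vesiquant_invalid")
  expect_error(motion_model("switching", p_passive_to_active = 1.5),
               class = "vesiquant_invalid")
})

test_that("switching ground truth matches the emitted states and positions", {
  sim <- simulate_trajectory(switching_test_model(), 120, 1, seed = 8)
  gt <- sim$ground_truth
  expect_length(gt$state, 120)
  expect_true(all(gt$state %in% c("active", "passive")))
  # noise-free truth differs from the observed track only by the noise
  expect_equal(sd(sim$trajectory$x - gt$x_true), 0.01, tolerance = 0.5)
  # active steps have constant speed, per run
  runs <- truth_active_runs(gt)
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    if (length(idx) < 3) next
    steps <- sqrt(diff(gt$x_true[idx])^2 + diff(gt$y_true[idx])^2)
    expect_equal(steps, rep(1, length(steps)), tolerance = 1e-9)
  }
})

test_that("tracks round-trip through the CSV interchange format", {
  mix <- list(list(model = switching_test_model(), weight = 1))
  pop <- simulate_population(mix, 5, 40, 0.5, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(pop$tracks, path)
  back <- read_tracks_csv(path)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$x, pop$tracks[[i]]$x, tolerance = 1e-12)
    expect_equal(back[[i]]$dt, 0.5, tolerance = 1e-9)
    expect_identical(back[[i]]$track_id, pop$tracks[[i]]$track_id)
  }
})
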