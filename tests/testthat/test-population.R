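test_that("class fractions sum to one and the histogram accounts for all runs", {
  mix <- list(
    list(model = motion_model("ballistic", speed = 1,
                              localization_noise_sd = 0.01), weight = 1),
    list(model = motion_model("brownian", diffusion_coeff = 0.1,
                              localization_noise_sd = 0.01), weight = 1))
  pop <- simulate_population(mix, 60, 60, 1, seed = 17)
  ms <- summarize_population(pop$tracks)
  expect_equal(sum(ms$fractions), 1, tolerance = 1e-12)
  expect_identical(sum(ms$histogram$count), nrow(ms$run_lengths))
  expect_identical(ms$n_tracks_input, 60L)
  expect_identical(ms$n_tracks_retained, 60L)
  # half-open 1-um bins starting at 0
  if (nrow(ms$histogram) > 0) {
    expect_identical(ms$histogram$bin_lo[1], 0)
    expect_true(all(ms$histogram$bin_hi - ms$histogram$bin_lo == 1))
  }
})

test_that("noiseless ballistic populations are nearly all processive", {
  mix <- list(list(model = motion_model("ballistic", speed = 1), weight = 1))
  pop <- simulate_population(mix, 200, 100, 1, seed = 5)
  ms <- summarize_population(pop$tracks)
  expect_gte(ms$fractions[["processive"]], 0.95)
})

test_that("tightly confined populations are nearly all non-processive", {
  mix <- list(list(model = motion_model("confined", diffusion_coeff = 0.1,
                                        confinement_radius = 0.3), weight = 1))
  pop <- simulate_population(mix, 200, 100, 1, seed = 6)
  ms <- summarize_population(pop$tracks)
  expect_gte(ms$fractions[["non_processive"]], 0.95)
})

test_that("mixture components map onto their expected classes", {
  # Ballistic tracks are recovered as processive and confined tracks as
  # non-processive at their 1/3 mixture shares. Brownian tracks straddle
  # the alpha = 1 class boundary by construction (the single-track exponent
  # estimate is centred at 1), so the diffusive class holds only the upper
  # half of the Brownian component and the rest lands in non-processive:
  # the class partition is checked accordingly.
  mix <- list(
    list(model = motion_model("ballistic", speed = 1), weight = 1),
    list(model = motion_model("brownian", diffusion_coeff = 0.1), weight = 1),
    list(model = motion_model("confined", diffusion_coeff = 0.1,
                              confinement_radius = 0.3), weight = 1))
  pop <- simulate_population(mix, 300, 100, 1, seed = 12)
  ms <- summarize_population(pop$tracks)
  kinds <- vapply(pop$ground_truth, `[[`, "", "kind")
  cls <- ms$tracks$class
  expect_lt(abs(ms$fractions[["processive"]] - 1 / 3), 0.07)
  expect_lt(abs(ms$fractions[["diffusive"]] + ms$fractions[["non_processive"]]
                - 2 / 3), 0.07)
  # per-component purity
  expect_gte(mean(cls[kinds == "ballistic"] == "processive"), 0.95)
  expect_gte(mean(cls[kinds == "confined"] == "non_processive"), 0.95)
  expect_gte(mean(cls[kinds == "brownian"] %in%
                    c("diffusive", "non_processive")), 0.95)
})

test_that("the processive fraction is monotone in ballistic speed", {
  fractions <- vapply(c(0.02, 0.1, 0.3, 1), function(v) {
    mix <- list(
      list(model = motion_model("ballistic", speed = v,
                                localization_noise_sd = 0.05), weight = 1),
      list(model = motion_model("brownian", diffusion_coeff = 0.05,
                                localization_noise_sd = 0.05), weight = 1))
    pop <- simulate_population(mix, 120, 80, 1, seed = 23)
    summarize_population(pop$tracks)$fractions[["processive"]]
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
})

test_that("an empty or fully filtered population is flagged, not zeroed", {
  ms <- summarize_population(list())
  expect_true(ms$undefined_fractions)
  expect_true(all(is.na(ms$fractions)))

  short <- replicate(5, trajectory(rnorm(10), rnorm(10), dt = 1),
                     simplify = FALSE)
  ms2 <- summarize_population(short)
  expect_identical(ms2$n_tracks_input, 5L)
  expect_identical(ms2$n_tracks_retained, 0L)
  expect_true(ms2$undefined_fractions)
})

test_that("print, summary and plot methods run on a summary object", {
  mix <- list(list(model = motion_model("ballistic", speed = 1), weight = 1))
  pop <- simulate_population(mix, 10, 40, 1, seed = 2)
  ms <- summarize_population(pop$tracks)
  expect_output(print(ms), "processive")
  expect_output(summary(ms), "histogram")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(ms))
})
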