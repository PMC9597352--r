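test_that("the CTCF formula evaluates directly and is linear in each operand", {
  expect_equal(ctcf(1000, 10, 5), 950)
  expect_equal(ctcf(1000, 10, 0), 1000)
  # superposition over random operands
  set.seed(19)
  for (rep in 1:20) {
    id1 <- runif(1, 0, 1e4); id2 <- runif(1, 0, 1e4)
    area <- runif(1, 1, 500); bg <- runif(1, 0, 20)
    expect_equal(suppressWarnings(ctcf(id1 + id2, area, bg)),
                 suppressWarnings(ctcf(id1, area, bg) + ctcf(id2, area, bg)) +
                   area * bg,
                 tolerance = 1e-9)
    expect_equal(suppressWarnings(ctcf(id1, area, 2 * bg) - ctcf(id1, area, bg)),
                 -area * bg, tolerance = 1e-9)
  }
  expect_warning(ctcf(10, 100, 5), "negative")
})

test_that("image-derived CTCF recovers a planted foreground sum", {
  img <- matrix(5, 60, 60)                 # uniform background 5
  cell <- matrix(FALSE, 60, 60); cell[20:29, 20:29] <- TRUE  # 100 px cell
  blob <- matrix(0, 60, 60); blob[22:26, 22:26] <- 16        # sums to 400
  img <- img + blob
  bg <- matrix(FALSE, 60, 60); bg[40:50, 40:50] <- TRUE
  val <- ctcf_from_image(img, cell, bg)
  expect_lt(abs(as.numeric(val) - 400) / 400, 0.01)
  ops <- attr(val, "operands")
  expect_equal(unname(ops["cell_area"]), 100)
  expect_error(ctcf_from_image(img, cell, cell), class = "vesiquant_invalid")
})

test_that("degradation fractions normalize to the pulse and are scale-free", {
  tc <- synth_decay_timecourse(200, half_life_min = 30)
  fr <- degradation_fractions(tc)
  expect_equal(fr$fraction, 2^(-c(0, 15, 30, 45, 60) / 30), tolerance = 1e-9)
  expect_equal(fr$fraction[1], 1)
  # scale invariance
  tc2 <- tc; tc2$mean_intensity <- tc2$mean_intensity * 17.3
  expect_equal(degradation_fractions(tc2)$fraction, fr$fraction,
               tolerance = 1e-12)
  # constant course, and a fully degraded endpoint
  const <- data.frame(t_min = c(0, 30, 60), mean_intensity = c(8, 8, 8))
  expect_true(all(degradation_fractions(const)$fraction == 1))
  gone <- data.frame(t_min = c(0, 60), mean_intensity = c(8, 0))
  expect_equal(degradation_fractions(gone)$fraction[2], 0)
  dead <- data.frame(t_min = c(0, 30), mean_intensity = c(0, 0))
  expect_error(degradation_fractions(dead), class = "vesiquant_degenerate")
})

test_that("fold change divides means and concentrates at the true ratio", {
  expect_equal(fold_change(6, 6), 1)
  expect_equal(fold_change(12, 6), 2)
  expect_error(fold_change(5, 0), class = "vesiquant_degenerate")
  set.seed(41)
  treated <- rnorm(1e4, mean = 150, sd = 30)
  control <- rnorm(1e4, mean = 100, sd = 30)
  expect_lt(abs(fold_change(mean(treated), mean(control)) - 1.5) / 1.5, 0.02)
})

test_that("pH calibration fits exactly on collinear points and rejects degenerate input", {
  cal <- synth_calibration_readings(-0.31, 2.46, seq(4, 6, by = 1 / 3))
  curve <- fit_ph_calibration(cal)
  expect_equal(curve$slope, -0.31, tolerance = 1e-9)
  expect_equal(curve$intercept, 2.46, tolerance = 1e-9)
  expect_equal(predict(curve, newdata = data.frame(ph = 5)),
               -0.31 * 5 + 2.46, tolerance = 1e-12)
  dup <- data.frame(ph = rep(5, 4), ratio_340_380 = rnorm(4))
  expect_error(fit_ph_calibration(dup), class = "vesiquant_invalid")
})

test_that("noisy calibration recovers the slope on average", {
  slopes <- vapply(1:100, function(s) {
    cal <- synth_calibration_readings(-0.31, 2.46, seq(4, 6, length.out = 7),
                                      noise_sd = 0.01, seed = 1000 + s)
    fit_ph_calibration(cal)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.31) / 0.31, 0.02)
})

test_that("pH round-trips through the calibration line", {
  cal <- synth_calibration_readings(-0.31, 2.46, seq(4, 6, by = 0.25))
  curve <- fit_ph_calibration(cal)
  for (p in c(4, 4.7, 5.58, 6)) {
    back <- ph_from_ratio(curve, -0.31 * p + 2.46)
    expect_lt(abs(as.numeric(back) - p), 1e-9)
    expect_false(attr(back, "out_of_range"))
  }
  out <- ph_from_ratio(curve, -0.31 * 7 + 2.46)
  expect_true(attr(out, "out_of_range"))
  flat <- structure(list(slope = 0, intercept = 1, sigma = NA, n = 5,
                         ph_range = c(4, 6)), class = "ph_calibration")
  expect_error(ph_from_ratio(flat, 1), class = "vesiquant_degenerate")
})

test_that("pH recovery error grows with calibration noise", {
  err_at <- function(noise_sd) {
    errs <- vapply(1:60, function(s) {
      cal <- synth_calibration_readings(-0.31, 2.46, seq(4, 6, length.out = 7),
                                        noise_sd = noise_sd, seed = 500 + s)
      curve <- fit_ph_calibration(cal)
      abs(as.numeric(ph_from_ratio(curve, -0.31 * 5.2 + 2.46)) - 5.2)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0.005, 0.02, 0.08), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})
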