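test_that("Kapur threshold equals the exhaustive brute-force maximizer", {
  set.seed(77)
  for (rep in 1:100) {
    # random histogram realized as an image of binned values
    n_bins <- 64L
    counts <- rpois(n_bins, lambda = rexp(n_bins, 1 / 20))
    counts[sample.int(n_bins, 2)] <- counts[sample.int(n_bins, 2)] + 200
    if (sum(counts > 0) < 2) next
    # pixel values at bin centers of [0, 64)
    vals <- rep(seq_len(n_bins) - 0.5, counts)
    img <- matrix(vals, nrow = 1)
    thr <- kapur_threshold(img, n_bins = n_bins)
    # oracle works on the same histogram the implementation builds
    lo <- min(vals); hi <- max(vals)
    breaks <- seq(lo, hi, length.out = n_bins + 1)
    bin <- pmin(findInterval(vals, breaks), n_bins)
    t_star <- brute_force_kapur_bin(tabulate(bin, nbins = n_bins))
    expect_equal(thr, breaks[t_star + 1], tolerance = 1e-12)
  }
})

test_that("two separated modes threshold strictly between them", {
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  thr <- kapur_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_error(kapur_threshold(matrix(5, 4, 4)), class = "vesiquant_degenerate")
})

test_that("a synthetic disk recovers its analytic area", {
  # disk of radius 10 px at pixel_size 0.1 um -> area ~ pi * (1 um)^2
  img <- matrix(0, 64, 64)
  d <- pixel_grid_disk <- outer((0:63 - 32)^2, (0:63 - 32)^2, `+`)
  img[d <= 10^2] <- 100
  seg <- segment_particles(img, threshold = 50, pixel_size = 0.1)
  expect_identical(nrow(seg$particles), 1L)
  expect_lt(abs(seg$particles$area_um2 - pi) / pi, 0.05)
  expect_equal(seg$particles$centroid_x_um, 3.2, tolerance = 1e-6)
  expect_equal(seg$particles$mean_intensity, 100)
})

test_that("disjoint disks are separate particles and counts match ground truth", {
  img <- matrix(0, 40, 40)
  img[5:9, 5:9] <- 50
  img[25:30, 25:30] <- 80
  seg <- segment_particles(img, threshold = 10)
  expect_identical(nrow(seg$particles), 2L)

  syn <- synth_two_channel_puncta(40, coloc_fraction = 0, seed = 13)
  thr <- kapur_threshold(syn$channel_a)
  seg_a <- segment_particles(syn$channel_a, thr)
  expect_identical(nrow(seg_a$particles), 40L)
})

test_that("labeling respects connectivity and agrees with an external oracle", {
  m <- matrix(0, 6, 6)
  m[1, 1] <- 1; m[2, 2] <- 1          # touch only diagonally
  seg8 <- segment_particles(m, 0.5, connectivity = 8)
  seg4 <- segment_particles(m, 0.5, connectivity = 4)
  expect_identical(nrow(seg8$particles), 1L)
  expect_identical(nrow(seg4$particles), 2L)

  # 4-connectivity cross-check against EBImage::bwlabel on random masks
  set.seed(31)
  for (rep in 1:10) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    ours <- segment_particles(mask + 0, 0.5, connectivity = 4)
    ref <- EBImage::bwlabel(mask + 0)
    expect_identical(max(ours$mask), max(as.matrix(ref)))
  }
})

test_that("segmentation is idempotent and translation-invariant", {
  syn <- synth_two_channel_puncta(25, 0, image_shape = c(128L, 128L), seed = 4)
  img <- syn$channel_a
  thr <- kapur_threshold(img)
  seg1 <- segment_particles(img, thr)
  # re-running on the binarized mask reproduces the same labels
  seg2 <- segment_particles((img > thr) + 0, 0.5)
  expect_identical(as.vector(seg1$mask), as.vector(seg2$mask))
  # padding the image on one side translates labels but preserves total area
  shifted <- rbind(matrix(0, 7, ncol(img)), img)
  seg3 <- segment_particles(shifted, thr)
  expect_identical(nrow(seg3$particles), nrow(seg1$particles))
  expect_equal(sum(seg3$particles$area_um2), sum(seg1$particles$area_um2))
})

test_that("min_area_px filtering drops specks and relabels consecutively", {
  img <- matrix(0, 20, 20)
  img[2, 2] <- 10                     # 1-px speck
  img[10:14, 10:14] <- 10             # 25-px block
  seg <- segment_particles(img, 5, min_area_px = 4)
  expect_identical(nrow(seg$particles), 1L)
  expect_identical(sort(unique(as.vector(seg$mask))), c(0L, 1L))
})

test_that("mean particle area averages correctly and flags empty regions", {
  tbl <- data.frame(label = 1:2, area_um2 = c(1, 3),
                    centroid_x_um = c(2, 12), centroid_y_um = c(2, 12),
                    mean_intensity = c(5, 5))
  expect_equal(mean_particle_area(tbl), 2)
  mask <- matrix(FALSE, 20, 20); mask[1:6, 1:6] <- TRUE
  expect_equal(mean_particle_area(tbl, mask, pixel_size = 1), 1)
  empty_mask <- matrix(FALSE, 20, 20)
  expect_error(mean_particle_area(tbl, empty_mask),
               class = "vesiquant_degenerate")
})
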