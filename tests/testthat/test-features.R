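make_stats <- function(mean_gm, sd_gm, mean_wm, sd_wm) {
  structure(list(mean_gm = mean_gm, sd_gm = sd_gm, mean_wm = mean_wm,
                 sd_wm = sd_wm, n_gm = 10, n_wm = 10, prob_threshold = 0.5),
            class = "tissue_stats")
}

test_that("junction thresholds follow the half-SD band formula", {
  thr <- junction_thresholds(make_stats(100, 10, 150, 8))
  expect_equal(thr$lower, 105)
  expect_equal(thr$upper, 146)

  thr0 <- junction_thresholds(make_stats(100, 0, 150, 0))
  expect_equal(c(thr0$lower, thr0$upper), c(100, 150))

  expect_error(junction_thresholds(make_stats(100, 40, 110, 40)),
               "degenerate GM-WM band")
})

test_that("junction map is zero for an ideal sharp two-phase volume", {
  d <- c(24, 24, 24)
  v <- volume3d(array(rep(c(80, 130), each = prod(d) / 2), d))
  mask <- binary_mask(array(1, d))
  fm <- junction_map(v, make_stats(80, 10, 130, 10), mask)
  expect_equal(fm$modality, "junction")
  expect_equal(max(abs(fm$volume$data)), 0)
})

test_that("a single in-band voxel yields the analytic impulse response", {
  d <- c(33, 33, 33)
  v <- volume3d(array(80, d))
  v$data[17, 17, 17] <- 100 # inside the band
  mask <- binary_mask(array(1, d))
  spec <- smoothing_spec(6)
  fm <- junction_map(v, make_stats(80, 10, 130, 10), mask, spec)
  g <- function(x) stats::dnorm(x, sd = spec$sigma_mm)
  grid <- -16:16
  analytic <- outer(outer(g(grid), g(grid)), g(grid))
  expect_lt(max(abs(fm$volume$data - analytic)), 1e-6)
})

test_that("junction map peaks at a blurred interface and is band-monotone", {
  # planar GM-WM interface replaced by a 4-voxel linear ramp
  d <- c(32, 32, 32)
  x <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
  v <- volume3d(array(80, d))
  v$data[x > 18] <- 130
  ramp <- x >= 15 & x <= 18
  v$data[ramp] <- 80 + (x[ramp] - 14) / 5 * 50
  mask <- binary_mask(array(1, d))
  fm <- junction_map(v, make_stats(80, 4, 130, 4), mask)
  peak <- arrayInd(which.max(fm$volume$data), d)
  expect_lte(abs(peak[1] - 16.5), 2) # within 2 voxels of the ramp mid-plane
  expect_true(all(fm$volume$data >= 0 & fm$volume$data <= 1))

  # enlarging the band never decreases any voxel value
  narrow <- junction_map(v, make_stats(80, 8, 130, 8), mask)
  wide <- junction_map(v, make_stats(80, 2, 130, 2), mask)
  expect_true(all(wide$volume$data - narrow$volume$data >= -1e-12))
})

test_that("extension map is the masked smoothed GM probability", {
  d <- c(24, 24, 24)
  lab <- array(0L, d)
  seg <- seg_from_labels(lab)
  mask <- binary_mask(array(1, d))
  fm <- extension_map(seg, mask)
  expect_equal(max(abs(fm$volume$data)), 0)

  lab[, , 12] <- 2L
  seg <- seg_from_labels(lab)
  # FWHM -> 0 limit: identity on the ribbon indicator
  fm_id <- extension_map(seg, mask, smoothing_spec(1e-3))
  expect_lt(max(abs(fm_id$volume$data - (lab == 2L))), 1e-3)

  # mass conservation for a blob with full interior kernel support
  d2 <- c(41, 41, 41)
  lab2 <- array(0L, d2)
  lab2[19:23, 19:23, 19:23] <- 2L
  seg2 <- seg_from_labels(lab2)
  fm2 <- extension_map(seg2, binary_mask(array(1, d2)), smoothing_spec(6))
  expect_equal(sum(fm2$volume$data) / sum(lab2 == 2L), 1, tolerance = 1e-3)
  expect_true(all(fm2$volume$data >= 0 & fm2$volume$data <= 1 + 1e-12))

  expect_error(extension_map(seg2, binary_mask(array(0, d2))),
               "empty cortical mask")
})

test_that("thickness of a flat slab equals its metric thickness", {
  d <- c(24, 24, 24)
  x <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
  lab <- array(1L, d)
  lab[x <= 9] <- 3L          # WM half-space
  lab[x > 9 & x <= 15] <- 2L # 6-voxel GM slab
  fm <- thickness_map(seg_from_labels(lab))
  interior <- lab == 2L & array(rep(seq_len(d[2]), each = d[1]), d) %in% 8:16
  expect_equal(stats::median(fm$volume$data[interior]), 6, tolerance = 1)
  expect_true(all(fm$volume$data[lab != 2L] == 0))
})

test_that("thickness of a spherical shell matches its width", {
  d <- c(48, 48, 48)
  ctr <- (d + 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d)
  r <- sqrt(colSums((t(idx) - ctr)^2))
  lab <- array(1L, d)
  lab[r < 15] <- 3L
  lab[r >= 15 & r < 20] <- 2L
  fm <- thickness_map(seg_from_labels(lab))
  expect_equal(stats::median(fm$volume$data[lab == 2L]), 5, tolerance = 1)
})

test_that("thickness is invariant under 90-degree grid rotations", {
  ph <- make_head_phantom(small_spec(noise_sd = 0, seed = 8,
                                     semi_axes = c(15, 12, 10)))
  fm <- thickness_map(seg_from_labels(ph$labels))
  rot <- aperm(ph$labels, c(2, 1, 3))[dim(ph$labels)[2]:1, , ]
  fm_rot <- thickness_map(seg_from_labels(rot))
  back <- aperm(fm_rot$volume$data[dim(rot)[1]:1, , ], c(2, 1, 3))
  expect_equal(back, fm$volume$data, tolerance = 1e-12)
})

test_that("thickness handles missing tissue classes", {
  d <- c(8, 8, 8)
  lab <- array(0L, d)
  lab[1:256] <- 3L
  expect_warning(fm <- thickness_map(seg_from_labels(lab)), "no GM")
  expect_equal(max(abs(fm$volume$data)), 0)
  lab_all_gm <- array(2L, d)
  expect_error(thickness_map(seg_from_labels(lab_all_gm)), "no WM")
})
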