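fmap <- function(data, modality = "extension", spacing = c(1, 1, 1)) {
  feature_map(volume3d(data, spacing), modality)
}

test_that("template mean and SD are voxel-wise with n-1 denominator", {
  d <- c(6, 6, 6)
  a <- fmap(array(10, d))
  b <- fmap(array(14, d))
  tpl <- build_template(list(a, b))
  expect_equal(tpl$mu$data, array(12, d))
  expect_equal(tpl$sigma$data, array(2.828427, d), tolerance = 1e-6)

  same <- build_template(list(a, a))
  expect_equal(max(same$sigma$data), 0)

  expect_error(build_template(list(a)), "at least 2")
  expect_error(build_template(list(a, fmap(array(1, d), "junction"))),
               "mixed modalities")
  expect_error(build_template(list(a, b), ages = c(1, 2, 3)), "length")
  expect_error(build_template(list(a, fmap(array(0, c(7, 7, 7))))),
               "same grid")
})

test_that("per-voxel age regression recovers a planted linear model", {
  set.seed(10)
  d <- c(8, 8, 8)
  ages <- seq(4, 16, length.out = 30)
  maps <- lapply(ages, function(a) {
    fmap(array(2 + 0.1 * a + rnorm(prod(d), 0, 0.05), d))
  })
  tpl <- build_template(maps, ages = ages)
  expect_true(all(abs(tpl$age_model$slope - 0.1) < 0.02))
  expect_true(all(abs(tpl$age_model$offset - 2) < 0.2))
  expect_equal(stats::median(tpl$age_model$resid_sd), 0.05, tolerance = 0.01)
})

test_that("z-maps are the floored standardized deviation", {
  d <- c(6, 6, 6)
  set.seed(11)
  maps <- lapply(1:5, function(i) fmap(array(rnorm(prod(d), 5, 1), d)))
  tpl <- build_template(maps)
  pat <- fmap(tpl$mu$data)
  expect_equal(max(abs(zmap(pat, tpl)$z$data)), 0)

  pat2 <- fmap(tpl$mu$data + 2 * tpl$sigma$data)
  z2 <- zmap(pat2, tpl)
  ok <- tpl$sigma$data > z2$sigma_floor
  expect_equal(unique(round(z2$z$data[ok], 10)), 2)

  # sigma = 0 with floor 1e-3 and deviation 0.01 gives z = 10
  tpl0 <- build_template(list(fmap(array(5, d)), fmap(array(5, d))))
  pat3 <- fmap(array(5.01, d))
  z3 <- zmap(pat3, tpl0, sigma_floor = 1e-3)
  expect_equal(unique(c(z3$z$data)), 10, tolerance = 1e-9)

  expect_error(zmap(fmap(array(0, d), "junction"), tpl), "modality")
})

test_that("age-adjusted z-scoring centers on the predicted value", {
  d <- c(6, 6, 6)
  ages <- seq(6, 12, length.out = 10)
  maps <- lapply(ages, function(a) fmap(array(2 + 0.1 * a, d)))
  tpl <- build_template(maps, ages = ages)
  pat <- fmap(array(2 + 0.1 * 9, d))
  z <- age_adjusted_zmap(pat, 9, tpl, sigma_floor = 1e-3)
  expect_lt(max(abs(z$z$data)), 1e-6)

  # noiseless cohort: deviation of 3 floors scores exactly 3
  pat2 <- fmap(array(2 + 0.1 * 9 + 3 * 1e-3, d))
  z2 <- age_adjusted_zmap(pat2, 9, tpl, sigma_floor = 1e-3)
  expect_equal(range(z2$z$data), c(3, 3), tolerance = 1e-6)

  expect_warning(age_adjusted_zmap(pat, 30, tpl), "outside the control")
  tpl_plain <- build_template(maps)
  expect_error(age_adjusted_zmap(pat, 9, tpl_plain), "no age model")
})

test_that("a planted lesion offset scores at its design z", {
  set.seed(12)
  d <- c(12, 12, 12)
  ages <- seq(6, 12, length.out = 30)
  maps <- lapply(ages, function(a) {
    fmap(array(2 + 0.1 * a + rnorm(prod(d), 0, 0.05), d))
  })
  tpl <- build_template(maps, ages = ages)
  patch <- array(FALSE, d)
  patch[4:8, 4:8, 4:8] <- TRUE
  pat <- array(2 + 0.1 * 9, d)
  pat[patch] <- pat[patch] + 0.25
  z <- age_adjusted_zmap(fmap(pat), 9, tpl)
  expect_equal(mean(z$z$data[patch]), 5, tolerance = 1)
})

test_that("subtraction map equals the element-wise difference", {
  set.seed(13)
  d <- c(6, 6, 6)
  maps <- lapply(1:3, function(i) fmap(array(rnorm(prod(d)), d)))
  tpl <- build_template(maps)
  expect_equal(max(abs(subtraction_map(fmap(tpl$mu$data), tpl)$volume$data)),
               0)
  pat <- fmap(tpl$mu$data + 3)
  expect_equal(range(subtraction_map(pat, tpl)$volume$data), c(3, 3),
               tolerance = 1e-12)

  rnd <- fmap(array(rnorm(prod(d)), d))
  got <- subtraction_map(rnd, tpl)$volume$data
  # brute-force voxel loop oracle
  want <- array(0, d)
  for (i in seq_len(prod(d))) want[i] <- rnd$volume$data[i] - tpl$mu$data[i]
  expect_equal(got, want)
})

test_that("cluster extraction groups, filters, sorts, and excludes", {
  d <- c(24, 24, 24)
  z <- array(0, d)
  z[3:5, 3:5, 3:5] <- 3
  z[15:17, 15:17, 15:17] <- 4
  zv <- volume3d(z)
  cs <- threshold_clusters(zv, 2)
  expect_equal(nrow(cs$clusters), 2)
  expect_equal(cs$clusters$volume_mm3, c(27, 27))
  expect_equal(cs$clusters$peak_z, c(4, 3)) # sorted by peak descending
  expect_equal(sum(cs$label_map > 0), 54)
  expect_true(all(z[cs$label_map > 0] > 2))

  excl <- array(0, d)
  excl[15:17, 15:17, 15:17] <- 1
  cs2 <- threshold_clusters(zv, 2, exclusion = binary_mask(excl))
  expect_equal(nrow(cs2$clusters), 1)
  expect_equal(cs2$clusters$peak_z, 3)

  empty <- threshold_clusters(volume3d(array(0, d)), 2)
  expect_equal(nrow(empty$clusters), 0)

  cs3 <- threshold_clusters(zv, 2, min_cluster_mm3 = 30)
  expect_equal(nrow(cs3$clusters), 0)
})

test_that("raising the threshold shrinks the labeled set monotonically", {
  set.seed(14)
  d <- c(20, 20, 20)
  zv <- volume3d(array(rnorm(prod(d)), d))
  zv <- smooth_gaussian(zv, smoothing_spec(3))
  lo <- threshold_clusters(zv, 0.1)
  hi <- threshold_clusters(zv, 0.3)
  expect_true(all(lo$label_map[hi$label_map > 0] > 0))
  expect_lte(sum(hi$label_map > 0), sum(lo$label_map > 0))
})

test_that("templates survive a save/load round trip", {
  set.seed(15)
  d <- c(6, 6, 6)
  ages <- c(6, 8, 10, 12)
  maps <- lapply(ages, function(a) {
    fmap(array(1 + 0.05 * a + rnorm(prod(d), 0, 0.01), d), "junction")
  })
  tpl <- build_template(maps, ages = ages)
  dir <- file.path(tempdir(), "tpl_test")
  manifest <- save_template(tpl, dir)
  back <- load_template(manifest)
  expect_equal(back$mu$data, tpl$mu$data, tolerance = 1e-12)
  expect_equal(back$sigma$data, tpl$sigma$data, tolerance = 1e-12)
  expect_equal(back$n, tpl$n)
  expect_equal(back$modality, "junction")
  expect_equal(back$age_model$slope, tpl$age_model$slope, tolerance = 1e-12)
  expect_error(load_template(file.path(tempdir(), "absent.json")),
               "not found")
})
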