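test_that("phantom generation is seeded and deterministic", {
  a <- make_head_phantom(small_spec(seed = 40))
  b <- make_head_phantom(small_spec(seed = 40))
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$labels, b$labels)
  c <- make_head_phantom(small_spec(seed = 41))
  expect_false(identical(a$t1$data, c$t1$data))
})

test_that("noiseless phantoms have exactly three in-brain intensities", {
  ph <- make_head_phantom(small_spec(noise_sd = 0))
  vals <- unique(ph$t1$data[ph$brain_mask$data > 0])
  expect_setequal(vals, c(30, 80, 130))
  expect_true(all(ph$t1$data[ph$brain_mask$data == 0] == 0))
})

test_that("phantom outputs share one grid and satisfy mask invariants", {
  ph <- make_head_phantom(small_spec(seed = 42))
  expect_true(check_same_grid(list(ph$t1, ph$brain_mask, ph$cortical_mask)))
  expect_true(all(ph$brain_mask$data %in% c(0, 1)))
  expect_true(all(ph$cortical_mask$data <= ph$brain_mask$data))
  expect_identical(ph$cortical_mask$data > 0, ph$labels == 2L)
  expect_error(phantom_spec(semi_axes = c(5, 5, 5), csf_mm = 3,
                            ribbon_mm = 4),
               "thinner than")
  expect_error(phantom_spec(intensities = c(csf = 100, gm = 80, wm = 130)),
               "CSF < GM < WM")
})

test_that("ribbon thickness is recovered by the thickness map", {
  ph <- make_head_phantom(phantom_spec(ribbon_mm = 5, noise_sd = 0))
  fm <- thickness_map(phantom_segmentation(ph))
  expect_equal(stats::median(fm$volume$data[ph$labels == 2L]), 5,
               tolerance = 1)
})

test_that("zero-radius lesions are exact no-ops", {
  ph <- make_head_phantom(small_spec(seed = 43))
  les <- insert_fcd_lesion(ph, lesion_spec(ph$center + c(0, 0, 10), 0))
  expect_identical(les$phantom$t1$data, ph$t1$data)
  expect_equal(sum(les$lesion_mask$data), 0)
})

test_that("junction blur floods the lesion with intermediate intensities", {
  ph <- make_head_phantom(phantom_spec(seed = 44, noise_sd = 2))
  center <- ph$center + c(0, 0, 14)
  les <- insert_fcd_lesion(ph, lesion_spec(center, 8, "junction_blur",
                                           ramp_mm = 4))
  n_lesion <- sum(les$lesion_mask$data)
  expect_gt(n_lesion, 0)
  between <- function(v, sel) sum(v[sel] > 85 & v[sel] < 125)
  in_les <- les$phantom$t1$data
  n_mid_lesion <- between(in_les, les$lesion_mask$data > 0)
  # matched unmodified region: mirror the lesion through the center
  mirror <- sphere_mask(ph$t1, ph$center - c(0, 0, 14), 8)
  ctrl_sel <- mirror$data > 0 & ph$labels > 0
  n_mid_ctrl <- between(ph$t1$data, ctrl_sel) *
    n_lesion / max(sum(ctrl_sel), 1)
  expect_gte(n_mid_lesion, 5 * max(n_mid_ctrl, 1))
})

test_that("thickening raises local thickness by the design delta", {
  ph <- make_head_phantom(phantom_spec(seed = 45, noise_sd = 0))
  les <- insert_fcd_lesion(ph, lesion_spec(ph$center + c(0, 0, 14), 8,
                                           "thickening", delta_mm = 3))
  base <- thickness_map(phantom_segmentation(ph))
  mod <- thickness_map(phantom_segmentation(les$phantom))
  base_med <- stats::median(base$volume$data[ph$labels == 2L])
  les_med <- stats::median(mod$volume$data[les$lesion_mask$data > 0])
  expect_equal(les_med - base_med, 3, tolerance = 1.5)
  expect_error(insert_fcd_lesion(ph, lesion_spec(c(0, 0, 0), 3)),
               "does not intersect")
})

test_that("carved cavities match sphere rasterization and touch nothing else", {
  ph <- make_head_phantom(phantom_spec(seed = 46))
  post <- carve_resection(ph, ph$center, 10)
  sph <- sphere_mask(ph$t1, ph$center, 10)
  expect_equal(sum(sph$data), 4 / 3 * pi * 1000, tolerance = 200 / 4189)
  changed <- ph$t1$data != post$data
  expect_true(all(changed == (sph$data > 0 &
                                ph$labels != 1L)))
  expect_identical(post$data[sph$data == 0], ph$t1$data[sph$data == 0])

  same <- carve_resection(ph, ph$center, 0)
  expect_identical(same$data, ph$t1$data)
  expect_error(carve_resection(ph, ph$center + c(30, 0, 0), 10),
               "outside the brain")
})

test_that("cohorts are reproducible with per-subject seeds and jitter", {
  spec <- small_spec(seed = 47)
  coh <- make_cohort(5, spec, jitter = 0, seed = 47)
  expect_length(coh, 5)
  # no jitter, no ages: identical geometry, different noise
  expect_identical(coh[[1]]$labels, coh[[2]]$labels)
  expect_false(identical(coh[[1]]$t1$data, coh[[2]]$t1$data))
  seeds <- vapply(coh, function(p) p$spec$seed, integer(1))
  expect_length(unique(seeds), 5)

  again <- make_cohort(5, spec, jitter = 0, seed = 47)
  expect_identical(coh[[3]]$t1$data, again[[3]]$t1$data)

  jit <- make_cohort(3, spec, jitter = 0.05, seed = 48)
  expect_false(identical(jit[[1]]$labels, jit[[2]]$labels))
  expect_error(make_cohort(1, spec), "n >= 2")
})

test_that("an aged cohort plants a recoverable thickness slope", {
  spec <- small_spec(seed = 49)
  ages <- seq(6, 12, length.out = 8)
  coh <- make_cohort(8, spec, jitter = 0, ages = ages,
                     age_thickness_slope = 0.3, seed = 49)
  ribbons <- vapply(coh, function(p) p$spec$ribbon_mm, numeric(1))
  expect_equal(ribbons, 4 + 0.3 * ages, tolerance = 1e-12)
})
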