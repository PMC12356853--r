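test_that("overlap metrics reproduce tabulated cohort worked examples", {
  m <- make_overlap_masks(1593, 3096, 1056)
  rep19 <- overlap_report(m$detected, m$reference)
  expect_equal(round(rep19$percent_overlay, 1), 34.1)
  expect_equal(rep19$dice, 2 * 1056 / (1593 + 3096), tolerance = 1e-12)
  expect_equal(rep19$dice, 0.450416, tolerance = 1e-5)
  expect_equal(rep19$overlap_mm3, 1056)

  same <- make_overlap_masks(500, 500, 500)
  repx <- overlap_report(same$detected, same$reference)
  expect_equal(repx$dice, 1)
  expect_equal(repx$percent_overlay, 100)

  # DICE is symmetric, percent overlay is not
  m2 <- make_overlap_masks(800, 2000, 400)
  ab <- overlap_report(m2$detected, m2$reference)
  ba <- overlap_report(m2$reference, m2$detected)
  expect_equal(ab$dice, ba$dice)
  expect_false(isTRUE(all.equal(ab$percent_overlay, ba$percent_overlay)))

  empty <- binary_mask(array(0, c(8, 8, 8)))
  one <- binary_mask(`[<-`(array(0, c(8, 8, 8)), 1, 1))
  expect_warning(r <- overlap_report(one, empty), "empty reference")
  expect_true(is.na(r$percent_overlay))
  expect_error(make_overlap_masks(10, 10, 11), "exceeds")
})

test_that("cluster overlap table counts touching clusters and coverage", {
  d <- c(24, 24, 24)
  z <- array(0, d)
  z[3:5, 3:5, 3:5] <- 3    # 27 voxels, inside reference
  z[15:17, 15:17, 15:17] <- 4 # disjoint from reference
  cs <- threshold_clusters(volume3d(z), 2)
  ref <- array(0, d)
  ref[1:10, 1:10, 1] <- 1 # 100 voxels
  ref[3:5, 3:5, 3:5] <- 1
  ref[3:5, 3:5, 1] <- 0
  refm <- binary_mask(ref)
  stopifnot(sum(ref) == 100 + 27 - 9)
  tab <- cluster_overlap_table(cs, refm)
  expect_equal(tab$n_overlapping, 1L)
  expect_equal(tab$n_total, 2L)
  expect_equal(tab$percent_reference_covered, 100 * 27 / sum(ref))

  none <- threshold_clusters(volume3d(array(0, d)), 2)
  tab0 <- cluster_overlap_table(none, refm)
  expect_equal(unlist(tab0[, 1:2]), c(n_overlapping = 0L, n_total = 0L))
  expect_equal(tab0$percent_reference_covered, 0)
  expect_error(cluster_overlap_table(cs, binary_mask(array(0, d))),
               "empty reference")
})

test_that("one fully contained cluster covers its share of the reference", {
  d <- c(16, 16, 16)
  z <- array(0, d)
  z[5:7, 5:7, 5:7] <- 3
  cs <- threshold_clusters(volume3d(z), 2)
  ref <- array(0, d)
  ref[4:8, 4:8, 4:8] <- 1 # 125 voxels containing the 27-voxel cluster
  ref <- binary_mask(ref)
  n_ref <- sum(ref$data)
  tab <- cluster_overlap_table(cs, ref)
  expect_equal(tab$n_overlapping, 1L)
  expect_equal(tab$n_total, 1L)
  expect_equal(tab$percent_reference_covered, 100 * 27 / n_ref)
})

test_that("ROC endpoints, perfect and inverted detectors", {
  d <- c(16, 16, 16)
  ref <- array(0, d)
  ref[4:6, 4:6, 4:6] <- 1
  refm <- binary_mask(ref)
  brain <- binary_mask(array(1, d))
  perfect <- roc_curve(volume3d(ref), refm, brain)
  expect_equal(perfect$auc, 1, tolerance = 1e-12)
  inverted <- roc_curve(volume3d(1 - ref), refm, brain)
  expect_equal(inverted$auc, 0, tolerance = 1e-12)
  expect_equal(perfect$points$tpr[1], 0)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(utils::tail(perfect$points$tpr, 1), 1)
  expect_equal(utils::tail(perfect$points$fpr, 1), 1)

  expect_warning(flat <- roc_curve(volume3d(array(1, d)), refm, brain),
                 "constant score")
  expect_equal(flat$auc, 0.5)

  outside <- binary_mask(`[<-`(array(0, d), cbind(1, 1, 1), 1))
  small_brain <- binary_mask(`[<-`(array(1, d), cbind(1, 1, 1), 0))
  expect_error(roc_curve(volume3d(ref), outside, small_brain),
               "outside the brain")
})

test_that("a random score map scores at chance level", {
  # mean over seeded replicates: one 5^3 reference has AUC sampling SD
  # ~0.026, so a single draw is uninformative at the 0.03 band
  set.seed(30)
  d <- c(32, 32, 32)
  ref <- array(0, d)
  ref[10:14, 10:14, 10:14] <- 1
  aucs <- vapply(1:10, function(i) {
    sc <- volume3d(array(runif(prod(d)), d))
    roc_curve(sc, binary_mask(ref), binary_mask(array(1, d)))$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("trapezoid AUC matches the rank-based oracle and is coherent", {
  set.seed(31)
  d <- c(32, 32, 32)
  ref <- array(0, d)
  ref[8:15, 8:15, 8:15] <- 1
  brain <- binary_mask(array(1, d))
  for (shift in c(0, 0.4, 1.2)) {
    sc <- array(rnorm(prod(d)), d)
    sc[ref > 0] <- sc[ref > 0] + shift
    roc <- roc_curve(volume3d(sc), binary_mask(ref), brain,
                     n_thresholds = 1e4)
    expect_equal(roc$auc, rank_auc(c(sc), c(ref) > 0), tolerance = 0.005)

    neg <- roc_curve(volume3d(-sc), binary_mask(ref), brain,
                     n_thresholds = 1e4)
    expect_equal(neg$auc, 1 - roc$auc, tolerance = 2 / 1e4 + 1e-6)

    boosted <- sc
    boosted[ref > 0] <- boosted[ref > 0] + 0.5
    roc_b <- roc_curve(volume3d(boosted), binary_mask(ref), brain,
                       n_thresholds = 1e4)
    expect_gte(roc_b$auc + 1e-3, roc$auc)
  }
})

test_that("volume summaries are mean/min/max", {
  s <- summarize_volumes(c(574, 4701, 1781))
  expect_equal(s$mean_mm3, mean(c(574, 4701, 1781)))
  expect_equal(s$min_mm3, 574)
  expect_equal(s$max_mm3, 4701)
  one <- summarize_volumes(42)
  expect_equal(unlist(one[, c("mean_mm3", "min_mm3", "max_mm3")]),
               c(mean_mm3 = 42, min_mm3 = 42, max_mm3 = 42))
  expect_error(summarize_volumes(numeric(0)), "non-empty")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  a <- c(5, 7, 9, 11)
  b <- a - c(1, 2, 3, 4)
  res <- paired_compare(a, b)
  expect_equal(res$statistic, 2.5 / (stats::sd(c(1, 2, 3, 4)) / 2),
               tolerance = 1e-12)
  expect_equal(res$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * stats::pt(-3.872983, df = 3),
               tolerance = 1e-6)
  expect_equal(res$p_value, 0.0305, tolerance = 5e-3)

  expect_warning(z <- paired_compare(a, a), "zero-variance")
  expect_equal(c(z$statistic, z$p_value), c(0, 1))
  expect_error(paired_compare(1:3, 1:4), "equal lengths")
})

test_that("Holm-Sidak adjustment matches a step-down loop oracle", {
  expect_equal(holm_sidak(0.3), 0.3)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(c(0.01, 0.04)), c(0.0199, 0.04))
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")

  oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 0
    for (i in seq_len(m)) {
      running <- max(running, 1 - (1 - p[o[i]])^(m - i + 1))
      adj[o[i]] <- min(running, 1)
    }
    adj
  }
  set.seed(32)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_equal(holm_sidak(p), oracle(p), tolerance = 1e-12)
  }
})

test_that("the Gaussian two-sided cutoff at 5 percent is 1.96", {
  expect_equal(round(z_cutoff(0.05), 2), 1.96)
  expect_equal(z_cutoff(0.05), stats::qnorm(0.975))
  expect_error(z_cutoff(0), "in \\(0, 1\\)")
})
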