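#' Three-class tissue segmentation by Gaussian mixture EM
#'
#' Fits a three-component Gaussian mixture to the in-mask T1 intensities by
#' expectation-maximization and assigns the components, in increasing order
#' of fitted mean, to CSF, gray matter (GM), and white matter (WM) - the
#' intensity ordering of T1-weighted images. Initialization is deterministic
#' (component means at the 25th/50th/75th in-mask intensity percentiles), so
#' identical inputs give bit-identical output; the `seed` argument is
#' accepted for interface symmetry with the stochastic stages but unused.
#' Per-voxel probabilities are the posterior responsibilities.
#'
#' Atlas priors and bias-field modeling are deliberately absent; externally
#' produced probability maps can enter the pipeline through
#' [accept_external_probmaps()] instead.
#'
#' @param vol A T1 `volume3d`.
#' @param brain_mask Non-empty `binary_mask`; voxels outside are background.
#' @param seed Ignored (the fit is deterministic); present for API symmetry.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-8).
#' @return A `tissue_seg` object: integer `labels` (0 background, 1 CSF,
#'   2 GM, 3 WM), probability arrays `prob_csf`/`prob_gm`/`prob_wm`, the
#'   fitted `mixture` (tibble), `stats` ([tissue_stats()]), and the
#'   log-likelihood trace.
#' @export
segment_tissues <- function(vol, brain_mask, seed = NULL, max_iter = 500,
                            tol = 1e-8) {
  stopifnot(is_volume3d(vol), is_binary_mask(brain_mask))
  assert_same_grid(vol, brain_mask)
  inside <- brain_mask$data > 0
  if (!any(inside)) stopf("empty brain mask")
  x <- vol$data[inside]
  if (length(unique(x)) < 3) {
    stopf("need at least 3 distinct in-mask intensities, found %d",
          length(unique(x)))
  }

  fit <- gmm3_em(x, max_iter = max_iter, tol = tol)

  d <- dim(vol$data)
  pr <- lapply(1:3, function(k) {
    a <- array(0, d)
    a[inside] <- fit$resp[, k]
    a
  })
  lab <- array(0L, d)
  lab[inside] <- max.col(fit$resp, ties.method = "first")

  seg <- structure(list(labels = lab,
                        prob_csf = pr[[1]], prob_gm = pr[[2]],
                        prob_wm = pr[[3]],
                        mixture = tibble::tibble(
                          tissue = c("csf", "gm", "wm"),
                          mean = fit$mu, sd = fit$sigma, weight = fit$w),
                        loglik = fit$loglik,
                        converged = fit$converged,
                        spacing = vol$spacing, affine = vol$affine,
                        space = vol$space),
                   class = "tissue_seg")
  seg$stats <- tissue_stats(vol, seg)
  seg
}

# EM for a 3-component 1D Gaussian mixture. Initialization is a
# deterministic Lloyd k-means, best of three fixed starts (quantile and
# equal-spaced seeds): plain quantile means can trap EM in a
# two-components-on-one-mode optimum when class proportions are skewed.
# The M-step floors sigma
# (constrained maximization), which keeps the likelihood ascent property
# even for noiseless (delta-like) classes.
gmm3_em <- function(x, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  s0 <- stats::sd(x)
  sig_floor <- max(1e-8 * s0, .Machine$double.xmin^0.25)

  starts <- list(
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7),
    stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7),
    min(x) + (1:3 - 0.5) / 3 * (max(x) - min(x)))
  km <- NULL
  for (centers in starts) {
    if (length(unique(centers)) < 3) next
    cand <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = matrix(centers, 3, 1),
                                     iter.max = 200, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(km) || cand$tot.withinss < km$tot.withinss)) {
      km <- cand
    }
  }
  if (is.null(km)) {
    centers <- sort(unique(x))[round(seq(1, length(unique(x)),
                                         length.out = 3))]
  }
  if (!is.null(km)) {
    mu <- as.numeric(km$centers)
    sigma <- vapply(1:3, function(k) {
      xs <- x[km$cluster == k]
      if (length(xs) > 1) stats::sd(xs) else 0
    }, numeric(1))
    sigma <- pmax(sigma, sig_floor)
    w <- pmax(km$size, 1) / n
    w <- w / sum(w)
  } else {
    mu <- centers
    sigma <- rep(max(s0 / 3, sig_floor), 3)
    w <- rep(1 / 3, 3)
  }

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * stats::dnorm(x, mu[k], sigma[k]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (length(ll_trace) > 0 && ll < ll_old - 1e-6 * abs(ll_old)) {
      stopf("EM log-likelihood decreased (internal error): %g -> %g",
            ll_old, ll)
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(vapply(1:3, function(k) {
      sum(resp[, k] * (x - mu[k])^2) / nk[k]
    }, numeric(1)))
    sigma <- pmax(sigma, sig_floor)
  }
  if (!converged) {
    nt <- length(ll_trace)
    warnf(paste0("EM did not converge in %d iterations ",
                 "(last log-likelihood delta %.3g)"),
          max_iter, if (nt > 1) ll_trace[nt] - ll_trace[nt - 1] else NA)
  }
  dens <- vapply(1:3, function(k) w[k] * stats::dnorm(x, mu[k], sigma[k]),
                 numeric(n))
  tot <- rowSums(dens)
  tot[tot == 0 | !is.finite(tot)] <- .Machine$double.xmin
  resp <- dens / tot

  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], w = w[ord],
       resp = resp[, ord, drop = FALSE], loglik = ll_trace,
       converged = converged)
}

#' @export
print.tissue_seg <- function(x, ...) {
  cat(sprintf("<tissue_seg> %s voxels, %d in brain\n",
              paste(dim(x$labels), collapse = "x"), sum(x$labels > 0)))
  print(x$mixture)
  invisible(x)
}

#' Wrap externally produced tissue probability maps
#'
#' Lets segmentations from external tools (SPM-style unified segmentation,
#' atlas-based methods, ...) enter the pipeline. Labels are derived by
#' argmax; if the accompanying T1 is supplied, per-tissue intensity
#' statistics are computed as well.
#'
#' @param prob_gm,prob_wm,prob_csf Probability `volume3d`s in \[0, 1\] on one
#'   grid, summing to at most 1 (+1e-6) per voxel.
#' @param t1 Optional T1 `volume3d` for [tissue_stats()].
#' @param prob_threshold Probability cutoff passed to [tissue_stats()].
#' @return A `tissue_seg`.
#' @export
accept_external_probmaps <- function(prob_gm, prob_wm, prob_csf, t1 = NULL,
                                     prob_threshold = 0.5) {
  stopifnot(is_volume3d(prob_gm), is_volume3d(prob_wm), is_volume3d(prob_csf))
  assert_same_grid(prob_gm, prob_wm, prob_csf, what = "probability maps")
  maps <- list(csf = prob_csf$data, gm = prob_gm$data, wm = prob_wm$data)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (min(m) < -1e-6 || max(m) > 1 + 1e-6) {
      stopf("prob_%s values outside [0, 1] (range %.4g..%.4g)", nm,
            min(m), max(m))
    }
    maps[[nm]] <- pmin(pmax(m, 0), 1)
  }
  total <- maps$csf + maps$gm + maps$wm
  if (max(total) > 1 + 1e-6) {
    stopf("tissue probabilities sum to %.4g > 1 at some voxel", max(total))
  }
  if (max(total) <= 0) stopf("no tissue assigned: all probability maps zero")

  d <- dim(prob_gm$data)
  stacked <- cbind(c(maps$csf), c(maps$gm), c(maps$wm))
  lab <- array(0L, d)
  any_tissue <- total > 0
  lab[any_tissue] <- max.col(stacked, ties.method = "first")[any_tissue]

  seg <- structure(list(labels = lab,
                        prob_csf = maps$csf, prob_gm = maps$gm,
                        prob_wm = maps$wm,
                        mixture = NULL, loglik = NULL, converged = NA,
                        spacing = prob_gm$spacing, affine = prob_gm$affine,
                        space = prob_gm$space),
                   class = "tissue_seg")
  if (!is.null(t1)) {
    assert_same_grid(prob_gm, t1, what = "T1 and probability maps")
    seg$stats <- tissue_stats(t1, seg, prob_threshold = prob_threshold)
  }
  seg
}

#' Per-tissue intensity statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of the T1 intensity
#' over voxels whose tissue probability exceeds `prob_threshold`. These
#' statistics (MeanGM, S.D.GM, MeanWM, S.D.WM) drive the junction band
#' thresholds; the default cutoff of 0.5 excludes partial-volume voxels that
#' would bias the class means toward each other. For T1-weighted input WM
#' should be brighter than GM - a violation is reported as a warning, not an
#' error.
#'
#' @param vol The T1 `volume3d` the segmentation was computed from.
#' @param seg A `tissue_seg`.
#' @param prob_threshold Tissue probability cutoff (default 0.5).
#' @return A `tissue_stats` object with fields `mean_gm`, `sd_gm`, `mean_wm`,
#'   `sd_wm`, `n_gm`, `n_wm`.
#' @export
tissue_stats <- function(vol, seg, prob_threshold = 0.5) {
  stopifnot(is_volume3d(vol), inherits(seg, "tissue_seg"))
  pick <- function(p, tissue) {
    sel <- p > prob_threshold
    if (!any(sel)) {
      stopf("no %s voxel exceeds probability threshold %.3g", tissue,
            prob_threshold)
    }
    vol$data[sel]
  }
  gm <- pick(seg$prob_gm, "GM")
  wm <- pick(seg$prob_wm, "WM")
  st <- structure(list(mean_gm = mean(gm),
                       sd_gm = if (length(gm) > 1) stats::sd(gm) else 0,
                       mean_wm = mean(wm),
                       sd_wm = if (length(wm) > 1) stats::sd(wm) else 0,
                       n_gm = length(gm), n_wm = length(wm),
                       prob_threshold = prob_threshold),
                  class = "tissue_stats")
  if (st$mean_wm <= st$mean_gm) {
    warnf("mean WM intensity (%.4g) not above mean GM (%.4g): input does not look T1-weighted",
          st$mean_wm, st$mean_gm)
  }
  st
}

#' @export
print.tissue_stats <- function(x, ...) {
  cat(sprintf(
    "<tissue_stats> GM %.4g +/- %.4g (n=%d), WM %.4g +/- %.4g (n=%d)\n",
    x$mean_gm, x$sd_gm, x$n_gm, x$mean_wm, x$sd_wm, x$n_wm))
  invisible(x)
}

#' Otsu threshold brain mask for real volumes
#'
#' Phantoms provide ground-truth brain masks; for real data a quick
#' foreground mask can be obtained by Otsu thresholding of the intensity
#' histogram.
#'
#' @param vol A `volume3d`.
#' @param n_bins Histogram resolution.
#' @return A `binary_mask` of voxels above the Otsu cut.
#' @export
otsu_mask <- function(vol, n_bins = 256) {
  stopifnot(is_volume3d(vol))
  x <- c(vol$data)
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mt <- m1[n_bins]
  between <- (mt * w1 - m1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  cut <- mids[which.max(between)]
  binary_mask(vol$data > cut, vol$spacing, vol$affine, vol$space)
}
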