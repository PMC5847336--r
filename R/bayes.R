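#' Posterior over helix frequency given an observed rescue factor
#'
#' Implements simulation-calibrated inference: calibration samples with the
#' same base-pair count as the probed helix and a simulated rescue factor in
#' the same bin as the observed one (bin width 0.05 by default) are
#' collected, and their simulated helix frequencies form the posterior
#' sample.  The point estimate is the sample median; a boundary-reflected
#' kernel density estimate on \[0, 1\] is attached for plotting and for
#' posterior combination.
#'
#' When the exact (n_bp, bin) cell holds fewer than `min_samples` entries
#' the match is progressively relaxed — first to the adjacent rescue-factor
#' bins, then additionally to adjacent base-pair counts — with each
#' relaxation logged.  Observed factors below (above) every populated bin
#' fall back to the lowest (highest) populated bin with a warning.
#'
#' @param observed a [helix_rescue()] result, or a bare numeric rescue
#'   factor (then `n_bp` is required).
#' @param calib an `m2r_calibration` table from [build_calibration()] or
#'   [make_calibration_fixture()].
#' @param n_bp base-pair count of the probed helix (taken from `observed`
#'   when it is a `helix_rescue`).
#' @param binwidth rescue-factor bin width (default 0.05).
#' @param min_samples minimum matched calibration samples before relaxation
#'   stops (default 20).
#' @param bw_adjust bandwidth multiplier for the attached KDE.
#' @return Object of class `freq_posterior` with fields `samples`,
#'   `median`, `kde`, `n_bp`, `observed_factor`, `relaxations`.
#' @export
posterior_frequency <- function(observed, calib, n_bp = NULL,
                                binwidth = 0.05, min_samples = 20L,
                                bw_adjust = 1) {
  stopifnot(binwidth > 0)
  if (inherits(observed, "helix_rescue")) {
    if (is.null(n_bp)) n_bp <- observed$n_pairs
    if (!is.null(observed$helix)) n_bp <- length(observed$helix$pairs)
    factor_obs <- observed$mean_factor
  } else {
    factor_obs <- as.numeric(observed)
    if (is.null(n_bp)) stop("n_bp is required with a bare rescue factor")
  }
  if (!nrow(calib)) stop("empty calibration table")

  bin_of <- function(f) as.integer(floor(f / binwidth))
  calib_bins <- bin_of(calib$rescue_factor)
  obs_bin <- bin_of(factor_obs)

  # boundary policy: clamp to the populated bin range for this n_bp (+/-1)
  near_nbp <- abs(calib$n_bp - n_bp) <= 1L
  if (!any(near_nbp))
    stop("calibration has no samples with ", n_bp, " +/- 1 base pairs")
  pop_rng <- range(calib_bins[near_nbp])
  clamped <- FALSE
  if (obs_bin < pop_rng[1]) { obs_bin <- pop_rng[1]; clamped <- TRUE }
  if (obs_bin > pop_rng[2]) { obs_bin <- pop_rng[2]; clamped <- TRUE }
  if (clamped)
    warning("observed rescue factor ", signif(factor_obs, 3),
            " outside populated calibration bins; using nearest populated bin",
            call. = FALSE)

  stages <- list(c(bin = 0L, nbp = 0L), c(bin = 1L, nbp = 0L),
                 c(bin = 1L, nbp = 1L), c(bin = 2L, nbp = 1L))
  relaxations <- character()
  samples <- numeric()
  for (s in stages) {
    sel <- abs(calib_bins - obs_bin) <= s[["bin"]] &
      abs(calib$n_bp - n_bp) <= s[["nbp"]]
    samples <- calib$frequency[sel]
    if (length(samples) >= min_samples) break
    relaxations <- c(relaxations,
                     sprintf("bin +/-%d, n_bp +/-%d: %d samples",
                             s[["bin"]], s[["nbp"]], length(samples)))
  }
  if (length(relaxations))
    message("posterior_frequency: relaxed match (",
            paste(relaxations, collapse = "; "), ")")
  if (!length(samples)) {
    # the observed factor fell into a gap between populated bins: snap to
    # the nearest populated bin rather than fail
    sel_nbp <- calib$n_bp == n_bp
    if (!any(sel_nbp)) sel_nbp <- near_nbp
    nearest <- calib_bins[sel_nbp][which.min(abs(calib_bins[sel_nbp] - obs_bin))]
    samples <- calib$frequency[sel_nbp & calib_bins == nearest]
    warning("no calibration samples within the relaxed match for bin ",
            obs_bin, " (factor ", signif(factor_obs, 3), ", ", n_bp,
            " bp); using nearest populated bin ", nearest, call. = FALSE)
  }
  if (!length(samples))
    stop("no calibration samples for rescue-factor bin ", obs_bin,
         " (factor ", signif(factor_obs, 3), ") at ", n_bp,
         " +/- 1 base pairs")
  structure(
    list(samples = samples, median = median(samples),
         kde = kde_reflect(samples, lower = 0, upper = 1,
                           bw_adjust = bw_adjust),
         n_bp = n_bp, observed_factor = factor_obs,
         relaxations = relaxations),
    class = "freq_posterior")
}

#' @export
print.freq_posterior <- function(x, ...) {
  cat(sprintf(
    "<freq_posterior> rescue factor %.3f (%d bp): median F = %.1f%%, %d samples, 95%% CI [%.1f%%, %.1f%%]\n",
    x$observed_factor, x$n_bp, 100 * x$median, length(x$samples),
    100 * quantile(x$samples, 0.025), 100 * quantile(x$samples, 0.975)))
  invisible(x)
}

#' @export
median.freq_posterior <- function(x, na.rm = FALSE, ...) x$median

#' @export
plot.freq_posterior <- function(x, main = "Helix frequency posterior", ...) {
  plot(x$kde$x, x$kde$y, type = "l", xlab = "Helix frequency F",
       ylab = "Posterior density", main = main, ...)
  abline(v = x$median, lty = 2)
  invisible(x)
}

#' Posterior over a helix-helix correlation value
#'
#' The correlation value `g(h1, h2) = F(h1 | h2) / F(h1)` is estimated from
#' two frequency posteriors: the probed helix in the wild-type background
#' (denominator) and in the background locking the other helix (numerator).
#' Posterior samples of `g` are all pairwise ratios locked/wt; when the full
#' cross-product exceeds `max_pairs`, a seeded subsample of pairs is taken.
#' Zero wild-type samples are excluded (logged); all-zero denominators are
#' an error.
#'
#' @param wt `freq_posterior` for the helix in the wild-type background.
#' @param locked `freq_posterior` for the same helix in the lock background.
#' @param max_pairs cap on the ratio cross-product (default 1e6).
#' @param bw_adjust KDE bandwidth multiplier.
#' @param pair_ref optional label, e.g. `"P1-P4B"`.
#' @return Object of class `corr_posterior` with fields `samples`,
#'   `median`, `support_above_1`, `kde`, `pair_ref`.
#' @export
posterior_correlation <- function(wt, locked, max_pairs = 1e6,
                                  bw_adjust = 1, pair_ref = NULL) {
  stopifnot(inherits(wt, "freq_posterior"),
            inherits(locked, "freq_posterior"))
  den <- wt$samples
  num <- locked$samples
  nz <- den > 0
  if (!any(nz)) stop("all wild-type frequency samples are zero; correlation undefined")
  if (!all(nz)) {
    message("posterior_correlation: excluding ", sum(!nz),
            " zero wild-type samples")
    den <- den[nz]
  }
  total <- length(num) * length(den)
  if (total <= max_pairs) {
    g <- as.vector(outer(num, den, `/`))
  } else {
    take <- as.integer(max_pairs)
    idx_n <- sample.int(length(num), take, replace = TRUE)
    idx_d <- sample.int(length(den), take, replace = TRUE)
    g <- num[idx_n] / den[idx_d]
  }
  structure(
    list(samples = g, median = median(g),
         support_above_1 = mean(g > 1),
         kde = kde_reflect(g, lower = 0, upper = Inf,
                           bw_adjust = bw_adjust),
         density = NULL, pair_ref = pair_ref),
    class = "corr_posterior")
}

#' @export
print.corr_posterior <- function(x, ...) {
  nm <- if (is.null(x$pair_ref)) "" else paste0(" ", x$pair_ref)
  cat(sprintf(
    "<corr_posterior>%s: median g = %.3f, P(g > 1) = %.2g, 95%% upper bound %.3f\n",
    nm, x$median, x$support_above_1,
    if (!is.null(x$density)) .grid_quantile(x$density$x, x$density$y, 0.95)
    else quantile(x$samples, 0.95)))
  invisible(x)
}

#' @export
median.corr_posterior <- function(x, na.rm = FALSE, ...) x$median

#' @export
plot.corr_posterior <- function(x, main = "Correlation value posterior", ...) {
  d <- if (!is.null(x$density)) x$density else x$kde
  plot(d$x, d$y, type = "l", xlab = "Correlation value g",
       ylab = "Posterior density", main = main, ...)
  abline(v = 1, lty = 3)
  abline(v = x$median, lty = 2)
  invisible(x)
}

#' Combine two correlation posteriors from flipped experiments
#'
#' Locking helix A and probing helix B estimates the same correlation value
#' as the flipped experiment (lock B, probe A).  Under a flat prior on `g`,
#' the combined posterior is proportional to the product of the two kernel
#' density estimates on a shared grid, renormalized by the trapezoid rule.
#' Samples are redrawn from the combined density by inverse-CDF sampling.
#'
#' @param a,b `corr_posterior` objects for the same helix pair.
#' @param n_grid grid size (default 2048); the grid spans
#'   `[0, max(4, 99.5th percentile of the pooled samples)]`.
#' @param n_samples samples drawn from the combined density.
#' @return A `corr_posterior` whose `density` field holds the combined
#'   gridded density.
#' @export
combine_posteriors <- function(a, b, n_grid = 2048L, n_samples = 10000L) {
  stopifnot(inherits(a, "corr_posterior"), inherits(b, "corr_posterior"))
  if (!is.null(a$pair_ref) && !is.null(b$pair_ref)) {
    norm_ref <- function(r) paste(sort(strsplit(r, "-", fixed = TRUE)[[1]]),
                                  collapse = "-")
    if (norm_ref(a$pair_ref) != norm_ref(b$pair_ref))
      stop("posteriors refer to different helix pairs: ",
           a$pair_ref, " vs ", b$pair_ref)
  }
  hi <- max(4, quantile(c(a$samples, b$samples), 0.995))
  grid <- seq(0, hi, length.out = n_grid)
  da <- approx(a$kde$x, a$kde$y, xout = grid, yleft = 0, yright = 0)$y
  db <- approx(b$kde$x, b$kde$y, xout = grid, yleft = 0, yright = 0)$y
  prod_d <- pmax(da * db, 0)
  area <- .trapz(grid, prod_d)
  # unit-mass densities with genuine overlap give areas of order 0.1-10;
  # anything smaller than 1e-8 is numerically indistinguishable from
  # disjoint supports
  if (!is.finite(area) || area <= 1e-8)
    stop("posterior product vanishes on the shared grid; the two experiments are inconsistent")
  y <- prod_d / area
  samples <- .grid_sample(grid, y, n_samples)
  cdf <- .grid_cdf(grid, y)
  support <- 1 - approx(grid, cdf, xout = 1, rule = 2)$y
  structure(
    list(samples = samples,
         median = .grid_quantile(grid, y, 0.5),
         support_above_1 = support,
         kde = list(x = grid, y = y, bw = NA_real_),
         density = list(x = grid, y = y),
         pair_ref = if (!is.null(a$pair_ref)) a$pair_ref else b$pair_ref),
    class = "corr_posterior")
}

#' Posterior mass above a threshold
#'
#' Fraction of posterior probability strictly above `threshold` — for the
#' default threshold 1, the posterior support for positive correlation
#' (the non-MWC regime).
#'
#' @param post a `corr_posterior` (sample-based or combined).
#' @param threshold non-negative cutoff (default 1).
#' @return numeric in \[0, 1\].
#' @export
posterior_support <- function(post, threshold = 1) {
  stopifnot(inherits(post, "corr_posterior"), threshold >= 0)
  if (!is.null(post$density)) {
    cdf <- .grid_cdf(post$density$x, post$density$y)
    return(1 - approx(post$density$x, cdf, xout = threshold, rule = 2)$y)
  }
  mean(post$samples > threshold)
}
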