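## Gaussian KDE with boundary reflection.
##
## Frequencies live on [0, 1] and correlation values on [0, Inf); a plain
## kernel estimate leaks mass past those boundaries.  Samples are reflected
## about each finite boundary and the density folded back, which preserves
## total mass and removes the boundary bias of the naive estimate.
##
## bw_adjust multiplies the Silverman ("nrd0") bandwidth; used by the
## robustness checks that halve/double the bandwidth.
kde_reflect <- function(samples, lower = 0, upper = Inf, n_grid = 512L,
                        bw_adjust = 1) {
  stopifnot(length(samples) >= 1, all(is.finite(samples)))
  if (length(unique(samples)) == 1L) {
    # degenerate posterior: represent as a narrow spike around the value
    center <- samples[1]
    hw <- max(abs(center) * 1e-3, 1e-3)
    x <- seq(max(lower, center - 4 * hw),
             if (is.finite(upper)) min(upper, center + 4 * hw) else center + 4 * hw,
             length.out = n_grid)
    y <- exp(-0.5 * ((x - center) / hw)^2)
    y <- y / .trapz(x, y)
    return(list(x = x, y = y, bw = hw))
  }
  bw <- stats::bw.nrd0(samples) * bw_adjust
  aug <- samples
  if (is.finite(lower)) aug <- c(aug, 2 * lower - samples)
  if (is.finite(upper)) aug <- c(aug, 2 * upper - samples)
  from <- if (is.finite(lower)) lower else min(samples) - 3 * bw
  to <- if (is.finite(upper)) upper else max(samples) + 3 * bw
  d <- stats::density(aug, bw = bw, from = from, to = to, n = n_grid)
  y <- d$y * length(aug) / length(samples)  # undo dilution by reflected copies
  area <- .trapz(d$x, y)
  list(x = d$x, y = y / area, bw = bw)
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## inverse-CDF draw and quantiles from a gridded density
.grid_cdf <- function(x, y) {
  n <- length(x)
  inc <- c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
  inc / inc[n]
}

.grid_quantile <- function(x, y, p) {
  cdf <- .grid_cdf(x, y)
  stats::approx(cdf, x, xout = p, ties = "ordered", rule = 2)$y
}

.grid_sample <- function(x, y, n, jitter = TRUE) {
  u <- runif(n)
  s <- .grid_quantile(x, y, u)
  s
}
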