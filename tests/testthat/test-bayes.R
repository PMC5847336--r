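make_calib <- function(factors, freqs, n_bp = 4L) {
  out <- data.frame(family = "toy", helix = sprintf("h%d", seq_along(factors)),
                    first_i = 1L, last_j = 20L, n_bp = n_bp,
                    rescue_factor = factors, frequency = freqs)
  class(out) <- c("m2r_calibration", class(out))
  out
}

test_that("degenerate calibrations give degenerate posteriors", {
  cal <- make_calib(runif(50, 0.4, 0.449), rep(0.5, 50))
  post <- posterior_frequency(0.42, cal, n_bp = 4L)
  expect_equal(post$median, 0.5)
  expect_true(all(post$samples == 0.5))
})

test_that("observed factors below every populated bin use the lowest bin", {
  cal <- make_calib(runif(60, 0.4, 0.6), runif(60, 0.3, 0.7))
  expect_warning(post <- posterior_frequency(-0.5, cal, n_bp = 4L),
                 "nearest populated bin")
  expect_true(length(post$samples) > 0)
})

test_that("bin starvation relaxes progressively with a log", {
  cal <- rbind(make_calib(rep(0.42, 5), rep(0.5, 5)),       # starved cell
               make_calib(rep(0.47, 30), rep(0.6, 30)),     # adjacent bin
               make_calib(rep(0.42, 30), rep(0.4, 30), n_bp = 5L))
  expect_message(post <- posterior_frequency(0.42, cal, n_bp = 4L),
                 "relaxed match")
  expect_gte(length(post$samples), 20L)
})

test_that("empty matches after relaxation raise a descriptive error", {
  cal <- make_calib(rep(0.9, 30), rep(0.9, 30), n_bp = 9L)
  expect_error(posterior_frequency(0.9, cal, n_bp = 4L), "base pairs")
})

test_that("posterior median is rank-monotone in the observed factor", {
  set.seed(1)
  # smooth synthetic calibration: frequency rises with rescue factor
  factors <- runif(4000, -0.5, 1)
  freqs <- pmin(pmax(0.1 + 0.8 * pmax(factors, 0) +
                       rnorm(4000, 0, 0.05), 0), 1)
  cal <- make_calib(factors, freqs)
  meds <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(f)
    posterior_frequency(f, cal, n_bp = 4L)$median, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("correlation posteriors are exhaustive ratio sets when small", {
  mk_post <- function(samples) {
    structure(list(samples = samples, median = median(samples),
                   kde = lm2r:::kde_reflect(samples, 0, 1),
                   n_bp = 4L, observed_factor = NA_real_,
                   relaxations = character()),
              class = "freq_posterior")
  }
  wt <- mk_post(rep(0.5, 40))
  locked <- mk_post(rep(0.05, 40))
  post <- posterior_correlation(wt, locked)
  expect_true(all(post$samples == 0.1))
  expect_equal(post$median, 0.1)
  expect_equal(post$support_above_1, 0)

  # self-ratio centres at 1
  self <- mk_post(runif(200, 0.3, 0.7))
  post_self <- posterior_correlation(self, self)
  expect_equal(post_self$median, 1, tolerance = 0.15)

  # printed-median check: F(locked) = 5%, F(wt) = 53% gives g ~ 0.094
  post_tab <- posterior_correlation(mk_post(0.53), mk_post(0.05))
  expect_equal(post_tab$median, 0.05 / 0.53, tolerance = 1e-12)
  expect_equal(post_tab$median, 0.094, tolerance = 1e-2)
})

test_that("zero wild-type samples are excluded or rejected", {
  mk_post <- function(samples) {
    structure(list(samples = samples, median = median(samples),
                   kde = lm2r:::kde_reflect(samples, 0, 1),
                   n_bp = 4L, observed_factor = NA_real_,
                   relaxations = character()),
              class = "freq_posterior")
  }
  expect_error(posterior_correlation(mk_post(rep(0, 10)), mk_post(0.5)),
               "undefined")
  expect_message(post <- posterior_correlation(mk_post(c(0, rep(0.5, 9))),
                                               mk_post(rep(0.25, 10))),
                 "excluding")
  expect_equal(post$median, 0.5)
})

test_that("combination multiplies densities under a flat prior", {
  set.seed(2)
  mk_corr <- function(samples) {
    structure(list(samples = samples, median = median(samples),
                   support_above_1 = mean(samples > 1),
                   kde = lm2r:::kde_reflect(samples, 0, Inf),
                   density = NULL, pair_ref = "H1-H2"),
              class = "corr_posterior")
  }
  # uniform(0, 2) x uniform(0, 2) stays uniform: support above 1 is 0.5
  u1 <- mk_corr(runif(20000, 0, 2))
  u2 <- mk_corr(runif(20000, 0, 2))
  comb <- combine_posteriors(u1, u2)
  expect_equal(comb$support_above_1, 0.5, tolerance = 0.06)

  # self-combination keeps the median and sharpens the spread
  g <- rnorm(5000, 1.2, 0.15)
  a <- mk_corr(g)
  self_comb <- combine_posteriors(a, a)
  expect_equal(self_comb$median, a$median, tolerance = 0.05)
  expect_lt(stats::sd(self_comb$samples), stats::sd(a$samples))

  # a sharp posterior dominates a broad one
  sharp <- mk_corr(rnorm(4000, 0.1, 0.01))
  broad <- mk_corr(abs(rnorm(4000, 0.3, 0.15)))
  dom <- combine_posteriors(sharp, broad)
  expect_gt(dom$median, 0.09)
  expect_lt(dom$median, 0.2)

  # commutative on the shared grid
  ab <- combine_posteriors(u1, u2)
  ba <- combine_posteriors(u2, u1)
  expect_equal(ab$density$y, ba$density$y, tolerance = 1e-12)
  expect_equal(ab$median, ba$median, tolerance = 1e-9)

  # mismatched helix pairs are rejected
  b2 <- mk_corr(runif(100, 0, 2)); b2$pair_ref <- "H1-H3"
  expect_error(combine_posteriors(u1, b2), "different helix pairs")
})

test_that("disjoint posteriors cannot be combined", {
  mk_corr <- function(samples) {
    structure(list(samples = samples, median = median(samples),
                   support_above_1 = mean(samples > 1),
                   kde = lm2r:::kde_reflect(samples, 0, Inf),
                   density = NULL, pair_ref = NULL),
              class = "corr_posterior")
  }
  lo <- mk_corr(rnorm(2000, 0.05, 0.002))
  hi <- mk_corr(rnorm(2000, 3.5, 0.002))
  expect_error(combine_posteriors(lo, hi), "inconsistent")
})

test_that("posterior support integrates the mass above a threshold", {
  set.seed(3)
  mk_corr <- function(samples) {
    structure(list(samples = samples, median = median(samples),
                   support_above_1 = mean(samples > 1),
                   kde = lm2r:::kde_reflect(samples, 0, Inf),
                   density = NULL, pair_ref = NULL),
              class = "corr_posterior")
  }
  u <- mk_corr(runif(20000, 0, 2))
  expect_equal(posterior_support(u, 1), 0.5, tolerance = 0.02)
  expect_equal(posterior_support(u, 0), 1)
  below <- mk_corr(runif(500, 0.1, 0.6))
  expect_equal(posterior_support(below, 1), 0)
  expect_equal(posterior_support(mk_corr(runif(500, 1.5, 2)), 1), 1)
})

test_that("posterior summaries survive an end-to-end fixture recovery", {
  cal <- make_calibration_fixture(120, seed = 8)
  ens <- exclusive_ensemble(0.8, n_bp = 4L, seed = 40)
  bis <- lm2r:::.bistable_construct(4L, 40L)
  quartets <- lapply(seq_len(4), function(r)
    make_quartet_fixture(ens, base_pair(bis$helixA[r, 1], bis$helixA[r, 2])))
  hr <- helix_rescue(quartets)
  post <- suppressWarnings(suppressMessages(
    posterior_frequency(hr$mean_factor, cal, n_bp = 4L)))
  expect_gt(post$median, 0.65)
  expect_lt(post$median, 0.95)
})
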