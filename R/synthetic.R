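#' Parse a dot-bracket secondary structure
#'
#' @param db dot-bracket string using `()` (and optionally `[]`, `{}`).
#' @return 2-column integer matrix of (i, j) pairs (i < j), zero rows for
#'   an open chain.
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  stacks <- list("(" = integer(), "[" = integer(), "{" = integer())
  pairs <- matrix(integer(), ncol = 2)
  for (k in seq_along(ch)) {
    c_k <- ch[k]
    if (c_k %in% names(openers)) {
      stacks[[c_k]] <- c(stacks[[c_k]], k)
    } else if (c_k %in% openers) {
      op <- names(openers)[match(c_k, openers)]
      s <- stacks[[op]]
      if (!length(s)) stop("unbalanced bracket at position ", k)
      pairs <- rbind(pairs, c(s[length(s)], k))
      stacks[[op]] <- s[-length(s)]
    } else if (c_k != ".") {
      stop("unexpected character '", c_k, "' in dot-bracket string")
    }
  }
  if (any(lengths(stacks) > 0)) stop("unbalanced bracket: unclosed opener")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Ground-truth toy ensemble of discrete secondary structures
#'
#' A toy ensemble emulates the structural heterogeneity probed by
#' mutate-map-rescue: a construct populates a small set of discrete
#' secondary structures with stated mixture weights, and its idealized
#' chemical reactivity is the weighted probability of being unpaired plus
#' additive Gaussian noise.
#'
#' @param construct an [rna_construct()].
#' @param structures character vector of dot-bracket strings, one per
#'   ensemble member, each as long as the construct sequence.
#' @param weights mixture probabilities (non-negative, summing to 1).
#' @param noise_sd additive Gaussian noise on simulated reactivities, in
#'   normalized reactivity units (default 0.1, a typical normalized SHAPE
#'   error).
#' @param seed integer seed making all profiles drawn from the ensemble
#'   deterministic.
#' @return Object of class `toy_ensemble`.
#' @export
toy_ensemble <- function(construct, structures, weights, noise_sd = 0.1,
                         seed = 1L) {
  stopifnot(inherits(construct, "rna_construct"))
  n <- nchar(construct$sequence)
  if (!length(structures)) stop("need at least one structure")
  if (any(nchar(structures) != n))
    stop("structures must match the sequence length (", n, ")")
  weights <- as.numeric(weights)
  if (length(weights) != length(structures))
    stop("one weight per structure required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  pair_tables <- lapply(structures, parse_dot_bracket)
  ch <- strsplit(construct$sequence, "")[[1]]
  for (pt in pair_tables) {
    if (nrow(pt) == 0) next
    bad <- !.is_pairable(ch[pt[, 1]], ch[pt[, 2]])
    if (any(bad))
      stop("structure pairs non-pairable bases at ",
           paste(pt[bad, 1], pt[bad, 2], sep = "-", collapse = ", "))
  }
  structure(
    list(construct = construct, structures = structures, weights = weights,
         pair_tables = pair_tables, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "toy_ensemble")
}

#' @export
print.toy_ensemble <- function(x, ...) {
  cat(sprintf("<toy_ensemble> %s: %d structures, weights %s, noise sd %.2g\n",
              x$construct$name, length(x$structures),
              paste(signif(x$weights, 3), collapse = "/"), x$noise_sd))
  invisible(x)
}

## per-position unpaired indicator of structure k (biological positions)
.unpaired_indicator <- function(ensemble, k) {
  n <- nchar(ensemble$construct$sequence)
  u <- rep(1, n)
  pt <- ensemble$pair_tables[[k]]
  if (nrow(pt)) u[c(pt[, 1], pt[, 2])] <- 0
  u
}

#' Idealized reactivity profile of a toy ensemble
#'
#' Per-position reactivity is the weighted fraction of structures in which
#' the position is unpaired, plus Gaussian noise of scale `noise_sd`,
#' clipped at 0.  Noise is seeded from the ensemble seed plus
#' `noise_stream`, so distinct profiles from one ensemble get independent
#' but reproducible noise.
#'
#' @param ensemble a [toy_ensemble()].
#' @param mutant_label label recorded on the profile.
#' @param noise_stream integer sub-stream selector (default 0).
#' @return a [reactivity_profile()] over the construct's positions.
#' @export
ensemble_profile <- function(ensemble, mutant_label = "WT",
                             noise_stream = 0L) {
  w <- ensemble$weights
  u <- vapply(seq_along(w), function(k) .unpaired_indicator(ensemble, k),
              numeric(nchar(ensemble$construct$sequence)))
  v <- as.vector(u %*% w)
  if (ensemble$noise_sd > 0) {
    v <- v + .seeded_noise(ensemble$seed + 1000L * noise_stream, length(v),
                           ensemble$noise_sd)
  }
  v <- pmax(v, 0)
  reactivity_profile(values = v,
                     positions = construct_positions(ensemble$construct),
                     construct_ref = ensemble$construct$name,
                     mutant_label = mutant_label, modifier = "synthetic")
}

## draw reproducible noise without disturbing the caller's RNG stream
.seeded_noise <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  rnorm(n, 0, sd)
}

## does structure k contain the pair?
.structure_has_pair <- function(ensemble, k, pair) {
  pt <- ensemble$pair_tables[[k]]
  nrow(pt) > 0 && any(pt[, 1] == pair$i & pt[, 2] == pair$j)
}

#' Build a ground-truth quartet fixture from a toy ensemble
#'
#' Emulates the ensemble response to the four variants of a
#' mutate-map-rescue experiment on one base pair:
#'
#' * wild type — the ensemble as given;
#' * single mutants — structures containing the probed pair lose their
#'   weight to an alternative (the next-highest-weight structure without
#'   the pair under `response_model = "next_best"`, or uniformly over all
#'   such structures under `"uniform"`; the fully open chain serves as the
#'   alternative when none exists);
#' * double mutant — the pair-containing structures regain their original
#'   weight, while a fraction `rearranged_fraction` of each remaining
#'   structure's weight moves to the open chain, emulating the rearranged
#'   ensemble members that make compensatory rescue only partial.
#'
#' The probed pair's true helix frequency (total weight of pair-containing
#' structures) is recorded on the returned quartet.
#'
#' @param ensemble a [toy_ensemble()]; must contain the pair in at least
#'   one structure.
#' @param pair a [base_pair()] (biological positions).
#' @param response_model `"next_best"` or `"uniform"`.
#' @param rearranged_fraction weight fraction of non-pair structures that
#'   rearranges in the double mutant (default 0.5).
#' @return an [quartet()] with attribute `"true_frequency"`.
#' @export
make_quartet_fixture <- function(ensemble, pair,
                                 response_model = c("next_best", "uniform"),
                                 rearranged_fraction = 0.5) {
  response_model <- match.arg(response_model)
  has_pair <- vapply(seq_along(ensemble$weights), function(k)
    .structure_has_pair(ensemble, k, pair), logical(1))
  if (!any(has_pair))
    stop(sprintf("pair (%d, %d) absent from all ensemble structures",
                 pair$i, pair$j))
  w <- ensemble$weights
  true_freq <- sum(w[has_pair])
  n <- nchar(ensemble$construct$sequence)
  open_db <- strrep(".", n)

  with_open <- function(weights, extra) {
    # append the open chain as an explicit ensemble member
    toy_ensemble(ensemble$construct,
                 c(ensemble$structures, open_db),
                 c(weights, extra),
                 noise_sd = ensemble$noise_sd, seed = ensemble$seed)
  }

  # single mutants: pair-containing weight moves to alternatives
  w_single <- w
  moved <- sum(w_single[has_pair])
  w_single[has_pair] <- 0
  open_w <- 0
  if (moved > 0) {
    alt <- which(!has_pair)
    if (!length(alt)) {
      open_w <- moved
    } else if (response_model == "next_best") {
      best <- alt[which.max(w[alt])]
      w_single[best] <- w_single[best] + moved
    } else {
      w_single[alt] <- w_single[alt] + moved / length(alt)
    }
  }
  e_single <- with_open(w_single, open_w)

  # double mutant: pair restored, other structures partially rearranged
  w_double <- w
  w_double[!has_pair] <- w[!has_pair] * (1 - rearranged_fraction)
  open_double <- sum(w[!has_pair]) * rearranged_fraction
  e_double <- with_open(w_double, open_double)

  q <- quartet(
    wt = ensemble_profile(ensemble, "WT", noise_stream = 0L),
    mutA = ensemble_profile(e_single, "mutA", noise_stream = 1L),
    mutB = ensemble_profile(e_single, "mutB", noise_stream = 2L),
    mutAB = ensemble_profile(e_double, "mutAB", noise_stream = 3L),
    pair = pair)
  attr(q, "true_frequency") <- true_freq
  q
}

## Deterministic toy construct holding two mutually exclusive helices of
## length n_bp: 5' arm pairs either with a central arm (registered helix,
## the probed one) or the central arm pairs with a 3' arm (alternative).
.bistable_construct <- function(n_bp, seed) {
  set <- c("A", "C", "G", "U")
  stem <- set[1 + (.lcg_stream(seed, n_bp) %% 4)]
  rc <- rev(vapply(stem, function(b) .wc_complement[[b]], character(1)))
  loop1 <- c("G", "A", "G", "U")
  # stem . rc . stem: the central rc arm can pair with either flank, giving
  # two mutually exclusive helices of equal length
  seq_ch <- c(stem, loop1, rc, loop1, stem)
  sequence <- paste(seq_ch, collapse = "")
  L <- n_bp; o1 <- L + 4L
  helixA <- cbind(seq_len(L), (o1 + L):(o1 + 1L))              # stem : rc
  helixB <- cbind((o1 + 1L):(o1 + L), (2L * o1 + L):(2L * o1 + 1L))  # rc : stem'
  db <- function(pairs) {
    ch <- rep(".", nchar(sequence))
    ch[pairs[, 1]] <- "("; ch[pairs[, 2]] <- ")"
    paste(ch, collapse = "")
  }
  construct <- rna_construct(sprintf("bistable%d_%d", n_bp, seed), sequence)
  list(construct = construct,
       helixA = helixA, helixB = helixB,
       dbA = db(helixA), dbB = db(helixB))
}

## small deterministic integer stream (keeps fixtures independent of R's RNG)
.lcg_stream <- function(seed, n) {
  x <- integer(n)
  state <- (as.numeric(seed) %% 2147483647) + 1
  for (k in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    x[k] <- as.integer(state %% 65536)
  }
  x
}

#' Generate a toy calibration table with known ground truth
#'
#' Builds `n_helices` deterministic two-structure toy ensembles whose
#' probed helix frequencies span 0.05 to 0.95, runs the synthetic
#' mutate-map-rescue quartet for every pair of each probed helix, and
#' packages the results as a calibration table.  The true frequencies are
#' retained in the `frequency` column, so recovery tests can hold out
#' fixtures and check that posteriors centre on the truth.
#'
#' Each ensemble holds two mutually exclusive helices (shared central
#' strand) with weights `f` and `1 - f`; helix lengths cycle through
#' `n_bp_range`.
#'
#' @param n_helices number of calibration helices (>= 1).
#' @param seed integer seed; the full table is bit-reproducible given
#'   `(n_helices, seed, noise_sd)`.
#' @param noise_sd reactivity noise passed to the toy ensembles
#'   (default 0.1).
#' @param n_bp_range integer vector of helix lengths to cycle through.
#' @return `m2r_calibration` data.frame (columns as in
#'   [build_calibration()]), with the ground-truth map in
#'   `attr(, "truth")`.
#' @export
make_calibration_fixture <- function(n_helices, seed = 1L, noise_sd = 0.1,
                                     n_bp_range = 3:6) {
  stopifnot(n_helices >= 1)
  freqs <- seq(0.05, 0.95, length.out = max(n_helices, 2L))[seq_len(n_helices)]
  rows <- vector("list", n_helices)
  for (k in seq_len(n_helices)) {
    n_bp <- n_bp_range[1L + (k - 1L) %% length(n_bp_range)]
    bis <- .bistable_construct(n_bp, seed + 7L * k)
    f <- freqs[k]
    ens <- toy_ensemble(bis$construct, c(bis$dbA, bis$dbB), c(f, 1 - f),
                        noise_sd = noise_sd, seed = seed + 1000L + k)
    factors <- vapply(seq_len(n_bp), function(r) {
      pr <- base_pair(bis$helixA[r, 1], bis$helixA[r, 2])
      q <- make_quartet_fixture(ens, pr)
      tryCatch(rescue_factor(q), lm2r_uninformative = function(e) NA_real_)
    }, numeric(1))
    kept <- factors[!is.na(factors)]
    rows[[k]] <- data.frame(
      family = bis$construct$name,
      helix = sprintf("fixture%03d", k),
      first_i = bis$helixA[1, 1], last_j = bis$helixA[1, 2],
      n_bp = n_bp,
      rescue_factor = if (length(kept)) mean(kept) else NA_real_,
      frequency = f)
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$rescue_factor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- setNames(out$frequency, out$helix)
  attr(out, "provenance") <- list(backend = "toy_ensemble", seed = seed,
                                  noise_sd = noise_sd)
  class(out) <- c("m2r_calibration", class(out))
  out
}

#' Deterministic random RNA sequences
#'
#' Seed-stable generator of uniform-composition RNA sequences for in-silico
#' calibration runs and tests.
#'
#' @param n number of sequences.
#' @param length_range integer vector `c(min, max)` of sequence lengths.
#' @param seed integer seed (does not disturb the caller's RNG stream).
#' @return Named character vector (`seq001`, `seq002`, ...).
#' @export
random_rna_sequences <- function(n, length_range = c(60L, 90L), seed = 1L) {
  stopifnot(n >= 1, length(length_range) == 2L)
  bases <- c("A", "C", "G", "U")
  out <- character(n)
  for (k in seq_len(n)) {
    stream <- .lcg_stream(seed + 131L * k, max(length_range) + 1L)
    len <- length_range[1] + stream[1] %% (length_range[2] - length_range[1] + 1L)
    out[k] <- paste(bases[1 + stream[1 + seq_len(len)] %% 4], collapse = "")
  }
  names(out) <- sprintf("seq%03d", seq_len(n))
  out
}

#' Condition a toy ensemble on a locked helix
#'
#' Emulates a lock mutant: ensemble members containing every pair of the
#' locked helix keep their (renormalized) weight, scaled by `1 - leak`;
#' the remaining members share the residual `leak` mass in proportion to
#' their original weights.  A small nonzero leak reflects that designed
#' lock mutations stabilize, but do not absolutely fix, the target helix.
#'
#' @param ensemble a [toy_ensemble()].
#' @param pairs 2-column matrix of (i, j) positions of the locked helix,
#'   or an [rna_helix()].
#' @param leak residual weight of non-locked structures (default 0.05).
#' @return A [toy_ensemble()] with the conditional weights.
#' @export
lock_ensemble <- function(ensemble, pairs, leak = 0.05) {
  if (inherits(pairs, "rna_helix"))
    pairs <- cbind(vapply(pairs$pairs, `[[`, integer(1), "i"),
                   vapply(pairs$pairs, `[[`, integer(1), "j"))
  stopifnot(is.matrix(pairs), ncol(pairs) == 2, leak >= 0, leak < 1)
  has_all <- vapply(seq_along(ensemble$weights), function(k) {
    pt <- ensemble$pair_tables[[k]]
    if (!nrow(pt)) return(FALSE)
    all(vapply(seq_len(nrow(pairs)), function(r)
      any(pt[, 1] == pairs[r, 1] & pt[, 2] == pairs[r, 2]), logical(1)))
  }, logical(1))
  if (!any(has_all))
    stop("no ensemble structure contains the full locked helix")
  w <- ensemble$weights
  w_in <- sum(w[has_all]); w_out <- sum(w[!has_all])
  new_w <- numeric(length(w))
  new_w[has_all] <- w[has_all] / w_in * (1 - if (w_out > 0) leak else 0)
  if (w_out > 0) new_w[!has_all] <- w[!has_all] / w_out * leak
  toy_ensemble(ensemble$construct, ensemble$structures, new_w,
               noise_sd = ensemble$noise_sd, seed = ensemble$seed + 1L)
}

#' Probe a toy-ensemble helix end to end
#'
#' Runs the full synthetic mutate-map-rescue chain for one helix of a toy
#' ensemble: one quartet fixture per base pair, helix-level rescue-factor
#' aggregation, and the simulation-calibrated frequency posterior.
#'
#' @param ensemble a [toy_ensemble()].
#' @param pairs 2-column matrix of (i, j) positions, or an [rna_helix()].
#' @param calib calibration table for [posterior_frequency()].
#' @param bw_adjust KDE bandwidth multiplier passed through.
#' @param ... further arguments to [posterior_frequency()].
#' @return a `freq_posterior`, with the helix-level rescue result in
#'   attribute `"rescue"`.
#' @export
probe_ensemble_helix <- function(ensemble, pairs, calib, bw_adjust = 1, ...) {
  if (inherits(pairs, "rna_helix"))
    pairs <- cbind(vapply(pairs$pairs, `[[`, integer(1), "i"),
                   vapply(pairs$pairs, `[[`, integer(1), "j"))
  quartets <- lapply(seq_len(nrow(pairs)), function(r)
    make_quartet_fixture(ensemble, base_pair(pairs[r, 1], pairs[r, 2])))
  hr <- helix_rescue(quartets)
  post <- posterior_frequency(hr$mean_factor, calib, n_bp = nrow(pairs),
                              bw_adjust = bw_adjust, ...)
  attr(post, "rescue") <- hr
  post
}
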