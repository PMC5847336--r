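#' Root-mean-square difference between two reactivity profiles
#'
#' `RMSD(A, B) = sqrt(mean((dA(i) - dB(i))^2))` over a set of compared
#' positions.  Symmetric, non-negative, and zero iff the profiles agree on
#' every compared position.
#'
#' @param a,b [reactivity_profile()]s (or bare numeric vectors over the same
#'   implicit positions).
#' @param positions biological positions to compare; defaults to the
#'   positions shared by both profiles.  Must be non-empty and covered by
#'   both profiles.
#' @return numeric scalar.
#' @export
profile_rmsd <- function(a, b, positions = NULL) {
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) != length(b)) stop("numeric profiles differ in length")
    va <- a; vb <- b
    if (!is.null(positions)) { va <- a[positions]; vb <- b[positions] }
  } else {
    if (is.null(positions))
      positions <- intersect(a$positions, b$positions)
    if (length(positions) == 0L) stop("empty comparison position set")
    va <- profile_values_at(a, positions)
    vb <- profile_values_at(b, positions)
  }
  if (!length(va)) stop("empty comparison position set")
  sqrt(mean((va - vb)^2))
}

#' Quartet of profiles interrogating one base pair
#'
#' Bundles the four reactivity profiles of a mutate-map-rescue experiment —
#' wild type, the two single mutants, and the compensatory double mutant —
#' with the base pair they probe and the positions used for comparison.
#'
#' @param wt,mutA,mutB,mutAB [reactivity_profile()]s sharing positions.
#' @param pair the probed [base_pair()] (optional for synthetic data).
#' @param comparison_positions positions used for RMSD; defaults to the
#'   positions shared by all four profiles.
#' @param exclude_mutated drop a +/-1 window around the probed pair's
#'   positions from the comparison set.
#' @return Object of class `m2r_quartet`.
#' @export
quartet <- function(wt, mutA, mutB, mutAB, pair = NULL,
                    comparison_positions = NULL, exclude_mutated = FALSE) {
  profs <- list(wt = wt, mutA = mutA, mutB = mutB, mutAB = mutAB)
  ok <- vapply(profs, inherits, logical(1), "reactivity_profile")
  if (!all(ok)) stop("all four quartet members must be reactivity profiles")
  shared <- Reduce(intersect, lapply(profs, `[[`, "positions"))
  if (is.null(comparison_positions)) {
    comparison_positions <- shared
  } else if (!all(comparison_positions %in% shared)) {
    stop("comparison_positions not covered by all four profiles")
  }
  if (exclude_mutated) {
    if (is.null(pair)) stop("exclude_mutated requires the probed pair")
    drop <- c(pair$i + -1:1, pair$j + -1:1)
    comparison_positions <- setdiff(comparison_positions, drop)
  }
  if (!length(comparison_positions)) stop("empty comparison position set")
  structure(
    list(wt = wt, mutA = mutA, mutB = mutB, mutAB = mutAB, pair = pair,
         comparison_positions = sort(as.integer(comparison_positions))),
    class = "m2r_quartet")
}

#' @export
print.m2r_quartet <- function(x, ...) {
  pr <- if (is.null(x$pair)) "?" else sprintf("(%d,%d)", x$pair$i, x$pair$j)
  f <- tryCatch(rescue_factor(x), error = function(e) NA_real_)
  cat(sprintf("<m2r_quartet> pair %s, %d compared positions, rescue factor %s\n",
              pr, length(x$comparison_positions),
              if (is.na(f)) "undefined" else sprintf("%.3f", f)))
  invisible(x)
}

#' Rescue factor of a quartet
#'
#' `1 - RMSD(WT, AB) / max(RMSD(WT, A), RMSD(WT, B))`.  Equals 1 when the
#' double mutant restores the wild-type profile exactly, 0 when it is as
#' disrupted as the worse single mutant, and may be negative when the
#' double mutant is more disrupted still (anti-rescue); the value is
#' returned unclipped.
#'
#' @param q an [quartet()] object.
#' @return numeric scalar `<= 1`.  Errors with condition class
#'   `lm2r_uninformative` when both single mutants match the wild type on
#'   the compared positions (denominator zero).
#' @export
rescue_factor <- function(q) {
  stopifnot(inherits(q, "m2r_quartet"))
  pos <- q$comparison_positions
  rA <- profile_rmsd(q$wt, q$mutA, pos)
  rB <- profile_rmsd(q$wt, q$mutB, pos)
  denom <- max(rA, rB)
  if (denom == 0)
    stop(structure(
      class = c("lm2r_uninformative", "error", "condition"),
      list(message = "uninformative quartet: both single mutants match wild type on compared positions",
           call = sys.call(-1))))
  1 - profile_rmsd(q$wt, q$mutAB, pos) / denom
}

#' Aggregate per-pair rescue factors over a helix
#'
#' Computes the rescue factor of each quartet and their arithmetic mean;
#' quartets flagged uninformative (denominator zero) are skipped with a
#' warning and do not enter the mean.
#'
#' @param quartets list of [quartet()]s, one per tested base pair.
#' @param helix optional [rna_helix()] the quartets interrogate.
#' @return Object of class `helix_rescue` with fields `helix`,
#'   `per_pair_factors`, `mean_factor`, `n_pairs`.
#' @export
helix_rescue <- function(quartets, helix = NULL) {
  if (inherits(quartets, "m2r_quartet")) quartets <- list(quartets)
  if (!length(quartets)) stop("helix_rescue needs at least one quartet")
  factors <- rep(NA_real_, length(quartets))
  for (k in seq_along(quartets)) {
    factors[k] <- tryCatch(rescue_factor(quartets[[k]]),
                           lm2r_uninformative = function(e) {
                             warning("skipping uninformative quartet ", k,
                                     call. = FALSE)
                             NA_real_
                           })
  }
  names(factors) <- vapply(quartets, function(q)
    if (is.null(q$pair)) NA_character_ else sprintf("%d-%d", q$pair$i, q$pair$j),
    character(1))
  kept <- factors[!is.na(factors)]
  if (!length(kept)) stop("all quartets were uninformative")
  structure(
    list(helix = helix, per_pair_factors = factors,
         mean_factor = mean(kept), n_pairs = length(kept)),
    class = "helix_rescue")
}

#' @export
print.helix_rescue <- function(x, ...) {
  nm <- if (is.null(x$helix)) "helix" else x$helix$name
  cat(sprintf("<helix_rescue> %s: mean rescue factor %.3f over %d pair(s)\n",
              nm, x$mean_factor, x$n_pairs))
  print(round(x$per_pair_factors, 3))
  invisible(x)
}

#' Classify a rescue factor into no / partial / full rescue
#'
#' @param factor numeric rescue factor(s).
#' @param thresholds length-2 numeric `c(t_low, t_high)` with
#'   `0 < t_low < t_high < 1`; factors below `t_low` are "no" rescue, at or
#'   above `t_high` "full", otherwise "partial".
#' @return factor with levels `no`, `partial`, `full`.
#' @export
classify_rescue <- function(factor, thresholds = c(0.2, 0.7)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] > 0,
            thresholds[1] < thresholds[2], thresholds[2] < 1)
  out <- ifelse(factor < thresholds[1], "no",
                ifelse(factor >= thresholds[2], "full", "partial"))
  base::factor(out, levels = c("no", "partial", "full"))
}
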