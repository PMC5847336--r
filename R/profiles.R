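#' Per-nucleotide reactivity profile
#'
#' Holds normalized chemical-mapping reactivities (dimensionless) over a set
#' of biological positions, with optional per-position uncertainties.
#'
#' @param values numeric vector of finite reactivities.
#' @param positions integer vector of biological positions, same length as
#'   `values`, strictly increasing.
#' @param construct_ref identifier of the probed construct.
#' @param mutant_label mutant label (`"WT"` for wild type).
#' @param modifier probe chemistry label (e.g. `"1M7"`, `"DMS"`, `"nomod"`).
#' @param errors optional numeric vector of per-position uncertainties.
#' @return Object of class `reactivity_profile`.
#' @export
reactivity_profile <- function(values, positions,
                               construct_ref = NA_character_,
                               mutant_label = "WT", modifier = "1M7",
                               errors = NULL) {
  values <- as.numeric(values)
  positions <- as.integer(positions)
  if (length(values) != length(positions))
    stop("values and positions must have equal length")
  if (!all(is.finite(values))) stop("reactivities must be finite")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!is.null(errors)) {
    errors <- as.numeric(errors)
    if (length(errors) != length(values))
      stop("errors must match values in length")
  }
  structure(
    list(values = values, positions = positions,
         construct_ref = construct_ref, mutant_label = mutant_label,
         modifier = modifier, errors = errors),
    class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("<reactivity_profile> %s %s [%s]: %d positions (%d..%d), mean %.3f\n",
              x$construct_ref, x$mutant_label, x$modifier,
              length(x$values), min(x$positions), max(x$positions),
              mean(x$values)))
  invisible(x)
}

#' @export
length.reactivity_profile <- function(x) length(x$values)

## values at given biological positions; errors if any position is missing
profile_values_at <- function(profile, positions) {
  idx <- match(positions, profile$positions)
  if (anyNA(idx))
    stop("profile ", profile$mutant_label, " lacks position(s) ",
         paste(positions[is.na(idx)], collapse = ", "))
  profile$values[idx]
}

## replace values, keep metadata
profile_with_values <- function(profile, values) {
  profile$values <- as.numeric(values)
  profile
}

#' Normalize a profile against its GAGUA reference loops
#'
#' Rescales all reactivities by a single factor so that the mean reactivity
#' over the construct's reference-loop positions equals 1.  Chemistries that
#' react with only part of the GAGUA loop can restrict the anchor with a
#' per-modifier position mask.
#'
#' @param profile a [reactivity_profile()] covering the reference loops.
#' @param construct an [rna_construct()] with `reference_loops` set.
#' @param loop_mask optional integer vector of biological positions; when
#'   given, only reference-loop positions in the mask anchor the scale.
#' @return Rescaled `reactivity_profile` (errors scaled by the same factor).
#' @export
normalize_profile <- function(profile, construct, loop_mask = NULL) {
  loops <- .reference_loop_positions(construct)
  anchor <- c(loops$five_prime, loops$three_prime)
  if (!is.null(loop_mask)) anchor <- intersect(anchor, loop_mask)
  if (length(anchor) == 0L) stop("empty reference-loop anchor set")
  m <- mean(profile_values_at(profile, anchor))
  if (!is.finite(m) || m <= 0)
    stop("reference-loop mean is ", signif(m, 3),
         "; cannot normalize (must be positive)")
  out <- profile_with_values(profile, profile$values / m)
  if (!is.null(out$errors)) out$errors <- out$errors / m
  out
}

.reference_loop_positions <- function(construct) {
  if (is.null(construct$reference_loops))
    stop("construct ", construct$name, " has no reference loops annotated")
  construct$reference_loops
}

#' Correct 5' to 3' signal attenuation
#'
#' Reverse-transcription read-out attenuates signal from the 5' towards the
#' 3' end.  The attenuation ratio is estimated as the 5' reference-loop mean
#' over the 3' reference-loop mean; the correction then multiplies each
#' position by a per-position geometric factor `r^x`, where `x` runs
#' linearly from 0 at the first profiled position to 1 at the last.  The
#' first position is unchanged, the last is scaled by the full ratio, and
#' the corrected 3' loop mean matches the 5' loop mean up to the within-loop
#' variation of the factor.
#'
#' @param profile a [reactivity_profile()] covering both reference loops.
#' @param construct an [rna_construct()] with `reference_loops` set.
#' @return Corrected `reactivity_profile`, with the estimated ratio in
#'   attribute `"attenuation_ratio"`.
#' @export
correct_attenuation <- function(profile, construct) {
  loops <- .reference_loop_positions(construct)
  v5 <- profile_values_at(profile, loops$five_prime)
  v3 <- profile_values_at(profile, loops$three_prime)
  m5 <- mean(v5); m3 <- mean(v3)
  if (!is.finite(m5) || !is.finite(m3) || m5 <= 0 || m3 <= 0)
    stop("reference-loop means must be positive to estimate attenuation")
  r <- m5 / m3
  lo <- min(profile$positions); hi <- max(profile$positions)
  f <- r ^ ((profile$positions - lo) / (hi - lo))
  out <- profile_with_values(profile, profile$values * f)
  if (!is.null(out$errors)) out$errors <- out$errors * f
  attr(out, "attenuation_ratio") <- r
  out
}

#' Subtract a no-modification background profile
#'
#' Per-position difference between a signal and its no-modification control,
#' floored at zero (reactivities are physically non-negative).
#'
#' @param signal,nomod [reactivity_profile()]s over identical positions.
#' @return Background-subtracted `reactivity_profile`.
#' @export
subtract_background <- function(signal, nomod) {
  if (length(signal$positions) != length(nomod$positions) ||
      !all(signal$positions == nomod$positions))
    stop("signal and background profiles are not position-aligned")
  out <- profile_with_values(signal, pmax(signal$values - nomod$values, 0))
  if (!is.null(signal$errors) && !is.null(nomod$errors))
    out$errors <- sqrt(signal$errors^2 + nomod$errors^2)
  out
}

#' Restrict a profile to a set of positions
#'
#' @param profile a [reactivity_profile()].
#' @param positions biological positions to keep (must all be present).
#' @return Restricted `reactivity_profile`.
#' @export
restrict_profile <- function(profile, positions) {
  positions <- sort(as.integer(positions))
  idx <- match(positions, profile$positions)
  if (anyNA(idx))
    stop("profile lacks position(s) ",
         paste(positions[is.na(idx)], collapse = ", "))
  out <- profile
  out$positions <- positions
  out$values <- profile$values[idx]
  if (!is.null(profile$errors)) out$errors <- profile$errors[idx]
  out
}

#' Export profiles as TSV
#'
#' Long-format table with one row per (profile, position): columns
#' `construct`, `mutant`, `modifier`, `position`, `value`, `error`.
#'
#' @param profiles a [reactivity_profile()], a list of them, or an
#'   [rdat()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  if (inherits(profiles, "rdat")) profiles <- profiles$profiles
  if (inherits(profiles, "reactivity_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(construct = p$construct_ref, mutant = p$mutant_label,
               modifier = p$modifier, position = p$positions,
               value = p$values,
               error = if (is.null(p$errors)) NA_real_ else p$errors))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
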