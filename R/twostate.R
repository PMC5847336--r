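#' Two-state linear decomposition of a reactivity profile
#'
#' Fits `target ~ f * stateA + (1 - f) * stateB` by least squares, with the
#' mixture fraction `f` clamped to \[0, 1\].  Used to validate helix-lock
#' mutants: a candidate intermediate profile (e.g. the ligand-free wild
#' type) should decompose into the two locked-state endpoint profiles with a
#' small residual.  Multi-modifier fits pass lists of per-modifier profiles
#' (normalized per modifier), which are concatenated and share one `f`.
#'
#' The unconstrained optimum is the closed-form projection
#' `f* = <t - B, A - B> / ||A - B||^2`; the reported fraction is `f*`
#' clamped to \[0, 1\], with the residual root-mean-square evaluated at the
#' clamped value.
#'
#' @param target,stateA,stateB [reactivity_profile()]s over identical
#'   positions, bare numeric vectors of equal length, or lists of profiles
#'   (one per modifier, concatenated).
#' @return Object of class `two_state_fit` with fields `fraction`,
#'   `fraction_unclamped`, `residual_rmsd`, `fitted`, `target`, and
#'   `endpoints`.  Methods: `print`, `coef`, `fitted`, `residuals`.
#' @export
two_state_fit <- function(target, stateA, stateB) {
  t_v <- .fit_values(target)
  a_v <- .fit_values(stateA)
  b_v <- .fit_values(stateB)
  if (length(t_v) != length(a_v) || length(t_v) != length(b_v))
    stop("the three profiles must cover identical positions")
  d <- a_v - b_v
  ss <- sum(d^2)
  if (ss == 0) stop("degenerate endpoints: stateA and stateB are identical")
  f_raw <- sum((t_v - b_v) * d) / ss
  f <- min(max(f_raw, 0), 1)
  fit <- f * a_v + (1 - f) * b_v
  structure(
    list(fraction = f, fraction_unclamped = f_raw,
         residual_rmsd = sqrt(mean((t_v - fit)^2)),
         fitted = fit, target = t_v,
         endpoints = list(stateA = stateA, stateB = stateB)),
    class = "two_state_fit")
}

.fit_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "reactivity_profile")) return(x$values)
  if (is.list(x)) {
    ok <- vapply(x, inherits, logical(1), "reactivity_profile")
    if (all(ok)) return(unlist(lapply(x, `[[`, "values"), use.names = FALSE))
  }
  stop("expected a reactivity profile, a numeric vector, or a list of profiles")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> fraction(stateA) = %.4f (unclamped %.4f), residual RMSD = %.4g\n",
              x$fraction, x$fraction_unclamped, x$residual_rmsd))
  invisible(x)
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(fraction = object$fraction)
}

#' @export
fitted.two_state_fit <- function(object, ...) object$fitted

#' @export
residuals.two_state_fit <- function(object, ...) object$target - object$fitted
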