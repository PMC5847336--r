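#' Mutant specification: a set of point substitutions
#'
#' @param position integer vector of biological positions (unique).
#' @param wt_base,new_base character vectors of single bases; `wt_base` must
#'   match the construct sequence when the spec is applied.
#' @return Object of class `mutant_spec` with a canonical hyphen-joined
#'   label such as `"A19U-U77A"` (substitutions ordered by position).
#' @seealso [parse_mutant_label()], [apply_mutations()]
#' @export
mutant_spec <- function(position = integer(), wt_base = character(),
                        new_base = character()) {
  position <- as.integer(position)
  if (anyDuplicated(position)) stop("substitution positions must be unique")
  if (length(wt_base) != length(position) ||
      length(new_base) != length(position))
    stop("position, wt_base and new_base must have equal length")
  if (length(position)) {
    stopifnot(all(wt_base %in% names(.wc_complement)),
              all(new_base %in% names(.wc_complement)))
    ord <- order(position)
    position <- position[ord]; wt_base <- wt_base[ord]; new_base <- new_base[ord]
  }
  structure(
    list(position = position, wt_base = wt_base, new_base = new_base),
    class = "mutant_spec")
}

#' @export
print.mutant_spec <- function(x, ...) {
  cat("<mutant_spec>", mutant_label(x), "\n"); invisible(x)
}

#' @export
length.mutant_spec <- function(x) length(x$position)

#' Canonical label of a mutant spec
#'
#' Wild type (no substitutions) is labelled `"WT"`; otherwise substitutions
#' are joined with hyphens in position order, e.g. `"A19U-U20A-A76U-U77A"`.
#'
#' @param spec a [mutant_spec()].
#' @return character scalar.
#' @export
mutant_label <- function(spec) {
  if (length(spec$position) == 0L) return("WT")
  paste(sprintf("%s%d%s", spec$wt_base, spec$position, spec$new_base),
        collapse = "-")
}

#' Parse a mutant label back into a mutant spec
#'
#' Inverse of [mutant_label()].  Accepts hyphen-, comma-, semicolon- or
#' whitespace-separated substitution strings of the form `A19U`.
#'
#' @param label character scalar (`"WT"` allowed).
#' @return a [mutant_spec()].
#' @export
parse_mutant_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  label <- trimws(label)
  if (!nzchar(label) || toupper(label) == "WT") return(mutant_spec())
  parts <- strsplit(label, "[-,;[:space:]]+")[[1]]
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([ACGU])([0-9]+)([ACGU])$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("cannot parse substitution(s): ", paste(parts[bad], collapse = ", "))
  mutant_spec(position = as.integer(vapply(m, `[[`, character(1), 3L)),
              wt_base = vapply(m, `[[`, character(1), 2L),
              new_base = vapply(m, `[[`, character(1), 4L))
}

#' Apply substitutions to a construct
#'
#' @param construct an [rna_construct()].
#' @param spec a [mutant_spec()]; each `wt_base` must match the construct
#'   at its position, otherwise the call errors with the offending position.
#' @return A new `rna_construct` whose name carries the mutant label and
#'   whose sequence differs exactly at the substituted positions.
#' @export
apply_mutations <- function(construct, spec) {
  stopifnot(inherits(construct, "rna_construct"), inherits(spec, "mutant_spec"))
  if (length(spec) == 0L) return(construct)
  found <- base_at(construct, spec$position)
  bad <- found != spec$wt_base
  if (any(bad))
    stop("wild-type base mismatch at position ",
         paste(sprintf("%d (expected %s, found %s)", spec$position[bad],
                       spec$wt_base[bad], found[bad]), collapse = "; "))
  ch <- strsplit(construct$sequence, "")[[1]]
  ch[spec$position - construct$numbering_offset] <- spec$new_base
  out <- construct
  out$sequence <- paste(ch, collapse = "")
  out$name <- paste0(construct$name, ":", mutant_label(spec))
  out
}

#' Design the compensatory quartet for one base pair
#'
#' For a candidate base pair at positions (i, j), designs the three mutants
#' of a mutate-map-rescue quartet: mutant A flips position i to its
#' Watson-Crick complement, mutant B flips position j to the original base
#' at i, and the double mutant AB combines both so the new bases again form
#' a Watson-Crick pair.  For Watson-Crick pairs this is the strand-swap
#' convention (A-U becomes U-A, G-C becomes C-G); G-U wobble pairs are
#' resolved to the Watson-Crick substitution that restores pairing in the
#' double mutant (G-U: G to C and U to G, giving C-G; U-G: U to A and G to
#' U, giving A-U).  Each single mutant breaks the pair; the double mutant
#' restores it.
#'
#' @param construct an [rna_construct()].
#' @param pair a [base_pair()] whose positions hold pairable bases.
#' @return Named list of [mutant_spec()]: `mutA`, `mutB`, `mutAB`.
#' @export
design_compensatory_quartet <- function(construct, pair) {
  stopifnot(inherits(pair, "base_pair"))
  a <- base_at(construct, pair$i)
  b <- base_at(construct, pair$j)
  if (!.is_pairable(a, b))
    stop(sprintf("%s%d-%s%d is not a Watson-Crick or G-U pair",
                 a, pair$i, b, pair$j))
  new_i <- .wc_complement[[a]]
  new_j <- a
  if (!.is_wc(new_i, new_j))
    stop("designed double mutant is not Watson-Crick")  # unreachable for valid input
  list(mutA = mutant_spec(pair$i, a, new_i),
       mutB = mutant_spec(pair$j, b, new_j),
       mutAB = mutant_spec(c(pair$i, pair$j), c(a, b), c(new_i, new_j)))
}

#' Design a double-base-pair lock mutant
#'
#' Switches two consecutive Watson-Crick base pairs of a helix to
#' alternative Watson-Crick pairs, preserving pairing in the mutant.  The
#' default alternative is the strand swap (A-U to U-A, G-C to C-G), which
#' keeps the helix locked while changing all four bases; `transversion =
#' TRUE` instead exchanges pair identity (A-U to C-G, G-C to U-A).
#'
#' @param construct an [rna_construct()].
#' @param helix an [rna_helix()] with at least two pairs from `start_index`.
#' @param start_index 1-based index of the first of the two pairs within the
#'   helix (default 1).
#' @param transversion use the identity-exchanging alternative instead of
#'   the strand swap.
#' @return A 4-substitution [mutant_spec()].
#' @export
design_double_pair_lock <- function(construct, helix, start_index = 1L,
                                    transversion = FALSE) {
  stopifnot(inherits(helix, "rna_helix"))
  if (start_index < 1L || start_index + 1L > length(helix$pairs))
    stop("helix has no two consecutive pairs at start_index ", start_index)
  pos <- integer(0); wt <- character(0); new <- character(0)
  for (k in start_index + 0:1) {
    p <- helix$pairs[[k]]
    a <- base_at(construct, p$i); b <- base_at(construct, p$j)
    if (!.is_wc(a, b))
      stop(sprintf("pair %s%d-%s%d is not Watson-Crick; lock design needs WC pairs",
                   a, p$i, b, p$j))
    if (transversion) {
      # A-U -> C-G, U-A -> G-C, G-C -> U-A, C-G -> A-U
      swap <- c(A = "C", U = "G", G = "U", C = "A")
      na <- swap[[a]]; nb <- .wc_complement[[na]]
    } else {
      na <- b; nb <- a
    }
    pos <- c(pos, p$i, p$j); wt <- c(wt, a, b); new <- c(new, na, nb)
  }
  mutant_spec(pos, wt, new)
}
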