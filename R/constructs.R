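#' RNA construct with biological numbering and reference annotations
#'
#' A construct couples an RNA sequence with the numbering convention used to
#' label positions and mutations, the window of nucleotides compared between
#' chemical-mapping profiles, and the positions of the flanking GAGUA
#' reference hairpin loops used for normalization and attenuation correction.
#'
#' Biological position labels relate to 1-based sequence indices through
#' `position = index + numbering_offset`.  All user-facing coordinates
#' (helices, mutant labels, profile positions) are biological.
#'
#' @param name identifier for the construct.
#' @param sequence RNA string over `A`, `C`, `G`, `U` (uppercase).
#' @param numbering_offset integer added to the 1-based sequence index to get
#'   the biological position label.  Default 0.
#' @param probed_region length-2 integer vector, first and last biological
#'   position compared between profiles (inclusive).  Defaults to the whole
#'   sequence.
#' @param reference_loops optional list with elements `five_prime` and
#'   `three_prime`, each a vector of biological positions of a GAGUA
#'   reference loop.  Must be disjoint from `probed_region`.
#' @return An object of class `rna_construct`.
#' @seealso [add_construct()] for the bundled adenine-riboswitch construct.
#' @export
rna_construct <- function(name, sequence, numbering_offset = 0L,
                          probed_region = NULL, reference_loops = NULL) {
  .check_rna(sequence)
  n <- nchar(sequence)
  numbering_offset <- as.integer(numbering_offset)
  if (is.null(probed_region))
    probed_region <- c(1L + numbering_offset, n + numbering_offset)
  probed_region <- as.integer(probed_region)
  if (length(probed_region) != 2L || probed_region[1] > probed_region[2])
    stop("probed_region must be c(first, last) with first <= last")
  idx <- probed_region - numbering_offset
  if (idx[1] < 1L || idx[2] > n)
    stop("probed_region outside sequence bounds")
  if (!is.null(reference_loops)) {
    if (!all(c("five_prime", "three_prime") %in% names(reference_loops)))
      stop("reference_loops needs elements 'five_prime' and 'three_prime'")
    loop_pos <- unlist(reference_loops, use.names = FALSE)
    loop_idx <- loop_pos - numbering_offset
    if (any(loop_idx < 1L | loop_idx > n))
      stop("reference_loops outside sequence bounds")
    probed <- seq.int(probed_region[1], probed_region[2])
    if (any(loop_pos %in% probed))
      stop("reference_loops must be disjoint from probed_region")
  }
  structure(
    list(name = name, sequence = sequence,
         numbering_offset = numbering_offset,
         probed_region = probed_region,
         reference_loops = reference_loops),
    class = "rna_construct")
}

#' @export
print.rna_construct <- function(x, ...) {
  cat(sprintf("<rna_construct> %s: %d nt, positions %d..%d (offset %+d)\n",
              x$name, nchar(x$sequence),
              1L + x$numbering_offset,
              nchar(x$sequence) + x$numbering_offset, x$numbering_offset))
  cat(sprintf("  probed region: %d..%d\n",
              x$probed_region[1], x$probed_region[2]))
  if (!is.null(x$reference_loops))
    cat(sprintf("  reference loops: 5' %s | 3' %s\n",
                paste(range(x$reference_loops$five_prime), collapse = "-"),
                paste(range(x$reference_loops$three_prime), collapse = "-")))
  invisible(x)
}

## biological positions covered by the construct
construct_positions <- function(construct) {
  seq.int(1L, nchar(construct$sequence)) + construct$numbering_offset
}

## biological positions of the probed region
probed_positions <- function(construct) {
  seq.int(construct$probed_region[1], construct$probed_region[2])
}

## base at a biological position
base_at <- function(construct, position) {
  idx <- position - construct$numbering_offset
  n <- nchar(construct$sequence)
  if (any(idx < 1L | idx > n))
    stop("position ", paste(position[idx < 1L | idx > n], collapse = ", "),
         " outside construct ", construct$name)
  substring(construct$sequence, idx, idx)
}

#' Base pair between two biological positions
#'
#' @param i,j biological positions with `i < j`.
#' @param construct optional [rna_construct()]; when supplied, the bases at
#'   `i` and `j` must form a Watson-Crick (A-U, G-C) or G-U wobble pair.
#' @return Object of class `base_pair` (named integer-ish list).
#' @export
base_pair <- function(i, j, construct = NULL) {
  i <- as.integer(i); j <- as.integer(j)
  if (!(length(i) == 1L && length(j) == 1L && i < j))
    stop("base_pair requires scalar positions with i < j")
  if (!is.null(construct)) {
    a <- base_at(construct, i); b <- base_at(construct, j)
    if (!.is_pairable(a, b))
      stop(sprintf("%s%d and %s%d cannot form a Watson-Crick or G-U pair",
                   a, i, b, j))
  }
  structure(list(i = i, j = j), class = "base_pair")
}

#' @export
print.base_pair <- function(x, ...) {
  cat(sprintf("<base_pair> (%d, %d)\n", x$i, x$j)); invisible(x)
}

#' Helix: an ordered run of stacked base pairs
#'
#' Pairs must be consecutive and nested: `i` ascending by one, `j`
#' descending by one.
#'
#' @param name helix label (e.g. `"P1"`).
#' @param pairs list of [base_pair()] objects, or a 2-column matrix of
#'   (i, j) positions.
#' @param construct optional [rna_construct()] used to validate pairability.
#' @return Object of class `rna_helix`.
#' @export
rna_helix <- function(name, pairs, construct = NULL) {
  if (is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(k) base_pair(pairs[k, 1], pairs[k, 2], construct))
  if (length(pairs) < 1L) stop("helix needs at least one pair")
  is_bp <- vapply(pairs, inherits, logical(1), "base_pair")
  if (!all(is_bp)) stop("pairs must be base_pair objects or a 2-column matrix")
  iv <- vapply(pairs, `[[`, integer(1), "i")
  jv <- vapply(pairs, `[[`, integer(1), "j")
  if (length(pairs) > 1L &&
      (!all(diff(iv) == 1L) || !all(diff(jv) == -1L)))
    stop("helix pairs must be consecutive and nested (i ascending, j descending)")
  if (any(iv >= jv)) stop("helix pairs must satisfy i < j")
  if (!is.null(construct)) {
    a <- base_at(construct, iv); b <- base_at(construct, jv)
    bad <- !.is_pairable(a, b)
    if (any(bad))
      stop("non-pairable positions in helix ", name, ": ",
           paste(sprintf("%s%d-%s%d", a[bad], iv[bad], b[bad], jv[bad]),
                 collapse = ", "))
  }
  structure(list(name = name, pairs = pairs), class = "rna_helix")
}

#' @export
print.rna_helix <- function(x, ...) {
  iv <- vapply(x$pairs, `[[`, integer(1), "i")
  jv <- vapply(x$pairs, `[[`, integer(1), "j")
  cat(sprintf("<rna_helix> %s: %d bp, %d..%d / %d..%d\n", x$name,
              length(x$pairs), min(iv), max(iv), min(jv), max(jv)))
  invisible(x)
}

#' @export
length.rna_helix <- function(x) length(x$pairs)

helix_positions <- function(helix) {
  c(vapply(helix$pairs, `[[`, integer(1), "i"),
    vapply(helix$pairs, `[[`, integer(1), "j"))
}
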