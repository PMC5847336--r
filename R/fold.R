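#' Secondary-structure partition-function backend
#'
#' A backend maps an RNA sequence to its equilibrium base-pair probability
#' (BPP) matrix, deterministically for fixed settings.  Two backends ship
#' with the package:
#'
#' * `"reference"` — a self-contained McCaskill inside/outside dynamic
#'   program over a simple per-pair energy model (defaults: G-C -3.0,
#'   A-U -2.0, G-U -1.0 kcal/mol per pair, minimum hairpin loop 3).  It is
#'   exact for its own model and carries no external dependency, so all
#'   package tests and calibrations can run anywhere.
#' * `"vienna"` — ViennaRNA's `RNAfold -p` (Turner nearest-neighbour
#'   energies), used when the `RNAfold` executable is on the `PATH`.
#'
#' @param name `"reference"` or `"vienna"`.
#' @param temperature folding temperature in degrees Celsius.
#' @param energies named numeric vector `c(AU=, GC=, GU=)` of per-pair
#'   energies in kcal/mol (reference backend only).
#' @param min_loop minimum number of unpaired nucleotides in a hairpin loop
#'   (reference backend only).
#' @return Object of class `fold_backend`.
#' @export
fold_backend <- function(name = c("reference", "vienna"), temperature = 37,
                         energies = c(AU = -2.0, GC = -3.0, GU = -1.0),
                         min_loop = 3L) {
  name <- match.arg(name)
  stopifnot(all(c("AU", "GC", "GU") %in% names(energies)))
  structure(
    list(name = name, temperature = temperature,
         energies = energies, min_loop = as.integer(min_loop)),
    class = "fold_backend")
}

#' @export
print.fold_backend <- function(x, ...) {
  cat(sprintf("<fold_backend> %s @ %g C\n", x$name, x$temperature))
  invisible(x)
}

#' Base-pair probability matrix of a sequence
#'
#' @param seq RNA string (A/C/G/U; T is accepted and read as U).
#' @param backend a [fold_backend()].
#' @return `n x n` symmetric matrix of pairing probabilities, class
#'   `bpp_matrix`, with the sequence attached as attribute `"sequence"`.
#' @export
fold_bpp <- function(seq, backend = fold_backend()) {
  seq <- toupper(chartr("Tt", "Uu", seq))
  .check_rna(seq)
  stopifnot(inherits(backend, "fold_backend"))
  p <- switch(backend$name,
              reference = .fold_reference(seq, backend),
              vienna = .fold_vienna(seq, backend))
  dimnames(p) <- NULL
  attr(p, "sequence") <- seq
  attr(p, "backend") <- backend$name
  class(p) <- c("bpp_matrix", class(p))
  p
}

.fold_reference <- function(seq, backend) {
  codes <- .base_code[strsplit(seq, "")[[1]]]
  RT <- 0.0019872 * (backend$temperature + 273.15)
  .bpp_mccaskill(as.integer(codes), backend$energies[["AU"]],
                 backend$energies[["GC"]], backend$energies[["GU"]],
                 RT, backend$min_loop)
}

.fold_vienna <- function(seq, backend) {
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold))
    stop("vienna backend: RNAfold executable not found on PATH for sequence ",
         substr(seq, 1, 12), "...")
  dir <- tempfile("vienna")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa <- file.path(dir, "in.fa")
  writeLines(c(">lm2r", seq), fa)
  old_wd <- setwd(dir)  # RNAfold writes its dot plot into the working dir
  on.exit(setwd(old_wd), add = TRUE)
  status <- system2(rnafold, c("-p", "--noPS", "-T", backend$temperature),
                    stdin = fa, stdout = file.path(dir, "out.txt"),
                    stderr = file.path(dir, "err.txt"))
  dp <- file.path(dir, "lm2r_dp.ps")
  if (!identical(status, 0L) || !file.exists(dp))
    stop("vienna backend: RNAfold failed for sequence ",
         substr(seq, 1, 12), "...")
  lines <- grep("ubox$", readLines(dp), value = TRUE)
  lines <- grep("^[0-9]+ [0-9]+ [0-9.eE+-]+ ubox$", lines, value = TRUE)
  n <- nchar(seq)
  p <- matrix(0, n, n)
  if (length(lines)) {
    parts <- do.call(rbind, strsplit(lines, " ", fixed = TRUE))
    i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2])
    prob <- as.numeric(parts[, 3])^2  # dot plot stores sqrt(p)
    p[cbind(i, j)] <- prob
    p[cbind(j, i)] <- prob
  }
  p
}

#' Idealized reactivity profile from a BPP matrix
#'
#' The simulated reactivity of position `i` is its probability of being
#' unpaired, `1 - sum_j p(i, j)`: fully paired positions read 0, fully
#' single-stranded positions read 1.
#'
#' @param bpp a `bpp_matrix` from [fold_bpp()].
#' @param construct_ref,mutant_label metadata for the resulting profile.
#' @return a [reactivity_profile()] over positions `1..n`.
#' @export
simulate_reactivity <- function(bpp, construct_ref = NA_character_,
                                mutant_label = "WT") {
  v <- 1 - rowSums(bpp)
  v <- pmin(pmax(v, 0), 1)
  reactivity_profile(values = v, positions = seq_along(v),
                     construct_ref = construct_ref,
                     mutant_label = mutant_label, modifier = "insilico")
}

#' Screen a BPP matrix for candidate helices
#'
#' Finds maximal runs of stacked pairable positions
#' `(i, j), (i+1, j-1), ...` in which every pair has probability at least
#' `min_bpp`, and keeps runs of at least `min_len` pairs.
#'
#' @param bpp a `bpp_matrix` from [fold_bpp()].
#' @param min_bpp probability cutoff in (0, 1); default 0.01.
#' @param min_len minimum helix length in base pairs; default 3.
#' @return List of [rna_helix()] objects (positions 1-based in the folded
#'   sequence); each carries its per-pair probabilities in attribute
#'   `"bpp"` and their mean in `"mean_bpp"`.
#' @export
screen_candidate_helices <- function(bpp, min_bpp = 0.01, min_len = 3L) {
  stopifnot(min_bpp > 0, min_bpp < 1, min_len >= 1)
  n <- nrow(bpp)
  cand <- bpp >= min_bpp
  cand[lower.tri(cand, diag = TRUE)] <- FALSE
  helices <- list()
  hit <- which(cand, arr.ind = TRUE)
  if (!nrow(hit)) return(helices)
  is_cand <- function(i, j) i >= 1 && j <= n && i < j && cand[i, j]
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1]; j <- hit[r, 2]
    if (is_cand(i - 1L, j + 1L)) next  # not the outermost pair of its run
    len <- 1L
    while (is_cand(i + len, j - len)) len <- len + 1L
    if (len < min_len) next
    iv <- i + 0:(len - 1L); jv <- j - 0:(len - 1L)
    h <- rna_helix(sprintf("H%d_%d", i, j),
                   pairs = cbind(iv, jv))
    attr(h, "bpp") <- bpp[cbind(iv, jv)]
    attr(h, "mean_bpp") <- mean(bpp[cbind(iv, jv)])
    helices[[length(helices) + 1L]] <- h
  }
  helices
}
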