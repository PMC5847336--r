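#' Simulate a mutate-map-rescue quartet in silico
#'
#' Designs the compensatory quartet for one base pair, folds wild type and
#' all three mutants with the backend, converts each BPP matrix to an
#' idealized reactivity profile (probability unpaired), and evaluates the
#' rescue factor over all positions.
#'
#' @param seq RNA sequence (string).
#' @param pair a [base_pair()] whose positions are pairable in `seq`.
#' @param backend a [fold_backend()].
#' @return Rescue factor (numeric scalar); `NA` with attribute
#'   `"reason"` when the quartet is uninformative (the single mutants do
#'   not perturb the simulated profile).
#' @export
simulate_quartet <- function(seq, pair, backend = fold_backend()) {
  construct <- rna_construct("insilico", toupper(chartr("Tt", "Uu", seq)))
  specs <- design_compensatory_quartet(construct, pair)
  fold1 <- function(spec, label) {
    mutseq <- apply_mutations(construct, spec)$sequence
    simulate_reactivity(fold_bpp(mutseq, backend), mutant_label = label)
  }
  wt <- simulate_reactivity(fold_bpp(construct$sequence, backend))
  q <- quartet(wt,
               fold1(specs$mutA, mutant_label(specs$mutA)),
               fold1(specs$mutB, mutant_label(specs$mutB)),
               fold1(specs$mutAB, mutant_label(specs$mutAB)),
               pair = pair)
  tryCatch(rescue_factor(q),
           lm2r_uninformative = function(e) {
             structure(NA_real_, reason = conditionMessage(e))
           })
}

#' Simulate M2R over every pair of a helix
#'
#' @param seq RNA sequence.
#' @param helix an [rna_helix()] (1-based positions in `seq`).
#' @param backend a [fold_backend()].
#' @return Mean simulated rescue factor over the helix's informative pairs
#'   (`NA` if none), with per-pair factors in attribute `"per_pair"`.
#' @export
simulate_helix_m2r <- function(seq, helix, backend = fold_backend()) {
  factors <- vapply(helix$pairs, function(p)
    as.numeric(simulate_quartet(seq, p, backend)), numeric(1))
  kept <- factors[!is.na(factors)]
  out <- if (length(kept)) mean(kept) else NA_real_
  attr(out, "per_pair") <- factors
  out
}

#' Build a rescue-factor / helix-frequency calibration table
#'
#' For each input sequence: fold, screen candidate helices (pair probability
#' at least `min_bpp`, length at least `min_len` base pairs), and simulate a
#' mutate-map-rescue quartet for every pair of every candidate helix.  Each
#' helix yields one calibration sample: its base-pair count, the mean
#' simulated rescue factor over its pairs, and its simulated frequency (the
#' mean base-pair probability over its pairs).
#'
#' @param sequences named character vector of RNA sequences, or the path to
#'   a FASTA file (read with Biostrings; T is converted to U).
#' @param backend a [fold_backend()].
#' @param min_bpp,min_len screening cutoffs (defaults 0.01 and 3).
#' @param max_helices_per_seq cap on screened helices taken per sequence
#'   (highest mean probability first); `Inf` keeps all.
#' @param seed integer recorded in the provenance and used for any sampling.
#' @return `data.frame` of class `m2r_calibration` with columns `family`,
#'   `helix`, `first_i`, `last_j`, `n_bp`, `rescue_factor`, `frequency`,
#'   and provenance in `attr(, "provenance")`.  Per-sequence failures are
#'   logged and skipped.
#' @export
build_calibration <- function(sequences, backend = fold_backend(),
                              min_bpp = 0.01, min_len = 3L,
                              max_helices_per_seq = Inf, seed = 1L) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- read_fasta_rna(sequences)
  if (!length(sequences)) stop("no input sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  rows <- list()
  for (nm in names(sequences)) {
    res <- tryCatch({
      seq <- toupper(chartr("Tt", "Uu", sequences[[nm]]))
      bpp <- fold_bpp(seq, backend)
      helices <- screen_candidate_helices(bpp, min_bpp = min_bpp,
                                          min_len = min_len)
      if (length(helices) > max_helices_per_seq) {
        ord <- order(vapply(helices, attr, numeric(1), "mean_bpp"),
                     decreasing = TRUE)
        helices <- helices[ord[seq_len(max_helices_per_seq)]]
      }
      lapply(helices, function(h) {
        f <- simulate_helix_m2r(seq, h, backend)
        if (is.na(f)) return(NULL)
        iv <- vapply(h$pairs, `[[`, integer(1), "i")
        jv <- vapply(h$pairs, `[[`, integer(1), "j")
        data.frame(family = nm, helix = h$name,
                   first_i = min(iv), last_j = max(jv),
                   n_bp = length(h$pairs),
                   rescue_factor = as.numeric(f),
                   frequency = attr(h, "mean_bpp"))
      })
    }, error = function(e) {
      message("build_calibration: skipping ", nm, ": ", conditionMessage(e))
      NULL
    })
    rows <- c(rows, res)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("calibration produced no samples")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    backend = backend$name, temperature = backend$temperature,
    min_bpp = min_bpp, min_len = min_len, seed = as.integer(seed),
    n_sequences = length(sequences),
    config_hash = .calibration_config_hash(backend, min_bpp, min_len))
  class(out) <- c("m2r_calibration", class(out))
  out
}

.calibration_config_hash <- function(backend, min_bpp, min_len) {
  s <- paste(backend$name, backend$temperature,
             paste(backend$energies, collapse = ","), backend$min_loop,
             min_bpp, min_len, sep = "|")
  # small stable polynomial hash (double-precision modular); provenance only
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read RNA sequences from FASTA
#'
#' @param path FASTA file; DNA alphabets are converted to RNA.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("Tt", "Uu", as.character(set)))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    message("read_fasta_rna: dropping ", sum(bad),
            " sequence(s) with non-ACGU characters")
    seqs <- seqs[!bad]
  }
  if (!length(seqs)) stop("no usable sequences in ", path)
  seqs
}

#' Write / read a calibration table as TSV
#'
#' The TSV carries the sample columns; run provenance is written to a JSON
#' sidecar `<path>.json` and restored on read when present.
#'
#' @param calib an `m2r_calibration` from [build_calibration()].
#' @param path TSV file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `m2r_calibration` table.
#' @export
write_calibration <- function(calib, path) {
  write.table(as.data.frame(calib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  prov <- attr(calib, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  class(out) <- c("m2r_calibration", class(out))
  out
}
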