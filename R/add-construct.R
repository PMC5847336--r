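## Full probed construct for the V. vulnificus add adenine riboswitch:
## the riboswitch flanked by 5' and 3' reference hairpins with GAGUA loops
## and single-stranded buffering.  Biological numbering follows the
## riboswitch convention (P1 closing pair A19-U77); offset verified against
## the published lock-mutant labels (lock-P1: A19U-U20A-A76U-U77A,
## lock-P4B: U82A-C83G-G115C-A116U, MutP2: A29C-A30G-U40C-U41G).
.ADD_SEQUENCE <- paste0(
  "GGACACGACUCGAGUAGAGUCGAAUGCGCUUCAUAUAAUCCUAAUGAUAUGGUUUGGGAGUUUCUACC",
  "AAGAGCCUUAAACUCUUGAUUAUGAAGUCUGUCGCUUUAUCCGAAAUUUUAUAAAGAGAAGACUCAUG",
  "AAUUACUUUGACCUGCCGACCGGAGUCGAGUAGACUCCAACAAAAGAAACAACAACAACAAC")

.ADD_OFFSET <- -14L

#' Bundled adenine-riboswitch construct
#'
#' The full probed construct of the *V. vulnificus* `add` adenine
#' riboswitch: the riboswitch domain flanked on both sides by reference
#' hairpins whose GAGUA loops anchor normalization and attenuation
#' correction.  Biological numbering uses the riboswitch convention
#' (aptamer helix P1 closed by the A19-U77 pair; Shine-Dalgarno plus AUG at
#' positions 112-122); the probed region spans the riboswitch domain
#' between the flanking hairpins.
#'
#' @return an [rna_construct()] named `"add"`.
#' @seealso [add_helices()] for the documented lock-mutant base pairs.
#' @export
add_construct <- function() {
  gagua <- gregexpr("GAGUA", .ADD_SEQUENCE)[[1]]
  five <- gagua[1] + 0:4 + .ADD_OFFSET
  three <- gagua[length(gagua)] + 0:4 + .ADD_OFFSET
  rna_construct(
    name = "add",
    sequence = .ADD_SEQUENCE,
    numbering_offset = .ADD_OFFSET,
    probed_region = c(13L, 140L),
    reference_loops = list(five_prime = five, three_prime = three))
}

#' Documented helices of the add riboswitch
#'
#' Base-pair registries for the helices whose lock mutants are published:
#' the two terminal pairs of the aptamer helix P1 (A19-U77, U20-A76) and of
#' the expression-platform helix P4B (U82-A116, C83-G115).  Full registries
#' of the remaining helices are construct-specific and should be supplied
#' from secondary-structure models via [rna_helix()].
#'
#' @return Named list of [rna_helix()] objects (`P1`, `P4B`).
#' @export
add_helices <- function() {
  con <- add_construct()
  list(P1 = rna_helix("P1", cbind(c(19L, 20L), c(77L, 76L)), con),
       P4B = rna_helix("P4B", cbind(c(82L, 83L), c(116L, 115L)), con))
}
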