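# Shared toy objects for the unit tests.

toy_construct <- function(sequence = "GGAAACGAGUACGGGAAACCCGAGUACUUCC",
                          name = "toy") {
  # no annotated loops; plain construct for mutation/profile tests
  rna_construct(name, sequence)
}

# construct with annotated GAGUA loops flanking a probed core
loop_construct <- function() {
  #         1234567890123456789012345678
  seq <- "GCGAGUACGCAUGCAUGCAUGCGAGUACGC"
  rna_construct("loopy", seq,
                probed_region = c(11L, 22L),
                reference_loops = list(five_prime = 3L:7L,
                                       three_prime = 23L:27L))
}

flat_profile <- function(values, construct, mutant_label = "WT") {
  reactivity_profile(values, construct_positions(construct),
                     construct_ref = construct$name,
                     mutant_label = mutant_label)
}

# quartet over bare positions 1..n from plain numeric vectors
vec_quartet <- function(wt, a, b, ab) {
  n <- length(wt)
  mk <- function(v, lab) reactivity_profile(v, seq_len(n), "vec", lab)
  quartet(mk(wt, "WT"), mk(a, "A"), mk(b, "B"), mk(ab, "AB"))
}

# ensemble of two mutually exclusive helices at weight f / 1 - f,
# built on the packaged bistable toy construct
exclusive_ensemble <- function(f, n_bp = 4L, seed = 11L, noise_sd = 0.1) {
  bis <- lm2r:::.bistable_construct(n_bp, seed)
  toy_ensemble(bis$construct, c(bis$dbA, bis$dbB), c(f, 1 - f),
               noise_sd = noise_sd, seed = seed)
}

# construct holding two independent hairpin modules; structures enumerate
# formation of each module independently with the given marginals
independent_ensemble <- function(fA, fB, seed = 5L, noise_sd = 0.1) {
  #  hairpinA: GGCCG AGUA CGGCC   hairpinB: GGCGG AGUA CCGCC
  seq <- paste0("GGCCGAGUACGGCC", "AAA", "GGCGGAGUACCGCC")
  con <- rna_construct(sprintf("indep_%d", seed), seq)
  hpA <- cbind(1:5, 14:10)          # 5 bp
  hpB <- cbind(18:22, 31:27)        # 5 bp
  db <- function(mods) {
    ch <- rep(".", nchar(seq))
    for (m in mods) { ch[m[, 1]] <- "("; ch[m[, 2]] <- ")" }
    paste(ch, collapse = "")
  }
  structures <- c(db(list(hpA, hpB)), db(list(hpA)), db(list(hpB)), db(list()))
  weights <- c(fA * fB, fA * (1 - fB), (1 - fA) * fB, (1 - fA) * (1 - fB))
  list(ensemble = toy_ensemble(con, structures, weights,
                               noise_sd = noise_sd, seed = seed),
       construct = con, hpA = hpA, hpB = hpB)
}
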