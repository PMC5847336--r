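# Brute-force Boltzmann oracle for base-pair probabilities.
#
# Enumerates every nested secondary structure (minimum hairpin loop
# enforced, Watson-Crick and G-U pairs admissible) of a short sequence,
# weights each structure by exp(-E/RT) with E the sum of its per-pair
# energies, and accumulates exact pair frequencies.  Exponential in the
# sequence length; intended for sequences up to ~18 nt.

oracle_pair_energy <- function(a, b, energies) {
  key <- paste0(a, b)
  switch(key,
         "AU" = , "UA" = energies[["AU"]],
         "GC" = , "CG" = energies[["GC"]],
         "GU" = , "UG" = energies[["GU"]],
         NA_real_)
}

# list of structures, each a 2-column matrix of pairs, for interval [i, j]
oracle_enumerate <- function(ch, i, j, min_loop, energies) {
  if (i > j) return(list(matrix(integer(), ncol = 2)))
  out <- list()
  # position i unpaired
  for (s in oracle_enumerate(ch, i + 1L, j, min_loop, energies))
    out[[length(out) + 1L]] <- s
  # position i paired to k
  ks <- if (i + min_loop + 1L <= j) seq.int(i + min_loop + 1L, j)
        else integer(0)
  for (k in ks) {
    if (is.na(oracle_pair_energy(ch[i], ch[k], energies))) next
    inner <- oracle_enumerate(ch, i + 1L, k - 1L, min_loop, energies)
    outer <- oracle_enumerate(ch, k + 1L, j, min_loop, energies)
    for (si in inner) for (so in outer)
      out[[length(out) + 1L]] <- rbind(c(i, k), si, so)
  }
  out
}

oracle_bpp <- function(seq, temperature = 37,
                       energies = c(AU = -2.0, GC = -3.0, GU = -1.0),
                       min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  RT <- 0.0019872 * (temperature + 273.15)
  structs <- oracle_enumerate(ch, 1L, n, min_loop, energies)
  p <- matrix(0, n, n)
  z <- 0
  for (s in structs) {
    e <- 0
    if (nrow(s))
      e <- sum(vapply(seq_len(nrow(s)), function(r)
        oracle_pair_energy(ch[s[r, 1]], ch[s[r, 2]], energies), numeric(1)))
    w <- exp(-e / RT)
    z <- z + w
    if (nrow(s)) {
      p[s] <- p[s] + w
      p[s[, 2:1, drop = FALSE]] <- p[s[, 2:1, drop = FALSE]] + w
    }
  }
  p / z
}

# short sequences exercised against the oracle: designed hairpins, a
# bistable switch, G-U-containing stems, and seeded random sequences
oracle_fixture_sequences <- function() {
  c(hairpin = "GGGGAAAACCCC",
    gu_stem = "GGUGAAAACGCC",
    bistable = "GGCAAAAGCCAAAAGGC",
    au_rich = "AAUUGAAAAUUCAAUU",
    random_rna_sequences(4, c(12L, 18L), seed = 424242))
}
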