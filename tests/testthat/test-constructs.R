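test_that("construct invariants are enforced", {
  expect_error(rna_construct("bad", "ACGT"), "uppercase RNA")
  expect_error(rna_construct("bad", ""), "non-empty")
  expect_error(rna_construct("bad", "ACGU", probed_region = c(1L, 9L)),
               "bounds")
  expect_error(
    rna_construct("bad", "GAGUAACGUACGU", probed_region = c(1L, 13L),
                  reference_loops = list(five_prime = 1:5,
                                         three_prime = 9:13)),
    "disjoint")
})

test_that("biological numbering maps through the offset", {
  con <- rna_construct("off", "AUGC", numbering_offset = 100L)
  expect_identical(construct_positions(con)[1], 101L)
  expect_identical(lm2r:::base_at(con, 101L), "A")
  expect_error(lm2r:::base_at(con, 1L), "outside")
})

test_that("applying an empty spec is the identity", {
  con <- toy_construct()
  expect_identical(apply_mutations(con, mutant_spec())$sequence,
                   con$sequence)
})

test_that("MutP2-style multi-substitution specs change exactly those bases", {
  con <- add_construct()
  spec <- parse_mutant_label("A29C-A30G-U40C-U41G")
  mut <- apply_mutations(con, spec)
  wt_ch <- strsplit(con$sequence, "")[[1]]
  mut_ch <- strsplit(mut$sequence, "")[[1]]
  changed <- which(wt_ch != mut_ch)
  expect_identical(changed + con$numbering_offset, c(29L, 30L, 40L, 41L))
  expect_identical(mut_ch[changed], c("C", "G", "C", "G"))
})

test_that("wild-type mismatches are rejected with position detail", {
  con <- add_construct()
  expect_error(apply_mutations(con, mutant_spec(19L, "G", "C")),
               "position 19.*expected G.*found A")
})

test_that("compensatory quartet design reproduces published conventions", {
  con <- add_construct()
  specs <- design_compensatory_quartet(con, base_pair(19L, 77L, con))
  expect_identical(vapply(specs, mutant_label, character(1)),
                   c(mutA = "A19U", mutB = "U77A", mutAB = "A19U-U77A"))

  # G-C pair: both sides flip to their complements
  gc <- rna_construct("gc", "GGGAAAACCC", numbering_offset = 198L)
  specs_gc <- design_compensatory_quartet(gc, base_pair(201L, 207L, gc))
  expect_identical(vapply(specs_gc, mutant_label, character(1)),
                   c(mutA = "G201C", mutB = "C207G",
                     mutAB = "G201C-C207G"))
})

test_that("single mutants break the pair and the double mutant restores it", {
  con <- toy_construct("GGAUGCAAAAGCAUCC")
  for (pr in list(c(3L, 14L), c(4L, 13L), c(5L, 12L))) {
    pair <- base_pair(pr[1], pr[2], con)
    specs <- design_compensatory_quartet(con, pair)
    check_pair <- function(spec) {
      m <- apply_mutations(con, spec)
      lm2r:::.is_wc(lm2r:::base_at(m, pair$i), lm2r:::base_at(m, pair$j))
    }
    expect_false(check_pair(specs$mutA))
    expect_false(check_pair(specs$mutB))
    expect_true(check_pair(specs$mutAB))
  }
})

test_that("G-U pairs resolve to a Watson-Crick double mutant", {
  con <- toy_construct("GGGUAAAAAACC")          # G3-U... no: use explicit pair
  con <- rna_construct("gu", "AGUCAAAAGAUU")
  pair <- base_pair(3L, 10L, con)               # U3 - A10? check: U-A is WC
  con <- rna_construct("gu", "AGGCAAAAGUCU")
  pair <- base_pair(3L, 10L, con)               # G3 - U10 wobble
  expect_identical(lm2r:::base_at(con, 3L), "G")
  expect_identical(lm2r:::base_at(con, 10L), "U")
  specs <- design_compensatory_quartet(con, pair)
  mab <- apply_mutations(con, specs$mutAB)
  expect_true(lm2r:::.is_wc(lm2r:::base_at(mab, 3L),
                            lm2r:::base_at(mab, 10L)))
  ma <- apply_mutations(con, specs$mutA)
  expect_false(lm2r:::.is_pairable(lm2r:::base_at(ma, 3L),
                                   lm2r:::base_at(ma, 10L)))
})

test_that("applying mutA then mutB equals applying mutAB", {
  con <- add_construct()
  specs <- design_compensatory_quartet(con, base_pair(19L, 77L, con))
  via_singles <- apply_mutations(apply_mutations(con, specs$mutA),
                                 specs$mutB)
  via_double <- apply_mutations(con, specs$mutAB)
  expect_identical(via_singles$sequence, via_double$sequence)
})

test_that("double-pair lock designs reproduce the published lock mutants", {
  con <- add_construct()
  h <- add_helices()
  expect_identical(mutant_label(design_double_pair_lock(con, h$P1)),
                   "A19U-U20A-A76U-U77A")
  expect_identical(mutant_label(design_double_pair_lock(con, h$P4B)),
                   "U82A-C83G-G115C-A116U")
})

test_that("lock mutants keep both pairs Watson-Crick", {
  con <- add_construct()
  for (h in add_helices()) {
    locked <- apply_mutations(con, design_double_pair_lock(con, h))
    for (p in h$pairs)
      expect_true(lm2r:::.is_wc(lm2r:::base_at(locked, p$i),
                                lm2r:::base_at(locked, p$j)))
    # transversion alternative also preserves pairing
    locked_tv <- apply_mutations(con,
                                 design_double_pair_lock(con, h, transversion = TRUE))
    for (p in h$pairs)
      expect_true(lm2r:::.is_wc(lm2r:::base_at(locked_tv, p$i),
                                lm2r:::base_at(locked_tv, p$j)))
  }
  expect_error(design_double_pair_lock(con, add_helices()$P1, start_index = 2L),
               "no two consecutive pairs")
})

test_that("mutant labels round-trip through the parser", {
  specs <- list(mutant_spec(),
                mutant_spec(19L, "A", "U"),
                parse_mutant_label("A19U-U20A-A76U-U77A"),
                mutant_spec(c(201L, 217L), c("G", "C"), c("C", "G")))
  for (s in specs)
    expect_identical(parse_mutant_label(mutant_label(s)), s)
  expect_identical(mutant_label(parse_mutant_label("WT")), "WT")
  expect_error(parse_mutant_label("A19X"), "cannot parse")
})

test_that("helix construction validates stacking and pairing", {
  con <- toy_construct("GGAUGCAAAAGCAUCC")
  h <- rna_helix("H", cbind(3:5, 14:12), con)
  expect_length(h, 3L)
  expect_error(rna_helix("H", cbind(c(3L, 5L), c(14L, 12L)), con),
               "consecutive")
  expect_error(rna_helix("H", cbind(6:7, 16:15), con), "cannot form")
})
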