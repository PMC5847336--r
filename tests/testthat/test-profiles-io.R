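test_that("profile construction enforces its invariants", {
  expect_error(reactivity_profile(c(1, NA), 1:2), "finite")
  expect_error(reactivity_profile(c(1, 2), c(2L, 1L)), "increasing")
  expect_error(reactivity_profile(c(1, 2, 3), 1:2), "equal length")
})

test_that("normalization anchors the reference-loop mean at 1", {
  con <- loop_construct()
  anchor <- c(con$reference_loops$five_prime, con$reference_loops$three_prime)
  v <- rep(0.5, 30)
  v[anchor] <- 2.0
  p <- flat_profile(v, con)
  norm <- normalize_profile(p, con)
  expect_equal(mean(profile_values_at(norm, anchor)), 1.0)
  expect_equal(norm$values, p$values / 2)

  # already normalized -> unchanged; idempotent in general
  expect_equal(normalize_profile(norm, con)$values, norm$values)

  p0 <- flat_profile(replace(rep(1, 30), anchor, 0), con)
  expect_error(normalize_profile(p0, con), "positive")
})

test_that("normalization commutes with restriction that keeps the anchors", {
  con <- loop_construct()
  v <- seq(0.1, 3, length.out = 30)
  p <- flat_profile(v, con)
  keep <- sort(c(3:7, 23:27, 11:18))
  a <- restrict_profile(normalize_profile(p, con), keep)
  b <- normalize_profile(restrict_profile(p, keep), con)
  expect_equal(a$values, b$values)
})

test_that("attenuation correction applies the closed-form geometric factor", {
  con <- loop_construct()
  v <- rep(1, 30)
  v[con$reference_loops$three_prime] <- 0.5   # 3' loop mean at half
  p <- flat_profile(v, con)
  corr <- correct_attenuation(p, con)
  r <- attr(corr, "attenuation_ratio")
  expect_equal(r, 2)
  # independent computation of the per-position factor
  expected <- v * 2 ^ ((p$positions - 1) / (30 - 1))
  expect_equal(corr$values, expected)
  expect_equal(corr$values[30], v[30] * 2)

  # equal loop means: profile unchanged
  flat <- flat_profile(rep(0.7, 30), con)
  expect_equal(correct_attenuation(flat, con)$values, flat$values)
})

test_that("background subtraction is elementwise and floored at zero", {
  con <- toy_construct("ACGUA")
  sig <- flat_profile(c(1.0, 0.5, 0.2, 0.9, 0.0), con)
  bg <- flat_profile(c(0.2, 0.6, 0.0, 0.1, 0.0), con, "nomod")
  out <- subtract_background(sig, bg)
  expect_equal(out$values, c(0.8, 0.0, 0.2, 0.8, 0.0))
  # zero background is the identity
  zero <- flat_profile(rep(0, 5), con, "nomod")
  expect_equal(subtract_background(sig, zero)$values, sig$values)
  short <- reactivity_profile(c(1, 2), 1:2)
  expect_error(subtract_background(sig, short), "aligned")
})

test_that("RDAT files round-trip bit-exactly", {
  con <- add_construct()
  set.seed(99)
  labels <- c("WT", "A19U", "U77A", "A19U-U77A")
  profiles <- lapply(labels, function(lab)
    reactivity_profile(round(runif(nchar(con$sequence)), 6),
                       construct_positions(con), con$name, lab,
                       errors = round(runif(nchar(con$sequence), 0, 0.1), 6)))
  x <- rdat("add_m2r_fixture", con, profiles,
            annotations = c("modifier:1M7", "experimentType:MutateMapRescue"))
  path <- tempfile(fileext = ".rdat")
  write_rdat(x, path)
  y <- suppressMessages(read_rdat(path))
  expect_identical(length(y$profiles), 4L)
  expect_identical(vapply(y$profiles, `[[`, character(1), "mutant_label"),
                   labels)
  expect_identical(y$construct$sequence, con$sequence)
  expect_identical(y$construct$numbering_offset, con$numbering_offset)
  for (k in 1:4) {
    expect_identical(y$profiles[[k]]$values, profiles[[k]]$values)
    expect_identical(y$profiles[[k]]$errors, profiles[[k]]$errors)
    expect_identical(y$profiles[[k]]$positions, profiles[[k]]$positions)
  }
  # and the re-written file is byte-identical
  path2 <- tempfile(fileext = ".rdat")
  write_rdat(y, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("RDAT rows of the wrong length raise a located parse error", {
  con <- toy_construct("GGGAAACCC")
  p <- flat_profile(rep(0.5, 9), con)
  path <- tempfile(fileext = ".rdat")
  write_rdat(rdat("bad", con, list(p)), path)
  lines <- readLines(path)
  i <- grep("^REACTIVITY:1", lines)
  lines[i] <- paste(c(strsplit(lines[i], "\t")[[1]], "0.1"), collapse = "\t")
  writeLines(lines, path)
  expect_error(suppressMessages(read_rdat(path)), "line.*REACTIVITY:1")
})

test_that("quartets can be assembled from an RDAT fixture", {
  con <- add_construct()
  ens_like <- lapply(c("WT", "A19U", "U77A", "A19U-U77A"), function(lab)
    reactivity_profile(seq(0, 1, length.out = nchar(con$sequence)),
                       construct_positions(con), con$name, lab))
  path <- tempfile(fileext = ".rdat")
  write_rdat(rdat("qfix", con, ens_like), path)
  y <- suppressMessages(read_rdat(path))
  labs <- vapply(y$profiles, `[[`, character(1), "mutant_label")
  q <- quartet(y$profiles[[match("WT", labs)]],
               y$profiles[[match("A19U", labs)]],
               y$profiles[[match("U77A", labs)]],
               y$profiles[[match("A19U-U77A", labs)]],
               pair = base_pair(19L, 77L, con),
               comparison_positions = probed_positions(con))
  expect_s3_class(q, "m2r_quartet")
  expect_identical(range(q$comparison_positions), c(13L, 140L))
})
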