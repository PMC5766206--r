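# The 2D energetic engine: single-strand and cofold MFE, constrained
# folding, opening energies, and the exhaustive-enumeration oracle.

test_that("folding reproduces hand-derived minimum-free-energy states", {
  # no complementary pairs possible
  r <- fold_mfe("AAAAAAAA", model = toy)
  expect_equal(r$energy, 0)
  expect_equal(r$structure, "........")

  # 4-pair hairpin, 3 stacks at -2 each (exhaustively confirmed below)
  r <- fold_mfe("GGGGAAAACCCC", model = toy)
  expect_equal(r$energy, -6)
  expect_equal(r$structure, "((((....))))")

  # all positions constrained unpaired forbids every pair
  r <- fold_mfe("GGGGAAAACCCC", constraint = strrep("x", 12), model = toy)
  expect_equal(r$energy, 0)
  expect_equal(r$structure, "............")

  expect_error(fold_mfe("GGTT"), class = "ribochain_input_error")
  expect_error(fold_mfe("GGGG", constraint = "xx"),
               class = "ribochain_input_error")
})

test_that("cofolding allows intermolecular pairs across the recorded nick", {
  r <- cofold_mfe("GGGG", "CCCC", model = toy)
  expect_equal(r$energy, -6)  # 4 intermolecular pairs, 3 stacks
  expect_equal(r$structure, "((((&))))")
  expect_equal(nrow(r$pairs), 4)

  r0 <- cofold_mfe("AAAA", "AAAA", model = toy)
  expect_equal(r0$energy, 0)
  expect_equal(nrow(r0$pairs), 0)

  # the innermost pair of GGGG&CCCC is a hairpin legal only across the nick
  expect_true(any(r$pairs[, 1] == 3 & r$pairs[, 2] == 4))
})

test_that("cofold energy is subadditive in the monomer energies", {
  set.seed(101)
  for (i in 1:25) {
    a <- random_rna(sample(4:12, 1))
    b <- random_rna(sample(4:12, 1))
    expect_lte(cofold_mfe(a, b, model = toy)$energy,
               fold_mfe(a, model = toy)$energy +
                 fold_mfe(b, model = toy)$energy)
  }
})

test_that("opening energies quantify toehold exposure", {
  # window already unpaired in the MFE structure
  expect_equal(opening_energy("GGGGAAAACCCC", c(4, 8), toy), 0)
  # opening the 5' arm of the hairpin removes all 3 stacks
  expect_equal(opening_energy("GGGGAAAACCCC", c(0, 4), toy), 6)
  # empty window is an inactive constraint
  expect_equal(opening_energy("GGGGAAAACCCC", c(5, 5), toy), 0)
  expect_error(opening_energy("GGGG", c(0, 9), toy),
               class = "ribochain_input_error")
})

test_that("opening energy is non-negative and constraints are monotone", {
  set.seed(202)
  for (i in 1:20) {
    s <- random_rna(14)
    w <- sort(sample(0:14, 2))
    if (w[1] == w[2]) next
    expect_gte(opening_energy(s, w, toy), 0)
    # adding unpaired constraints never lowers the energy
    cons <- rep(FALSE, 14)
    cons[(w[1] + 1):w[2]] <- TRUE
    e_con <- fold_mfe(s, constraint = cons, model = toy)$energy
    expect_gte(e_con, fold_mfe(s, model = toy)$energy)
  }
})

test_that("enumeration agrees with hand counts on tiny sequences", {
  # 4 nt cannot host a legal hairpin (minimum 3 unpaired): empty only
  e <- enumerate_structures("GCGC", model = toy)
  expect_equal(nrow(e), 1)
  expect_equal(e$structure, "....")
  expect_equal(e$energy, 0)

  # GCGCGC: the empty structure plus the single legal pair (0,5)
  e <- enumerate_structures("GCGCGC", model = toy)
  expect_equal(nrow(e), 2)
  expect_setequal(e$structure, c("......", "(....)"))

  expect_error(enumerate_structures(strrep("A", 20), model = toy),
               class = "ribochain_input_error")
})

test_that("fold_mfe matches the exhaustive oracle including tie-breaking", {
  set.seed(303)
  for (i in 1:60) {
    s <- random_rna(sample(6:12, 1))
    en <- enumerate_structures(s, model = toy)
    expect_equal(fold_mfe(s, model = toy)$energy, min(en$energy))
    # deterministic tie-break: lexicographically smallest co-optimal
    co <- en$structure[abs(en$energy - min(en$energy)) < 1e-9]
    expect_identical(fold_mfe(s, model = toy)$structure, lex_min(co))
  }
})

test_that("cofold agrees with enumeration over the nicked concatenation", {
  set.seed(404)
  for (i in 1:20) {
    a <- random_rna(sample(3:6, 1))
    b <- random_rna(sample(3:6, 1))
    en <- enumerate_structures(paste0(a, b), model = toy, cuts = nchar(a))
    expect_equal(cofold_mfe(a, b, model = toy)$energy, min(en$energy))
  }
})

test_that("identical inputs give bit-identical structures", {
  set.seed(505)
  s <- random_rna(30)
  r1 <- fold_mfe(s, model = toy)
  r2 <- fold_mfe(s, model = toy)
  expect_identical(r1$structure, r2$structure)
  expect_identical(r1$energy, r2$energy)
})

test_that("G-U wobble pairs fold only when the model enables them", {
  s <- "GGGGUUUU"  # foldable only through wobble pairs
  expect_equal(fold_mfe(s, model = toy)$energy, 0)
  gu <- toy_energy_model(allow_gu = TRUE)
  r <- fold_mfe(s, model = gu)
  expect_equal(r$energy, -1)  # 2 G-U pairs (hairpin minimum), 1 wobble stack
})
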