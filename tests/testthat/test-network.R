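# Network energetics: toehold detection, interaction energetics,
# hierarchical assembly and cross-talk matrices.

test_that("toehold detection reports exposed complementary runs", {
  # unstructured strand against a partner containing the complement
  hits <- detect_toeholds("AAAAAA", "CCUUUUUUCC", min_len = 4,
                          model = toy)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$exposed))
  expect_true(all(hits$complementarity == 1))

  # fully paired hairpin exposes only its loop; a 4-nt A loop cannot match
  # a G-only partner
  expect_equal(nrow(detect_toeholds("GGGGAAAACCCC", "GGGGGG",
                                    min_len = 4, model = toy)), 0)
  # min_len longer than the molecule
  expect_equal(nrow(detect_toeholds("AAAA", "UUUU", min_len = 10,
                                    model = toy)), 0)
})

test_that("interaction energetics decompose into hybridization and activation", {
  e <- interaction_energetics("GGGG", "CCCC", c(0, 4), c(0, 4), model = toy)
  expect_equal(e$dG_hyb, -6)
  expect_equal(e$dG_act, 0)
  expect_equal(unname(e$landmarks), c(0, 0, -6))

  # identical non-complementary homopolymers
  e0 <- interaction_energetics("AAAA", "AAAA", c(0, 4), c(0, 4), model = toy)
  expect_equal(e0$dG_hyb, 0)
  expect_equal(e0$dG_act, 0)

  # toehold sequestered in a 4-pair stem costs its opening energy
  e1 <- interaction_energetics("GGGGAAAACCCC", "AAAA", c(0, 4), c(0, 4),
                               model = toy)
  expect_equal(e1$dG_act, 6)
  expect_true(is.data.frame(tidy(e1)))
})

test_that("activation energies are non-negative for any interaction", {
  set.seed(21)
  for (i in 1:15) {
    a <- random_rna(10); b <- random_rna(10)
    e <- interaction_energetics(a, b, c(0, 4), c(0, 4), model = toy)
    expect_gte(e$dG_act, 0)
  }
})

test_that("a two-member complex equals the plain cofold", {
  cf <- cofold_mfe("GGGG", "CCCC", model = toy)
  cx <- assemble_complex(c(a = "GGGG", b = "CCCC"), model = toy)
  expect_equal(cx$energy, cf$energy)
  expect_identical(cx$structure, cf$structure)
})

test_that("assembly freezes earlier intermolecular pairs", {
  seqs <- fixture_au$sequences
  cx12 <- assemble_complex(seqs[c("SR", "SRR")], model = toy)
  cx <- assemble_complex(seqs, model = toy)
  key <- function(p) paste(p[, 1], p[, 2], sep = ":")
  expect_true(all(key(cx12$frozen) %in% key(cx$pairs)))
  # re-serialization invariance: write -> read -> recompute energy
  p <- parse_dotbracket(cx$structure)
  expect_equal(structure_energy(p$pairs, paste(unlist(cx$seqs), collapse = ""),
                                toy, cuts = p$cuts),
               cx$energy)
  expect_error(assemble_complex(c(a = "GGGG"), model = toy),
               class = "ribochain_input_error")
  expect_error(assemble_complex(seqs, order = list("SR", "SRR"), model = toy),
               class = "ribochain_input_error")
})

test_that("single-network cross-talk equals its own platform energetics", {
  m <- crosstalk_matrix(list(net = fixture_au$network), model = toy)
  expect_equal(nrow(m), 1)
  plat_expected <- fixture_au$expected$dG_hyb[2]
  expect_equal(m$dG_hyb, plat_expected)
  expect_equal(m$gap, 0)
})

test_that("cross-talk entries are computed independently per direction", {
  nets <- list(A = fixture_au$network, B = fixture_gc$network)
  m <- crosstalk_matrix(nets, model = toy)
  expect_equal(nrow(m), 4)
  expect_true(all(m$dG_hyb[m$cognate] < 0))
  expect_true(all(m$dG_hyb[!m$cognate] == 0))
  # swapping the networks transposes the matrix
  m2 <- crosstalk_matrix(list(A = fixture_gc$network,
                              B = fixture_au$network), model = toy)
  get <- function(mm, i, j) mm$dG_hyb[mm$up_network == i & mm$down_network == j]
  expect_equal(get(m, "A", "B"), get(m2, "B", "A"))
  expect_equal(get(m, "B", "A"), get(m2, "A", "B"))
})

test_that("toehold annotations are recomputed after mutation, never stale", {
  s <- "AAAAAA"
  before <- detect_toeholds(s, "CCUUUUUUCC", min_len = 4, model = toy)
  expect_equal(nrow(before), 1)
  # mutate the run so the complement no longer matches perfectly
  after <- detect_toeholds("AAGGAA", "CCUUUUUUCC", min_len = 4, model = toy)
  expect_equal(nrow(after), 0)
})
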