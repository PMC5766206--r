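# The linear design objective: interaction, RBS and structure terms, and
# the full per-network breakdown.

test_that("interaction terms score desired and undesired pairs oppositely", {
  w <- objective_weights()
  e <- list(dG_hyb = -6, dG_act = 0)
  expect_equal(interaction_term(e, TRUE, w), -6)
  expect_equal(interaction_term(list(dG_hyb = 0, dG_act = 0), FALSE, w), 0)
  # the same energetics scored desired vs undesired are negatives
  e2 <- list(dG_hyb = -3, dG_act = 1.5)
  expect_equal(interaction_term(e2, TRUE, w),
               -interaction_term(e2, FALSE, w))
  # alpha_act weights the activation part only
  w2 <- objective_weights(alpha_act = 2)
  expect_equal(interaction_term(e2, TRUE, w2), -3 + 2 * 1.5)
  # hinge variant penalizes only favorable undesired aggregates
  wh <- objective_weights(undesired_hinge = TRUE)
  expect_equal(interaction_term(list(dG_hyb = 3, dG_act = 0), FALSE, wh), 0)
  expect_equal(interaction_term(list(dG_hyb = -3, dG_act = 0), FALSE, wh), 3)
  expect_error(objective_weights(w_desired = -1),
               class = "ribochain_input_error")
})

test_that("the RBS term rewards occlusion OFF and exposure ON", {
  # UTR with the 'RBS' window [0,4) locked in a 4-pair stem when alone;
  # a GGGG partner invades the 3' arm, leaving a co-optimal open state
  utr <- "GGGGAAAACCCC"
  on_cplx <- assemble_complex(c(utr = utr, trig = "GGGG"), model = toy)
  sc <- rbs_term(utr, on_cplx, c(0, 4), "utr", objective_weights(), toy)
  expect_equal(sc, -6)
  # RBS unpaired in both states scores zero
  utr2 <- "AAAAAAAA"
  on2 <- assemble_complex(c(utr = utr2, trig = "CCCC"), model = toy)
  expect_equal(rbs_term(utr2, on2, c(0, 4), "utr", objective_weights(), toy), 0)
  # doubling w_rbs_off doubles the OFF contribution only
  sc2 <- rbs_term(utr, on_cplx, c(0, 4), "utr",
                  objective_weights(w_rbs_off = 2), toy)
  expect_equal(sc2, -12)
  expect_error(rbs_term(utr, on_cplx, NULL, "utr", objective_weights(), toy),
               class = "ribochain_spec_error")
})

test_that("the structure term is the weighted base-pair distance", {
  w <- objective_weights(w_struct = 3)
  expect_equal(structure_term("((..))", "((..))", w), 0)
  expect_equal(structure_term("((..))", "......", w), 6)
  expect_equal(structure_term("......", "((..))", w), 6)
})

test_that("the total objective is linear and additive over terms", {
  net <- fixture_au$network
  bd <- total_objective(net, toy)
  expect_equal(objective_total(bd), sum(bd$value))
  expect_lt(objective_total(bd), 0)
  expect_true(all(bd$value[bd$type == "undesired"] == 0))

  # un-declaring a desired interaction flips its term sign (the pair
  # becomes implicitly undesired), changing the total by twice the term
  term1 <- bd$value[bd$term == "SR -> SRR"]
  net2 <- net
  net2$interactions <- net$interactions[-1, ]
  bd2 <- total_objective(net2, toy)
  expect_equal(objective_total(bd) - objective_total(bd2), 2 * term1)
  expect_equal(bd2$value[bd2$term == "SR -> SRR"], -term1)

  # scaling a weight scales only its terms
  bd3 <- total_objective(net, toy, objective_weights(w_desired = 2))
  expect_equal(bd3$value[bd3$type == "desired"],
               2 * bd$value[bd$type == "desired"])
  expect_equal(bd3$value[bd3$type == "rbs"], bd$value[bd$type == "rbs"])

  expect_equal(glance(bd)$total, objective_total(bd))
})

test_that("structural sub-objectives enter the breakdown", {
  net <- fixture_au$network
  target <- fold_mfe(fixture_au$sequences[["SRR"]], model = toy)$structure
  net$subobjectives <- list(SRR = target)
  bd <- total_objective(net, toy)
  expect_equal(bd$value[bd$term == "structure:SRR"], 0)
  # a fully unpaired target is missed by every stem pair
  net$subobjectives <- list(SRR = strrep(".", nchar(target)))
  bd2 <- total_objective(net, toy)
  expect_gt(bd2$value[bd2$term == "structure:SRR"], 0)
})

test_that("the planted solution outscores random assignments", {
  net <- fixture_au$network
  planted <- objective_total(total_objective(net, toy))
  lens <- setNames(net$species$length, net$species$id)
  set.seed(31)
  worse <- 0
  for (i in 1:100) {
    seqs <- lapply(lens, function(n) random_rna(n))
    bd <- total_objective(set_sequences(net, seqs), toy)
    if (objective_total(bd) > planted) worse <- worse + 1
  }
  expect_gte(worse, 99)
})
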