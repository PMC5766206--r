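# Correlation testing, induction-state objective energies and the
# energy/activity regression.

test_that("pearson_r validates its inputs", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_error(pearson_r(1:2, 1:2), class = "ribochain_input_error")
  expect_error(pearson_r(1:5, rep(1, 5)), class = "ribochain_input_error")
  # orthogonalized vectors correlate to numerical zero
  set.seed(5)
  x <- rnorm(50)
  y <- rnorm(50)
  y <- y - mean(y) - cor(x, y) * 0  # raw noise
  y <- residuals(lm(y ~ x))        # Gram-Schmidt step against x
  expect_lt(abs(pearson_r(x, y)), 1e-12)
})

test_that("the Student t-based correlation test matches cor.test", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    ct <- cor.test(x, y)
    res <- correlation_test(cor(x, y), n)
    expect_equal(res$t, unname(ct$statistic), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ct$parameter))
  }
})

test_that("correlation test edge cases behave as documented", {
  expect_equal(correlation_test(0, 10)$t, 0)
  expect_equal(correlation_test(0, 10)$p, 1)
  d <- correlation_test(1, 5)
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
  expect_error(correlation_test(0.5, 2), class = "ribochain_input_error")
  # symmetry in the sign of r; monotone decreasing in |r|
  expect_equal(correlation_test(0.4, 12)$p, correlation_test(-0.4, 12)$p)
  ps <- vapply(seq(0.05, 0.95, by = 0.1),
               function(r) correlation_test(r, 12)$p, 0.0)
  expect_true(all(diff(ps) < 0))
})

test_that("induction-state energies decompose into their components", {
  net <- fixture_au$network
  expect_equal(induction_objective_energy(net, "uninduced", toy), 0)

  # 'both': platform interaction energetics plus RBS de-repression in the
  # full complex, each recomputed independently here
  seqs <- fixture_au$sequences
  cx12 <- assemble_complex(seqs[c("SR", "SRR")], model = toy)
  prow <- net$interactions[2, ]
  e <- interaction_energetics(cx12, seqs[["SRRR"]], prow$up_window[[1]],
                              prow$down_window[[1]], up_strand = "SRR",
                              model = toy)
  cx <- assemble_complex(seqs, model = toy)
  derep <- opening_energy(cx, net$rbs_window, toy, strand = "SRRR")
  expect_equal(induction_objective_energy(net, "both", toy),
               e$dG_hyb + e$dG_act + derep)

  # IPTG alone activates only SR, which shares no complementarity with the
  # 5' UTR in this fixture: the hybridization term vanishes
  e_iptg <- induction_objective_energy(net, "IPTG", toy)
  ie <- interaction_energetics(seqs[["SR"]], seqs[["SRRR"]],
                               net$interactions$up_window[[1]],
                               prow$down_window[[1]], model = toy)
  expect_equal(ie$dG_hyb, 0)
  # remaining energy is activation plus residual RBS occlusion
  expect_gte(e_iptg, 0)
  # aTc alone (SRR without its trigger) cannot open the platform either
  expect_gt(induction_objective_energy(net, "aTc", toy),
            induction_objective_energy(net, "both", toy))
})

test_that("the regression recovers the thermodynamic identity exactly", {
  RT <- 1.987e-3 * 310.15
  dG <- seq(-9, -2, length.out = 12)
  rec <- data.frame(energy = dG, measured = kd_from_energy(dG))
  fit <- energy_activity_regression(rec)
  expect_equal(fit$slope, 1 / RT, tolerance = 1e-9)
  expect_equal(fit$cor$r, 1, tolerance = 1e-12)
  expect_true(fit$cor$degenerate)
  expect_error(
    energy_activity_regression(data.frame(energy = dG, measured = rep(2, 12))),
    class = "ribochain_input_error")
  expect_error(
    energy_activity_regression(data.frame(energy = dG,
                                          measured = rep(-1, 12))),
    class = "ribochain_input_error")
  g <- glance(fit)
  expect_true(all(c("slope", "r", "p.value") %in% names(g)))
})

test_that("the regression recovers a noisy generating slope", {
  RT <- 1.987e-3 * 310.15
  set.seed(2024)
  hits <- 0
  for (rep in 1:100) {
    dG <- runif(12, -10, -2)
    logkd <- dG / RT + rnorm(12, sd = 0.5)
    fit <- energy_activity_regression(
      data.frame(energy = dG, measured = exp(logkd)))
    se <- summary(fit$fit)$coefficients[2, 2]
    if (abs(fit$slope - 1 / RT) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
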