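# Monte Carlo simulated annealing: proposals, acceptance, determinism and
# convergence.

test_that("proposals mutate exactly one mutable position", {
  seqs <- list(a = "ACGU", b = "GGGG")
  masks <- list(a = c(FALSE, FALSE, TRUE, FALSE), b = rep(FALSE, 4))
  set.seed(1)
  for (i in 1:20) {
    p <- propose_mutation(seqs, masks)
    expect_equal(p$species, "a")
    expect_equal(p$pos, 2)
    expect_identical(p$seqs$b, "GGGG")
    diff <- which(strsplit(p$seqs$a, "")[[1]] != strsplit(seqs$a, "")[[1]])
    expect_equal(diff, 3)
    expect_true(p$to != p$from)
  }
  expect_error(propose_mutation(seqs, list(a = rep(FALSE, 4), b = rep(FALSE, 4))),
               class = "ribochain_config_error")
})

test_that("proposal positions are uniform over the joint mask", {
  seqs <- list(a = strrep("A", 6), b = strrep("C", 4))
  masks <- list(a = rep(TRUE, 6), b = rep(TRUE, 4))
  set.seed(42)
  hits <- table(replicate(10000, {
    p <- propose_mutation(seqs, masks)
    paste(p$species, p$pos)
  }))
  expect_equal(length(hits), 10)
  expect_gt(chisq.test(as.numeric(hits))$p.value, 0.01)
})

test_that("Metropolis acceptance follows the annealing law", {
  expect_true(metropolis_accept(-1, 0.5))
  expect_true(metropolis_accept(0, 0.5))
  expect_error(metropolis_accept(1, 0), class = "ribochain_input_error")
  set.seed(7)
  # delta = temperature: closed-form acceptance probability exp(-1)
  acc <- mean(replicate(1e5, metropolis_accept(2, 2)))
  expect_lt(abs(acc - exp(-1)), 0.01)
  # delta -> infinity is never accepted
  set.seed(8)
  expect_false(any(replicate(200, metropolis_accept(1e6, 1))))
})

test_that("annealing the proposal/acceptance loop recovers a known optimum", {
  target <- "ACGUACGUACGU"
  tch <- strsplit(target, "")[[1]]
  hamming <- function(s) sum(strsplit(s, "")[[1]] != tch)
  masks <- list(x = rep(TRUE, 12))
  for (sd in 1:10) {
    set.seed(sd)
    seqs <- list(x = random_rna(12))
    cur <- hamming(seqs$x)
    for (step in 1:5000) {
      if (cur == 0) break
      p <- propose_mutation(seqs, masks)
      d <- hamming(p$seqs$x) - cur
      if (metropolis_accept(d, 1e-6)) { seqs <- p$seqs; cur <- cur + d }
    }
    expect_equal(cur, 0)
  }
})

test_that("design runs are reproducible and best-so-far is monotone", {
  net <- fixture_au$network
  sched <- anneal_schedule(t_initial = 3, cooling = 0.9,
                           steps_per_temperature = 10, n_temperatures = 4)
  r1 <- design(net, schedule = sched, seed = 99, model = toy)
  r2 <- design(net, schedule = sched, seed = 99, model = toy)
  expect_identical(r1$best_sequences, r2$best_sequences)
  expect_identical(r1$trace, r2$trace)
  expect_equal(nrow(r1$trace), 40)
  expect_true(all(diff(r1$trace$best) <= 0))
  expect_equal(r1$best_objective, min(r1$trace$best))
  expect_error(design(net, schedule = sched, model = toy),
               class = "ribochain_input_error")  # seed is mandatory
})

test_that("a zero-length schedule evaluates the initial sequences", {
  net <- fixture_au$network
  sched <- anneal_schedule(n_temperatures = 0)
  r <- design(net, schedule = sched, seed = 5, model = toy)
  expect_equal(nrow(r$trace), 0)
  expect_identical(r$best_sequences,
                   setNames(as.list(fixture_au$sequences),
                            names(fixture_au$sequences)))
  expect_equal(r$best_objective,
               objective_total(total_objective(net, toy)))
})

test_that("sequential design never mutates frozen species", {
  net <- fixture_au$network
  # freeze SR and SRR; design only the platform
  net$species$mutable[[1]] <- rep(FALSE, net$species$length[1])
  net$species$mutable[[2]] <- rep(FALSE, net$species$length[2])
  sched <- anneal_schedule(t_initial = 3, cooling = 0.9,
                           steps_per_temperature = 25, n_temperatures = 4)
  r <- design(net, schedule = sched, seed = 17, model = toy)
  expect_identical(r$best_sequences$SR, fixture_au$sequences[["SR"]])
  expect_identical(r$best_sequences$SRR, fixture_au$sequences[["SRR"]])
})

test_that("evaluate() reproduces a design result and reports all pairs", {
  net <- fixture_au$network
  sched <- anneal_schedule(t_initial = 3, cooling = 0.9,
                           steps_per_temperature = 10, n_temperatures = 3)
  r <- design(net, schedule = sched, seed = 3, model = toy)
  ev <- evaluate(set_sequences(net, r$best_sequences), toy)
  expect_equal(ev$objective, r$best_objective)
  # report rows: declared interactions plus implicit undesired pairs
  expect_equal(nrow(ev$energetics), 4)
  expect_equal(nrow(ev$homodimers), 3)
  expect_true(all(c("accept_rate", "best_objective") %in% names(glance(r))))
  expect_s3_class(tidy(r), "tbl_df")
})

test_that("crossed non-cognate pairs score worse than cognate pairs", {
  m <- crosstalk_matrix(list(A = fixture_au$network, B = fixture_gc$network),
                        model = toy)
  for (i in c("A", "B")) {
    cog <- m$dG_hyb[m$up_network == i & m$cognate]
    non <- m$dG_hyb[m$up_network == i & !m$cognate]
    expect_true(all(cog < non))
  }
})
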