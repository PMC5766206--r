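# Mass-action equilibrium, thermodynamic Kd and the gel mass-fraction
# conversions.

test_that("kd_from_energy implements the closed form", {
  expect_equal(kd_from_energy(0), 1)                       # reference state
  RT <- 1.987e-3 * 310.15
  expect_equal(kd_from_energy(-6), exp(-6 / RT))
  expect_equal(kd_from_energy(-6), 5.9e-5, tolerance = 0.02)
  expect_true(all(diff(kd_from_energy(seq(-10, 0, by = 0.5))) > 0))
  expect_error(kd_from_energy(-1, temperature = -5),
               class = "ribochain_input_error")
})

test_that("log(Kd) is exactly linear in the hybridization energy", {
  dG <- seq(-12, -0.5, length.out = 25)
  lk <- log(kd_from_energy(dG))
  fit <- lm(lk ~ dG)
  RT <- 1.987e-3 * 310.15
  expect_equal(unname(coef(fit)[2]), 1 / RT, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("the two-species equilibrium matches the quadratic closed form", {
  sys <- equilibrium_system(c(A = 1e-6, B = 1e-6),
                            data.frame(complex = "AB", r1 = "A", r2 = "B",
                                       kd = 1e-6))
  st <- solve_equilibrium(sys)
  ab <- st$concentration[st$species == "AB"]
  expect_equal(ab, (3 - sqrt(5)) / 2 * 1e-6, tolerance = 1e-9)
  expect_lt(attr(st, "residual"), 1e-9)

  # extreme Kd limits
  weak <- solve_equilibrium(equilibrium_system(
    c(A = 1e-6, B = 1e-6),
    data.frame(complex = "AB", r1 = "A", r2 = "B", kd = 1e6)))
  expect_lt(weak$concentration[weak$species == "AB"], 1e-17)
  tight <- solve_equilibrium(equilibrium_system(
    c(A = 1e-6, B = 2e-6),
    data.frame(complex = "AB", r1 = "A", r2 = "B", kd = 1e-18)))
  expect_equal(tight$concentration[tight$species == "AB"], 1e-6,
               tolerance = 1e-5)
})

test_that("per-strand conservation holds in randomized chain systems", {
  set.seed(77)
  for (i in 1:20) {
    totals <- c(A = runif(1, 0.1, 5) * 1e-6, B = runif(1, 0.1, 5) * 1e-6,
                C = runif(1, 0.1, 5) * 1e-6)
    rx <- data.frame(complex = c("AB", "ABC"),
                     r1 = c("A", "AB"), r2 = c("B", "C"),
                     kd = 10^runif(2, -9, -3))
    st <- solve_equilibrium(equilibrium_system(totals, rx))
    expect_lt(attr(st, "residual"), 1e-9)
    expect_true(all(st$concentration >= 0))
    # total mass is conserved across bands
    mws <- c(A = 30000, B = 35000, C = 40000)
    mf <- mass_fractions(st, equilibrium_system(totals, rx), mws)
    expect_equal(sum(mf$mass_fraction), 1, tolerance = 1e-9)
  }
})

test_that("gel mass fractions convert to the hand-derived apparent Kd", {
  # ~20 ng of each strand in a 20 uL mix, both 30 kDa, half the mass in
  # the complex band
  kd <- mass_fraction_to_kd(0.5, mass_a = 20, mass_b = 20, volume = 20e-6,
                            mw_a = 30000, mw_b = 30000)
  expect_equal(kd, 20e-9 / 30000 / 2 / 20e-6, tolerance = 1e-9)
  expect_equal(kd, 1.6667e-8, tolerance = 1e-4)

  sat <- mass_fraction_to_kd(1, 20, 20, 20e-6, 30000, 30000)
  expect_equal(as.numeric(sat), 0)
  expect_equal(attr(sat, "flag"), "saturated")
  none <- mass_fraction_to_kd(0, 20, 20, 20e-6, 30000, 30000)
  expect_true(is.infinite(none))
  expect_error(mass_fraction_to_kd(0.9, 10, 30, 20e-6, 30000, 30000),
               class = "ribochain_input_error")
})

test_that("mass fraction and apparent Kd are exact inverses", {
  set.seed(88)
  for (i in 1:40) {
    f <- runif(1, 0.01, 0.99)
    ma <- runif(1, 5, 50); mb <- runif(1, 5, 50)
    mwa <- runif(1, 2e4, 6e4); mwb <- runif(1, 2e4, 6e4)
    # skip stoichiometrically impossible fractions
    ok <- tryCatch({
      kd <- mass_fraction_to_kd(f, ma, mb, 20e-6, mwa, mwb); TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    back <- predict_mass_fraction(kd, ma, mb, 20e-6, mwa, mwb)
    expect_equal(back, f, tolerance = 1e-9)
  }
  # Kd = 0 with equimolar equal-MW partners consumes everything
  expect_equal(predict_mass_fraction(0, 20, 20, 20e-6, 30000, 30000), 1)
})

test_that("molecular weights come from the sequence when not supplied", {
  expect_equal(mw_rna("ACGU"),
               329.21 + 305.18 + 345.21 + 306.17 + 18.02)
  kd1 <- mass_fraction_to_kd(0.4, 20, 20, 20e-6,
                             seq_a = strrep("A", 30), seq_b = strrep("U", 30))
  expect_gt(kd1, 0)
})
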