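test_that("1:1 equilibrium matches its closed form and limits", {
  expect_identical(solveEquilibrium1to1(1e-6, 1e-6, 0), 0)
  # quadratic root (3e-6 - sqrt(5)*1e-6)/2 for P = Q = 1e-6, Ka = 1e6
  expect_equal(solveEquilibrium1to1(1e-6, 1e-6, 1e6),
               (3e-6 - sqrt(5) * 1e-6) / 2, tolerance = 1e-12)
  # stoichiometric limit at huge Ka
  expect_equal(solveEquilibrium1to1(1e-6, 2.5e-6, 1e15), 1e-6,
               tolerance = 1e-9)
  expect_equal(solveEquilibrium1to1(4e-6, 1.5e-6, 1e15), 1.5e-6,
               tolerance = 1e-9)
  expect_error(solveEquilibrium1to1(-1e-6, 1e-6, 1e6), ">= 0")
})

test_that("closed-form solver agrees with bisection across a parameter sweep", {
  set.seed(99)
  for (i in 1:60) {
    P <- 10^runif(1, -9, -4)
    Q <- 10^runif(1, -9, -4)
    Ka <- 10^runif(1, 2, 12)
    x <- solveEquilibrium1to1(P, Q, Ka)
    xo <- bisect1to1(P, Q, Ka)
    expect_equal(x, xo, tolerance = 1e-10,
                 info = sprintf("P=%g Q=%g Ka=%g", P, Q, Ka))
    # the root satisfies the mass-action condition Ka [P_free][Q_free] = [PQ]
    expect_equal(Ka * (P - x) * (Q - x), x, tolerance = 1e-6)
  }
})

test_that("equilibrium is monotone in Ka and in either total", {
  Kas <- 10^seq(2, 10, length.out = 20)
  expect_true(all(diff(solveEquilibrium1to1(1.6e-6, 2e-6, Kas)) >= 0))
  Ps <- seq(1e-7, 5e-6, length.out = 20)
  expect_true(all(diff(solveEquilibrium1to1(Ps, 2e-6, 1e6)) >= 0))
  Qs <- seq(0, 5e-6, length.out = 20)
  expect_true(all(diff(solveEquilibrium1to1(1.6e-6, Qs, 1e6)) >= 0))
})

test_that("competitive solver reduces, symmetrizes and conserves mass", {
  # marker absent: identical to the 1:1 solver
  red <- solveEquilibriumCompetitive(1.6e-6, 2e-6, 0, 3.98e6, 1e6)
  expect_equal(unname(red["PQ"]),
               solveEquilibrium1to1(1.6e-6, 2e-6, 3.98e6),
               tolerance = 1e-10)
  expect_equal(unname(red["PM"]), 0)

  # symmetric ligands bind equally
  sym <- solveEquilibriumCompetitive(1.6e-6, 2e-6, 2e-6, 1e6, 1e6)
  expect_equal(unname(sym["PQ"]), unname(sym["PM"]), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:25) {
    P <- 10^runif(1, -8, -5); Q <- 10^runif(1, -8, -5)
    M <- 10^runif(1, -8, -5)
    KaQ <- 10^runif(1, 3, 9); KaM <- 10^runif(1, 3, 9)
    eq <- solveEquilibriumCompetitive(P, Q, M, KaQ, KaM)
    # all three mass balances to 1e-12 relative
    expect_equal(eq[["P_free"]] + eq[["PQ"]] + eq[["PM"]], P,
                 tolerance = 1e-12)
    expect_equal(eq[["Q_free"]] + eq[["PQ"]], Q, tolerance = 1e-12)
    expect_equal(eq[["M_free"]] + eq[["PM"]], M, tolerance = 1e-12)
  }
})

test_that("competitive solver agrees with the brute-force grid oracle", {
  set.seed(13)
  for (i in 1:15) {
    P <- 10^runif(1, -7, -5); Q <- 10^runif(1, -7, -5)
    M <- 10^runif(1, -7, -5)
    KaQ <- 10^runif(1, 4, 8); KaM <- 10^runif(1, 4, 8)
    eq <- solveEquilibriumCompetitive(P, Q, M, KaQ, KaM)
    or <- bruteCompetitive(P, Q, M, KaQ, KaM)
    expect_equal(eq[["PQ"]], or[["PQ"]], tolerance = 1e-6)
    expect_equal(eq[["PM"]], or[["PM"]], tolerance = 1e-6)
  }
})

test_that("identical configs give bit-identical series", {
  cfg <- simConfig(seed = 123L, noiseSigmaFrac = 0.02)
  a <- simulateTitration(cfg)
  b <- simulateTitration(cfg)
  expect_identical(intensities(a$series), intensities(b$series))
  c <- simulateTitration(simConfig(seed = 124L, noiseSigmaFrac = 0.02))
  expect_false(identical(intensities(a$series), intensities(c$series)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulateTitration(simConfig(seed = 1L)))
  expect_identical(.Random.seed, before)
})

test_that("dynamic-model data return the generating Stern-Volmer constant", {
  sim <- simulateTitration(simConfig("dynamic", KsvTrue = 2.51e5,
                                     noiseSigmaFrac = 0))
  res <- sternVolmerFit(extractQuenchCurve(sim$series))
  expect_equal(res@Ksv, 2.51e5, tolerance = 1e-10)
})

test_that("static-model data return the generating Ka through the full chain", {
  sim <- simulateTitration(simConfig(KaTrue = 1e6, noiseSigmaFrac = 0))
  fit <- doubleLogFit(extractQuenchCurve(sim$series), 1.6e-6)
  expect_equal(fit@Ka, 1e6, tolerance = 1e-3)
  expect_equal(fit@nSites, 1, tolerance = 1e-3)
})

test_that("a dim complex raises F relative to the dark-complex model", {
  dark <- simulateTitration(simConfig(noiseSigmaFrac = 0))
  dim <- simulateTitration(simConfig(noiseSigmaFrac = 0,
                                     complexBrightness = 0.3))
  fD <- extractQuenchCurve(dark$series)@F
  fB <- extractQuenchCurve(dim$series)@F
  expect_true(all(fB[-1] > fD[-1]))
})

test_that("multi-temperature study reproduces the generating thermodynamics", {
  st <- simulateStudy(simConfig(temperatures = c(298, 303, 308),
                                deltaH = 95970, deltaS = 448.58,
                                noiseSigmaFrac = 0))
  Ka <- vapply(st$series, function(s)
    doubleLogFit(extractQuenchCurve(s), proteinConc(s))@Ka, numeric(1))
  th <- vantHoffFit(Ka, c(298, 303, 308))
  expect_equal(th@deltaH, 95970, tolerance = 0.01)
  expect_equal(th@deltaS, 448.58, tolerance = 0.01)
  expect_equal(unname(st$truth$Ka_by_T),
               exp(-95970 / (8.314 * c(298, 303, 308)) + 448.58 / 8.314))
})
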