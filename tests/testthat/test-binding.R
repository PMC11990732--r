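test_that("double-log plot is exactly linear with slope 1 for 1:1 noise-free data", {
  # analytic oracle: under 1:1 mass action with a dark complex,
  # (F0-F)/F = [PQ]/[P_free] and [Q] - [P](F0-F)/F0 = [Q_free], so the
  # regression is exactly y = log10(Ka) + 1 * x
  for (Ka in c(1e5, 1e6, 3.98e6)) {
    fit <- doubleLogFit(makeStaticCurve(Ka), proteinConc = 1.6e-6)
    expect_equal(fit@Ka, Ka, tolerance = 1e-3)
    expect_equal(fit@nSites, 1, tolerance = 1e-3)
    expect_equal(fit@Rsquared, 1, tolerance = 1e-10)
    expect_identical(fit@pointsDropped, 0L)
  }
})

test_that("a curve generated from the 298 K table constant refits to it", {
  fit <- doubleLogFit(makeStaticCurve(3.98e6), proteinConc = 1.6e-6)
  expect_equal(log10(fit@Ka), log10(3.98e6), tolerance = 0.01)
})

test_that("degenerate curves are rejected", {
  flat <- QuenchCurve(seq(0, 3.2e-6, length.out = 5), 1000, rep(1000, 5))
  expect_error(doubleLogFit(flat, 1.6e-6), "no quenching signal")
  short <- QuenchCurve(c(0, 1e-6, 2e-6), 1000, c(1000, 900, 800))
  expect_error(doubleLogFit(short, 1.6e-6), ">= 3 positive-concentration")
})

test_that("points with non-positive log arguments are dropped and counted", {
  cv <- makeStaticCurve(1e6)
  # make the first positive-concentration point quench-free: dF = 0 there
  F <- cv@F
  F[2] <- cv@F0
  cv2 <- QuenchCurve(cv@concentrations, cv@F0, F)
  fit <- doubleLogFit(cv2, 1.6e-6)
  expect_identical(fit@pointsDropped, 1L)
  expect_identical(fit@pointsUsed, 7L)
})

test_that("log10 Ka estimates concentrate on the truth as noise shrinks", {
  # consistency: at 0.2% intensity noise the estimator sits close to the
  # generating constant (fixed-wavelength reading avoids the argmax
  # selection bias that noisy peak-picking introduces)
  err <- function(noise) {
    cfg <- simConfig(KaTrue = 1e6, noiseSigmaFrac = noise)
    vapply(1:25, function(i) {
      cfg$seed <- 1000L + i
      sim <- simulateTitration(cfg)
      cv <- extractQuenchCurve(sim$series, mode = "fixed", wavelength = 337)
      log10(doubleLogFit(cv, 1.6e-6)@Ka) - 6
    }, numeric(1))
  }
  eLow <- err(0.002)
  eHigh <- err(0.01)
  expect_lt(median(abs(eLow)), 0.2)
  expect_lt(median(abs(eLow)), median(abs(eHigh)))
})

test_that("displacement percentages and site call follow the strict rule", {
  mk <- function(Ka) new("BindingResult", Ka = Ka, log10KaStderr = 0.01,
                         nSites = 1.2, nStderr = 0.01, Rsquared = 0.99,
                         temperature = 298, pointsUsed = 8L,
                         pointsDropped = 0L)
  d <- displacementAnalysis(mk(3.98e6), mk(3.47e5), mk(3.55e6))
  expect_equal(d@pctReductionSite1, 100 * (3.98e6 - 3.47e5) / 3.98e6)
  expect_equal(round(d@pctReductionSite1, 2), 91.28)
  expect_equal(round(d@pctReductionSite2, 2), 10.80)
  expect_identical(d@siteCall, "site_I")

  # no displacement at all
  d0 <- displacementAnalysis(mk(3.98e6), mk(3.98e6), mk(3.98e6))
  expect_equal(d0@pctReductionSite1, 0)
  expect_identical(d0@siteCall, "indeterminate")

  # apparent enhancement by both markers: warning, not an error
  expect_warning(
    dneg <- displacementAnalysis(mk(1e6), mk(2e6), mk(3e6)),
    "indeterminate")
  expect_identical(dneg@siteCall, "indeterminate")

  # temperature mismatch is an error
  mk303 <- mk(3.47e5); mk303@temperature <- 303
  expect_error(displacementAnalysis(mk(3.98e6), mk303, mk(3.55e6)),
               "temperature")
})

test_that("displacement percentages are invariant to rescaling all Ka", {
  mk <- function(Ka) new("BindingResult", Ka = Ka, log10KaStderr = 0.01,
                         nSites = 1, nStderr = 0.01, Rsquared = 0.99,
                         temperature = 298, pointsUsed = 8L,
                         pointsDropped = 0L)
  a <- displacementAnalysis(mk(4e6), mk(4e5), mk(3.6e6))
  b <- displacementAnalysis(mk(4e9), mk(4e8), mk(3.6e9))
  expect_equal(a@pctReductionSite1, b@pctReductionSite1)
  expect_equal(a@pctReductionSite2, b@pctReductionSite2)
  expect_identical(a@siteCall, b@siteCall)
})

test_that("competitive simulation depresses the apparent binding constant", {
  base <- simConfig(KaTrue = 3.98e6, noiseSigmaFrac = 0)
  comp <- simConfig("static_competitive", KaTrue = 3.98e6,
                    markerKa = 5e6, markerConc = 1.6e-6,
                    noiseSigmaFrac = 0)
  kaBinary <- doubleLogFit(extractQuenchCurve(simulateTitration(base)$series),
                           1.6e-6)@Ka
  kaTernary <- doubleLogFit(extractQuenchCurve(simulateTitration(comp)$series),
                            1.6e-6)@Ka
  expect_lt(kaTernary, kaBinary)
})
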