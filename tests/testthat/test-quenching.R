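test_that("Stern-Volmer fit recovers the generating constant exactly", {
  # noise-free curves generated from the linear law fit back to >= 10 sig figs
  for (Ksv in c(2.51e5, 1e3, 4.7e7)) {
    res <- sternVolmerFit(makeSvCurve(Ksv))
    expect_equal(res@Ksv, Ksv, tolerance = 1e-10)
    expect_equal(res@intercept, 1, tolerance = 1e-9)
    expect_equal(res@Rsquared, 1, tolerance = 1e-12)
  }
})

test_that("bimolecular rate constant is Ksv/tau0", {
  res <- sternVolmerFit(makeSvCurve(2.51e5), tau0 = 1e-8)
  expect_equal(res@Kq, 2.51e13, tolerance = 1e-10)
  res2 <- sternVolmerFit(makeSvCurve(2.51e5), tau0 = 8e-9)
  expect_equal(res2@Kq, res2@Ksv / 8e-9)
})

test_that("no quenching gives a zero slope", {
  cv <- QuenchCurve(c(0, 1e-6, 2e-6, 3e-6), 1000, rep(1000, 4))
  res <- sternVolmerFit(cv)
  expect_equal(res@Ksv, 0)
  expect_equal(res@Rsquared, 1)  # degenerate flat line, reported as perfect
})

test_that("Ksv is invariant to intensity rescaling", {
  base <- makeSvCurve(3.3e5)
  for (c0 in c(0.01, 7, 1e4)) {
    scaled <- QuenchCurve(base@concentrations, c0 * base@F0, c0 * base@F)
    expect_equal(sternVolmerFit(scaled)@Ksv,
                 sternVolmerFit(base)@Ksv, tolerance = 1e-12)
  }
})

test_that("fit preconditions are enforced", {
  expect_error(sternVolmerFit(QuenchCurve(c(0, 1e-6), 1000, c(1000, 900))),
               "3 distinct concentrations")
  expect_error(
    sternVolmerFit(QuenchCurve(c(0, 0, 0), 1000, c(1000, 1000, 1000))),
    "3 distinct concentrations")
})

test_that("static-model data yield a dilute-limit slope near the generating Ka", {
  # with [P] tiny and Ka*[Q] << 1, F0/F = 1 + Ka*[Q] almost exactly
  Ka <- 1e6
  cv <- makeStaticCurve(Ka, P = 1e-9, concs = seq(0, 5e-8, length.out = 9))
  expect_equal(sternVolmerFit(cv)@Ksv, Ka, tolerance = 0.01)
})

test_that("mechanism classification separates static, dynamic and conflicting evidence", {
  fitAt <- function(Ksv, tK)
    sternVolmerFit(makeSvCurve(Ksv, temperature = tK))

  # falling Ksv with temperature + Kq far above the diffusion limit -> static
  static <- classifyMechanism(list(fitAt(2.51e5, 298), fitAt(2.43e5, 303),
                                   fitAt(2.30e5, 308)))
  expect_identical(static@verdict, "static")
  expect_identical(static@ksvTrend, "decreasing")
  expect_true(static@kqExceedsDiffusionLimit)

  # rising Ksv with Kq below the limit -> dynamic
  dynamic <- classifyMechanism(list(fitAt(1.0e2, 298), fitAt(1.2e2, 303),
                                    fitAt(1.4e2, 308)))
  expect_identical(dynamic@verdict, "dynamic")

  # rising trend (dynamic signature) but Kq above the limit -> indeterminate
  conflict <- classifyMechanism(list(fitAt(1.0e3, 298), fitAt(1.2e3, 303),
                                     fitAt(1.4e3, 308)))
  expect_identical(conflict@verdict, "indeterminate")
  expect_identical(conflict@ksvTrend, "increasing")
  expect_true(conflict@kqExceedsDiffusionLimit)

  # ties count as non-monotone
  tie <- classifyMechanism(list(fitAt(2e5, 298), fitAt(2e5, 303)))
  expect_identical(tie@ksvTrend, "non-monotone")
  expect_identical(tie@verdict, "indeterminate")

  expect_error(classifyMechanism(list(fitAt(2e5, 298))),
               ">= 2 temperatures")
})

test_that("classification orders results by temperature before reading the trend", {
  fitAt <- function(Ksv, tK)
    sternVolmerFit(makeSvCurve(Ksv, temperature = tK))
  shuffled <- classifyMechanism(list(fitAt(2.30e5, 308), fitAt(2.51e5, 298),
                                     fitAt(2.43e5, 303)))
  expect_identical(shuffled@verdict, "static")
})
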