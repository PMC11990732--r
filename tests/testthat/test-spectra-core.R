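test_that("titration series constructor enforces its invariants", {
  wl <- 300:450
  f <- 1000 * exp(-(wl - 337)^2 / (2 * 25^2))
  ok <- TitrationSeries(wl, cbind(f, 0.9 * f), c(0, 1e-6),
                        proteinConc = 1.6e-6, temperature = 298,
                        excitationNm = 295)
  expect_s4_class(ok, "TitrationSeries")
  expect_equal(quencherConcs(ok), c(0, 1e-6))

  expect_error(TitrationSeries(rev(wl), cbind(f, f), c(0, 1e-6),
                               1.6e-6, 298, 295),
               "strictly increasing")
  expect_error(TitrationSeries(wl, cbind(f, f), c(1e-6, 2e-6),
                               1.6e-6, 298, 295),
               "quencher_conc = 0")
  expect_error(TitrationSeries(wl, cbind(f, -f), c(0, 1e-6),
                               1.6e-6, 298, 295),
               "finite and >= 0")
  expect_error(TitrationSeries(wl, cbind(f, f), c(0, 1e-6),
                               proteinConc = 0, 298, 295),
               "protein_conc")
})

test_that("write/read round-trips a simulated series within text precision", {
  sim <- simulateTitration(simConfig(seed = 7L, absorbanceScale = 1e4))
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeTitration(sim$series, csv, yml)
  back <- readTitration(csv, yml)
  expect_equal(wavelengths(back), wavelengths(sim$series))
  expect_equal(intensities(back), intensities(sim$series),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(quencherConcs(back), quencherConcs(sim$series))
  expect_equal(proteinConc(back), proteinConc(sim$series))
  expect_equal(temperatureK(back), temperatureK(sim$series))
  expect_equal(colData(back)$absorbance_ex, colData(sim$series)$absorbance_ex,
               tolerance = 1e-12)
})

test_that("readTitration rejects malformed inputs", {
  csv <- withr::local_tempfile(fileext = ".csv")
  meta <- list(protein_conc_M = 1.6e-6, quencher_concs_M = c(0, 1e-6, 2e-6),
               temperature_K = 298, excitation_nm = 295)

  writeLines(c("wl,a,b", "300,1,1", "301,2,2"), csv)
  expect_error(readTitration(csv, meta), "wavelength_nm")

  writeLines(c("wavelength_nm,a,b", "300,1,1", "301,2,2"), csv)
  expect_error(readTitration(csv, meta), "mismatch")

  writeLines(c("wavelength_nm,a,b,c", "301,1,1,1", "300,2,2,2"), csv)
  expect_error(readTitration(csv, meta), "non-monotone")

  expect_error(readTitration(csv, meta[-1]), "missing")
})

test_that("inner-filter correction applies the mean-of-absorbances exponent", {
  expect_identical(innerFilterCorrect(100, 0, 0), 100)
  expect_equal(innerFilterCorrect(100, 0.1, 0.1), 100 * 10^0.1)
  expect_equal(innerFilterCorrect(50, 0.2, 0), 50 * 10^0.1)
  expect_error(innerFilterCorrect(100, -0.1, 0), "negative absorbance")
})

test_that("correction is multiplicative: correcting a sum equals summing corrections", {
  set.seed(11)
  f1 <- runif(50, 0, 100); f2 <- runif(50, 0, 100)
  expect_equal(innerFilterCorrect(f1 + f2, 0.13, 0.07),
               innerFilterCorrect(f1, 0.13, 0.07) +
                 innerFilterCorrect(f2, 0.13, 0.07))
})

test_that("series-level correction uses per-point absorbances and clears them", {
  sim <- simulateTitration(simConfig(noiseSigmaFrac = 0,
                                     absorbanceScale = 1e4))
  aEx <- colData(sim$series)$absorbance_ex
  aEm <- colData(sim$series)$absorbance_em
  cor <- innerFilterCorrect(sim$series)
  expect_false("absorbance_ex" %in% colnames(colData(cor)))
  j <- ncol(sim$series)
  expect_equal(intensities(cor)[, j],
               intensities(sim$series)[, j] * 10^((aEx[j] + aEm[j]) / 2))
  # absent absorbances: no-op
  plain <- simulateTitration(simConfig(noiseSigmaFrac = 0))$series
  expect_identical(intensities(innerFilterCorrect(plain)),
                   intensities(plain))
})

test_that("peak-mode curve extraction recovers the band centre and holds it fixed", {
  sim <- simulateTitration(simConfig(noiseSigmaFrac = 0, KaTrue = 1e6))
  cv <- extractQuenchCurve(sim$series, mode = "peak")
  expect_equal(cv@wavelength, 337, tolerance = 1e-6)
  # F values follow the generator's signal scale at the fixed peak
  expect_equal(cv@F / cv@F0, sim$truth$signal_scale, tolerance = 1e-9)
})

test_that("fixed-wavelength extraction interpolates on the grid", {
  sim <- simulateTitration(simConfig(noiseSigmaFrac = 0))
  cv <- extractQuenchCurve(sim$series, mode = "fixed", wavelength = 360.5)
  wl <- wavelengths(sim$series)
  manual <- apply(intensities(sim$series), 2,
                  function(f) approx(wl, f, xout = 360.5)$y)
  expect_equal(unname(cv@F), unname(manual))
  expect_error(extractQuenchCurve(sim$series, mode = "fixed",
                                  wavelength = 500),
               "outside the grid")
  expect_error(extractQuenchCurve(sim$series, mode = "fixed"),
               "requires a wavelength")
})

test_that("identical spectra give F/F0 = 1 everywhere", {
  wl <- 300:450
  f <- 800 * exp(-(wl - 337)^2 / 900)
  ts <- TitrationSeries(wl, cbind(f, f, f, f), c(0, 1e-6, 2e-6, 3e-6),
                        1.6e-6, 298, 295)
  cv <- extractQuenchCurve(ts)
  expect_equal(cv@F / cv@F0, rep(1, 4))
})

test_that("noise-free quenching intensities are non-increasing in concentration", {
  for (mech in c("static_1to1", "dynamic")) {
    sim <- simulateTitration(simConfig(mech, noiseSigmaFrac = 0))
    cv <- extractQuenchCurve(sim$series)
    expect_true(all(diff(cv@F) <= 0), info = mech)
  }
})

test_that("quench-curve validity ties F0 to the zero-concentration point", {
  expect_error(QuenchCurve(c(0, 1e-6), 1000, c(900, 800)),
               "zero concentration")
  expect_error(QuenchCurve(c(0, 1e-6), 1000, c(1000, -5)), "finite and > 0")
  expect_s4_class(QuenchCurve(c(0, 1e-6), 1000, c(1000, 900)),
                  "QuenchCurve")
})
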