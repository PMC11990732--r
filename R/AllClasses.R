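#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData assay<- colData<-
#' @importFrom stats lm coef rnorm setNames uniroot var
#' @importFrom utils packageVersion
NULL

#' Single emission (or synchronous) spectrum
#'
#' One fluorescence scan at a fixed quencher concentration: intensity versus
#' wavelength, together with the acquisition conditions. Absorbances at the
#' excitation and emission wavelengths are optional (`NA` when not recorded)
#' and are only needed for the inner-filter correction.
#'
#' @slot wavelengths numeric, strictly increasing wavelength grid (nm).
#' @slot intensities numeric, fluorescence intensities (a.u.), same length as
#'   `wavelengths`, finite and non-negative.
#' @slot excitationNm numeric(1), excitation wavelength (nm).
#' @slot temperature numeric(1), temperature (K).
#' @slot quencherConc numeric(1), total quencher concentration (mol/L).
#' @slot absorbanceEx numeric(1), optical density at the excitation
#'   wavelength, or `NA`.
#' @slot absorbanceEm numeric(1), optical density at the emission wavelength,
#'   or `NA`.
#' @exportClass EmissionSpectrum
setClass("EmissionSpectrum",
  representation(
    wavelengths  = "numeric",
    intensities  = "numeric",
    excitationNm = "numeric",
    temperature  = "numeric",
    quencherConc = "numeric",
    absorbanceEx = "numeric",
    absorbanceEm = "numeric"
  ),
  prototype(absorbanceEx = NA_real_, absorbanceEm = NA_real_)
)

setValidity("EmissionSpectrum", function(object) {
  msg <- character()
  w <- object@wavelengths
  f <- object@intensities
  if (length(w) != length(f))
    msg <- c(msg, "wavelengths and intensities must have the same length")
  if (length(w) > 1L && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(!is.finite(f)) || any(f < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@quencherConc) != 1L || object@quencherConc < 0)
    msg <- c(msg, "quencherConc must be a single value >= 0")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single value > 0")
  for (s in c("absorbanceEx", "absorbanceEm")) {
    a <- slot(object, s)
    if (!is.na(a) && a < 0)
      msg <- c(msg, paste(s, "must be >= 0 (negative absorbance flags corrupt input)"))
  }
  if (length(msg)) msg else TRUE
})

#' Fluorescence titration series
#'
#' A set of spectra recorded at fixed protein concentration and increasing
#' total quencher (ligand) concentration at a single temperature, stored as a
#' \linkS4class{SummarizedExperiment}: the `"intensity"` assay is a wavelength
#' x titration-point matrix, `rowData` carries the wavelength grid, `colData`
#' the per-point quencher concentrations (and optional absorbances), and
#' `metadata` the shared conditions (protein concentration, temperature,
#' excitation wavelength, optional synchronous-scan offset, label).
#'
#' The first titration point must be at zero quencher concentration: it
#' defines the unquenched reference intensity F0.
#'
#' @exportClass TitrationSeries
setClass("TitrationSeries", contains = "SummarizedExperiment")

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (!("intensity" %in% assayNames(object)))
    return("assay 'intensity' is required")
  rd <- rowData(object)
  if (!("wavelength_nm" %in% colnames(rd)))
    return("rowData column 'wavelength_nm' is required")
  w <- rd$wavelength_nm
  if (length(w) > 1L && any(diff(w) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  a <- assay(object, "intensity")
  if (any(!is.finite(a)) || any(a < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  cd <- colData(object)
  if (!("quencher_conc" %in% colnames(cd)))
    return("colData column 'quencher_conc' is required")
  q <- cd$quencher_conc
  if (any(q < 0))
    msg <- c(msg, "quencher concentrations must be >= 0")
  if (length(q) && q[1L] != 0)
    msg <- c(msg, "first titration point must have quencher_conc = 0 (defines F0)")
  if (length(q) > 1L && any(diff(q) < 0))
    msg <- c(msg, "quencher concentrations must be ascending")
  md <- metadata(object)
  pc <- md$protein_conc
  if (is.null(pc) || length(pc) != 1L || !is.finite(pc) || pc <= 0)
    msg <- c(msg, "metadata protein_conc must be a single value > 0")
  tK <- md$temperature
  if (is.null(tK) || length(tK) != 1L || !is.finite(tK) || tK <= 0)
    msg <- c(msg, "metadata temperature must be a single value > 0 (K)")
  if (is.null(md$excitation_nm))
    msg <- c(msg, "metadata excitation_nm is required")
  for (s in c("absorbance_ex", "absorbance_em")) {
    if (s %in% colnames(cd) && any(cd[[s]] < 0, na.rm = TRUE))
      msg <- c(msg, paste("colData", s, "must be >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' Quenching curve F0/F versus quencher concentration
#'
#' Intensities read at one wavelength across a titration: the unquenched
#' reference `F0` and the intensity `F` at each total quencher concentration.
#' This is the direct input to \code{\link{sternVolmerFit}} and
#' \code{\link{doubleLogFit}}.
#'
#' @slot concentrations numeric, total quencher concentrations (mol/L).
#' @slot F0 numeric(1), unquenched intensity (a.u.), > 0.
#' @slot F numeric, intensity at each concentration (a.u.), > 0.
#' @slot temperature numeric(1), temperature (K).
#' @slot wavelength numeric(1), wavelength at which intensities were read (nm);
#'   may be `NA` for externally supplied curves.
#' @exportClass QuenchCurve
setClass("QuenchCurve",
  representation(
    concentrations = "numeric",
    F0             = "numeric",
    F              = "numeric",
    temperature    = "numeric",
    wavelength     = "numeric"
  ),
  prototype(wavelength = NA_real_)
)

setValidity("QuenchCurve", function(object) {
  msg <- character()
  if (length(object@concentrations) != length(object@F))
    msg <- c(msg, "concentrations and F must have the same length")
  if (length(object@F0) != 1L || !is.finite(object@F0) || object@F0 <= 0)
    msg <- c(msg, "F0 must be a single positive value")
  if (any(!is.finite(object@F)) || any(object@F <= 0))
    msg <- c(msg, "all F must be finite and > 0")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be >= 0")
  i0 <- which(object@concentrations == 0)
  if (length(i0) && any(abs(object@F[i0] - object@F0) >
                        1e-9 * abs(object@F0)))
    msg <- c(msg, "F at zero concentration must equal F0")
  if (length(msg)) msg else TRUE
})

#' Stern-Volmer fit result
#'
#' @slot Ksv numeric(1), Stern-Volmer quenching constant (L/mol), the slope of
#'   F0/F on quencher concentration.
#' @slot KsvStderr numeric(1), standard error of the slope (L/mol).
#' @slot intercept numeric(1), freely fitted intercept of the Stern-Volmer line.
#' @slot Kq numeric(1), bimolecular quenching rate constant Ksv/tau0
#'   (L mol^-1 s^-1).
#' @slot tau0 numeric(1), unquenched fluorophore lifetime (s).
#' @slot Rsquared numeric(1), squared Pearson correlation of the line.
#' @slot temperature numeric(1), K.
#' @slot nPoints integer(1), points used in the fit.
#' @exportClass QuenchingResult
setClass("QuenchingResult",
  representation(
    Ksv = "numeric", KsvStderr = "numeric", intercept = "numeric",
    Kq = "numeric", tau0 = "numeric", Rsquared = "numeric",
    temperature = "numeric", nPoints = "integer"
  )
)

setValidity("QuenchingResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@Kq, object@Ksv / object@tau0,
                        tolerance = 1e-12)))
    msg <- c(msg, "Kq must equal Ksv / tau0")
  if (object@Rsquared < 0 || object@Rsquared > 1 + 1e-12)
    msg <- c(msg, "Rsquared must lie in [0, 1]")
  if (object@nPoints < 3L)
    msg <- c(msg, "nPoints must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Quenching-mechanism classification
#'
#' @slot verdict character(1), one of `"static"`, `"dynamic"`,
#'   `"indeterminate"`.
#' @slot ksvTrend character(1), temperature trend of Ksv: `"decreasing"`,
#'   `"increasing"` or `"non-monotone"`.
#' @slot kqExceedsDiffusionLimit logical(1), whether every Kq exceeds the
#'   diffusion-limited maximum for collisional quenching.
#' @slot evidence character(1), human-readable summary of both criteria.
#' @exportClass MechanismCall
setClass("MechanismCall",
  representation(
    verdict = "character", ksvTrend = "character",
    kqExceedsDiffusionLimit = "logical", evidence = "character"
  )
)

setValidity("MechanismCall", function(object) {
  msg <- character()
  if (!object@verdict %in% c("static", "dynamic", "indeterminate"))
    msg <- c(msg, "unknown verdict")
  if (!object@ksvTrend %in% c("decreasing", "increasing", "non-monotone"))
    msg <- c(msg, "unknown ksvTrend")
  if (object@verdict == "static" &&
      !(object@ksvTrend == "decreasing" || object@kqExceedsDiffusionLimit))
    msg <- c(msg, "static verdict requires decreasing Ksv trend or Kq above the diffusion limit")
  if (length(msg)) msg else TRUE
})

#' Double-logarithm binding fit result
#'
#' @slot Ka numeric(1), apparent binding constant (L/mol).
#' @slot log10KaStderr numeric(1), standard error of the fitted intercept
#'   log10(Ka).
#' @slot nSites numeric(1), apparent number of binding sites (slope).
#' @slot nStderr numeric(1), standard error of the slope.
#' @slot Rsquared numeric(1).
#' @slot temperature numeric(1), K.
#' @slot pointsUsed integer(1), titration points entering the regression.
#' @slot pointsDropped integer(1), points excluded for non-positive log
#'   arguments.
#' @exportClass BindingResult
setClass("BindingResult",
  representation(
    Ka = "numeric", log10KaStderr = "numeric",
    nSites = "numeric", nStderr = "numeric", Rsquared = "numeric",
    temperature = "numeric", pointsUsed = "integer",
    pointsDropped = "integer"
  )
)

setValidity("BindingResult", function(object) {
  msg <- character()
  if (!is.finite(object@Ka) || object@Ka <= 0)
    msg <- c(msg, "Ka must be > 0")
  if (object@pointsUsed < 3L)
    msg <- c(msg, "pointsUsed must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Site-marker displacement result
#'
#' Compares the binary (protein + ligand) binding constant with the constants
#' refit in the presence of Sudlow site I and site II markers; the larger
#' percent reduction assigns the site.
#'
#' @slot KaBinary numeric(1), L/mol.
#' @slot KaTernarySite1 numeric(1), L/mol, in presence of the site I marker.
#' @slot KaTernarySite2 numeric(1), L/mol, in presence of the site II marker.
#' @slot pctReductionSite1 numeric(1), percent reduction relative to binary.
#' @slot pctReductionSite2 numeric(1), percent reduction relative to binary.
#' @slot siteCall character(1), `"site_I"`, `"site_II"` or `"indeterminate"`.
#' @exportClass DisplacementResult
setClass("DisplacementResult",
  representation(
    KaBinary = "numeric", KaTernarySite1 = "numeric",
    KaTernarySite2 = "numeric", pctReductionSite1 = "numeric",
    pctReductionSite2 = "numeric", siteCall = "character"
  )
)

setValidity("DisplacementResult", function(object) {
  ok1 <- isTRUE(all.equal(
    object@pctReductionSite1,
    100 * (object@KaBinary - object@KaTernarySite1) / object@KaBinary))
  ok2 <- isTRUE(all.equal(
    object@pctReductionSite2,
    100 * (object@KaBinary - object@KaTernarySite2) / object@KaBinary))
  if (!ok1 || !ok2)
    return("percent reductions must equal 100*(KaBinary - KaTernary)/KaBinary")
  if (!object@siteCall %in% c("site_I", "site_II", "indeterminate"))
    return("unknown siteCall")
  if (object@siteCall == "site_I" &&
      !(object@pctReductionSite1 > object@pctReductionSite2))
    return("site_I call requires strictly larger reduction by the site I marker")
  if (object@siteCall == "site_II" &&
      !(object@pctReductionSite2 > object@pctReductionSite1))
    return("site_II call requires strictly larger reduction by the site II marker")
  TRUE
})

#' Van't Hoff thermodynamics result
#'
#' @slot deltaH numeric(1), standard enthalpy change (J/mol).
#' @slot deltaS numeric(1), standard entropy change (J mol^-1 K^-1).
#' @slot deltaGPerT named numeric, Gibbs energy (J/mol) at each input
#'   temperature (names are temperatures in K).
#' @slot Rsquared numeric(1), of the van't Hoff line.
#' @slot modePerT named character, route used for each Gibbs value:
#'   `"from_HS"` (deltaH - T*deltaS) or `"from_lnKa"` (-RT ln Ka).
#' @slot forceInterpretation character(1), dominant binding force implied by
#'   the signs of deltaH and deltaS: `"hydrophobic"`, `"vdw_or_hbond"`,
#'   `"electrostatic"` or `"other"`.
#' @exportClass ThermoResult
setClass("ThermoResult",
  representation(
    deltaH = "numeric", deltaS = "numeric", deltaGPerT = "numeric",
    Rsquared = "numeric", modePerT = "character",
    forceInterpretation = "character"
  )
)

setValidity("ThermoResult", function(object) {
  msg <- character()
  tK <- as.numeric(names(object@deltaGPerT))
  if (any(is.na(tK)))
    return("deltaGPerT must be named by temperature (K)")
  fromHS <- object@modePerT == "from_HS"
  expect <- object@deltaH - tK * object@deltaS
  if (any(fromHS) && any(abs(object@deltaGPerT[fromHS] - expect[fromHS]) >
                         1e-6 * pmax(abs(expect[fromHS]), 1)))
    msg <- c(msg, "from_HS Gibbs energies must equal deltaH - T*deltaS")
  if (!object@forceInterpretation %in%
      c("hydrophobic", "vdw_or_hbond", "electrostatic", "other"))
    msg <- c(msg, "unknown forceInterpretation")
  if (length(msg)) msg else TRUE
})

#' Docking free-energy record
#'
#' Post-processing of a docking score: unit conversion (thermochemical
#' calorie, 4.184 J/cal) and the implied inhibition constant
#' Ki = exp(deltaG / RT).
#'
#' @slot deltaGkcal numeric(1), docking free energy (kcal/mol).
#' @slot deltaGkJ numeric(1), the same energy in kJ/mol.
#' @slot Ki numeric(1), implied inhibition constant (mol/L).
#' @slot temperature numeric(1), K.
#' @slot siteLabel character(1), free-text binding-site label.
#' @exportClass DockingRecord
setClass("DockingRecord",
  representation(
    deltaGkcal = "numeric", deltaGkJ = "numeric", Ki = "numeric",
    temperature = "numeric", siteLabel = "character"
  )
)

setValidity("DockingRecord", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@deltaGkJ, 4.184 * object@deltaGkcal)))
    msg <- c(msg, "deltaGkJ must equal 4.184 * deltaGkcal")
  expectKi <- exp(object@deltaGkJ * 1000 / (8.314 * object@temperature))
  if (!isTRUE(all.equal(object@Ki, expectKi, tolerance = 1e-9)))
    msg <- c(msg, "Ki must equal exp(deltaG / RT)")
  if (length(msg)) msg else TRUE
})

#' Synchronous-fluorescence shift result
#'
#' Peak position (by parabolic sub-grid interpolation) of each synchronous
#' scan in a titration, the net peak shift from first to last concentration,
#' its direction call, and the fractional intensity loss at the peak.
#'
#' @slot deltaLambdaMode numeric(1), scan offset in nm (15 probes Tyr, 60
#'   probes Trp environments).
#' @slot peakByConc named numeric, interpolated peak wavelength (nm) per
#'   quencher concentration (names are concentrations, mol/L).
#' @slot netShift numeric(1), final minus initial peak wavelength (nm).
#' @slot direction character(1), `"red"`, `"blue"` or `"none"` under the
#'   shift tolerance.
#' @slot intensityDropFraction numeric(1), 1 - F_last/F_first at the
#'   respective peaks, in [0, 1] for quenched series.
#' @exportClass ShiftResult
setClass("ShiftResult",
  representation(
    deltaLambdaMode = "numeric", peakByConc = "numeric",
    netShift = "numeric", direction = "character",
    intensityDropFraction = "numeric"
  )
)

setValidity("ShiftResult", function(object) {
  if (!object@direction %in% c("red", "blue", "none"))
    return("unknown direction")
  TRUE
})

#' Consolidated study report
#'
#' Output of \code{\link{runStudy}}: per-temperature quenching and binding
#' results, the mechanism call, thermodynamics, and the optional displacement,
#' synchronous-shift and docking blocks, plus provenance (input hashes,
#' config, package version) and any per-stage errors.
#'
#' @slot quenching list of \linkS4class{QuenchingResult}, named by temperature.
#' @slot binding list of \linkS4class{BindingResult}, named by temperature.
#' @slot mechanism \linkS4class{MechanismCall} or `NULL`.
#' @slot thermo \linkS4class{ThermoResult} or `NULL`.
#' @slot displacement \linkS4class{DisplacementResult} or `NULL`.
#' @slot shifts list of \linkS4class{ShiftResult}, possibly empty.
#' @slot docking list of \linkS4class{DockingRecord}, possibly empty.
#' @slot provenance list: config, input hashes, software version.
#' @slot stageErrors named list of messages for stages that failed or were
#'   skipped, with reasons.
#' @exportClass StudyReport
setClass("StudyReport",
  representation(
    quenching = "list", binding = "list", mechanism = "ANY",
    thermo = "ANY", displacement = "ANY", shifts = "list",
    docking = "list", provenance = "list", stageErrors = "list"
  ),
  prototype(mechanism = NULL, thermo = NULL, displacement = NULL)
)
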