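#' Construct a titration series
#'
#' Builds a validated \linkS4class{TitrationSeries} from a wavelength grid, an
#' intensity matrix (one column per titration point, ascending quencher
#' concentration, first column at zero quencher) and the shared acquisition
#' conditions.
#'
#' @param wavelengths numeric, strictly increasing wavelength grid (nm).
#' @param intensities numeric matrix, `length(wavelengths)` rows and one
#'   column per quencher concentration (a.u.).
#' @param quencherConcs numeric, ascending total quencher concentrations
#'   (mol/L), first element 0.
#' @param proteinConc numeric(1), total protein concentration (mol/L).
#' @param temperature numeric(1), K.
#' @param excitationNm numeric(1), excitation wavelength (nm).
#' @param absorbanceEx,absorbanceEm optional numeric vectors (one value per
#'   titration point) of optical densities at the excitation and emission
#'   wavelengths, used by \code{\link{innerFilterCorrect}}.
#' @param deltaLambda optional numeric(1); for synchronous scans, the fixed
#'   emission-excitation offset in nm (15 or 60).
#' @param label free-text label.
#' @return A \linkS4class{TitrationSeries}.
#' @examples
#' wl <- 300:450
#' f0 <- 1000 * exp(-(wl - 337)^2 / (2 * 25^2))
#' ts <- TitrationSeries(wl, cbind(f0, 0.8 * f0), c(0, 1e-6),
#'                       proteinConc = 1.6e-6, temperature = 298,
#'                       excitationNm = 295)
#' quencherConcs(ts)
#' @export
TitrationSeries <- function(wavelengths, intensities, quencherConcs,
                            proteinConc, temperature, excitationNm,
                            absorbanceEx = NULL, absorbanceEm = NULL,
                            deltaLambda = NA_real_, label = "") {
  intensities <- as.matrix(intensities)
  cd <- DataFrame(quencher_conc = as.numeric(quencherConcs))
  if (!is.null(absorbanceEx)) cd$absorbance_ex <- as.numeric(absorbanceEx)
  if (!is.null(absorbanceEm)) cd$absorbance_em <- as.numeric(absorbanceEm)
  rownames(cd) <- sprintf("Q%02d", seq_len(nrow(cd)))
  colnames(intensities) <- rownames(cd)
  se <- SummarizedExperiment(
    assays  = SimpleList(intensity = unname(intensities)),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = cd,
    metadata = list(protein_conc = proteinConc,
                    temperature = temperature,
                    excitation_nm = excitationNm,
                    delta_lambda = deltaLambda,
                    label = label)
  )
  colnames(se) <- rownames(cd)
  new("TitrationSeries", se)
}

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("quencherConcs", function(x) standardGeneric("quencherConcs"))

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("proteinConc", function(x) standardGeneric("proteinConc"))

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("temperatureK", function(x) standardGeneric("temperatureK"))

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("excitationNm", function(x) standardGeneric("excitationNm"))

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("deltaLambda", function(x) standardGeneric("deltaLambda"))

#' Accessors for TitrationSeries
#'
#' @param x a \linkS4class{TitrationSeries}.
#' @return `wavelengths`: the wavelength grid (nm); `intensities`: the
#'   intensity matrix; `quencherConcs`: quencher concentrations (mol/L);
#'   `proteinConc`, `temperatureK`, `excitationNm`, `deltaLambda`: the scalar
#'   conditions.
#' @name TitrationSeries-accessors
NULL

#' @rdname TitrationSeries-accessors
setMethod("wavelengths", "TitrationSeries",
          function(x) rowData(x)$wavelength_nm)

#' @rdname TitrationSeries-accessors
setMethod("intensities", "TitrationSeries",
          function(x) assay(x, "intensity"))

#' @rdname TitrationSeries-accessors
setMethod("quencherConcs", "TitrationSeries",
          function(x) colData(x)$quencher_conc)

#' @rdname TitrationSeries-accessors
setMethod("proteinConc", "TitrationSeries",
          function(x) metadata(x)$protein_conc)

#' @rdname TitrationSeries-accessors
setMethod("temperatureK", "TitrationSeries",
          function(x) metadata(x)$temperature)

#' @rdname TitrationSeries-accessors
setMethod("excitationNm", "TitrationSeries",
          function(x) metadata(x)$excitation_nm)

#' @rdname TitrationSeries-accessors
setMethod("deltaLambda", "TitrationSeries",
          function(x) metadata(x)$delta_lambda)

#' Extract one spectrum from a titration series
#'
#' @param series a \linkS4class{TitrationSeries}.
#' @param i index of the titration point.
#' @return An \linkS4class{EmissionSpectrum} carrying the point's intensities,
#'   concentration and any recorded absorbances.
#' @export
getSpectrum <- function(series, i) {
  stopifnot(is(series, "TitrationSeries"),
            i >= 1L, i <= ncol(series))
  cd <- colData(series)
  aEx <- if ("absorbance_ex" %in% colnames(cd)) cd$absorbance_ex[i] else NA_real_
  aEm <- if ("absorbance_em" %in% colnames(cd)) cd$absorbance_em[i] else NA_real_
  new("EmissionSpectrum",
      wavelengths = wavelengths(series),
      intensities = intensities(series)[, i],
      excitationNm = excitationNm(series),
      temperature = temperatureK(series),
      quencherConc = quencherConcs(series)[i],
      absorbanceEx = aEx, absorbanceEm = aEm)
}

setMethod("show", "TitrationSeries", function(object) {
  q <- quencherConcs(object)
  cat("TitrationSeries with", ncol(object), "spectra,",
      nrow(object), "wavelengths\n")
  cat(sprintf("  wavelength: %.6g-%.6g nm | excitation %.6g nm | T = %.6g K\n",
              min(wavelengths(object)), max(wavelengths(object)),
              excitationNm(object), temperatureK(object)))
  cat(sprintf("  [protein] = %.3g M | [quencher] = %.3g-%.3g M\n",
              proteinConc(object), min(q), max(q)))
  dl <- deltaLambda(object)
  if (length(dl) == 1L && !is.na(dl))
    cat(sprintf("  synchronous scan, delta-lambda = %g nm\n", dl))
  invisible(NULL)
})

setMethod("show", "EmissionSpectrum", function(object) {
  cat(sprintf(
    "EmissionSpectrum: %d points, %.6g-%.6g nm | [Q] = %.3g M | T = %.6g K\n",
    length(object@wavelengths), min(object@wavelengths),
    max(object@wavelengths), object@quencherConc, object@temperature))
  invisible(NULL)
})

setMethod("show", "QuenchCurve", function(object) {
  cat(sprintf(
    "QuenchCurve: %d points | F0 = %.4g | F0/F range %.4g-%.4g | T = %.6g K\n",
    length(object@concentrations), object@F0,
    min(object@F0 / object@F), max(object@F0 / object@F),
    object@temperature))
  invisible(NULL)
})

#' Construct a quenching curve directly
#'
#' For externally tabulated data; \code{\link{extractQuenchCurve}} builds the
#' curve from a \linkS4class{TitrationSeries}.
#'
#' @param concentrations numeric, total quencher concentrations (mol/L).
#' @param F0 numeric(1), unquenched intensity.
#' @param F numeric, intensity per concentration.
#' @param temperature numeric(1), K.
#' @param wavelength optional numeric(1), nm.
#' @return A \linkS4class{QuenchCurve}.
#' @export
QuenchCurve <- function(concentrations, F0, F, temperature = 298,
                        wavelength = NA_real_) {
  new("QuenchCurve", concentrations = as.numeric(concentrations),
      F0 = as.numeric(F0), F = as.numeric(F),
      temperature = as.numeric(temperature),
      wavelength = as.numeric(wavelength))
}
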