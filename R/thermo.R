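#' Gas constant, J mol^-1 K^-1
#' @keywords internal
.RGAS <- 8.314

#' Van't Hoff analysis of temperature-dependent binding constants
#'
#' Fits \eqn{\ln K_a = -\Delta H^0/(RT) + \Delta S^0/R} by ordinary least
#' squares of \eqn{\ln K_a} on \eqn{1/T}: the slope gives
#' \eqn{\Delta H^0 = -R \cdot slope} and the intercept
#' \eqn{\Delta S^0 = R \cdot intercept}. The Gibbs energy at each input
#' temperature is reported from \eqn{\Delta G^0 = \Delta H^0 - T\Delta S^0}
#' (mode `"from_HS"`), the route that is internally exact for the fitted
#' pair; the \eqn{-RT\ln K_a} route is available via
#' \code{\link{gibbsFromKa}}.
#'
#' The dominant binding force is read from the signs: positive
#' \eqn{\Delta H^0} and \eqn{\Delta S^0} indicate hydrophobic interactions,
#' both negative indicate van der Waals contacts or hydrogen bonds, and
#' \eqn{\Delta H^0 \approx 0} (within `enthalpyZeroTol`) with positive
#' \eqn{\Delta S^0} indicates electrostatic forces. The near-zero band takes
#' precedence so every sign pair maps to exactly one verdict.
#'
#' @param Ka numeric, binding constants (L/mol), or a named numeric whose
#'   names are temperatures in K.
#' @param temperatures numeric, temperatures in K (omit when `Ka` is named).
#' @param enthalpyZeroTol numeric(1), half-width in J/mol of the
#'   "approximately zero" enthalpy band for the electrostatic rule (default
#'   4000).
#' @return A \linkS4class{ThermoResult} (energies in J/mol, entropy in
#'   J mol^-1 K^-1).
#' @examples
#' vantHoffFit(c(`298` = 3.98e6, `303` = 8.13e6, `308` = 13.99e6))
#' @export
vantHoffFit <- function(Ka, temperatures = NULL, enthalpyZeroTol = 4000) {
  if (is.null(temperatures)) {
    temperatures <- as.numeric(names(Ka))
    if (any(is.na(temperatures)))
      stop("supply temperatures, or name Ka by temperature (K)")
  }
  Ka <- as.numeric(Ka)
  if (length(Ka) != length(temperatures))
    stop("Ka and temperatures must have the same length")
  if (length(unique(temperatures)) < 2L)
    stop("van't Hoff analysis needs >= 2 distinct temperatures")
  if (any(Ka <= 0) || any(temperatures <= 0))
    stop("Ka and temperatures must be positive")
  invT <- 1 / temperatures
  lnKa <- log(Ka)
  fit <- lm(lnKa ~ invT)
  dH <- -.RGAS * unname(coef(fit)[2L])
  dS <- .RGAS * unname(coef(fit)[1L])
  r2 <- if (length(Ka) == 2L || var(lnKa) == 0) 1
        else stats::cor(invT, lnKa)^2
  dG <- dH - temperatures * dS
  names(dG) <- as.character(temperatures)
  new("ThermoResult",
      deltaH = dH, deltaS = dS, deltaGPerT = dG, Rsquared = r2,
      modePerT = setNames(rep("from_HS", length(dG)), names(dG)),
      forceInterpretation = .forceCall(dH, dS, enthalpyZeroTol))
}

.forceCall <- function(dH, dS, tol) {
  if (abs(dH) < tol && dS > 0) "electrostatic"
  else if (dH > 0 && dS > 0)   "hydrophobic"
  else if (dH < 0 && dS < 0)   "vdw_or_hbond"
  else                         "other"
}

setMethod("show", "ThermoResult", function(object) {
  cat(sprintf(
    "ThermoResult: dH = %.2f kJ/mol | dS = %.2f J/mol/K | R^2 = %.4f | force: %s\n",
    object@deltaH / 1000, object@deltaS, object@Rsquared,
    object@forceInterpretation))
  for (tn in names(object@deltaGPerT))
    cat(sprintf("  dG(%s K) = %.2f kJ/mol [%s]\n", tn,
                object@deltaGPerT[[tn]] / 1000, object@modePerT[[tn]]))
  invisible(NULL)
})

#' Gibbs energy from a binding constant
#'
#' \eqn{\Delta G^0 = -RT \ln K_a} with R = 8.314 J/mol/K.
#'
#' @param Ka numeric, binding constant(s), L/mol, > 0.
#' @param temperature numeric, K, > 0.
#' @return Gibbs energy in J/mol (vectorized).
#' @examples
#' gibbsFromKa(3.98e6, 298) / 1000   # about -37.66 kJ/mol
#' @export
gibbsFromKa <- function(Ka, temperature) {
  if (any(Ka <= 0) || any(temperature <= 0))
    stop("Ka and temperature must be positive")
  -.RGAS * temperature * log(Ka)
}

#' Post-process a docking free energy
#'
#' Converts a docking score from kcal/mol to kJ/mol (thermochemical calorie,
#' factor 4.184) and derives the implied inhibition constant
#' \eqn{K_i = \exp(\Delta G / RT)} (mol/L; below 1 M for negative
#' \eqn{\Delta G}).
#'
#' @param deltaGkcal numeric(1), docking free energy, kcal/mol.
#' @param temperature numeric(1), K (default 298).
#' @param siteLabel free-text label for the docked site.
#' @return A \linkS4class{DockingRecord}.
#' @examples
#' dockingPostprocess(-8.17, 298)   # -34.18 kJ/mol, Ki about 1.02e-6 M
#' @export
dockingPostprocess <- function(deltaGkcal, temperature = 298,
                               siteLabel = "") {
  stopifnot(length(deltaGkcal) == 1L, temperature > 0)
  kJ <- 4.184 * deltaGkcal
  new("DockingRecord",
      deltaGkcal = deltaGkcal, deltaGkJ = kJ,
      Ki = exp(kJ * 1000 / (.RGAS * temperature)),
      temperature = temperature,
      siteLabel = as.character(siteLabel))
}

setMethod("show", "DockingRecord", function(object) {
  cat(sprintf(
    "DockingRecord%s @ %g K: dG = %.2f kcal/mol = %.2f kJ/mol | Ki = %.3g M\n",
    if (nzchar(object@siteLabel)) paste0(" [", object@siteLabel, "]") else "",
    object@temperature, object@deltaGkcal, object@deltaGkJ, object@Ki))
  invisible(NULL)
})
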