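#' Double-logarithm binding fit with free-ligand depletion correction
#'
#' Estimates the apparent binding constant \eqn{K_a} and number of binding
#' sites \eqn{n} from a quenching curve via the modified double-logarithm
#' relation
#' \deqn{\log \frac{F_0 - F}{F} = \log K_a +
#'       n \log\!\left([Q] - [P]\frac{F_0 - F}{F_0}\right)}
#' where \eqn{[Q]} is the total quencher and \eqn{[P]} the total protein
#' concentration; the \eqn{[P](F_0-F)/F_0} term corrects the total quencher
#' for the fraction bound (free-ligand depletion). Logs are base 10; ordinary
#' least squares of y on x gives the slope \eqn{n} and intercept
#' \eqn{\log_{10} K_a}, with standard errors from the fit.
#'
#' Points whose log arguments are non-positive (no measurable quenching, or a
#' depletion-corrected free-ligand estimate at or below zero) are dropped and
#' counted in `pointsDropped`.
#'
#' @param curve a \linkS4class{QuenchCurve} with a zero-concentration F0 and
#'   at least 3 positive-concentration points.
#' @param proteinConc numeric(1), total protein concentration (mol/L).
#' @return A \linkS4class{BindingResult}.
#' @examples
#' q <- seq(0, 3.2e-6, length.out = 9)
#' cplx <- solveEquilibrium1to1(1.6e-6, q, 1e6)
#' F <- 1000 * (1.6e-6 - cplx) / 1.6e-6
#' fit <- doubleLogFit(QuenchCurve(q, 1000, F), 1.6e-6)
#' fit   # recovers Ka = 1e6, n = 1
#' @export
doubleLogFit <- function(curve, proteinConc) {
  stopifnot(is(curve, "QuenchCurve"), proteinConc > 0)
  q <- curve@concentrations
  F0 <- curve@F0
  pos <- q > 0
  if (sum(pos) < 3L)
    stop("double-log fit needs >= 3 positive-concentration points")
  q <- q[pos]; F <- curve@F[pos]
  dF <- F0 - F
  if (all(dF <= 0))
    stop("no quenching signal: F >= F0 at every point")
  yArg <- dF / F
  xArg <- q - proteinConc * dF / F0
  usable <- yArg > 0 & xArg > 0
  dropped <- sum(!usable)
  if (sum(usable) < 3L)
    stop(sprintf(
      "only %d usable points after dropping %d with non-positive log arguments",
      sum(usable), dropped))
  x <- log10(xArg[usable])
  y <- log10(yArg[usable])
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # noise-free input fits exactly
  r2 <- stats::cor(x, y)^2
  new("BindingResult",
      Ka = 10^unname(coef(fit)[1L]),
      log10KaStderr = unname(sm[1L, 2L]),
      nSites = unname(coef(fit)[2L]),
      nStderr = unname(sm[2L, 2L]),
      Rsquared = r2,
      temperature = curve@temperature,
      pointsUsed = sum(usable),
      pointsDropped = as.integer(dropped))
}

setMethod("show", "BindingResult", function(object) {
  cat(sprintf(
    "BindingResult @ %g K: Ka = %.4g L/mol (log10 Ka = %.4f +/- %.2g) | n = %.3f +/- %.2g | R^2 = %.4f | %d points (%d dropped)\n",
    object@temperature, object@Ka, log10(object@Ka),
    object@log10KaStderr, object@nSites, object@nStderr,
    object@Rsquared, object@pointsUsed, object@pointsDropped))
  invisible(NULL)
})

#' Competitive site-marker displacement analysis
#'
#' Compares the binding constant of the binary protein-ligand system with the
#' constants refit after pre-incubating the protein with a Sudlow site I
#' marker (e.g. warfarin) or a site II marker (e.g. ibuprofen). The percent
#' reduction for each marker is
#' \deqn{100 \times (K_a^{binary} - K_a^{ternary}) / K_a^{binary}}
#' and the ligand is assigned to the site whose marker causes the strictly
#' larger reduction. When both reductions are negative (apparent enhancement
#' by both markers) the call is `"indeterminate"` with a warning; equal
#' reductions are also indeterminate.
#'
#' @param binary \linkS4class{BindingResult} for the two-component system.
#' @param ternarySite1 \linkS4class{BindingResult} with the site I marker
#'   present.
#' @param ternarySite2 \linkS4class{BindingResult} with the site II marker
#'   present.
#' @return A \linkS4class{DisplacementResult}. Percent reductions are kept at
#'   full precision; rounding is a presentation concern.
#' @export
displacementAnalysis <- function(binary, ternarySite1, ternarySite2) {
  stopifnot(is(binary, "BindingResult"),
            is(ternarySite1, "BindingResult"),
            is(ternarySite2, "BindingResult"))
  temps <- c(binary@temperature, ternarySite1@temperature,
             ternarySite2@temperature)
  if (length(unique(temps)) != 1L)
    stop("all three binding results must share one temperature")
  kb <- binary@Ka
  p1 <- 100 * (kb - ternarySite1@Ka) / kb
  p2 <- 100 * (kb - ternarySite2@Ka) / kb
  if (p1 < 0 && p2 < 0) {
    warning("both markers increase the apparent Ka; site assignment is indeterminate")
    call <- "indeterminate"
  } else if (p1 > p2) {
    call <- "site_I"
  } else if (p2 > p1) {
    call <- "site_II"
  } else {
    call <- "indeterminate"
  }
  new("DisplacementResult",
      KaBinary = kb, KaTernarySite1 = ternarySite1@Ka,
      KaTernarySite2 = ternarySite2@Ka,
      pctReductionSite1 = p1, pctReductionSite2 = p2,
      siteCall = call)
}

setMethod("show", "DisplacementResult", function(object) {
  cat(sprintf(
    "DisplacementResult: Ka(binary) = %.4g | site I marker -> %.2f%% | site II marker -> %.2f%% | call: %s\n",
    object@KaBinary, object@pctReductionSite1,
    object@pctReductionSite2, object@siteCall))
  invisible(NULL)
})
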