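#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation
#' \deqn{F_0/F = 1 + K_{SV} [Q]}
#' by ordinary least squares of the intensity ratio on total quencher
#' concentration. The slope is the Stern-Volmer constant \eqn{K_{SV}}; the
#' intercept is fitted freely (not pinned at 1) and reported. The bimolecular
#' quenching rate constant is \eqn{K_q = K_{SV}/\tau_0}, with \eqn{\tau_0}
#' the unquenched fluorophore lifetime. R-squared is the squared Pearson
#' correlation of the line.
#'
#' A \eqn{K_q} far above the diffusion-controlled limit (~2e10 L/mol/s) is
#' one line of evidence for static quenching; see
#' \code{\link{classifyMechanism}}.
#'
#' @param curve a \linkS4class{QuenchCurve} with at least 3 distinct
#'   concentrations.
#' @param tau0 numeric(1), unquenched fluorophore lifetime in seconds
#'   (default `1e-8`, the value consistent with serum-albumin quenching-rate
#'   tabulations; adjust for other fluorophores).
#' @return A \linkS4class{QuenchingResult}.
#' @examples
#' cv <- QuenchCurve(c(0, 1e-6, 2e-6, 3e-6), 1000,
#'                   1000 / (1 + 2.51e5 * c(0, 1e-6, 2e-6, 3e-6)))
#' sternVolmerFit(cv)
#' @export
sternVolmerFit <- function(curve, tau0 = 1e-8) {
  stopifnot(is(curve, "QuenchCurve"), tau0 > 0)
  q <- curve@concentrations
  if (length(unique(q)) < 3L)
    stop("Stern-Volmer fit needs at least 3 distinct concentrations")
  if (any(curve@F <= 0))
    stop("non-positive intensity in curve")
  ratio <- curve@F0 / curve@F
  fit <- lm(ratio ~ q)
  sm <- suppressWarnings(summary(fit))  # noise-free input fits exactly
  r2 <- if (var(ratio) == 0) 1 else stats::cor(q, ratio)^2
  ksv <- unname(coef(fit)[2L])
  new("QuenchingResult",
      Ksv = ksv,
      KsvStderr = unname(sm$coefficients[2L, 2L]),
      intercept = unname(coef(fit)[1L]),
      Kq = ksv / tau0, tau0 = tau0,
      Rsquared = r2,
      temperature = curve@temperature,
      nPoints = length(q))
}

setMethod("show", "QuenchingResult", function(object) {
  cat(sprintf(
    "QuenchingResult @ %g K: Ksv = %.4g +/- %.2g L/mol | Kq = %.4g L/mol/s (tau0 = %.3g s) | R^2 = %.4f | n = %d\n",
    object@temperature, object@Ksv, object@KsvStderr, object@Kq,
    object@tau0, object@Rsquared, object@nPoints))
  invisible(NULL)
})

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Static quenching (ground-state complex formation) is indicated by a
#' quenching constant that falls as temperature rises and by an apparent
#' bimolecular rate constant above the diffusion-controlled collisional
#' maximum; dynamic (collisional) quenching shows the opposite trend with
#' \eqn{K_q} at or below that limit. The verdict is `"static"` when the
#' \eqn{K_{SV}} values strictly decrease with temperature and every
#' \eqn{K_q} exceeds the threshold, `"dynamic"` when they strictly increase
#' and no \eqn{K_q} exceeds it, and `"indeterminate"` otherwise (both
#' evidence flags are always reported). Trends use strict monotonicity; ties
#' count as non-monotone.
#'
#' @param results list of \linkS4class{QuenchingResult} at two or more
#'   distinct temperatures (any order; sorted internally).
#' @param kqThreshold numeric(1), diffusion-limited maximum for collisional
#'   quenching, L/mol/s (default `2e10`).
#' @return A \linkS4class{MechanismCall}.
#' @export
classifyMechanism <- function(results, kqThreshold = 2e10) {
  if (length(results) < 2L)
    stop("mechanism classification needs results at >= 2 temperatures")
  stopifnot(all(vapply(results, is, logical(1), "QuenchingResult")))
  temps <- vapply(results, slot, numeric(1), "temperature")
  if (anyDuplicated(temps))
    stop("temperatures must be distinct")
  o <- order(temps)
  ksv <- vapply(results, slot, numeric(1), "Ksv")[o]
  kq <- vapply(results, slot, numeric(1), "Kq")[o]
  trend <- if (all(diff(ksv) < 0)) "decreasing"
           else if (all(diff(ksv) > 0)) "increasing"
           else "non-monotone"
  exceeds <- all(kq > kqThreshold)
  verdict <- if (trend == "decreasing" && exceeds) "static"
             else if (trend == "increasing" && !exceeds) "dynamic"
             else "indeterminate"
  evidence <- sprintf(
    "Ksv %s with temperature (%s L/mol at %s K); Kq %s the %.3g L/mol/s diffusion limit",
    trend, paste(signif(ksv, 4), collapse = ", "),
    paste(sort(temps), collapse = ", "),
    if (exceeds) "all exceed" else "do not all exceed", kqThreshold)
  new("MechanismCall", verdict = verdict, ksvTrend = trend,
      kqExceedsDiffusionLimit = exceeds, evidence = evidence)
}

setMethod("show", "MechanismCall", function(object) {
  cat("MechanismCall:", object@verdict, "\n  ", object@evidence, "\n")
  invisible(NULL)
})
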