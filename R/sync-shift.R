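#' Synchronous-fluorescence peak-shift analysis
#'
#' Locates the emission peak of each synchronous scan in a titration by
#' parabolic sub-grid interpolation, and reports the net peak shift from the
#' first (zero-quencher) to the last concentration, its direction, and the
#' fractional intensity loss at the peak. A blue shift (toward shorter
#' wavelengths) reports increased hydrophobicity around the probed residues;
#' a red shift reports increased polarity. Scans at an offset of
#' \eqn{\Delta\lambda} = 15 nm probe the tyrosine environment, 60 nm the
#' tryptophan environment.
#'
#' @param series a \linkS4class{TitrationSeries} of synchronous scans,
#'   tagged with a `delta_lambda` metadata value (see
#'   \code{\link{TitrationSeries}}), with at least 2 concentrations.
#' @param shiftTolerance numeric(1), nm; net shifts within ± this tolerance
#'   are called `"none"` (default 0.5 nm, below which grid/interpolation
#'   error dominates a 1 nm-sampled band).
#' @return A \linkS4class{ShiftResult}.
#' @export
synchronousShift <- function(series, shiftTolerance = 0.5) {
  stopifnot(is(series, "TitrationSeries"))
  if (ncol(series) < 2L)
    stop("shift analysis needs >= 2 concentrations")
  wl <- wavelengths(series)
  a <- intensities(series)
  peaks <- matrix(NA_real_, nrow = ncol(a), ncol = 3L)
  for (j in seq_len(ncol(a))) {
    f <- a[, j]
    if (max(f) <= 0 || diff(range(f)) < 1e-12 * max(abs(f), 1))
      stop("flat spectrum at titration point ", j,
           ": no identifiable peak above the noise floor")
    pk <- .parabolicPeak(wl, f)
    if (pk["boundary"] == 1)
      stop("spectrum at titration point ", j,
           " peaks at the grid boundary: no interior peak")
    peaks[j, ] <- pk
  }
  q <- quencherConcs(series)
  peakByConc <- setNames(peaks[, 1L], as.character(q))
  net <- peaks[nrow(peaks), 1L] - peaks[1L, 1L]
  direction <- if (net < -shiftTolerance) "blue"
               else if (net > shiftTolerance) "red"
               else "none"
  dl <- deltaLambda(series)
  new("ShiftResult",
      deltaLambdaMode = if (length(dl) == 1L && !is.na(dl)) dl else NA_real_,
      peakByConc = peakByConc,
      netShift = net,
      direction = direction,
      intensityDropFraction = 1 - peaks[nrow(peaks), 2L] / peaks[1L, 2L])
}

setMethod("show", "ShiftResult", function(object) {
  mode <- if (is.na(object@deltaLambdaMode)) "" else
    sprintf(" (delta-lambda = %g nm, %s probe)", object@deltaLambdaMode,
            if (object@deltaLambdaMode == 15) "Tyr"
            else if (object@deltaLambdaMode == 60) "Trp" else "unassigned")
  cat(sprintf(
    "ShiftResult%s: net shift = %+.2f nm (%s) | peak intensity drop = %.1f%%\n",
    mode, object@netShift, object@direction,
    100 * object@intensityDropFraction))
  invisible(NULL)
})

#' Absorbance trend across a titration
#'
#' Regresses the optical density at a reference wavelength on total quencher
#' concentration and calls the trend by the sign of the slope. A rising
#' ground-state absorbance with added ligand supports complex formation
#' (static quenching); a flat trend supports a purely collisional (dynamic)
#' mechanism.
#'
#' @param concentrations numeric, total quencher concentrations (mol/L),
#'   >= 3 values.
#' @param absorbance numeric, optical densities at the reference wavelength,
#'   one per concentration.
#' @param flatTolerance numeric(1); the trend is `"flat"` when the predicted
#'   relative change in OD across the concentration range is below this
#'   fraction (default 0.01).
#' @return A list with `verdict` (`"increasing"`, `"decreasing"` or
#'   `"flat"`), `slope` (OD per mol/L) and `relative_change` over the range.
#' @export
uvTrend <- function(concentrations, absorbance, flatTolerance = 0.01) {
  if (length(concentrations) < 3L)
    stop("trend extraction needs >= 3 concentrations")
  if (length(concentrations) != length(absorbance))
    stop("concentrations and absorbance must have the same length")
  fit <- lm(absorbance ~ concentrations)
  slope <- unname(coef(fit)[2L])
  ref <- abs(unname(coef(fit)[1L]))
  if (ref == 0) ref <- max(abs(absorbance), .Machine$double.eps)
  rel <- slope * diff(range(concentrations)) / ref
  verdict <- if (abs(rel) < flatTolerance) "flat"
             else if (slope > 0) "increasing"
             else "decreasing"
  list(verdict = verdict, slope = slope, relative_change = rel)
}
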