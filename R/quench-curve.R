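# Sub-grid peak location by a 3-point parabola through the discrete argmax
# and its neighbours. Returns c(wavelength, intensity) at the vertex; falls
# back to the grid point when the argmax sits on a boundary (caller decides
# whether that is an error).
.parabolicPeak <- function(wl, f) {
  i <- which.max(f)
  if (i == 1L || i == length(f))
    return(c(wavelength = wl[i], intensity = f[i], boundary = 1))
  y1 <- f[i - 1L]; y2 <- f[i]; y3 <- f[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0)
    return(c(wavelength = wl[i], intensity = y2, boundary = 0))
  # offset of the vertex in grid units, assuming a locally uniform grid
  d <- 0.5 * (y1 - y3) / denom
  h <- (wl[i + 1L] - wl[i - 1L]) / 2
  peakWl <- wl[i] + d * h
  peakF <- y2 - 0.25 * (y1 - y3) * d
  c(wavelength = peakWl, intensity = peakF, boundary = 0)
}

# Linear interpolation of a spectrum at one wavelength inside the grid.
.interpAt <- function(wl, f, at) {
  if (at < wl[1L] || at > wl[length(wl)])
    stop(sprintf("wavelength %.6g nm is outside the grid (%.6g-%.6g nm)",
                 at, wl[1L], wl[length(wl)]))
  stats::approx(wl, f, xout = at)$y
}

#' Extract a quenching curve from a titration series
#'
#' Reads the reference intensity F0 from the zero-concentration spectrum and
#' the intensity F of every titration point at one fixed wavelength, yielding
#' the \linkS4class{QuenchCurve} that the Stern-Volmer and double-logarithm
#' fits consume.
#'
#' In `"peak"` mode the wavelength is the sub-grid (parabolically
#' interpolated) emission maximum of the zero-concentration spectrum, held
#' fixed across the series so that all F0/F ratios compare intensities at a
#' single wavelength. In `"fixed"` mode the caller supplies the wavelength
#' and intensities are linearly interpolated on the grid.
#'
#' @param series a \linkS4class{TitrationSeries} whose first point is at zero
#'   quencher concentration.
#' @param mode `"peak"` (default) or `"fixed"`.
#' @param wavelength numeric(1), required for `mode = "fixed"`; must lie
#'   within the wavelength grid.
#' @return A \linkS4class{QuenchCurve} over the positive-concentration points
#'   (the zero point defines F0 and is kept as the first curve point).
#' @export
extractQuenchCurve <- function(series, mode = c("peak", "fixed"),
                               wavelength = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  mode <- match.arg(mode)
  q <- quencherConcs(series)
  if (!any(q == 0))
    stop("series has no zero-concentration spectrum; F0 is undefined")
  wl <- wavelengths(series)
  a <- intensities(series)
  i0 <- which(q == 0)[1L]
  if (mode == "peak") {
    pk <- .parabolicPeak(wl, a[, i0])
    at <- unname(pk["wavelength"])
  } else {
    if (is.null(wavelength))
      stop("mode 'fixed' requires a wavelength")
    at <- wavelength
  }
  F <- vapply(seq_len(ncol(a)), function(j) .interpAt(wl, a[, j], at),
              numeric(1))
  QuenchCurve(concentrations = q, F0 = F[i0], F = F,
              temperature = temperatureK(series), wavelength = at)
}
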