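#' Inner-filter correction of fluorescence intensities
#'
#' Corrects observed intensities for attenuation of the excitation beam and
#' reabsorption of emitted light by the sample:
#' \deqn{F_{cor} = F_{obs} \times 10^{(A_{ex} + A_{em})/2}}
#' where \eqn{A_{ex}} and \eqn{A_{em}} are the optical densities at the
#' excitation and emission wavelengths. The correction is multiplicative and
#' applied element-wise.
#'
#' For a \linkS4class{TitrationSeries} the per-point absorbances are taken
#' from `colData` columns `absorbance_ex` / `absorbance_em`; if they are
#' absent the series is returned unchanged (no correction is possible and
#' none was requested when the data were assembled).
#'
#' @param x observed intensities (numeric vector/matrix), an
#'   \linkS4class{EmissionSpectrum}, or a \linkS4class{TitrationSeries}.
#' @param absorbanceEx,absorbanceEm optical densities (dimensionless); for
#'   the numeric method, scalars or vectors recycled against `x`. Ignored for
#'   spectrum/series inputs, which carry their own absorbances.
#' @param ... passed between methods.
#' @return Corrected intensities of the same shape/class as `x`.
#' @examples
#' innerFilterCorrect(100, 0.1, 0.1)   # 125.8925...
#' @export
setGeneric("innerFilterCorrect",
           function(x, ...) standardGeneric("innerFilterCorrect"))

#' @rdname innerFilterCorrect
setMethod("innerFilterCorrect", "numeric",
  function(x, absorbanceEx, absorbanceEm) {
    .ifcCheck(x, absorbanceEx, absorbanceEm)
    x * 10^((absorbanceEx + absorbanceEm) / 2)
  })

#' @rdname innerFilterCorrect
setMethod("innerFilterCorrect", "matrix",
  function(x, absorbanceEx, absorbanceEm) {
    .ifcCheck(x, absorbanceEx, absorbanceEm)
    # one absorbance pair per column (titration point)
    if (length(absorbanceEx) == ncol(x) && ncol(x) > 1L)
      sweep(x, 2L, 10^((absorbanceEx + absorbanceEm) / 2), `*`)
    else
      x * 10^((absorbanceEx + absorbanceEm) / 2)
  })

#' @rdname innerFilterCorrect
setMethod("innerFilterCorrect", "EmissionSpectrum",
  function(x) {
    if (is.na(x@absorbanceEx) || is.na(x@absorbanceEm))
      stop("spectrum carries no absorbances; inner-filter correction needs A_ex and A_em")
    x@intensities <- innerFilterCorrect(x@intensities,
                                        x@absorbanceEx, x@absorbanceEm)
    x@absorbanceEx <- NA_real_
    x@absorbanceEm <- NA_real_
    validObject(x)
    x
  })

#' @rdname innerFilterCorrect
setMethod("innerFilterCorrect", "TitrationSeries",
  function(x) {
    cd <- colData(x)
    if (!all(c("absorbance_ex", "absorbance_em") %in% colnames(cd)))
      return(x)
    a <- innerFilterCorrect(assay(x, "intensity"),
                            cd$absorbance_ex, cd$absorbance_em)
    SummarizedExperiment::assay(x, "intensity") <- a
    colData(x)$absorbance_ex <- NULL
    colData(x)$absorbance_em <- NULL
    validObject(x)
    x
  })

.ifcCheck <- function(f, aEx, aEm) {
  if (any(f < 0, na.rm = TRUE))
    stop("negative observed intensity")
  if (any(aEx < 0) || any(aEm < 0))
    stop("negative absorbance flags corrupt input")
  invisible(TRUE)
}
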