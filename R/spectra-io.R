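#' Read a titration series from delimited text
#'
#' Reads spectrofluorometer-style tabular exports: a one-line header, the
#' wavelength grid in a column named `wavelength_nm`, and one intensity column
#' per titration point, ordered by ascending quencher concentration. The
#' acquisition conditions come from a metadata record — either a named list or
#' the path of a YAML/JSON file with keys `protein_conc_M`,
#' `quencher_concs_M`, `temperature_K`, `excitation_nm`, and optionally
#' `delta_lambda_nm`, `label` and an `absorbance` table with `ex`/`em`
#' vectors.
#'
#' @param path delimited text file (comma- or tab-separated; the separator is
#'   sniffed from the header line).
#' @param meta named list, or path to a YAML or JSON metadata file.
#' @return A validated \linkS4class{TitrationSeries}.
#' @seealso \code{\link{writeTitration}}
#' @export
readTitration <- function(path, meta) {
  meta <- .resolveMeta(meta)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!("wavelength_nm" %in% colnames(tab)))
    stop("missing 'wavelength_nm' column in ", path)
  wl <- tab$wavelength_nm
  if (any(diff(wl) <= 0))
    stop("non-monotone wavelength grid in ", path)
  intens <- as.matrix(tab[, setdiff(colnames(tab), "wavelength_nm"),
                          drop = FALSE])
  concs <- as.numeric(meta$quencher_concs_M)
  if (ncol(intens) != length(concs))
    stop(sprintf(
      "column/concentration mismatch: %d intensity columns but %d concentrations in metadata",
      ncol(intens), length(concs)))
  ab <- meta$absorbance
  TitrationSeries(
    wavelengths = wl, intensities = intens, quencherConcs = concs,
    proteinConc = as.numeric(meta$protein_conc_M),
    temperature = as.numeric(meta$temperature_K),
    excitationNm = as.numeric(meta$excitation_nm),
    absorbanceEx = if (!is.null(ab)) as.numeric(ab$ex) else NULL,
    absorbanceEm = if (!is.null(ab)) as.numeric(ab$em) else NULL,
    deltaLambda = if (!is.null(meta$delta_lambda_nm))
      as.numeric(meta$delta_lambda_nm) else NA_real_,
    label = if (!is.null(meta$label)) meta$label else "")
}

.resolveMeta <- function(meta) {
  if (is.character(meta) && length(meta) == 1L) {
    meta <- if (grepl("\\.json$", meta, ignore.case = TRUE))
      jsonlite::read_json(meta, simplifyVector = TRUE)
    else
      yaml::read_yaml(meta)
  }
  required <- c("protein_conc_M", "quencher_concs_M", "temperature_K",
                "excitation_nm")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing: ", paste(missing, collapse = ", "))
  meta
}

#' Write a titration series as delimited text plus metadata
#'
#' Inverse of \code{\link{readTitration}}: writes the spectra table (CSV,
#' full double precision) and, when `metaPath` is given, a YAML metadata file
#' that `readTitration` accepts back.
#'
#' @param series a \linkS4class{TitrationSeries}.
#' @param path output CSV path.
#' @param metaPath optional YAML metadata path.
#' @return Invisibly, the metadata list.
#' @export
writeTitration <- function(series, path, metaPath = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  intens <- intensities(series)
  colnames(intens) <- sprintf("intensity_%02d", seq_len(ncol(intens)))
  tab <- data.frame(wavelength_nm = wavelengths(series), intens,
                    check.names = FALSE)
  utils::write.table(format(tab, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- list(protein_conc_M = proteinConc(series),
               quencher_concs_M = as.numeric(quencherConcs(series)),
               temperature_K = temperatureK(series),
               excitation_nm = excitationNm(series),
               label = metadata(series)$label)
  dl <- deltaLambda(series)
  if (length(dl) == 1L && !is.na(dl)) meta$delta_lambda_nm <- dl
  cd <- colData(series)
  if (all(c("absorbance_ex", "absorbance_em") %in% colnames(cd)))
    meta$absorbance <- list(ex = as.numeric(cd$absorbance_ex),
                            em = as.numeric(cd$absorbance_em))
  if (!is.null(metaPath)) yaml::write_yaml(meta, metaPath)
  invisible(meta)
}
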