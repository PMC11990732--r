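# Convert an S4 result object to a plain named list for JSON serialization.
.s4ToList <- function(x) {
  if (is.null(x)) return(NULL)
  out <- lapply(slotNames(class(x)), function(s) {
    v <- slot(x, s)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  names(out) <- slotNames(class(x))
  out
}

#' Run a full binding-study analysis from a config
#'
#' Orchestrates the pipeline — inner-filter correction, quench-curve
#' extraction, Stern-Volmer fits, mechanism classification, double-log
#' binding fits, van't Hoff thermodynamics, and the optional site-marker
#' displacement, synchronous-shift and docking blocks — and assembles a
#' \linkS4class{StudyReport}. Stages whose inputs are absent or invalid are
#' skipped with a recorded reason; downstream stages that depend on them are
#' skipped too, so partial configs yield partial reports.
#'
#' The config is a named list (or the path of a YAML file) with elements:
#' \describe{
#'   \item{titrations}{list of titration inputs, one per temperature: either
#'     a \linkS4class{TitrationSeries}, or a list with `file` and `meta`
#'     paths for \code{\link{readTitration}}.}
#'   \item{marker_site1, marker_site2}{optional titration inputs recorded
#'     with a Sudlow site I / site II marker present, for displacement
#'     analysis (matched to the binary result at the same temperature).}
#'   \item{synchronous}{optional list of synchronous-scan titration inputs
#'     (tagged with `delta_lambda`).}
#'   \item{docking}{optional list of records with `delta_G_kcal` and
#'     optionally `temperature`, `site_label`.}
#'   \item{tau0, kq_threshold, mode, wavelength, shift_tolerance}{analysis
#'     parameters; defaults 1e-8 s, 2e10 L/mol/s, `"peak"`, `NULL`, 0.5 nm.}
#' }
#'
#' @param config named list or YAML file path.
#' @return A \linkS4class{StudyReport}.
#' @seealso \code{\link{writeStudyReport}}
#' @export
runStudy <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  tau0 <- config$tau0 %||% 1e-8
  kqThr <- config$kq_threshold %||% 2e10
  mode <- config$mode %||% "peak"
  shiftTol <- config$shift_tolerance %||% 0.5
  errors <- list()
  hashes <- list()

  loadSeries <- function(entry, what) {
    if (is(entry, "TitrationSeries")) {
      hashes[[what]] <<- "in-memory"
      return(entry)
    }
    s <- readTitration(entry$file, entry$meta)
    hashes[[what]] <<- unname(tools::md5sum(entry$file))
    s
  }

  quench <- list(); binding <- list()
  if (is.null(config$titrations) || !length(config$titrations)) {
    errors$titrations <- "no titration inputs in config"
  } else {
    for (i in seq_along(config$titrations)) {
      tag <- paste0("titration_", i)
      res <- tryCatch({
        s <- loadSeries(config$titrations[[i]], tag)
        s <- innerFilterCorrect(s)
        curve <- extractQuenchCurve(s, mode = mode,
                                    wavelength = config$wavelength)
        tK <- as.character(temperatureK(s))
        quench[[tK]] <- sternVolmerFit(curve, tau0 = tau0)
        binding[[tK]] <- doubleLogFit(curve, proteinConc(s))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) errors[[tag]] <- res
    }
  }

  mech <- NULL
  if (length(quench) >= 2L) {
    mech <- tryCatch(classifyMechanism(unname(quench), kqThreshold = kqThr),
                     error = function(e) { errors$mechanism <<- conditionMessage(e); NULL })
  } else errors$mechanism <- ">=2 temperatures required"

  thermo <- NULL
  if (length(binding) >= 2L) {
    KaByT <- setNames(vapply(binding, slot, numeric(1), "Ka"),
                      names(binding))
    thermo <- tryCatch(vantHoffFit(KaByT),
                       error = function(e) { errors$thermo <<- conditionMessage(e); NULL })
  } else errors$thermo <- ">=2 temperatures required"

  displacement <- NULL
  if (!is.null(config$marker_site1) && !is.null(config$marker_site2)) {
    displacement <- tryCatch({
      fitTernary <- function(entry, what) {
        s <- innerFilterCorrect(loadSeries(entry, what))
        doubleLogFit(extractQuenchCurve(s, mode = mode,
                                        wavelength = config$wavelength),
                     proteinConc(s))
      }
      t1 <- fitTernary(config$marker_site1, "marker_site1")
      t2 <- fitTernary(config$marker_site2, "marker_site2")
      bTag <- as.character(t1@temperature)
      bin <- binding[[bTag]] %||% stop(
        "no binary binding result at ", bTag, " K for displacement")
      displacementAnalysis(bin, t1, t2)
    }, error = function(e) { errors$displacement <<- conditionMessage(e); NULL })
  } else if (!is.null(config$marker_site1) || !is.null(config$marker_site2)) {
    errors$displacement <- "both marker_site1 and marker_site2 inputs are required"
  }

  shifts <- list()
  for (i in seq_along(config$synchronous %||% list())) {
    tag <- paste0("synchronous_", i)
    res <- tryCatch({
      s <- loadSeries(config$synchronous[[i]], tag)
      sh <- synchronousShift(s, shiftTolerance = shiftTol)
      nm <- if (!is.na(sh@deltaLambdaMode))
        paste0("dl", sh@deltaLambdaMode) else tag
      shifts[[nm]] <- sh
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[tag]] <- res
  }

  docking <- list()
  for (d in config$docking %||% list()) {
    docking[[length(docking) + 1L]] <- dockingPostprocess(
      d$delta_G_kcal, temperature = d$temperature %||% 298,
      siteLabel = d$site_label %||% "")
  }

  new("StudyReport",
      quenching = quench, binding = binding, mechanism = mech,
      thermo = thermo, displacement = displacement, shifts = shifts,
      docking = docking,
      provenance = list(
        config = config[setdiff(names(config),
                                c("titrations", "marker_site1",
                                  "marker_site2", "synchronous"))],
        analysis_parameters = list(tau0 = tau0, kq_threshold = kqThr,
                                   mode = mode, shift_tolerance = shiftTol),
        input_hashes = hashes,
        package_version = as.character(packageVersion("quenchbind"))),
      stageErrors = errors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a study report to JSON
#'
#' Full precision is retained in the JSON; rounding (2 decimals for kJ/mol
#' quantities, 2-3 significant figures for constants) happens only in the
#' printed tables of the `show` method.
#'
#' @param report a \linkS4class{StudyReport}.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly), or the JSON string when `path` is `NULL`.
#' @export
writeStudyReport <- function(report, path = NULL) {
  stopifnot(is(report, "StudyReport"))
  x <- list(
    quenching = lapply(report@quenching, .s4ToList),
    binding = lapply(report@binding, .s4ToList),
    mechanism = .s4ToList(report@mechanism),
    thermo = .s4ToList(report@thermo),
    displacement = .s4ToList(report@displacement),
    shifts = lapply(report@shifts, .s4ToList),
    docking = lapply(report@docking, .s4ToList),
    provenance = report@provenance,
    stage_errors = report@stageErrors)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                            null = "null"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport (quenchbind",
      object@provenance$package_version %||% "", ")\n")
  if (length(object@quenching)) {
    cat("\nQuenching (Stern-Volmer):\n  T(K)  Ksv(L/mol)   Kq(L/mol/s)  R^2\n")
    for (tn in names(object@quenching)) {
      r <- object@quenching[[tn]]
      cat(sprintf("  %-5s %-12.3g %-12.3g %.3f\n",
                  tn, r@Ksv, r@Kq, r@Rsquared))
    }
  }
  if (!is.null(object@mechanism))
    cat("  mechanism:", object@mechanism@verdict, "\n")
  if (length(object@binding)) {
    cat("\nBinding (double-log):\n  T(K)  Ka(L/mol)    n      R^2\n")
    for (tn in names(object@binding)) {
      r <- object@binding[[tn]]
      cat(sprintf("  %-5s %-12.3g %-6.3f %.3f\n",
                  tn, r@Ka, r@nSites, r@Rsquared))
    }
  }
  if (!is.null(object@thermo)) {
    th <- object@thermo
    cat(sprintf(
      "\nThermodynamics: dH = %.2f kJ/mol, dS = %.2f J/mol/K, force: %s\n",
      th@deltaH / 1000, th@deltaS, th@forceInterpretation))
    for (tn in names(th@deltaGPerT))
      cat(sprintf("  dG(%s K) = %.2f kJ/mol\n", tn,
                  th@deltaGPerT[[tn]] / 1000))
  }
  if (!is.null(object@displacement)) show(object@displacement)
  for (sh in object@shifts) show(sh)
  for (d in object@docking) show(d)
  if (length(object@stageErrors)) {
    cat("\nSkipped/failed stages:\n")
    for (nm in names(object@stageErrors))
      cat("  ", nm, ": ", object@stageErrors[[nm]], "\n", sep = "")
  }
  invisible(NULL)
})
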