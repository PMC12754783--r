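## Orchestration layer. This is an analysis package, not a shell tool: the
## exported surface is runPipeline(), and inst/scripts/g4ligandms-cli.R is a
## thin Rscript wrapper over it.

.allowedKeys <- list(
  simulate = c("out", "seed", "M0", "KD1", "KD2", "grid", "standard_conc",
               "noise_cv", "drift_per_uM", "response_ML", "response_ML2",
               "adduct_lambda"),
  screen   = c("out", "input", "detection_floor"),
  titrate  = c("out", "input", "M0", "standard_conc", "drift_model"),
  ccs      = c("out", "input", "z", "ion_mass", "temperature"),
  adducts  = c("out", "input", "min_excess", "n_sigma", "n_max"),
  melt     = c("out", "input", "low_window", "high_window"),
  cd       = c("out", "input", "conc", "path_length")
)

.configHash <- function(txt) {
  ## polynomial rolling hash; exact in doubles (< 2^53)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(command, config) {
  list(command = command,
       config_hash = .configHash(jsonlite::toJSON(config,
                                                  auto_unbox = TRUE)),
       package = "G4LigandMS",
       version = as.character(utils::packageVersion("G4LigandMS")))
}

#' Run a pipeline command
#'
#' Orchestrates end-to-end runs over the package's modules. Commands:
#' \describe{
#'   \item{simulate}{Generate a seeded synthetic titration series (per-point
#'     SpeciesTable CSVs plus \code{series.csv} manifest) under \code{out}.}
#'   \item{screen}{Read a cells manifest (\code{cells.csv} with columns dna,
#'     ligand, file, M0, L0) from \code{input} and write the fraction-bound
#'     heatmap CSV and per-cell JSON.}
#'   \item{titrate}{Read a titration directory (\code{series.csv} manifest)
#'     and write the fit report JSON and fitted-curve CSV.}
#'   \item{ccs}{Read drift records from \code{input}, run the stepped-field
#'     fit and write a CCS table CSV.}
#'   \item{adducts}{Read a SpeciesTable CSV and write per-stoichiometry
#'     specificity calls as JSON.}
#'   \item{melt}{Read melting curves and write per-curve Tm results as
#'     JSON.}
#'   \item{cd}{Read a CD CSV and write the molar-ellipticity table.}
#' }
#' Unknown configuration keys are rejected. Every report embeds a
#' provenance block (command, config hash, package version). Runs are
#' deterministic for a fixed seed.
#'
#' @param command One of the commands above.
#' @param config Named list, or path to a JSON file holding one.
#' @return Invisibly, a list of written report paths.
#' @export
runPipeline <- function(command, config) {
  command <- match.arg(command, names(.allowedKeys))
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .allowedKeys[[command]])
  if (length(unknown))
    stop("unknown config key(s) for '", command, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(command, config)
  writeReport <- function(obj, file) {
    obj$provenance <- prov
    path <- file.path(out, file)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  paths <- switch(command,
    simulate = {
      cfg <- simConfig(seed = config$seed %||% 1L,
                       noiseSigma = config$noise_cv %||% 0,
                       response = c(rM = 1,
                                    rML = config$response_ML %||% 1,
                                    rML2 = config$response_ML2 %||% 1),
                       adductLambda = config$adduct_lambda %||% 0.8)
      sim <- simulateTitration(M0 = config$M0 %||% 10,
                               grid = config$grid,
                               KD1 = config$KD1, KD2 = config$KD2,
                               cfg = cfg,
                               driftPerUM = config$drift_per_uM %||% 0,
                               standardConc = config$standard_conc %||% 4)
      files <- sprintf("point_%02d.csv", seq_along(sim$series@L0))
      for (i in seq_along(files))
        writeSpeciesTable(sim$series@tables[[i]], file.path(out, files[i]))
      utils::write.csv(data.frame(L0 = sim$series@L0, file = files),
                       file.path(out, "series.csv"), row.names = FALSE)
      list(writeReport(list(ledger = sim$ledger), "simulate_report.json"))
    },
    screen = {
      mf <- utils::read.csv(file.path(config$input, "cells.csv"))
      cells <- lapply(seq_len(nrow(mf)), function(i)
        list(dna = mf$dna[i], ligand = mf$ligand[i],
             table = readSpeciesTable(file.path(config$input, mf$file[i])),
             sample = bindingSample(mf$M0[i], mf$L0[i])))
      sc <- screenPanel(cells,
                        detectionFloor = config$detection_floor %||% 0.01)
      csv <- file.path(out, "heatmap.csv")
      utils::write.csv(sc$fractionBound, csv, row.names = TRUE)
      meta <- exportScreen(sc)
      list(csv, writeReport(list(cells = meta), "screen_report.json"))
    },
    titrate = {
      series <- readTitrationDir(config$input, M0 = config$M0,
                                 standardConc = config$standard_conc %||% 4)
      fit <- fitTitration(series,
                          driftModel = config$drift_model %||% "linear")
      curve <- file.path(out, "fitted_curve.csv")
      rep <- exportTitrationFit(fit, series, curvePath = curve)
      list(curve, writeReport(rep, "titration_fit.json"))
    },
    ccs = {
      records <- readDriftRecords(config$input)
      fit <- fitSteppedField(records)
      ccs <- masonSchamp(fit@K0, config$z, config$ion_mass,
                         config$temperature %||%
                           records[[1L]]@temperature)
      csv <- file.path(out, "ccs.csv")
      utils::write.csv(data.frame(K0 = fit@K0, t0 = fit@t0,
                                  r_squared = fit@rSquared,
                                  z = config$z, ccs = ccs),
                       csv, row.names = FALSE)
      list(csv, writeReport(list(K0 = fit@K0, t0 = fit@t0, ccs = ccs),
                            "ccs_report.json"))
    },
    adducts = {
      tb <- readSpeciesTable(config$input)
      nMax <- config$n_max %||% 6
      calls <- lapply(stats::setNames(0:2, c("M", "ML", "ML2")),
                      function(lc) {
        prof <- adductProfileFromTable(tb, lc, nMax = nMax)
        if (sum(prof@counts) <= 0) return(NULL)
        callSpecific(prof, minExcess = config$min_excess %||% 1.5,
                     nSigma = config$n_sigma %||% 3)
      })
      calls <- Filter(Negate(is.null), calls)
      path <- file.path(out, "adduct_calls.json")
      out2 <- exportAdductCalls(calls)
      list(writeReport(list(calls = out2), "adduct_calls.json"))
    },
    melt = {
      curves <- readMeltingCurves(config$input)
      res <- lapply(curves, function(cv) {
        bl <- suppressWarnings(
          fitBaselines(cv, lowWindow = config$low_window,
                       highWindow = config$high_window))
        bl <- refineBaselinesTwoState(cv, bl)
        mr <- suppressWarnings(meltingTemperature(foldedFraction(cv, bl)))
        list(tm = if (is.na(mr@tm)) "undetermined" else mr@tm,
             multiple_crossings = mr@multipleCrossings)
      })
      list(writeReport(list(curves = res), "melt_report.json"))
    },
    cd = {
      spec <- readCDSpectrum(config$input, conc = config$conc,
                             pathLength = config$path_length)
      de <- molarEllipticity(spec)
      csv <- file.path(out, "molar_ellipticity.csv")
      utils::write.csv(data.frame(wavelength = spec@wavelength,
                                  delta_epsilon = de),
                       csv, row.names = FALSE)
      list(csv, writeReport(list(n_points = length(de)), "cd_report.json"))
    })
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
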