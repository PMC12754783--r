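#' Construct a titration series
#'
#' @param L0 Distinct ligand concentrations (uM), >= 0; >= 3 points required
#'   (>= 4 recommended: the model has 3 free shape parameters plus scale).
#' @param tables List of \linkS4class{SpeciesTable}, one per point.
#' @param M0 DNA concentration (uM).
#' @param standardConc dT6 concentration (uM).
#' @return A \linkS4class{TitrationSeries}.
#' @export
titrationSeries <- function(L0, tables, M0, standardConc = 4) {
  new("TitrationSeries", L0 = as.numeric(L0), tables = tables, M0 = M0,
      standardConc = standardConc)
}

#' Internal-standard response drift analysis
#'
#' The ratio of total DNA intensity to dT6 internal-standard intensity is
#' regressed against ligand concentration. A drifting ratio indicates that
#' foldamer concentration changes the electrospray response of DNA; each
#' point's correction factor renormalizes it to the L0 = 0 ratio.
#'
#' @param series A \linkS4class{TitrationSeries}.
#' @param model "linear" (ratio affine in L0, the default) or "constant".
#' @return A list: \code{drift} (relative slope, per uM), \code{factors}
#'   (per-point correction factors), \code{intercept}, \code{slope},
#'   \code{excluded} (points with zero standard intensity, corrected with
#'   factor 1 and a warning).
#' @export
responseDrift <- function(series, model = c("linear", "constant")) {
  stopifnot(is(series, "TitrationSeries"))
  model <- match.arg(model)
  std <- vapply(series@tables, standardIntensity, numeric(1))
  tot <- vapply(series@tables, function(tb)
    sum(stoichiometryIntensities(tb, 0:2)), numeric(1))
  excluded <- std <= 0
  if (any(excluded))
    warning(sum(excluded),
            " point(s) with zero standard intensity excluded from drift fit")
  if (all(excluded)) stop("no usable internal-standard intensities",
                          call. = FALSE)
  ratio <- tot / std
  L0 <- series@L0
  if (model == "constant" || sum(!excluded) < 2L) {
    b0 <- mean(ratio[!excluded])
    b1 <- 0
  } else {
    fit <- stats::lm(ratio ~ L0, subset = !excluded)
    b0 <- unname(stats::coef(fit)[1L])
    b1 <- unname(stats::coef(fit)[2L])
  }
  pred <- b0 + b1 * L0
  factors <- ifelse(excluded | pred <= 0, 1, b0 / pred)
  list(drift = b1 / b0, factors = factors, intercept = b0, slope = b1,
       excluded = excluded)
}

#' Predicted species intensities for one titration point
#'
#' Solves the sequential-binding equilibrium and applies relative response
#' factors (r_M is fixed at 1): intensities are proportional to (M, r_ML x
#' ML, r_ML2 x ML2) up to a shared electrospray scale.
#'
#' @param sample A \linkS4class{BindingSample}.
#' @param KD1,KD2 Dissociation constants (uM), > 0.
#' @param rML,rML2 Relative response factors (>= 0).
#' @return Named numeric c(M =, ML =, ML2 =).
#' @export
modelIntensities <- function(sample, KD1, KD2, rML = 1, rML2 = 1) {
  stopifnot(rML >= 0, rML2 >= 0)
  st <- solveEquilibrium(sample, KD1, KD2)
  c(M = st@freeM, ML = rML * st@ML, ML2 = rML2 * st@ML2)
}

## Observed per-point intensity matrix (rows = points, cols = M, ML, ML2),
## after optional drift correction.
.titrationIntensityMatrix <- function(series, driftModel) {
  ints <- t(vapply(series@tables, function(tb)
    stoichiometryIntensities(tb, 0:2), numeric(3)))
  colnames(ints) <- c("M", "ML", "ML2")
  if (driftModel != "none") {
    std <- vapply(series@tables, standardIntensity, numeric(1))
    if (any(std > 0)) {
      rd <- suppressWarnings(responseDrift(series, model = driftModel))
      ints <- ints * rd$factors
      attr(ints, "drift") <- rd$drift
    } else attr(ints, "drift") <- 0
  } else attr(ints, "drift") <- 0
  ints
}

#' Fit a titration series with the sequential-binding model
#'
#' Weighted least squares on normalized species intensities (each point's
#' intensities divided by their sum, removing the unknown global spray
#' scale), with KD1, KD2 and the complex response factors r_ML, r_ML2 free.
#' Parameters are log-transformed and bounded (KD in [1e-4, 1e4] uM,
#' responses in [0.01, 100]). Weights are Poisson-like (sigma proportional
#' to sqrt(I), floored at 3 x the table noise sigma). Standard errors come
#' from the local quadratic approximation at the optimum.
#'
#' @param series A \linkS4class{TitrationSeries}.
#' @param init Optional named vector c(KD1 =, KD2 =, rML =, rML2 =); the
#'   default initializes the KDs from the single-point estimator at the
#'   mid-titration point and the responses at 1.
#' @param driftModel "linear", "constant" or "none": internal-standard
#'   response-drift correction applied to the intensities before fitting.
#' @param weighting "poisson" (default) or "equal".
#' @return A \linkS4class{TitrationFit}.
#' @export
fitTitration <- function(series, init = NULL,
                         driftModel = c("linear", "constant", "none"),
                         weighting = c("poisson", "equal")) {
  stopifnot(is(series, "TitrationSeries"))
  validObject(series)
  if (length(series@L0) < 3L)
    stop("at least 3 titration points required (3 free shape parameters); ",
         ">= 4 recommended", call. = FALSE)
  driftModel <- match.arg(driftModel)
  weighting <- match.arg(weighting)
  ints <- .titrationIntensityMatrix(series, driftModel)
  driftCoef <- attr(ints, "drift")
  tot <- rowSums(ints)
  usable <- tot > 0
  if (sum(ints[, "ML"]) + sum(ints[, "ML2"]) <= 0) {
    return(new("TitrationFit", KD1 = NA_real_, KD2 = NA_real_,
               KD1SE = NA_real_, KD2SE = NA_real_, rML = NA_real_,
               rML2 = NA_real_, drift = driftCoef, residualNorm = NA_real_,
               converged = TRUE, censor = "above"))
  }
  fObs <- ints[usable, , drop = FALSE] / tot[usable]
  L0u <- series@L0[usable]
  ## Poisson-like sigma on fractions via the delta method, floored at the
  ## noise threshold so empty channels keep finite weight.
  if (weighting == "poisson") {
    floorI <- pmax(3 * vapply(series@tables, noiseSigma, numeric(1))[usable],
                   1e-6 * max(tot))
    sigI <- sqrt(pmax(ints[usable, , drop = FALSE], floorI))
    sigF <- sigI / tot[usable]
    sigF <- sigF / mean(sigF)       # relative weights only
  } else {
    sigF <- matrix(1, nrow(fObs), 3L)
  }
  lower <- log(c(1e-4, 1e-4, 0.01, 0.01))
  upper <- log(c(1e4, 1e4, 100, 100))
  if (is.null(init)) {
    mid <- which.min(abs(series@L0 - stats::median(series@L0[series@L0 > 0])))
    smpl <- bindingSample(series@M0, series@L0[mid],
                          standardConc = series@standardConc)
    conc <- suppressWarnings(
      concentrationsFromIntensities(ints[mid, ], smpl))
    k1 <- 1; k2 <- 4
    if (!any(is.na(conc))) {
      L <- freeLigand(smpl, conc["ML"], conc["ML2"])
      br <- kdSinglePoint(conc["M"], conc["ML"], conc["ML2"], L)
      if (br@KD1Censor == "none") k1 <- br@KD1
      if (br@KD2Censor == "none") k2 <- br@KD2 else k2 <- 4 * k1
    }
    init <- c(KD1 = k1, KD2 = k2, rML = 1, rML2 = 1)
  }
  theta0 <- pmin(pmax(log(init), lower + 1e-9), upper - 1e-9)
  predict_f <- function(theta) {
    p <- exp(theta)
    t(vapply(L0u, function(l0) {
      mi <- modelIntensities(bindingSample(series@M0, l0), p[1L], p[2L],
                             p[3L], p[4L])
      mi / sum(mi)
    }, numeric(3)))
  }
  objective <- function(theta) {
    r <- (fObs - predict_f(theta)) / sigF
    sum(r * r)
  }
  opt <- stats::optim(theta0, objective, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(factr = 1e1, maxit = 1000L))
  ## polish: the quadratic valley near the optimum can stall L-BFGS-B
  opt2 <- stats::optim(opt$par, function(th)
    objective(pmin(pmax(th, lower), upper)),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 2000L))
  converged <- opt$convergence == 0
  if (opt2$value < opt$value)
    opt <- list(par = pmin(pmax(opt2$par, lower), upper),
                value = opt2$value)
  converged <- converged || opt2$convergence == 0
  theta <- opt$par
  ssr <- opt$value
  nObs <- length(fObs)
  dof <- max(nObs - length(theta), 1L)
  se <- rep(NA_real_, 4L)
  H <- tryCatch(stats::optimHess(theta, objective), error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(2 * solve(H) * max(ssr, 1e-30) / dof,
                    error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  p <- unname(exp(theta))
  new("TitrationFit", KD1 = p[1L], KD2 = p[2L],
      KD1SE = p[1L] * se[1L], KD2SE = p[2L] * se[2L],
      rML = p[3L], rML2 = p[4L], drift = driftCoef,
      residualNorm = sqrt(ssr), converged = converged, censor = "none")
}

#' Read a titration series from a directory
#'
#' Expects a manifest \code{series.csv} with columns \code{L0} and
#' \code{file} (per-point SpeciesTable CSVs relative to the directory).
#'
#' @param dir Directory path.
#' @param M0 DNA concentration (uM).
#' @param standardConc dT6 concentration (uM).
#' @return A \linkS4class{TitrationSeries}.
#' @export
readTitrationDir <- function(dir, M0, standardConc = 4) {
  manifest <- file.path(dir, "series.csv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  mf <- utils::read.csv(manifest)
  tables <- lapply(file.path(dir, mf$file), readSpeciesTable)
  titrationSeries(mf$L0, tables, M0, standardConc)
}

#' Export a titration fit
#'
#' Writes a JSON fit report and a fitted-curve CSV (fine L0 grid with the
#' predicted species fractions and fraction of DNA bound).
#'
#' @param fit A \linkS4class{TitrationFit}.
#' @param series The fitted \linkS4class{TitrationSeries}.
#' @param jsonPath,curvePath Output paths (NULL skips).
#' @param nGrid Number of grid points for the fitted curve.
#' @return Invisibly, the report list.
#' @export
exportTitrationFit <- function(fit, series, jsonPath = NULL,
                               curvePath = NULL, nGrid = 101L) {
  report <- list(KD1 = fit@KD1, KD1_se = fit@KD1SE, KD2 = fit@KD2,
                 KD2_se = fit@KD2SE, r_ML = fit@rML, r_ML2 = fit@rML2,
                 drift = fit@drift, residual_norm = fit@residualNorm,
                 converged = fit@converged, censor = fit@censor,
                 M0 = series@M0, L0 = series@L0)
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(curvePath) && fit@censor == "none") {
    grid <- seq(0, max(series@L0), length.out = nGrid)
    curve <- t(vapply(grid, function(l0) {
      st <- solveEquilibrium(bindingSample(series@M0, l0), fit@KD1, fit@KD2)
      c(L0 = l0, M = st@freeM, ML = st@ML, ML2 = st@ML2,
        fraction_bound = fractionBound(st@freeM, st@ML, st@ML2))
    }, numeric(5)))
    utils::write.csv(as.data.frame(curve), curvePath, row.names = FALSE)
  }
  invisible(report)
}
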