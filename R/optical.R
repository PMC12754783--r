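#' Construct a CD spectrum
#'
#' @param wavelength Ascending wavelengths (nm).
#' @param ellipticity Blank-subtracted ellipticity (mdeg).
#' @param conc Molar oligonucleotide concentration (mol/L).
#' @param pathLength Path length (cm).
#' @return A \linkS4class{CDSpectrum}.
#' @export
cdSpectrum <- function(wavelength, ellipticity, conc, pathLength) {
  new("CDSpectrum", wavelength = as.numeric(wavelength),
      ellipticity = as.numeric(ellipticity), conc = conc,
      pathLength = pathLength)
}

#' Construct a melting curve
#'
#' @param temperature Temperatures (degC), monotone within the ramp.
#' @param absorbance Absorbance values.
#' @param wavelength Monitoring wavelength (260, 295 or 335 nm).
#' @param direction "heating" or "cooling".
#' @param rampRate Ramp rate (degC/min).
#' @return A \linkS4class{MeltingCurve}.
#' @export
meltingCurve <- function(temperature, absorbance, wavelength = 295,
                         direction = "heating", rampRate = 0.2) {
  new("MeltingCurve", temperature = as.numeric(temperature),
      absorbance = as.numeric(absorbance), wavelength = wavelength,
      direction = direction, rampRate = rampRate)
}

#' Convert ellipticity to molar ellipticity
#'
#' Delta-epsilon = theta / (32980 c l), point-wise, with theta in mdeg, c in
#' mol/L and l in cm.
#'
#' @param spec A \linkS4class{CDSpectrum} (blank already subtracted).
#' @return Numeric vector of molar ellipticity (M-1 cm-1), one per
#'   wavelength.
#' @export
molarEllipticity <- function(spec) {
  stopifnot(is(spec, "CDSpectrum"))
  validObject(spec)
  spec@ellipticity / (msConstants("cd_factor") * spec@conc * spec@pathLength)
}

#' Subtract the 335 nm internal reference channel
#'
#' The absorbance at 335 nm carries no DNA transition and serves as an
#' additive drift reference; it is interpolated onto the analytical curve's
#' temperatures and subtracted before baseline fitting.
#'
#' @param curve Analytical \linkS4class{MeltingCurve} (260 or 295 nm).
#' @param reference 335 nm \linkS4class{MeltingCurve}.
#' @return Corrected \linkS4class{MeltingCurve}.
#' @export
subtractReference <- function(curve, reference) {
  stopifnot(is(curve, "MeltingCurve"), is(reference, "MeltingCurve"))
  if (reference@wavelength != 335)
    stop("reference curve must be the 335 nm channel", call. = FALSE)
  ref <- stats::approx(reference@temperature, reference@absorbance,
                       xout = curve@temperature, rule = 2)$y
  meltingCurve(curve@temperature, curve@absorbance - ref,
               curve@wavelength, curve@direction, curve@rampRate)
}

#' Fit folded and unfolded baselines
#'
#' Ordinary linear fits of absorbance against temperature inside two
#' flanking windows (defaults: the lowest and highest 15% of the temperature
#' span). Which window belongs to the folded species follows the sign
#' convention of the monitored wavelength: at 295 nm the folded G4 absorbs
#' higher, at 260 nm the unfolded strand does (duplex hyperchromicity).
#'
#' @param curve A \linkS4class{MeltingCurve} (reference-corrected).
#' @param lowWindow,highWindow Numeric length-2 temperature intervals; NULL
#'   uses the default flanks. Windows must not overlap and must contain at
#'   least 5 points each.
#' @param refine Number of refinement iterations: after the window fits,
#'   baselines are refit on the points the current folded fraction assigns
#'   confidently to one state (theta > 0.95 or < 0.05), which removes the
#'   bias from transition tails reaching into fixed windows. 0 disables.
#' @return List with \code{unfolded} and \code{folded} affine coefficients
#'   c(intercept, slope) (the L0 and L1 of the folded-fraction conversion).
#' @export
fitBaselines <- function(curve, lowWindow = NULL, highWindow = NULL,
                         refine = 3L) {
  stopifnot(is(curve, "MeltingCurve"))
  temp <- curve@temperature
  A <- curve@absorbance
  span <- range(temp)
  if (is.null(lowWindow))
    lowWindow <- c(span[1L], span[1L] + 0.15 * diff(span))
  if (is.null(highWindow))
    highWindow <- c(span[2L] - 0.15 * diff(span), span[2L])
  lowWindow <- sort(lowWindow)
  highWindow <- sort(highWindow)
  if (lowWindow[2L] > highWindow[1L])
    stop("baseline windows overlap", call. = FALSE)
  Arange <- diff(range(A))
  fitOne <- function(idx, checkCurvature = TRUE) {
    if (sum(idx) < 5L)
      stop("baseline window must contain at least 5 points", call. = FALSE)
    t <- temp[idx]; a <- A[idx]
    fit <- stats::lm(a ~ t)
    if (checkCurvature && sum(idx) >= 6L) {
      ## curvature beyond a line signals a window inside the transition
      fit2 <- stats::lm(a ~ t + I(t^2))
      dev <- max(abs(stats::fitted(fit2) - stats::fitted(fit)))
      if (dev > 0.005 * Arange)
        warning("baseline window shows curvature (", signif(dev, 2),
                " absorbance); window may lie inside the transition")
    }
    unname(stats::coef(fit))
  }
  cLow <- fitOne(temp >= lowWindow[1L] & temp <= lowWindow[2L])
  cHigh <- fitOne(temp >= highWindow[1L] & temp <= highWindow[2L])
  mid <- function(co, win) co[1L] + co[2L] * mean(win)
  ## 295 nm: folded absorbs higher; 260 nm: unfolded absorbs higher
  foldedIsHigher <- curve@wavelength == 295
  if ((mid(cLow, lowWindow) >= mid(cHigh, highWindow)) == foldedIsHigher) {
    bl <- list(unfolded = cHigh, folded = cLow)
  } else {
    bl <- list(unfolded = cLow, folded = cHigh)
  }
  for (i in seq_len(refine)) {
    L0 <- bl$unfolded[1L] + bl$unfolded[2L] * temp
    L1 <- bl$folded[1L] + bl$folded[2L] * temp
    den <- L0 - L1
    if (any(abs(den) < 1e-12 * max(abs(A), 1))) break
    theta <- (L0 - A) / den
    iU <- theta < 0.05
    iF <- theta > 0.95
    if (sum(iU) < 5L || sum(iF) < 5L) break
    bl <- list(unfolded = fitOne(iU, checkCurvature = FALSE),
               folded = fitOne(iF, checkCurvature = FALSE))
  }
  bl
}

#' Model-assisted baseline refinement
#'
#' Window baselines extrapolate across the transition, so small two-state
#' tails reaching into the windows bias the crossing temperature whenever
#' the transition is not fully developed within the scan. This refinement
#' fits the full two-state decomposition A(T) = L0(T) (1 - theta) + L1(T)
#' theta, with theta the two-state sigmoid, jointly in the four baseline
#' coefficients and the two shape parameters, initialized from the window
#' estimates. Only the refined baselines are returned; the folded-fraction
#' conversion and the 0.5-crossing definition of T_M are unchanged (the
#' sigmoid serves as a baseline model, its shape parameters are not
#' reported).
#'
#' @param curve A \linkS4class{MeltingCurve}.
#' @param baselines Initial baselines; default from \code{\link{fitBaselines}}.
#' @return A baselines list as from \code{\link{fitBaselines}}. Falls back
#'   to the initial estimates (with a warning) when the global fit fails,
#'   e.g. on multiphasic curves.
#' @export
refineBaselinesTwoState <- function(curve, baselines = NULL) {
  stopifnot(is(curve, "MeltingCurve"))
  if (is.null(baselines))
    baselines <- suppressWarnings(fitBaselines(curve))
  temp <- curve@temperature
  A <- curve@absorbance
  R <- msConstants("R_gas")
  ## initial shape: crossing and slope of the window-based theta curve
  init <- tryCatch({
    ffc <- foldedFraction(curve, baselines)
    mr <- suppressWarnings(meltingTemperature(ffc))
    tm0 <- if (is.na(mr@tm)) stats::median(temp) else mr@tm
    i <- which.min(abs(temp - tm0))
    ii <- max(2L, min(i, length(temp) - 1L))
    slope <- abs((ffc@theta[ii + 1L] - ffc@theta[ii - 1L]) /
                 (temp[ii + 1L] - temp[ii - 1L]))
    dH0 <- max(5e4, min(1e6, 4 * R * (tm0 + 273.15)^2 * slope))
    c(tm = tm0, dH = dH0)
  }, error = function(e) c(tm = stats::median(temp), dH = 2e5))
  obj <- function(par) {
    TK <- temp + 273.15
    th <- 1 / (1 + exp(-par[6L] / R * (1 / TK - 1 / (par[5L] + 273.15))))
    pred <- (par[1L] + par[2L] * temp) * (1 - th) +
      (par[3L] + par[4L] * temp) * th
    sum((A - pred)^2)
  }
  start <- c(baselines$unfolded, baselines$folded, init["tm"], init["dH"])
  fit <- tryCatch(
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000L, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(fit))
    fit <- tryCatch(
      stats::optim(fit$par, obj, method = "BFGS",
                   control = list(maxit = 1000L, reltol = 1e-14)),
      error = function(e) fit)
  if (is.null(fit) || !is.finite(fit$value) ||
      fit$value > obj(start) + 1e-12) {
    warning("two-state refinement failed; keeping window baselines")
    return(baselines)
  }
  list(unfolded = unname(fit$par[1:2]), folded = unname(fit$par[3:4]))
}

#' Convert a melting curve to folded fraction
#'
#' theta(T) = (L0(T) - A(T)) / (L0(T) - L1(T)) with L0 and L1 the unfolded
#' and folded baselines. Values may fall slightly outside [0, 1] from noise
#' and are preserved, not clipped.
#'
#' @param curve A \linkS4class{MeltingCurve}.
#' @param baselines Result of \code{\link{fitBaselines}}.
#' @return A \linkS4class{FoldedFractionCurve}.
#' @export
foldedFraction <- function(curve, baselines) {
  stopifnot(is(curve, "MeltingCurve"))
  temp <- curve@temperature
  L0 <- baselines$unfolded[1L] + baselines$unfolded[2L] * temp
  L1 <- baselines$folded[1L] + baselines$folded[2L] * temp
  den <- L0 - L1
  if (any(abs(den) < 1e-12 * max(abs(curve@absorbance), 1)))
    stop("baselines coincide within the data range", call. = FALSE)
  theta <- (L0 - curve@absorbance) / den
  new("FoldedFractionCurve", temperature = temp, theta = theta,
      baselineUnfolded = baselines$unfolded,
      baselineFolded = baselines$folded, direction = curve@direction)
}

#' Melting temperature
#'
#' T_M is the temperature at which the folded fraction crosses 0.5, located
#' by linear interpolation at the first crossing in the ramp direction. With
#' multiple crossings the first is reported and the result flagged. When
#' theta never reaches 0.5 the result is undetermined, with the observed
#' theta range reported.
#'
#' @param ffc A \linkS4class{FoldedFractionCurve}.
#' @return A \linkS4class{MeltingResult}.
#' @export
meltingTemperature <- function(ffc) {
  stopifnot(is(ffc, "FoldedFractionCurve"))
  temp <- ffc@temperature
  theta <- ffc@theta
  if (temp[1L] > temp[length(temp)]) {  # analyse along the ramp direction
    temp <- rev(temp); theta <- rev(theta)
    ord <- rev(seq_along(temp))
  }
  d <- theta - 0.5
  cross <- which(d[-length(d)] * d[-1L] < 0 | d[-length(d)] == 0)
  if (!length(cross)) {
    if (d[length(d)] == 0) cross <- length(d)
    else return(new("MeltingResult", tm = NA_real_,
                    thetaRange = range(theta), multipleCrossings = FALSE))
  }
  i <- cross[1L]
  tm <- if (d[i] == 0) temp[i] else
    temp[i] + (0.5 - theta[i]) * (temp[i + 1L] - temp[i]) /
      (theta[i + 1L] - theta[i])
  multi <- length(cross) > 1L
  if (multi) warning("theta crosses 0.5 more than once; reporting the ",
                     "first crossing (possible multiphasic melt)")
  new("MeltingResult", tm = tm, thetaRange = range(theta),
      multipleCrossings = multi)
}

#' Ligand-induced melting temperature shift
#'
#' Delta T_m = T_m(with ligand) - T_m(without), signed. Undetermined (NA)
#' when either T_m is undetermined.
#'
#' @param withLigand,without \linkS4class{MeltingResult} objects.
#' @return Signed temperature difference (degC) or NA.
#' @export
deltaTm <- function(withLigand, without) {
  stopifnot(is(withLigand, "MeltingResult"), is(without, "MeltingResult"))
  if (is.na(withLigand@tm) || is.na(without@tm)) return(NA_real_)
  withLigand@tm - without@tm
}

#' Heating/cooling hysteresis
#'
#' |T_m(heating) - T_m(cooling)|; slow-folding G4s show hysteresis at finite
#' ramp rates.
#'
#' @param heating,cooling \linkS4class{MeltingResult} objects.
#' @return Absolute difference (degC) or NA.
#' @export
hysteresis <- function(heating, cooling) {
  stopifnot(is(heating, "MeltingResult"), is(cooling, "MeltingResult"))
  if (is.na(heating@tm) || is.na(cooling@tm)) return(NA_real_)
  abs(heating@tm - cooling@tm)
}

#' Read / write melting curves as CSV
#'
#' Columns: temperature, absorbance, wavelength, direction.
#'
#' @param path CSV path.
#' @return A list of \linkS4class{MeltingCurve}, one per
#'   (wavelength, direction) combination present.
#' @export
readMeltingCurves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("temperature", "absorbance", "wavelength", "direction")
  if (!all(need %in% names(df)))
    stop("melting CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  groups <- split(df, list(df$wavelength, df$direction), drop = TRUE)
  lapply(groups, function(g)
    meltingCurve(g$temperature, g$absorbance, g$wavelength[1L],
                 g$direction[1L]))
}

#' @rdname readMeltingCurves
#' @param curves List of \linkS4class{MeltingCurve}.
#' @export
writeMeltingCurves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(temperature = cv@temperature, absorbance = cv@absorbance,
               wavelength = cv@wavelength, direction = cv@direction)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CD spectrum from CSV
#'
#' Columns: wavelength, mdeg.
#'
#' @param path CSV path.
#' @param conc Molar concentration (mol/L).
#' @param pathLength Path length (cm).
#' @return A \linkS4class{CDSpectrum}.
#' @export
readCDSpectrum <- function(path, conc, pathLength) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("wavelength", "mdeg") %in% names(df)))
    stop("CD CSV must have columns: wavelength, mdeg", call. = FALSE)
  cdSpectrum(df$wavelength, df$mdeg, conc, pathLength)
}
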