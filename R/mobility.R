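#' Construct a drift record
#'
#' One arrival-time distribution recorded at a fixed drift voltage, with the
#' drift-tube pressure and temperature metadata needed for the stepped-field
#' analysis.
#'
#' @param time Ascending arrival times (ms).
#' @param intensity Non-negative intensities.
#' @param deltaV Drift voltage (V).
#' @param pressure Drift-tube pressure (Torr).
#' @param temperature Drift-tube temperature (K).
#' @return A \linkS4class{DriftRecord}.
#' @export
driftRecord <- function(time, intensity, deltaV, pressure, temperature) {
  new("DriftRecord", time = as.numeric(time),
      intensity = as.numeric(intensity), deltaV = deltaV,
      pressure = pressure, temperature = temperature)
}

#' Apex arrival time by parabolic interpolation
#'
#' Sub-bin apex estimate: a parabola through the maximum intensity point and
#' its two neighbours. Falls back to the raw maximum at the boundaries.
#'
#' @param record A \linkS4class{DriftRecord}.
#' @return Apex time (ms).
#' @export
apexTime <- function(record) {
  stopifnot(is(record, "DriftRecord"))
  y <- record@intensity
  t <- record@time
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(t[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(t[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  dt <- (t[i + 1L] - t[i - 1L]) / 2
  t[i] + delta * dt
}

#' Stepped-field linear fit for reduced mobility
#'
#' Regresses the apex arrival time against (L^2 p T0) / (p0 T) x 1/deltaV
#' across drift voltages: the slope is 1/K0 and the intercept the dead time
#' t0. Pressure and temperature must be consistent across records.
#'
#' @param records List of >= 2 \linkS4class{DriftRecord} for one species at
#'   distinct voltages.
#' @param peakPicker Function DriftRecord -> apex time (ms); default
#'   \code{\link{apexTime}}.
#' @param L Drift-tube length (cm); default 78.1.
#' @param T0,p0 Reference temperature (K) and pressure (Torr) of the reduced
#'   mobility; registry defaults 273.15 K and 760 Torr.
#' @param ptTolerance Maximum allowed relative spread of p and T.
#' @return A \linkS4class{SteppedFieldFit}.
#' @export
fitSteppedField <- function(records, peakPicker = apexTime,
                            L = msConstants("drift_tube_length"),
                            T0 = msConstants("T0"), p0 = msConstants("p0"),
                            ptTolerance = 0.02) {
  if (length(records) < 2L)
    stop("at least 2 drift voltages required", call. = FALSE)
  dV <- vapply(records, function(r) r@deltaV, numeric(1))
  if (length(unique(dV)) < 2L)
    stop("drift voltages must be distinct", call. = FALSE)
  p <- vapply(records, function(r) r@pressure, numeric(1))
  temp <- vapply(records, function(r) r@temperature, numeric(1))
  if (diff(range(p)) / mean(p) > ptTolerance ||
      diff(range(temp)) / mean(temp) > ptTolerance)
    stop("pressure/temperature inconsistent across records", call. = FALSE)
  tA <- vapply(records, peakPicker, numeric(1))
  x <- (L^2 * p * T0) / (p0 * temp) / dV        # cm^2 / V
  fit <- stats::lm(tA ~ x)
  slope <- unname(stats::coef(fit)[2L])         # ms per (cm^2/V)
  if (!is.finite(slope) || slope <= 0)
    stop("fitted mobility is non-positive; check arrival times",
         call. = FALSE)
  K0 <- 1000 / slope                            # cm^2 V^-1 s^-1
  r2 <- if (length(records) > 2L) summary(fit)$r.squared else 1
  new("SteppedFieldFit", K0 = K0, t0 = unname(stats::coef(fit)[1L]),
      rSquared = r2, nPoints = length(records))
}

#' Collision cross section from reduced mobility (Mason-Schamp)
#'
#' CCS = (3/16) (z e) / (N0 K0) sqrt(2 pi / (mu k_B T)) with the reduced
#' mass mu = m_ion m_gas / (m_ion + m_gas), N0 the Loschmidt gas number
#' density, and helium as drift gas.
#'
#' @param K0 Reduced mobility (cm2 V-1 s-1), > 0.
#' @param z Charge magnitude.
#' @param ionMass Ion mass (Da).
#' @param temperature Drift-tube temperature (K).
#' @param gasMass Drift-gas mass (Da); default helium.
#' @param N0 Gas number density at the mobility reference state (m^-3).
#' @return CCS in Angstrom^2.
#' @export
masonSchamp <- function(K0, z, ionMass, temperature,
                        gasMass = msConstants("m_He"),
                        N0 = msConstants("N0")) {
  stopifnot(K0 > 0, z >= 1, ionMass > 0, temperature > 0)
  const <- msConstants()
  mu <- ionMass * gasMass / (ionMass + gasMass) * const$amu_kg
  K0si <- K0 * 1e-4                              # m^2 V^-1 s^-1
  ccs <- (3 / 16) * (z * const$e_charge) / (N0 * K0si) *
    sqrt(2 * pi / (mu * const$k_B * temperature))
  ccs * 1e20                                     # m^2 -> A^2
}

#' Reduced mobility from collision cross section
#'
#' Exact inverse of \code{\link{masonSchamp}}.
#'
#' @param ccs CCS (Angstrom^2), > 0.
#' @inheritParams masonSchamp
#' @return K0 in cm2 V-1 s-1.
#' @export
invertMasonSchamp <- function(ccs, z, ionMass, temperature,
                              gasMass = msConstants("m_He"),
                              N0 = msConstants("N0")) {
  stopifnot(ccs > 0)
  const <- msConstants()
  mu <- ionMass * gasMass / (ionMass + gasMass) * const$amu_kg
  K0si <- (3 / 16) * (z * const$e_charge) / (N0 * ccs * 1e-20) *
    sqrt(2 * pi / (mu * const$k_B * temperature))
  K0si * 1e4
}

#' Validate instrument settings against a reference calibrant CCS
#'
#' Settings are accepted when the measured calibrant CCS is within the
#' tolerance (default 2%) of the published reference value:
#' |measured - reference| / reference <= tolerance.
#'
#' @param measured Measured CCS (Angstrom^2).
#' @param reference Published reference CCS (Angstrom^2).
#' @param tolerance Relative tolerance (default 0.02).
#' @return List with \code{pass} (logical) and \code{relativeError}.
#' @export
validateCalibrant <- function(measured, reference, tolerance = 0.02) {
  stopifnot(measured > 0, reference > 0)
  err <- abs(measured - reference) / reference
  list(pass = err <= tolerance, relativeError = err)
}

#' Reconstruct a CCS distribution from one arrival-time distribution
#'
#' Transforms the arrival-time axis point-wise through the stepped-field
#' relation inverted at this record's voltage, pressure and temperature:
#' t_A -> K0(t_A) -> CCS. Because CCS is linear in (t_A - t0) the transform
#' is strictly monotone and preserves mode count; abundance is carried over
#' as a density with the Jacobian |dt/dCCS| so integrated area is preserved.
#' Points with t_A <= t0 are dropped with a warning.
#'
#' @param record A \linkS4class{DriftRecord}.
#' @param fit A \linkS4class{SteppedFieldFit} for this species (provides t0).
#' @param z Charge magnitude of the species.
#' @param ionMass Ion mass (Da).
#' @param L,T0,p0 Drift-tube length and mobility reference state.
#' @param gasMass,N0 Drift-gas mass and number density.
#' @return data.frame with ascending \code{ccs} (Angstrom^2) and
#'   \code{abundance} (density per Angstrom^2).
#' @export
ccsDistribution <- function(record, fit, z, ionMass,
                            L = msConstants("drift_tube_length"),
                            T0 = msConstants("T0"),
                            p0 = msConstants("p0"),
                            gasMass = msConstants("m_He"),
                            N0 = msConstants("N0")) {
  stopifnot(is(record, "DriftRecord"), is(fit, "SteppedFieldFit"))
  keep <- record@time > fit@t0
  if (!all(keep))
    warning(sum(!keep), " point(s) with t_A <= t0 dropped")
  t <- record@time[keep]
  y <- record@intensity[keep]
  if (length(t) < 2L) stop("too few points above the dead time",
                           call. = FALSE)
  driftS <- (t - fit@t0) / 1000                 # s
  x <- (L^2 * record@pressure * T0) / (p0 * record@temperature) /
    record@deltaV                               # cm^2/V
  K0t <- x / driftS                             # cm^2 V^-1 s^-1
  ccs <- vapply(K0t, masonSchamp, numeric(1), z = z, ionMass = ionMass,
                temperature = record@temperature, gasMass = gasMass, N0 = N0)
  ## CCS is linear in t: constant Jacobian dt/dCCS
  jac <- (t[2L] - t[1L]) / (ccs[2L] - ccs[1L])
  data.frame(ccs = ccs, abundance = y * abs(jac))
}

#' Read drift records from a CSV file
#'
#' Format: comment header lines \code{# delta_V:}, \code{# pressure_torr:},
#' \code{# temperature_K:} followed by \code{time_ms,intensity} rows. Several
#' records may be concatenated in one file, each with its own header block.
#'
#' @param path CSV path.
#' @return A list of \linkS4class{DriftRecord}.
#' @export
readDriftRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^# delta_V:", lines)
  if (!length(starts)) stop("no '# delta_V:' header found", call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    chunk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    getNum <- function(key) {
      ln <- grep(paste0("^# ", key, ":"), chunk, value = TRUE)
      as.numeric(sub(".*: *", "", ln[1L]))
    }
    rows <- chunk[!grepl("^#", chunk) & nzchar(chunk) &
                  !grepl("^time", chunk)]
    df <- utils::read.csv(text = rows, header = FALSE)
    driftRecord(df[[1L]], df[[2L]], getNum("delta_V"),
                getNum("pressure_torr"), getNum("temperature_K"))
  })
}

#' Write drift records to a CSV file
#'
#' @param records List of \linkS4class{DriftRecord}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDriftRecords <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(c(sprintf("# delta_V: %.10g", r@deltaV),
                 sprintf("# pressure_torr: %.10g", r@pressure),
                 sprintf("# temperature_K: %.10g", r@temperature),
                 "time_ms,intensity"), con)
    utils::write.table(data.frame(r@time, r@intensity), con, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
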