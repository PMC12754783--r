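#' Simulation configuration
#'
#' Seeded configuration for the synthetic-data generators. Defaults encode
#' the experimental conditions the analysis modules assume: the 7-point
#' titration grid (0, 5, 10, 15, 20, 30, 40 uM ligand at 10 uM DNA), the
#' stepped-field drift protocol (8 voltages between 400 and 1500 V, 78.1 cm
#' tube, 3.95 Torr, 296 K, 0.3 ms dead time), Fig.-2-like K+ adduct ladders
#' (Poisson background mean 0.8), and negative-mode charge states 4-6 for
#' 6-8 kDa DNA.
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param peakSigma Gaussian peak width in the m/z domain (Th).
#' @param noiseSigma Additive Gaussian noise sd on spectra (intensity units).
#' @param response Relative response factors c(rM, rML, rML2); rM must be 1.
#' @param adductLambda Poisson mean of the nonspecific K+ background.
#' @param specificK Specific K+ count per stoichiometry c(M, ML, ML2).
#' @param chargeStates Monitored charge states.
#' @param chargeWeights Relative abundance per charge state.
#' @param titrationGrid Ligand concentrations (uM).
#' @param meltingTm,meltingEnthalpy Two-state melting midpoint (degC) and
#'   van't Hoff enthalpy (kJ/mol).
#' @param baselineUnfolded,baselineFolded Affine absorbance baselines
#'   c(intercept, slope); at 295 nm the folded baseline is the higher one.
#' @param driftVoltages,driftPressure,driftTemperature,driftT0 Stepped-field
#'   protocol: voltages (V), pressure (Torr), temperature (K), dead time (ms).
#' @param arrivalSigma Arrival-peak width (ms).
#' @param intensityScale Intensity units per uM of DNA species.
#' @return A classed list ("SimConfig").
#' @export
simConfig <- function(seed = 1L, peakSigma = 0.25, noiseSigma = 0,
                      response = c(rM = 1, rML = 1, rML2 = 1),
                      adductLambda = 0.8,
                      specificK = c(M = 1L, ML = 2L, ML2 = 2L),
                      chargeStates = 4:6,
                      chargeWeights = c(0.3, 0.5, 0.2),
                      titrationGrid = c(0, 5, 10, 15, 20, 30, 40),
                      meltingTm = 55, meltingEnthalpy = 200,
                      baselineUnfolded = c(0.25, 2e-4),
                      baselineFolded = c(0.80, -3e-4),
                      driftVoltages = seq(400, 1500, length.out = 8),
                      driftPressure = 3.95, driftTemperature = 296,
                      driftT0 = 0.3, arrivalSigma = 0.15,
                      intensityScale = 1000) {
  stopifnot(response[1L] == 1, adductLambda >= 0, peakSigma > 0,
            noiseSigma >= 0, length(chargeStates) == length(chargeWeights))
  structure(list(seed = as.integer(seed), peakSigma = peakSigma,
                 noiseSigma = noiseSigma, response = response,
                 adductLambda = adductLambda, specificK = specificK,
                 chargeStates = chargeStates, chargeWeights = chargeWeights,
                 titrationGrid = titrationGrid, meltingTm = meltingTm,
                 meltingEnthalpy = meltingEnthalpy,
                 baselineUnfolded = baselineUnfolded,
                 baselineFolded = baselineFolded,
                 driftVoltages = driftVoltages,
                 driftPressure = driftPressure,
                 driftTemperature = driftTemperature, driftT0 = driftT0,
                 arrivalSigma = arrivalSigma,
                 intensityScale = intensityScale),
            class = "SimConfig")
}

## weights of the K+ ladder for one stoichiometry: a shift by the specific
## count convolved with the Poisson nonspecific background, truncated to the
## monitored ladder
.adductWeights <- function(nMax, kSpecific, lambda) {
  n <- 0:nMax
  w <- ifelse(n >= kSpecific, stats::dpois(n - kSpecific, lambda), 0)
  if (sum(w) <= 0) w[kSpecific + 1L] <- 1
  w / sum(w)
}

#' Simulate a native mass spectrum with ground-truth ledger
#'
#' Species concentrations come from the forward equilibrium model; each
#' stoichiometry's intensity is split over the K+ adduct ladder (specific
#' shift convolved with the Poisson nonspecific background) and the
#' monitored charge states, rendered as Gaussian peaks, with optional
#' additive Gaussian noise. The ledger records every true peak area.
#'
#' @param sample A \linkS4class{BindingSample}.
#' @param KD1,KD2 True dissociation constants (uM).
#' @param target An \linkS4class{Oligo}.
#' @param ligandObj A \linkS4class{Ligand}.
#' @param cfg A \code{\link{simConfig}}.
#' @param nMax K+ ladder length (default 6).
#' @param mzStep m/z grid spacing (Th).
#' @param standard Optional \linkS4class{Oligo} rendered as internal
#'   standard (e.g. dT6) at \code{sample@standardConc} and charge 2; NULL
#'   omits it.
#' @return A list: \code{spectrum} (\linkS4class{MassSpectrum}),
#'   \code{ledger} (data.frame of true areas per species with columns
#'   ligand_count, k_count, z, mz, area, collision), \code{state}
#'   (\linkS4class{EquilibriumState}), \code{standardArea}.
#' @export
simulateSpectrum <- function(sample, KD1, KD2, target, ligandObj,
                             cfg = simConfig(), nMax = 6L, mzStep = 0.02,
                             standard = NULL) {
  set.seed(cfg$seed)
  st <- solveEquilibrium(sample, KD1, KD2)
  conc <- c(st@freeM, st@ML, st@ML2)
  ledger <- do.call(rbind, lapply(0:2, function(lc) {
    wK <- .adductWeights(nMax, cfg$specificK[lc + 1L], cfg$adductLambda)
    tot <- conc[lc + 1L] * cfg$response[lc + 1L] * cfg$intensityScale
    do.call(rbind, lapply(seq_along(cfg$chargeStates), function(iz) {
      z <- cfg$chargeStates[iz]
      mzs <- vapply(0:nMax, function(n)
        speciesMz(speciesKey(target, lc, n, 0L, z), ligandObj), numeric(1))
      data.frame(ligand_count = lc, k_count = 0:nMax, z = z, mz = mzs,
                 area = tot * cfg$chargeWeights[iz] * wK)
    }))
  }))
  ## collision flag: peaks of different stoichiometry closer than 3 sigma
  ledger$collision <- FALSE
  ord <- order(ledger$mz)
  lm_ <- ledger[ord, ]
  close <- which(diff(lm_$mz) < 3 * cfg$peakSigma &
                 diff(lm_$ligand_count) != 0)
  if (length(close)) {
    idx <- unique(c(ord[close], ord[close + 1L]))
    ledger$collision[idx] <- TRUE
  }
  stdArea <- 0
  stdMz <- numeric(0)
  if (!is.null(standard)) {
    stdArea <- sample@standardConc * cfg$intensityScale
    stdMz <- speciesMz(speciesKey(standard, 0L, 0L, 0L, 2L))
  }
  allMz <- c(ledger$mz, stdMz)
  grid <- seq(min(allMz) - 10, max(allMz) + 10, by = mzStep)
  intensity <- numeric(length(grid))
  addPeak <- function(center, area) {
    if (area <= 0) return()
    lo <- findInterval(center - 6 * cfg$peakSigma, grid)
    hi <- findInterval(center + 6 * cfg$peakSigma, grid) + 1L
    idx <- max(1L, lo):min(length(grid), hi)
    intensity[idx] <<- intensity[idx] + area *
      stats::dnorm(grid[idx], center, cfg$peakSigma)
  }
  for (i in seq_len(nrow(ledger))) addPeak(ledger$mz[i], ledger$area[i])
  if (length(stdMz)) addPeak(stdMz, stdArea)
  if (cfg$noiseSigma > 0)
    intensity <- pmax(intensity +
                      stats::rnorm(length(grid), 0, cfg$noiseSigma), 0)
  list(spectrum = massSpectrum(grid, intensity,
                               sampleId = sprintf("sim-seed%d", cfg$seed)),
       ledger = ledger, state = st, standardArea = stdArea,
       standardMz = if (length(stdMz)) stdMz else NA_real_)
}

#' Simulate a titration series with ground-truth ledger
#'
#' One species table per grid point, built from the forward equilibrium
#' model with the configured response factors and adduct structure. Optional
#' multiplicative log-normal intensity noise and a linear response drift
#' (DNA response changing with ligand concentration while the dT6 standard
#' stays constant) can be injected.
#'
#' @param M0 DNA concentration (uM).
#' @param grid Ligand concentrations (uM); default from \code{cfg}.
#' @param KD1,KD2 True dissociation constants (uM).
#' @param cfg A \code{\link{simConfig}}; \code{cfg$noiseSigma} here acts as
#'   the multiplicative noise coefficient of variation.
#' @param driftPerUM Injected relative response drift per uM ligand
#'   (e.g. -0.005 loses 20% DNA response by 40 uM).
#' @param standardConc dT6 concentration (uM).
#' @param nMax K+ ladder length.
#' @return A list: \code{series} (\linkS4class{TitrationSeries}) and
#'   \code{ledger} (true KD1, KD2, responses, drift).
#' @export
simulateTitration <- function(M0, grid = NULL, KD1, KD2, cfg = simConfig(),
                              driftPerUM = 0, standardConc = 4, nMax = 6L) {
  set.seed(cfg$seed)
  if (is.null(grid)) grid <- cfg$titrationGrid
  tables <- lapply(grid, function(l0) {
    st <- solveEquilibrium(bindingSample(M0, l0,
                                         standardConc = standardConc),
                           KD1, KD2)
    conc <- c(st@freeM, st@ML, st@ML2)
    driftFac <- 1 + driftPerUM * l0
    entries <- do.call(rbind, lapply(0:2, function(lc) {
      wK <- .adductWeights(nMax, cfg$specificK[lc + 1L], cfg$adductLambda)
      tot <- conc[lc + 1L] * cfg$response[lc + 1L] * cfg$intensityScale *
        driftFac
      data.frame(ligand_count = lc, k_count = 0:nMax, nh4_count = 0L,
                 z = 0L, intensity = tot * wK)
    }))
    if (cfg$noiseSigma > 0) {
      cv <- cfg$noiseSigma
      entries$intensity <- entries$intensity *
        stats::rlnorm(nrow(entries), -cv^2 / 2, cv)
    }
    stdInt <- standardConc * cfg$intensityScale
    if (cfg$noiseSigma > 0)
      stdInt <- stdInt * stats::rlnorm(1L, -cfg$noiseSigma^2 / 2,
                                       cfg$noiseSigma)
    new("SpeciesTable", entries = entries, noiseSigma = 0,
        standardIntensity = stdInt, ambiguous = data.frame())
  })
  list(series = titrationSeries(grid, tables, M0, standardConc),
       ledger = list(KD1 = KD1, KD2 = KD2, rML = cfg$response[2L],
                     rML2 = cfg$response[3L], driftPerUM = driftPerUM))
}

#' Simulate stepped-field drift records
#'
#' Inverts the Mason-Schamp equation at the target CCS to get the reduced
#' mobility, places Gaussian arrival peaks at the stepped-field arrival
#' times for each voltage, and optionally jitters the peak centers. Several
#' CCS populations give multimodal records.
#'
#' @param ccsTrue Target CCS value(s) (Angstrom^2); a vector simulates a
#'   multimodal population.
#' @param z Charge magnitude.
#' @param ionMass Ion mass (Da).
#' @param cfg A \code{\link{simConfig}} (drift protocol block).
#' @param weights Relative population weights (default equal).
#' @param jitterSD Relative sd of multiplicative jitter on arrival times.
#' @param L Drift-tube length (cm).
#' @param T0,p0 Mobility reference state.
#' @param timeStep Arrival-axis spacing (ms).
#' @return List of \linkS4class{DriftRecord}, one per voltage.
#' @export
simulateDrift <- function(ccsTrue, z, ionMass, cfg = simConfig(),
                          weights = NULL, jitterSD = 0,
                          L = msConstants("drift_tube_length"),
                          T0 = msConstants("T0"), p0 = msConstants("p0"),
                          timeStep = 0.02) {
  set.seed(cfg$seed)
  stopifnot(length(cfg$driftVoltages) >= 2L)
  if (is.null(weights)) weights <- rep(1, length(ccsTrue))
  K0 <- vapply(ccsTrue, invertMasonSchamp, numeric(1), z = z,
               ionMass = ionMass, temperature = cfg$driftTemperature)
  lapply(cfg$driftVoltages, function(dV) {
    x <- (L^2 * cfg$driftPressure * T0) / (p0 * cfg$driftTemperature) / dV
    centers <- cfg$driftT0 + 1000 * x / K0
    if (jitterSD > 0)
      centers <- centers * (1 + stats::rnorm(length(centers), 0, jitterSD))
    tmax <- max(centers) + 8 * cfg$arrivalSigma
    tAxis <- seq(timeStep, tmax, by = timeStep)
    intens <- numeric(length(tAxis))
    for (i in seq_along(centers))
      intens <- intens + weights[i] *
        stats::dnorm(tAxis, centers[i], cfg$arrivalSigma)
    driftRecord(tAxis, intens, dV, cfg$driftPressure, cfg$driftTemperature)
  })
}

#' Simulate a two-state UV-melting curve
#'
#' theta(T) follows the two-state van't Hoff expression (unfolding enthalpy
#' \code{cfg$meltingEnthalpy}, midpoint \code{cfg$meltingTm}); absorbance is
#' A(T) = L0(T) (1 - theta) + L1(T) theta plus optional Gaussian noise.
#' theta(Tm) = 0.5 exactly.
#'
#' @param cfg A \code{\link{simConfig}} (melting block).
#' @param direction "heating" or "cooling".
#' @param tempRange Scan range (degC).
#' @param step Temperature step (degC).
#' @param noiseSD Additive absorbance noise sd.
#' @return A list: \code{curve} (\linkS4class{MeltingCurve}, 295 nm) and
#'   \code{thetaTrue}.
#' @export
simulateMelting <- function(cfg = simConfig(), direction = "heating",
                            tempRange = c(10, 90), step = 0.5,
                            noiseSD = 0) {
  set.seed(cfg$seed)
  temp <- seq(tempRange[1L], tempRange[2L], by = step)
  if (direction == "cooling") temp <- rev(temp)
  R <- msConstants("R_gas")
  dH <- cfg$meltingEnthalpy * 1000           # J/mol
  TmK <- cfg$meltingTm + 273.15
  TK <- temp + 273.15
  ## unfolding equilibrium constant; K(Tm) = 1
  K <- exp(-dH / R * (1 / TK - 1 / TmK))
  theta <- 1 / (1 + K)
  L0 <- cfg$baselineUnfolded[1L] + cfg$baselineUnfolded[2L] * temp
  L1 <- cfg$baselineFolded[1L] + cfg$baselineFolded[2L] * temp
  A <- L0 * (1 - theta) + L1 * theta
  if (noiseSD > 0) A <- A + stats::rnorm(length(A), 0, noiseSD)
  list(curve = meltingCurve(temp, A, wavelength = 295,
                            direction = direction),
       thetaTrue = theta)
}

## CD band fixtures (delta-epsilon amplitude, center nm, width nm). Band
## positions are conventional signatures, not fitted science.
.cdBands <- list(
  parallel     = data.frame(amp = c(10, -5), center = c(264, 245),
                            width = c(9, 7)),
  antiparallel = data.frame(amp = c(8, -4), center = c(295, 265),
                            width = c(10, 10)),
  hybrid       = data.frame(amp = c(5, 4, -3), center = c(290, 268, 240),
                            width = c(10, 9, 7))
)

#' Simulate a CD spectrum
#'
#' Sum of fixed Gaussian bands encoding the conventional topology
#' signatures (parallel: positive ~264 nm, negative ~245 nm; antiparallel:
#' positive ~295 nm; hybrid: a mixture), generated in molar-ellipticity
#' units and converted to mdeg by inverting the molar-ellipticity relation.
#'
#' @param topology "parallel", "antiparallel" or "hybrid".
#' @param conc Molar concentration (mol/L).
#' @param pathLength Path length (cm).
#' @param cfg A \code{\link{simConfig}}.
#' @param noiseSD Additive mdeg noise sd.
#' @param wavelength Wavelength axis (nm).
#' @return A \linkS4class{CDSpectrum} (mdeg) with attribute
#'   \code{deltaEpsilonTrue}.
#' @export
simulateCD <- function(topology = c("parallel", "antiparallel", "hybrid"),
                       conc = 1e-5, pathLength = 0.2, cfg = simConfig(),
                       noiseSD = 0, wavelength = seq(220, 340, by = 0.5)) {
  topology <- match.arg(topology)
  set.seed(cfg$seed)
  bands <- .cdBands[[topology]]
  de <- rowSums(vapply(seq_len(nrow(bands)), function(i)
    bands$amp[i] * exp(-0.5 * ((wavelength - bands$center[i]) /
                               bands$width[i])^2),
    numeric(length(wavelength))))
  mdeg <- de * msConstants("cd_factor") * conc * pathLength
  if (noiseSD > 0) mdeg <- mdeg + stats::rnorm(length(mdeg), 0, noiseSD)
  spec <- cdSpectrum(wavelength, mdeg, conc, pathLength)
  attr(spec, "deltaEpsilonTrue") <- de
  spec
}
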