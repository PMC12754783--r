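#' @import methods
NULL

## ---------------------------------------------------------------------------
## masses module types
## ---------------------------------------------------------------------------

#' Oligonucleotide target
#'
#' A DNA target in the screening panel: a sequence over \{A, C, G, T\} and the
#' number of strands in the assembled structure (1 for intramolecular G4s,
#' 2 for bimolecular, 4 for tetramolecular, per panel morphology).
#'
#' @slot name Sample-sheet name of the sequence (e.g. "5YEY").
#' @slot sequence DNA sequence of one strand, 5'->3'.
#' @slot strandCount Number of identical strands in the assembly (1, 2 or 4).
#' @export
setClass("Oligo",
  representation(name = "character", sequence = "character",
                 strandCount = "integer"),
  prototype(strandCount = 1L))

setValidity("Oligo", function(object) {
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    return("sequence must be a single non-empty string")
  bad <- gregexpr("[^ACGT]", object@sequence)[[1L]]
  if (bad[1L] != -1L)
    return(sprintf("invalid character '%s' at position %d (alphabet ACGT)",
                   substr(object@sequence, bad[1L], bad[1L]), bad[1L]))
  if (length(object@strandCount) != 1L || is.na(object@strandCount) ||
      object@strandCount < 1L)
    return("strandCount must be a positive integer")
  TRUE
})

#' Foldamer ligand
#'
#' A ligand L with a user-supplied neutral mass (the quinoline/pyridine
#' oligoamide foldamers carry one ammonium side chain per quinoline unit;
#' their accurate masses are measured, not computed from sequence).
#'
#' @slot name Ligand name, e.g. "QQPQ".
#' @slot neutralMass Neutral monomer mass in Da.
#' @slot chargeSites Number of ammonium side chains (informational).
#' @export
setClass("Ligand",
  representation(name = "character", neutralMass = "numeric",
                 chargeSites = "integer"),
  prototype(chargeSites = 0L))

setValidity("Ligand", function(object) {
  if (length(object@neutralMass) != 1L || !is.finite(object@neutralMass) ||
      object@neutralMass <= 0)
    return("neutralMass must be a positive number")
  if (object@chargeSites < 0L) return("chargeSites must be >= 0")
  TRUE
})

#' Ion species identity
#'
#' Identity of one ion species in a negative-mode native mass spectrum:
#' the DNA target, the number of bound ligands (0 = M, 1 = ML, 2 = ML2),
#' the numbers of K+ and NH4+ adducts, and the charge magnitude z.
#'
#' @slot target An \linkS4class{Oligo}.
#' @slot ligandCount Number of bound ligands (>= 0).
#' @slot kCount Number of K+ adducts (>= 0).
#' @slot nh4Count Number of NH4+ adducts (>= 0).
#' @slot z Charge magnitude (>= 1); ions are [species - z H]^z-.
#' @export
setClass("SpeciesKey",
  representation(target = "Oligo", ligandCount = "integer",
                 kCount = "integer", nh4Count = "integer", z = "integer"),
  prototype(ligandCount = 0L, kCount = 0L, nh4Count = 0L, z = 1L))

setValidity("SpeciesKey", function(object) {
  if (object@ligandCount < 0L || object@kCount < 0L || object@nh4Count < 0L)
    return("adduct and ligand counts must be >= 0")
  if (object@z < 1L) return("charge magnitude z must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## spectra module types
## ---------------------------------------------------------------------------

#' Mass spectrum
#'
#' A profile or centroided mass spectrum: strictly increasing m/z axis and
#' non-negative intensities.
#'
#' @slot mz Strictly increasing m/z values (Th).
#' @slot intensity Non-negative intensities (arbitrary units).
#' @slot polarity "negative" (native DNA MS) or "positive".
#' @slot sampleId Sample identifier.
#' @export
setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric",
                 polarity = "character", sampleId = "character"),
  prototype(polarity = "negative", sampleId = ""))

setValidity("MassSpectrum", function(object) {
  if (length(object@mz) == 0L) return("empty spectrum")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (any(diff(object@mz) <= 0)) return("mz must be strictly increasing")
  if (any(object@intensity < 0)) return("intensities must be >= 0")
  TRUE
})

#' Background-corrected species intensities for one sample
#'
#' Integrated, noise-corrected intensities per ion species. \code{entries} is
#' keyed by the columns \code{ligand_count}, \code{k_count}, \code{nh4_count},
#' \code{z}; \code{intensity} holds the corrected value.
#'
#' @slot entries data.frame with columns ligand_count, k_count, nh4_count, z,
#'   intensity.
#' @slot noiseSigma Per-point noise standard deviation used for correction.
#' @slot standardIntensity Integrated intensity of the dT6 internal standard.
#' @slot ambiguous data.frame of windows excluded for overlap ambiguity
#'   (possibly empty), same key columns plus center, half_width.
#' @export
setClass("SpeciesTable",
  representation(entries = "data.frame", noiseSigma = "numeric",
                 standardIntensity = "numeric", ambiguous = "data.frame"),
  prototype(noiseSigma = 0, standardIntensity = 0,
            ambiguous = data.frame()))

setValidity("SpeciesTable", function(object) {
  need <- c("ligand_count", "k_count", "nh4_count", "z", "intensity")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@entries) && any(object@entries$intensity < 0))
    return("corrected intensities must be >= 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## equilibria module types
## ---------------------------------------------------------------------------

#' One binding sample
#'
#' Total concentrations for one screening or titration point. The screening
#' panel used 10 uM DNA, 20 uM foldamer and 4 uM dT6 internal standard in
#' 100 mM TMAA + 0.5 mM KCl.
#'
#' @slot M0 Total DNA concentration (uM), > 0.
#' @slot L0 Total ligand concentration (uM), >= 0.
#' @slot standardConc Internal standard (dT6) concentration (uM).
#' @slot electrolyte Free-text electrolyte description.
#' @export
setClass("BindingSample",
  representation(M0 = "numeric", L0 = "numeric", standardConc = "numeric",
                 electrolyte = "character"),
  prototype(standardConc = 4, electrolyte = "100 mM TMAA + 0.5 mM KCl"))

setValidity("BindingSample", function(object) {
  if (!is.finite(object@M0) || object@M0 <= 0) return("M0 must be > 0")
  if (!is.finite(object@L0) || object@L0 < 0) return("L0 must be >= 0")
  TRUE
})

#' Solved equilibrium state
#'
#' Species concentrations satisfying both sequential-binding mass balances:
#' M0 = [M] + [ML] + [ML2] and L0 = [L] + [ML] + 2 [ML2] (relative 1e-9).
#'
#' @slot freeM,freeL,ML,ML2 Species concentrations (uM).
#' @slot M0,L0 Totals the state was solved for (uM).
#' @export
setClass("EquilibriumState",
  representation(freeM = "numeric", freeL = "numeric", ML = "numeric",
                 ML2 = "numeric", M0 = "numeric", L0 = "numeric"))

setValidity("EquilibriumState", function(object) {
  v <- c(object@freeM, object@freeL, object@ML, object@ML2)
  if (any(!is.finite(v)) || any(v < -1e-12)) return("concentrations must be >= 0")
  mBal <- object@freeM + object@ML + object@ML2
  lBal <- object@freeL + object@ML + 2 * object@ML2
  if (abs(mBal - object@M0) > 1e-9 * max(object@M0, 1))
    return("DNA mass balance violated")
  if (abs(lBal - object@L0) > 1e-9 * max(object@L0, 1))
    return("ligand mass balance violated")
  TRUE
})

#' Binding result for one sample
#'
#' Sequential dissociation constants with censoring flags, fraction of bound
#' DNA, and the cooperativity class. A censor flag "above" means the true KD
#' exceeds the reported bound (species below detection), "below" the converse;
#' "none" marks a point estimate.
#'
#' @slot KD1,KD2 Dissociation constants (uM); bound value when censored.
#' @slot KD1Censor,KD2Censor One of "none", "above", "below", "undetermined".
#' @slot fractionBound Fraction of DNA bound, in [0, 1] (NA if undetermined).
#' @slot cooperativity One of "positive", "negative", "non-cooperative",
#'   "undetermined".
#' @export
setClass("BindingResult",
  representation(KD1 = "numeric", KD2 = "numeric",
                 KD1Censor = "character", KD2Censor = "character",
                 fractionBound = "numeric", cooperativity = "character"),
  prototype(KD1Censor = "none", KD2Censor = "none",
            cooperativity = "undetermined"))

setValidity("BindingResult", function(object) {
  okc <- c("none", "above", "below", "undetermined")
  if (!object@KD1Censor %in% okc || !object@KD2Censor %in% okc)
    return("invalid censor flag")
  if (!is.na(object@fractionBound) &&
      (object@fractionBound < -1e-12 || object@fractionBound > 1 + 1e-12))
    return("fractionBound must lie in [0, 1]")
  if (!object@cooperativity %in%
      c("positive", "negative", "non-cooperative", "undetermined"))
    return("invalid cooperativity class")
  TRUE
})

## ---------------------------------------------------------------------------
## titration module types
## ---------------------------------------------------------------------------

#' Titration series
#'
#' Species tables across a ligand-concentration grid at fixed DNA
#' concentration (the instrument grid was 0, 5, 10, 15, 20, 30, 40 uM ligand
#' at 10 uM DNA).
#'
#' @slot L0 Ligand concentrations (uM), distinct, >= 0.
#' @slot tables List of \linkS4class{SpeciesTable}, one per L0.
#' @slot M0 DNA concentration (uM).
#' @slot standardConc dT6 concentration (uM).
#' @export
setClass("TitrationSeries",
  representation(L0 = "numeric", tables = "list", M0 = "numeric",
                 standardConc = "numeric"),
  prototype(standardConc = 4))

setValidity("TitrationSeries", function(object) {
  if (length(object@L0) != length(object@tables))
    return("one SpeciesTable required per L0")
  if (anyDuplicated(object@L0)) return("L0 values must be distinct")
  if (any(object@L0 < 0)) return("L0 values must be >= 0")
  if (length(object@L0) < 1L) return("at least one point required")
  if (!all(vapply(object@tables, is, logical(1), "SpeciesTable")))
    return("tables must all be SpeciesTable objects")
  TRUE
})

#' Titration fit
#'
#' Result of the sequential-binding weighted least-squares fit with free
#' response factors (r_M is fixed at 1).
#'
#' @slot KD1,KD2 Fitted dissociation constants (uM).
#' @slot KD1SE,KD2SE Standard errors from the local quadratic approximation.
#' @slot rML,rML2 Relative response factors of the complexes.
#' @slot drift Response-drift coefficient (relative change per uM ligand).
#' @slot residualNorm Weighted residual norm at the optimum.
#' @slot converged Optimizer convergence flag.
#' @slot censor "none" or "above" (no detectable complex anywhere).
#' @export
setClass("TitrationFit",
  representation(KD1 = "numeric", KD2 = "numeric", KD1SE = "numeric",
                 KD2SE = "numeric", rML = "numeric", rML2 = "numeric",
                 drift = "numeric", residualNorm = "numeric",
                 converged = "logical", censor = "character"),
  prototype(drift = 0, censor = "none"))

setValidity("TitrationFit", function(object) {
  if (object@censor == "none" &&
      (object@KD1 <= 0 || object@KD2 <= 0)) return("KD values must be > 0")
  if (object@censor == "none" && (object@rML < 0 || object@rML2 < 0))
    return("response factors must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## mobility module types
## ---------------------------------------------------------------------------

#' Arrival-time distribution at one drift voltage
#'
#' @slot time Ascending arrival times (ms).
#' @slot intensity Non-negative intensities.
#' @slot deltaV Drift voltage (V), > 0.
#' @slot pressure Drift-tube pressure (Torr), > 0.
#' @slot temperature Drift-tube temperature (K), > 0.
#' @export
setClass("DriftRecord",
  representation(time = "numeric", intensity = "numeric", deltaV = "numeric",
                 pressure = "numeric", temperature = "numeric"))

setValidity("DriftRecord", function(object) {
  if (length(object@time) != length(object@intensity))
    return("time and intensity lengths differ")
  if (length(object@time) && any(diff(object@time) <= 0))
    return("time axis must be strictly increasing")
  if (any(object@intensity < 0)) return("intensities must be >= 0")
  if (object@deltaV <= 0) return("deltaV must be > 0")
  if (object@pressure <= 0 || object@temperature <= 0)
    return("pressure and temperature must be > 0")
  TRUE
})

#' Stepped-field linear fit
#'
#' @slot K0 Reduced mobility (cm2 V-1 s-1), > 0.
#' @slot t0 Dead time (ms).
#' @slot rSquared Coefficient of determination of the linear fit.
#' @slot nPoints Number of drift voltages used (>= 2).
#' @export
setClass("SteppedFieldFit",
  representation(K0 = "numeric", t0 = "numeric", rSquared = "numeric",
                 nPoints = "integer"))

setValidity("SteppedFieldFit", function(object) {
  if (!is.finite(object@K0) || object@K0 <= 0) return("K0 must be > 0")
  if (object@nPoints < 2L) return("at least 2 drift voltages required")
  TRUE
})

#' Collision cross section result
#'
#' @slot ccs Collision cross section (Angstrom^2), > 0.
#' @slot z Charge magnitude.
#' @slot ionMass Ion mass (Da).
#' @slot gasMass Drift-gas mass (Da; helium 4.0026).
#' @export
setClass("CCSResult",
  representation(ccs = "numeric", z = "integer", ionMass = "numeric",
                 gasMass = "numeric"),
  prototype(gasMass = 4.0026))

setValidity("CCSResult", function(object) {
  if (!is.finite(object@ccs) || object@ccs <= 0) return("ccs must be > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## adducts module types
## ---------------------------------------------------------------------------

#' K+ adduct intensity profile for one stoichiometry
#'
#' @slot counts Non-negative intensities indexed by adduct number n = 0..nmax.
#' @slot ligandCount Stoichiometry context (0 = M, 1 = ML, 2 = ML2).
#' @export
setClass("AdductProfile",
  representation(counts = "numeric", ligandCount = "integer"),
  prototype(ligandCount = 0L))

setValidity("AdductProfile", function(object) {
  if (length(object@counts) < 2L)
    return("profile needs n_max >= 1 (at least two adduct channels)")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' Specific-adduct call
#'
#' Specific K+ adducts of a G4 sit between consecutive G-quartets, so n
#' specific K+ imply n + 1 quartets; nonspecific electrospray adducts follow
#' an approximately Poisson background.
#'
#' @slot specificN Integer set of specific adduct counts (possibly empty).
#' @slot lambda Fitted Poisson mean of the nonspecific background.
#' @slot scale Fitted background amplitude (total background intensity).
#' @slot quartetCount max(specificN) + 1, or NA when undetermined.
#' @slot minExcess Neighbour-ratio threshold used.
#' @export
setClass("SpecificityCall",
  representation(specificN = "integer", lambda = "numeric", scale = "numeric",
                 quartetCount = "integer", minExcess = "numeric"),
  prototype(specificN = integer(0), quartetCount = NA_integer_,
            minExcess = 1.5))

setValidity("SpecificityCall", function(object) {
  if (length(object@specificN)) {
    if (is.na(object@quartetCount) ||
        object@quartetCount != max(object@specificN) + 1L)
      return("quartetCount must equal max(specificN) + 1")
  }
  if (!is.na(object@lambda) && object@lambda < 0)
    return("lambda must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## optical module types
## ---------------------------------------------------------------------------

#' Circular dichroism spectrum
#'
#' @slot wavelength Ascending wavelengths (nm).
#' @slot ellipticity Ellipticity (mdeg), blank-subtracted.
#' @slot conc Molar oligonucleotide concentration (mol/L), > 0.
#' @slot pathLength Cuvette path length (cm), > 0.
#' @export
setClass("CDSpectrum",
  representation(wavelength = "numeric", ellipticity = "numeric",
                 conc = "numeric", pathLength = "numeric"))

setValidity("CDSpectrum", function(object) {
  if (length(object@wavelength) != length(object@ellipticity))
    return("wavelength and ellipticity lengths differ")
  if (length(object@wavelength) && any(diff(object@wavelength) <= 0))
    return("wavelength must be strictly ascending")
  if (object@conc <= 0 || object@pathLength <= 0)
    return("conc and pathLength must be > 0")
  TRUE
})

#' UV-melting curve
#'
#' @slot temperature Temperatures (degC), monotone within the ramp.
#' @slot absorbance Absorbance values (335 nm-corrected before analysis).
#' @slot wavelength Monitoring wavelength: 260, 295 or 335 nm.
#' @slot direction "heating" or "cooling".
#' @slot rampRate Ramp rate (degC/min), informational.
#' @export
setClass("MeltingCurve",
  representation(temperature = "numeric", absorbance = "numeric",
                 wavelength = "numeric", direction = "character",
                 rampRate = "numeric"),
  prototype(wavelength = 295, direction = "heating", rampRate = 0.2))

setValidity("MeltingCurve", function(object) {
  if (length(object@temperature) != length(object@absorbance))
    return("temperature and absorbance lengths differ")
  d <- diff(object@temperature)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    return("temperature must be monotone within a ramp")
  if (!object@wavelength %in% c(260, 295, 335))
    return("wavelength must be 260, 295 or 335 nm")
  if (!object@direction %in% c("heating", "cooling"))
    return("direction must be 'heating' or 'cooling'")
  TRUE
})

#' Folded-fraction curve
#'
#' @slot temperature Temperatures (degC).
#' @slot theta Folded fraction; nominally in [0, 1], noise may exceed.
#' @slot baselineUnfolded,baselineFolded Affine coefficients c(intercept,
#'   slope) of the unfolded (L0) and folded (L1) baselines.
#' @slot direction Ramp direction inherited from the melting curve.
#' @export
setClass("FoldedFractionCurve",
  representation(temperature = "numeric", theta = "numeric",
                 baselineUnfolded = "numeric", baselineFolded = "numeric",
                 direction = "character"),
  prototype(direction = "heating"))

setValidity("FoldedFractionCurve", function(object) {
  if (length(object@temperature) != length(object@theta))
    return("temperature and theta lengths differ")
  if (length(object@baselineUnfolded) != 2L ||
      length(object@baselineFolded) != 2L)
    return("baselines must be affine coefficient pairs c(intercept, slope)")
  TRUE
})

#' Melting temperature result
#'
#' @slot tm Melting temperature (degC); NA when theta never crosses 0.5.
#' @slot thetaRange Range of observed theta, reported when undetermined.
#' @slot multipleCrossings TRUE if theta crosses 0.5 more than once.
#' @export
setClass("MeltingResult",
  representation(tm = "numeric", thetaRange = "numeric",
                 multipleCrossings = "logical"),
  prototype(multipleCrossings = FALSE))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "Oligo", function(object) {
  cat(sprintf("Oligo '%s': %s (%d nt) x %d strand(s)\n", object@name,
              object@sequence, nchar(object@sequence), object@strandCount))
})

setMethod("show", "SpeciesKey", function(object) {
  stoich <- c("M", "ML", "ML2")[min(object@ligandCount, 2L) + 1L]
  if (object@ligandCount > 2L) stoich <- sprintf("ML%d", object@ligandCount)
  cat(sprintf("SpeciesKey: %s [%s + %d K + %d NH4]^%d-\n", stoich,
              object@target@name, object@kCount, object@nh4Count, object@z))
})

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum '%s': %d points, m/z %.2f-%.2f, %s mode\n",
              object@sampleId, length(object@mz), min(object@mz),
              max(object@mz), object@polarity))
})

setMethod("show", "SpeciesTable", function(object) {
  cat(sprintf("SpeciesTable: %d species entries, noise sigma %.3g, dT6 %.3g\n",
              nrow(object@entries), object@noiseSigma,
              object@standardIntensity))
  if (nrow(object@entries)) print(utils::head(object@entries, 10))
})

setMethod("show", "EquilibriumState", function(object) {
  cat(sprintf(
    "EquilibriumState (uM): [M]=%.4g [L]=%.4g [ML]=%.4g [ML2]=%.4g\n",
    object@freeM, object@freeL, object@ML, object@ML2))
})

setMethod("show", "BindingResult", function(object) {
  fmt <- function(v, c) switch(c, none = sprintf("%.3g uM", v),
                               above = sprintf("> %.3g uM", v),
                               below = sprintf("< %.3g uM", v),
                               "undetermined")
  cat(sprintf("BindingResult: KD1 %s, KD2 %s, fraction bound %.3f, %s\n",
              fmt(object@KD1, object@KD1Censor),
              fmt(object@KD2, object@KD2Censor),
              object@fractionBound, object@cooperativity))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries: %d points, M0 = %.3g uM, L0 = %s uM\n",
    length(object@L0), object@M0, paste(object@L0, collapse = ", ")))
})

setMethod("show", "TitrationFit", function(object) {
  cat(sprintf(
    "TitrationFit: KD1 = %.4g +/- %.2g uM, KD2 = %.4g +/- %.2g uM\n",
    object@KD1, object@KD1SE, object@KD2, object@KD2SE))
  cat(sprintf("  responses r_ML = %.3g, r_ML2 = %.3g; converged: %s\n",
              object@rML, object@rML2, object@converged))
})

setMethod("show", "DriftRecord", function(object) {
  cat(sprintf(
    "DriftRecord: %d points, dV = %.0f V, p = %.2f Torr, T = %.1f K\n",
    length(object@time), object@deltaV, object@pressure, object@temperature))
})

setMethod("show", "SteppedFieldFit", function(object) {
  cat(sprintf(
    "SteppedFieldFit: K0 = %.4g cm2/V/s, t0 = %.3g ms (R2 = %.5f, n = %d)\n",
    object@K0, object@t0, object@rSquared, object@nPoints))
})

setMethod("show", "CCSResult", function(object) {
  cat(sprintf("CCSResult: %.1f A2 (z = %d, ion %.1f Da, gas %.4f Da)\n",
              object@ccs, object@z, object@ionMass, object@gasMass))
})

setMethod("show", "SpecificityCall", function(object) {
  sn <- if (length(object@specificN))
    paste(object@specificN, collapse = ", ") else "none"
  qc <- if (is.na(object@quartetCount)) "undetermined"
        else as.character(object@quartetCount)
  cat(sprintf(
    "SpecificityCall: specific n = {%s}, lambda = %.3g, quartets = %s\n",
    sn, object@lambda, qc))
})

setMethod("show", "MeltingResult", function(object) {
  if (is.na(object@tm)) {
    cat(sprintf("MeltingResult: undetermined (theta in [%.2f, %.2f])\n",
                object@thetaRange[1], object@thetaRange[2]))
  } else {
    cat(sprintf("MeltingResult: Tm = %.2f degC%s\n", object@tm,
                if (object@multipleCrossings) " (multiple crossings)" else ""))
  }
})
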