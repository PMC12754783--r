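#' Physical constants and mass bookkeeping registry
#'
#' Single registry for every physical constant and adduct-mass convention used
#' across the package, so that mass arithmetic, the Mason-Schamp equation and
#' the optical conversions all draw from one place.
#'
#' Conventions for negative-mode native MS of nucleic acids:
#' \itemize{
#'   \item A K+ adduct replaces a proton on the phosphate backbone, so each
#'     adduct shifts the neutral mass by \code{dK = m(K) - m(H) = +37.9559} Da.
#'   \item An NH4+ adduct likewise replaces a proton: \code{dNH4 = +17.0265} Da.
#'   \item Charge z is the magnitude of the negative charge; each charge
#'     removes one proton (1.007276 Da).
#' }
#'
#' The gas number density \code{N0} (Loschmidt constant) is evaluated at
#' \code{T0 = 273.15} K and \code{p0 = 760} Torr (1 atm). Both are exposed as
#' overridable arguments where they enter a computation, but the registry
#' default follows the standard Loschmidt convention.
#'
#' @param name Optional constant name; when missing the full named list is
#'   returned.
#' @return A named list of constants, or a single numeric value when
#'   \code{name} is given.
#' @examples
#' msConstants("proton_mass")
#' msConstants()$dK
#' @export
msConstants <- function(name) {
  const <- list(
    proton_mass   = 1.007276,        # Da, mass of H+
    dK            = 37.9559,         # Da, K replaces H (38.963707 - 1.007825)
    dNH4          = 17.0265,         # Da, NH4 replaces H
    m_He          = 4.0026,          # Da, drift gas (helium)
    e_charge      = 1.602176634e-19, # C
    k_B           = 1.380649e-23,    # J/K
    N0            = 2.686780111e25,  # m^-3, Loschmidt constant at T0, p0
    T0            = 273.15,          # K, reference temperature for N0
    p0            = 760,             # Torr, reference pressure for N0
    amu_kg        = 1.66053906660e-27, # kg per Da
    R_gas         = 8.31446261815324,  # J/(mol K)
    cd_factor     = 32980,           # mdeg -> molar ellipticity denominator
    drift_tube_length = 78.1         # cm, drift tube length
  )
  if (missing(name)) return(const)
  if (!name %in% names(const)) {
    stop("unknown constant: ", name, call. = FALSE)
  }
  const[[name]]
}

## Element masses used by the oligonucleotide mass calculator.
## Average masses: IUPAC 2021 standard atomic weights.
## Monoisotopic: lightest-isotope masses.
.elementMasses <- function(mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (mode == "average") {
    c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994, P = 30.973762)
  } else {
    c(H = 1.0078250319, C = 12, N = 14.0030740052,
      O = 15.9949146221, P = 30.97376151)
  }
}

## Elemental composition of 2'-deoxyribonucleosides (free nucleoside,
## base + deoxyribose). A strand of n residues with 5'-OH and 3'-OH termini is
## n nucleosides joined by (n-1) phosphodiester bridges; each bridge adds HPO3
## and removes H2O.
.nucleosideFormula <- list(
  A = c(C = 10, H = 13, N = 5, O = 3, P = 0),
  C = c(C =  9, H = 13, N = 3, O = 4, P = 0),
  G = c(C = 10, H = 13, N = 5, O = 4, P = 0),
  T = c(C = 10, H = 14, N = 2, O = 5, P = 0)
)
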