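#' Construct a binding sample
#'
#' @param M0 Total DNA concentration (uM), > 0.
#' @param L0 Total ligand concentration (uM), >= 0.
#' @param standardConc dT6 internal-standard concentration (uM).
#' @param electrolyte Electrolyte description.
#' @return A \linkS4class{BindingSample}.
#' @examples
#' bindingSample(M0 = 10, L0 = 20)  # the screening condition
#' @export
bindingSample <- function(M0, L0, standardConc = 4,
                          electrolyte = "100 mM TMAA + 0.5 mM KCl") {
  new("BindingSample", M0 = M0, L0 = L0, standardConc = standardConc,
      electrolyte = electrolyte)
}

#' Species concentrations from intensities
#'
#' Converts per-stoichiometry intensities to concentrations assuming equal
#' response: [M*] = M0 * I(M*) / (I(M) + I(ML) + I(ML2)). The concentrations
#' sum to M0 exactly.
#'
#' @param intensities A \linkS4class{SpeciesTable} (summed over the adduct
#'   ladder and charge states) or a numeric vector of length 3: I(M), I(ML),
#'   I(ML2).
#' @param sample A \linkS4class{BindingSample}.
#' @return Named numeric c(M =, ML =, ML2 =) in uM; all NA when every
#'   intensity is zero (undetermined, with a warning).
#' @export
concentrationsFromIntensities <- function(intensities, sample) {
  stopifnot(is(sample, "BindingSample"))
  if (is(intensities, "SpeciesTable"))
    intensities <- stoichiometryIntensities(intensities, 0:2)
  stopifnot(length(intensities) == 3L, all(intensities >= 0))
  tot <- sum(intensities)
  if (tot <= 0) {
    warning("all species intensities are zero; concentrations undetermined")
    return(c(M = NA_real_, ML = NA_real_, ML2 = NA_real_))
  }
  conc <- sample@M0 * intensities / tot
  names(conc) <- c("M", "ML", "ML2")
  conc
}

#' Free ligand concentration by difference
#'
#' [L] = L0 - [ML] - 2 [ML2]. With noisy intensities the difference can be
#' non-positive; the result is then clamped at 0 and flagged censored
#' (attribute \code{censored = TRUE}), never reported negative.
#'
#' @param sample A \linkS4class{BindingSample}.
#' @param ML,ML2 Complex concentrations (uM).
#' @return Free ligand concentration (uM) with logical attribute
#'   \code{censored}.
#' @export
freeLigand <- function(sample, ML, ML2) {
  stopifnot(is(sample, "BindingSample"))
  L <- sample@L0 - ML - 2 * ML2
  if (L <= 0) return(structure(0, censored = TRUE))
  structure(L, censored = FALSE)
}

#' Fraction of bound DNA
#'
#' (ML + ML2) / (M + ML + ML2); the concise screening readout.
#'
#' @param M,ML,ML2 Species concentrations (or intensities; the ratio is
#'   response-invariant under equal response).
#' @return Value in [0, 1]; NA with a warning when all inputs are zero.
#' @export
fractionBound <- function(M, ML, ML2) {
  stopifnot(M >= 0, ML >= 0, ML2 >= 0)
  tot <- M + ML + ML2
  if (tot <= 0) {
    warning("all species zero; fraction bound undetermined")
    return(NA_real_)
  }
  (ML + ML2) / tot
}

#' Classify binding cooperativity
#'
#' For two sequential sites the statistical (non-cooperative) expectation is
#' KD2 = 4 KD1: with equal independent microscopic site constants kd, the
#' macroscopic constants are KD1 = kd/2 and KD2 = 2 kd. Binding is positively
#' cooperative when KD2 < 4 KD1 and negatively cooperative when KD2 > 4 KD1;
#' a relative band of width \code{epsilon} around the boundary is classified
#' non-cooperative.
#'
#' @param KD1,KD2 Dissociation constants (uM).
#' @param KD1Censor,KD2Censor Censor flags ("none" for point values).
#' @param epsilon Relative half-width of the non-cooperative band.
#' @return One of "positive", "negative", "non-cooperative", "undetermined".
#' @examples
#' classifyCooperativity(1.5, 22)   # "negative" (22 > 6)
#' classifyCooperativity(75, 40)    # "positive" (40 < 300)
#' @export
classifyCooperativity <- function(KD1, KD2, KD1Censor = "none",
                                  KD2Censor = "none", epsilon = 1e-6) {
  if (KD1Censor != "none" || KD2Censor != "none" ||
      is.na(KD1) || is.na(KD2)) return("undetermined")
  bound <- 4 * KD1
  if (KD2 < bound * (1 - epsilon)) return("positive")
  if (KD2 > bound * (1 + epsilon)) return("negative")
  "non-cooperative"
}

#' Single-point dissociation constants
#'
#' KD1 = [M][L]/[ML] and KD2 = [ML][L]/[ML2] from one sample's species
#' concentrations. Zero denominators produce one-sided censored bounds using
#' \code{detectionFloor} as pseudo-concentration (a species below the
#' detection floor at a single concentration cannot distinguish very weak
#' binding from none, so the result is a bound, not a point value). Censored
#' free ligand (attribute from \code{\link{freeLigand}}) yields undetermined
#' constants.
#'
#' @param M,ML,ML2 Species concentrations (uM), >= 0.
#' @param L Free ligand concentration (uM), possibly carrying the
#'   \code{censored} attribute.
#' @param detectionFloor Pseudo-concentration for unobserved species (uM).
#' @return A \linkS4class{BindingResult}.
#' @export
kdSinglePoint <- function(M, ML, ML2, L, detectionFloor = 0.01) {
  if (any(c(M, ML, ML2, L) < 0)) stop("concentrations must be >= 0",
                                      call. = FALSE)
  fb <- fractionBound(M, ML, ML2)
  lCensored <- isTRUE(attr(L, "censored"))
  L <- as.numeric(L)
  if (lCensored || L == 0) {
    res <- new("BindingResult", KD1 = NA_real_, KD2 = NA_real_,
               KD1Censor = "undetermined", KD2Censor = "undetermined",
               fractionBound = fb, cooperativity = "undetermined")
    return(res)
  }
  if (ML > 0) {
    if (M > 0) { kd1 <- M * L / ML; c1 <- "none" }
    else { kd1 <- detectionFloor * L / ML; c1 <- "below" }
  } else {
    kd1 <- M * L / detectionFloor; c1 <- "above"
  }
  if (ML2 > 0) {
    if (ML > 0) { kd2 <- ML * L / ML2; c2 <- "none" }
    else { kd2 <- detectionFloor * L / ML2; c2 <- "below" }
  } else {
    if (ML > 0) { kd2 <- ML * L / detectionFloor; c2 <- "above" }
    else { kd2 <- NA_real_; c2 <- "undetermined" }
  }
  new("BindingResult", KD1 = kd1, KD2 = kd2, KD1Censor = c1, KD2Censor = c2,
      fractionBound = fb,
      cooperativity = classifyCooperativity(kd1, kd2, c1, c2))
}

#' Solve the sequential-binding equilibrium
#'
#' Forward model of the two-step equilibrium M + L <-> ML (KD1) and
#' ML + L <-> ML2 (KD2): finds the unique state satisfying both mass
#' balances. Bound ligand is strictly monotone in free L, so the state is
#' found by bracketed root finding on free L over [0, L0].
#'
#' @param sample A \linkS4class{BindingSample}.
#' @param KD1,KD2 Dissociation constants (uM), > 0.
#' @return An \linkS4class{EquilibriumState}.
#' @examples
#' solveEquilibrium(bindingSample(10, 20), KD1 = 1.5, KD2 = 22)
#' @export
solveEquilibrium <- function(sample, KD1, KD2) {
  stopifnot(is(sample, "BindingSample"), KD1 > 0, KD2 > 0)
  M0 <- sample@M0
  L0 <- sample@L0
  if (L0 == 0) {
    return(new("EquilibriumState", freeM = M0, freeL = 0, ML = 0, ML2 = 0,
               M0 = M0, L0 = 0))
  }
  species <- function(L) {
    den <- 1 + L / KD1 + L * L / (KD1 * KD2)
    M <- M0 / den
    ML <- M * L / KD1
    ML2 <- ML * L / KD2
    list(M = M, ML = ML, ML2 = ML2)
  }
  g <- function(L) {
    s <- species(L)
    L + s$ML + 2 * s$ML2 - L0
  }
  root <- stats::uniroot(g, interval = c(0, L0),
                         tol = max(1e-14 * L0, 1e-15), maxiter = 2000L)
  if (abs(root$f.root) > 1e-6 * max(L0, 1))
    stop("equilibrium solver did not converge: residual ", root$f.root,
         " at L = ", root$root, call. = FALSE)
  L <- root$root
  s <- species(L)
  ## enforce the ligand balance exactly (root tolerance leaves ~1e-14)
  Lexact <- L0 - s$ML - 2 * s$ML2
  new("EquilibriumState", freeM = s$M, freeL = max(Lexact, 0), ML = s$ML,
      ML2 = s$ML2, M0 = M0, L0 = L0)
}

#' Binding result from a species table
#'
#' Convenience chain for one screening sample: intensities summed per
#' stoichiometry, converted to concentrations, free ligand by difference,
#' then single-point KD determination.
#'
#' @param table A \linkS4class{SpeciesTable}.
#' @param sample A \linkS4class{BindingSample}.
#' @param detectionFloor Passed to \code{\link{kdSinglePoint}}.
#' @return A \linkS4class{BindingResult}, or NULL when all intensities are
#'   zero (absent cell).
#' @export
bindingResultFromTable <- function(table, sample, detectionFloor = 0.01) {
  conc <- suppressWarnings(concentrationsFromIntensities(table, sample))
  if (any(is.na(conc))) return(NULL)
  L <- freeLigand(sample, conc["ML"], conc["ML2"])
  kdSinglePoint(conc["M"], conc["ML"], conc["ML2"], L,
                detectionFloor = detectionFloor)
}

#' Screen a DNA x foldamer panel
#'
#' Assembles the fraction-of-DNA-bound heatmap and the per-cell binding
#' results for a screening panel. Cells with all-zero intensities are marked
#' absent (NA), not zero.
#'
#' @param cells A list; each element is
#'   \code{list(dna =, ligand =, table =, sample =)} with character names,
#'   a \linkS4class{SpeciesTable} and a \linkS4class{BindingSample}.
#' @param detectionFloor Passed to \code{\link{kdSinglePoint}}.
#' @return A list with \code{fractionBound} (matrix rows = DNA, cols =
#'   foldamer; NA = absent) and \code{results} (named list of
#'   \linkS4class{BindingResult} or NULL, keyed "dna|ligand").
#' @export
screenPanel <- function(cells, detectionFloor = 0.01) {
  stopifnot(length(cells) >= 1L)
  dnas <- unique(vapply(cells, `[[`, character(1), "dna"))
  ligs <- unique(vapply(cells, `[[`, character(1), "ligand"))
  hm <- matrix(NA_real_, length(dnas), length(ligs),
               dimnames = list(dnas, ligs))
  results <- list()
  for (cell in cells) {
    res <- bindingResultFromTable(cell$table, cell$sample,
                                  detectionFloor = detectionFloor)
    key <- paste(cell$dna, cell$ligand, sep = "|")
    results[key] <- list(res)  # keep NULL (absent) entries in the list
    if (!is.null(res)) hm[cell$dna, cell$ligand] <- res@fractionBound
  }
  list(fractionBound = hm, results = results)
}

#' Export a screening heatmap
#'
#' Writes the fraction-bound matrix as CSV and the full per-cell results
#' (with censoring metadata) as JSON.
#'
#' @param screen Result of \code{\link{screenPanel}}.
#' @param csvPath,jsonPath Output paths (either may be NULL to skip).
#' @return Invisibly, the JSON-ready list.
#' @export
exportScreen <- function(screen, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(screen$fractionBound, csvPath, row.names = TRUE)
  meta <- lapply(screen$results, function(r) {
    if (is.null(r)) return(list(absent = TRUE))
    list(KD1 = r@KD1, KD1_censor = r@KD1Censor, KD2 = r@KD2,
         KD2_censor = r@KD2Censor, fraction_bound = r@fractionBound,
         cooperativity = r@cooperativity)
  })
  if (!is.null(jsonPath))
    jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(meta)
}
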