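#' Construct an oligonucleotide target
#'
#' @param name Sequence name.
#' @param sequence DNA sequence (characters A, C, G, T; case-insensitive).
#' @param strandCount Number of strands in the assembled structure (1, 2, 4).
#' @return An \linkS4class{Oligo}.
#' @examples
#' oligo("TG4T", "TGGGGT", strandCount = 4)
#' @export
oligo <- function(name, sequence, strandCount = 1L) {
  new("Oligo", name = as.character(name),
      sequence = toupper(as.character(sequence)),
      strandCount = as.integer(strandCount))
}

#' Construct a foldamer ligand
#'
#' Foldamer masses are user inputs (measured accurate masses); they are not
#' computed from monomer composition.
#'
#' @param name Ligand name, e.g. "QQPQ".
#' @param neutralMass Neutral mass in Da.
#' @param chargeSites Number of ammonium side chains.
#' @return A \linkS4class{Ligand}.
#' @export
ligand <- function(name, neutralMass, chargeSites = 0L) {
  new("Ligand", name = as.character(name), neutralMass = neutralMass,
      chargeSites = as.integer(chargeSites))
}

#' Construct an ion species key
#'
#' @param target An \linkS4class{Oligo}.
#' @param ligandCount Bound ligands: 0 (M), 1 (ML), 2 (ML2), ...
#' @param kCount Number of K+ adducts.
#' @param nh4Count Number of NH4+ adducts.
#' @param z Charge magnitude (negative mode), >= 1.
#' @return A \linkS4class{SpeciesKey}.
#' @export
speciesKey <- function(target, ligandCount = 0L, kCount = 0L, nh4Count = 0L,
                       z = 1L) {
  new("SpeciesKey", target = target, ligandCount = as.integer(ligandCount),
      kCount = as.integer(kCount), nh4Count = as.integer(nh4Count),
      z = as.integer(z))
}

#' Neutral mass of an oligonucleotide assembly
#'
#' Computes the neutral mass of the full assembly (strandCount identical
#' strands) from elemental composition. A strand of n residues with 5'-OH and
#' 3'-OH termini is n deoxyribonucleosides joined by n - 1 phosphodiester
#' bridges; each bridge contributes HPO3 and removes H2O. No terminal
#' phosphate (standard synthetic oligonucleotide).
#'
#' @param x An \linkS4class{Oligo}.
#' @param mode "average" (default; matches unresolved native-MS envelopes) or
#'   "monoisotopic".
#' @return Neutral mass in Da (assembly = strand mass x strandCount).
#' @examples
#' oligoNeutralMass(oligo("dT6", "TTTTTT"))
#' @export
oligoNeutralMass <- function(x, mode = c("average", "monoisotopic")) {
  stopifnot(is(x, "Oligo"))
  validObject(x)
  mode <- match.arg(mode)
  em <- .elementMasses(mode)
  bases <- strsplit(x@sequence, "")[[1L]]
  formula <- Reduce(`+`, .nucleosideFormula[bases])
  n <- length(bases)
  ## n - 1 phosphodiester bridges: +HPO3, -H2O each
  formula["H"] <- formula["H"] + (n - 1) * (1 - 2)
  formula["O"] <- formula["O"] + (n - 1) * (3 - 1)
  formula["P"] <- formula["P"] + (n - 1)
  strand <- sum(formula * em[names(formula)])
  strand * x@strandCount
}

#' m/z of an adducted negative ion
#'
#' m/z of the ion [M + ligandCount L + kCount K + nh4Count NH4 - (z +
#' kCount + nh4Count) H]^z-: every K+ or NH4+ adduct replaces a backbone
#' proton (shifts of +37.9559 and +17.0265 Da respectively) and each negative
#' charge removes one proton.
#'
#' @param key A \linkS4class{SpeciesKey}.
#' @param ligandObj A \linkS4class{Ligand}, required when
#'   \code{key} has \code{ligandCount > 0}; ignored otherwise.
#' @param mode Mass mode passed to \code{\link{oligoNeutralMass}}.
#' @return m/z in Th.
#' @examples
#' g4 <- oligo("5YEY", "GGGTTAGGGTTAGGGTTTGGG")
#' speciesMz(speciesKey(g4, z = 5))
#' @export
speciesMz <- function(key, ligandObj = NULL,
                      mode = c("average", "monoisotopic")) {
  stopifnot(is(key, "SpeciesKey"))
  validObject(key)
  mode <- match.arg(mode)
  const <- msConstants()
  m <- oligoNeutralMass(key@target, mode)
  if (key@ligandCount > 0L) {
    if (is.null(ligandObj))
      stop("ligandObj required for ligandCount > 0", call. = FALSE)
    stopifnot(is(ligandObj, "Ligand"))
    m <- m + key@ligandCount * ligandObj@neutralMass
  }
  m <- m + key@kCount * const$dK + key@nh4Count * const$dNH4
  (m - key@z * const$proton_mass) / key@z
}

#' Read a sample sheet
#'
#' Reads a CSV sample sheet with columns \code{name}, \code{sequence},
#' \code{strand_count}, \code{ligand_name}, \code{ligand_mass} and returns a
#' list with the parsed \linkS4class{Oligo} and \linkS4class{Ligand} objects
#' per row.
#'
#' @param path CSV file path.
#' @return A list of rows; each row is \code{list(oligo = , ligand = )}
#'   (\code{ligand} is NULL when \code{ligand_name} is empty or NA).
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "strand_count", "ligand_name", "ligand_mass")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    lg <- if (is.na(df$ligand_name[i]) || !nzchar(df$ligand_name[i])) NULL
          else ligand(df$ligand_name[i], df$ligand_mass[i])
    list(oligo = oligo(df$name[i], df$sequence[i], df$strand_count[i]),
         ligand = lg)
  })
}
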