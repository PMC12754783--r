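## Shared fixtures and independent oracles.

## Panel sequences used across tests
seq222T <- "TGGGTTGGGTTGGGTTGGGT"
seq5YEY <- "GGGTTAGGGTTAGGGTTTGGG"
seqTG4T <- "TGGGGT"

fixtureOligo <- function() oligo("222T", seq222T)
fixtureLigand <- function() ligand("QQPQ", 1000, chargeSites = 3L)

## Independent oracle for oligonucleotide masses: sums
## 2'-deoxyribonucleoside-5'-monophosphate elemental formulas, removes
## (n - 1) waters for the phosphodiester condensations and one HPO3 for the
## free 5'-OH terminus. Different tabulation route from the implementation
## (which builds from nucleosides plus bridges).
oracleStrandMass <- function(sequence, mode = "average") {
  em <- if (mode == "average") {
    c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994, P = 30.973762)
  } else {
    c(H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
      P = 30.97376151)
  }
  dNMP <- list(  # nucleoside-5'-monophosphates
    A = c(C = 10, H = 14, N = 5, O = 6, P = 1),
    C = c(C = 9,  H = 14, N = 3, O = 7, P = 1),
    G = c(C = 10, H = 14, N = 5, O = 7, P = 1),
    T = c(C = 10, H = 15, N = 2, O = 8, P = 1))
  bases <- strsplit(sequence, "")[[1]]
  f <- Reduce(`+`, dNMP[bases])
  n <- length(bases)
  f <- f - (n - 1) * c(C = 0, H = 2, N = 0, O = 1, P = 0)  # - (n-1) H2O
  f <- f - c(C = 0, H = 1, N = 0, O = 3, P = 1)            # - HPO3 (5'-OH)
  sum(f * em[names(f)])
}

## random DNA sequence under the current RNG state
randomSequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## calibrant ion mass: (dTG4T)4 . (NH4)3, deprotonated z times
calibrantIonMass <- function(z) {
  oligoNeutralMass(oligo("TG4T", seqTG4T, strandCount = 4L)) +
    3 * msConstants("dNH4") - z * msConstants("proton_mass")
}

## noise-free equal-response species table at one screening condition
equalResponseTable <- function(M0, L0, KD1, KD2) {
  st <- solveEquilibrium(bindingSample(M0, L0), KD1, KD2)
  entries <- data.frame(ligand_count = 0:2, k_count = 2L, nh4_count = 0L,
                        z = 0L,
                        intensity = c(st@freeM, st@ML, st@ML2) * 100)
  new("SpeciesTable", entries = entries, noiseSigma = 0,
      standardIntensity = 400, ambiguous = data.frame())
}
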