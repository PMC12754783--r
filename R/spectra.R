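#' Construct a mass spectrum
#'
#' @param mz Strictly increasing m/z axis (Th).
#' @param intensity Non-negative intensities.
#' @param polarity "negative" or "positive".
#' @param sampleId Sample identifier.
#' @return A \linkS4class{MassSpectrum}.
#' @export
massSpectrum <- function(mz, intensity, polarity = "negative",
                         sampleId = "") {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      polarity = polarity, sampleId = sampleId)
}

#' Read a mass spectrum
#'
#' Reads either a two-column m/z-intensity text table (whitespace- or
#' comma-separated, optional header) or an mzML file (first spectrum; see
#' \code{\link{readMzML}} for the supported subset). Profile data are passed
#' through unmodified; invariants (ascending m/z, non-negative intensity,
#' non-empty) are enforced.
#'
#' @param path File path.
#' @param format "auto" (by extension), "table" or "mzML".
#' @param ... Passed to \code{\link{massSpectrum}} (polarity, sampleId).
#' @return A \linkS4class{MassSpectrum}.
#' @export
readSpectrum <- function(path, format = c("auto", "table", "mzML"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML"
              else "table"
  }
  if (format == "mzML") return(readMzML(path, ...))
  df <- tryCatch(utils::read.table(path, header = FALSE,
                                   comment.char = "#"),
                 error = function(e) NULL)
  if (is.null(df) || ncol(df) < 2L)
    df <- utils::read.csv(path, header = FALSE, comment.char = "#")
  ## tolerate a header line
  if (is.character(df[[1L]]) || is.factor(df[[1L]])) {
    suppressWarnings(v <- as.numeric(as.character(df[[1L]])))
    if (is.na(v[1L])) df <- df[-1L, , drop = FALSE]
    df[] <- lapply(df, function(col) as.numeric(as.character(col)))
  }
  if (nrow(df) == 0L) stop("empty spectrum: ", path, call. = FALSE)
  massSpectrum(df[[1L]], df[[2L]], ...)
}

#' Write a spectrum as a two-column table
#'
#' @param spec A \linkS4class{MassSpectrum}.
#' @param path Output path.
#' @param sep Column separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeSpectrumTable <- function(spec, path, sep = "\t") {
  stopifnot(is(spec, "MassSpectrum"))
  utils::write.table(data.frame(mz = spec@mz, intensity = spec@intensity),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Integrate a m/z window
#'
#' Trapezoidal integral of intensity over [center - halfWidth, center +
#' halfWidth]. A window with no overlap with the spectrum range returns 0
#' with a warning.
#'
#' @param spec A \linkS4class{MassSpectrum} (profile data).
#' @param center Window center (Th).
#' @param halfWidth Window half width (Th), > 0.
#' @return Non-negative raw intensity (area, intensity x Th).
#' @export
integrateWindow <- function(spec, center, halfWidth) {
  stopifnot(is(spec, "MassSpectrum"), halfWidth > 0)
  lo <- center - halfWidth
  hi <- center + halfWidth
  mz <- spec@mz
  if (hi < mz[1L] || lo > mz[length(mz)]) {
    warning("integration window [", lo, ", ", hi,
            "] outside spectrum range; returning 0")
    return(0)
  }
  idx <- which(mz >= lo & mz <= hi)
  if (length(idx) < 2L) return(0)
  x <- mz[idx]
  y <- spec@intensity[idx]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Estimate spectral noise from a blank region
#'
#' Standard deviation of the intensities inside a species-free m/z interval.
#'
#' @param spec A \linkS4class{MassSpectrum}.
#' @param blankRegion Numeric length-2: m/z interval without assigned species.
#' @param windows Optional data.frame of species windows (columns
#'   \code{center}, \code{half_width}); the blank region must not overlap any.
#' @return Per-point noise sigma (>= 0).
#' @export
estimateNoise <- function(spec, blankRegion, windows = NULL) {
  stopifnot(is(spec, "MassSpectrum"), length(blankRegion) == 2L)
  blankRegion <- sort(blankRegion)
  if (!is.null(windows) && nrow(windows)) {
    lo <- windows$center - windows$half_width
    hi <- windows$center + windows$half_width
    if (any(lo < blankRegion[2L] & hi > blankRegion[1L]))
      stop("blank region overlaps a species window", call. = FALSE)
  }
  idx <- which(spec@mz >= blankRegion[1L] & spec@mz <= blankRegion[2L])
  if (length(idx) < 10L)
    stop("blank region must contain at least 10 points", call. = FALSE)
  stats::sd(spec@intensity[idx])
}

#' Noise-correct a raw integrated intensity
#'
#' Subtracts three times the noise standard deviation from an integrated
#' signal and clamps at zero. For a window summing \code{nPoints} independent
#' noise samples the per-point sigma scales by sqrt(nPoints); \code{spacing}
#' converts to area units when the raw value is a trapezoidal integral.
#'
#' @param raw Raw integrated intensity (>= 0).
#' @param sigma Per-point noise standard deviation.
#' @param nPoints Number of points in the window.
#' @param spacing m/z spacing (Th per point) when \code{raw} is an area;
#'   1 when it is a plain sum.
#' @return max(raw - 3 * sigma * sqrt(nPoints) * spacing, 0).
#' @export
correctIntensity <- function(raw, sigma, nPoints, spacing = 1) {
  stopifnot(raw >= 0, sigma >= 0, nPoints >= 1)
  max(raw - 3 * sigma * sqrt(nPoints) * spacing, 0)
}

#' Build integration windows for a target's species
#'
#' Places one window per (stoichiometry, K+ adduct, NH4+ adduct, charge)
#' combination at the computed species m/z. The default half width is 1.0 Th
#' scaled by 4/z (average-mass isotope envelopes narrow as 1/z; 1.0 Th is
#' calibrated for z = 4 envelopes of 6-8 kDa DNA).
#'
#' @param target An \linkS4class{Oligo}.
#' @param ligandObj A \linkS4class{Ligand} or NULL for free DNA only.
#' @param ligandCounts Stoichiometries to monitor (default 0:2).
#' @param chargeStates Charge magnitudes to monitor.
#' @param kMax Adduct ladder length (default 0:6 K+).
#' @param nh4Counts NH4+ adduct counts (default 0).
#' @param halfWidth Half width at z = 4 (Th); scaled by 4/z per charge state.
#' @param mode Mass mode.
#' @return data.frame with columns ligand_count, k_count, nh4_count, z,
#'   center, half_width.
#' @export
speciesWindows <- function(target, ligandObj = NULL, ligandCounts = 0:2,
                           chargeStates = 4:6, kMax = 6L, nh4Counts = 0L,
                           halfWidth = 1.0,
                           mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.null(ligandObj)) ligandCounts <- 0L
  grid <- expand.grid(ligand_count = ligandCounts, k_count = 0:kMax,
                      nh4_count = nh4Counts, z = chargeStates)
  grid$center <- vapply(seq_len(nrow(grid)), function(i) {
    key <- speciesKey(target, grid$ligand_count[i], grid$k_count[i],
                      grid$nh4_count[i], grid$z[i])
    speciesMz(key, ligandObj, mode)
  }, numeric(1))
  grid$half_width <- halfWidth * 4 / grid$z
  grid[order(grid$center), ]
}

#' Build a species table from a spectrum
#'
#' Integrates every species window, applies 3-sigma noise correction, and
#' returns adduct- and charge-resolved corrected intensities. Windows of
#' different stoichiometry whose edges approach closer than \code{tolerance}
#' cannot be attributed unambiguously; both are excluded and logged in the
#' \code{ambiguous} slot (deterministic exclusion rather than signal
#' splitting).
#'
#' @param spec A \linkS4class{MassSpectrum}.
#' @param windows data.frame from \code{\link{speciesWindows}}.
#' @param sigma Per-point noise sigma (e.g. from \code{\link{estimateNoise}}).
#' @param tolerance Minimum allowed edge-to-edge gap (Th) between windows of
#'   different ligand_count before they are flagged ambiguous.
#' @param standardWindow Optional c(center, halfWidth) for the dT6 internal
#'   standard.
#' @return A \linkS4class{SpeciesTable}.
#' @export
buildSpeciesTable <- function(spec, windows, sigma = 0, tolerance = 0.1,
                              standardWindow = NULL) {
  stopifnot(is(spec, "MassSpectrum"))
  w <- windows[order(windows$center), , drop = FALSE]
  ambiguous <- rep(FALSE, nrow(w))
  if (nrow(w) > 1L) {
    for (i in seq_len(nrow(w) - 1L)) {
      gap <- (w$center[i + 1L] - w$half_width[i + 1L]) -
             (w$center[i] + w$half_width[i])
      if (gap < tolerance && w$ligand_count[i] != w$ligand_count[i + 1L])
        ambiguous[c(i, i + 1L)] <- TRUE
    }
  }
  if (any(ambiguous))
    message(sum(ambiguous),
            " window(s) excluded as ambiguous (stoichiometry overlap)")
  keep <- w[!ambiguous, , drop = FALSE]
  dmz <- stats::median(diff(spec@mz))
  vals <- vapply(seq_len(nrow(keep)), function(i) {
    raw <- suppressWarnings(
      integrateWindow(spec, keep$center[i], keep$half_width[i]))
    n <- max(1L, sum(spec@mz >= keep$center[i] - keep$half_width[i] &
                     spec@mz <= keep$center[i] + keep$half_width[i]))
    correctIntensity(raw, sigma, n, spacing = dmz)
  }, numeric(1))
  entries <- keep[, c("ligand_count", "k_count", "nh4_count", "z")]
  entries$intensity <- vals
  rownames(entries) <- NULL
  stdInt <- 0
  if (!is.null(standardWindow)) {
    raw <- suppressWarnings(
      integrateWindow(spec, standardWindow[1L], standardWindow[2L]))
    n <- max(1L, sum(spec@mz >= standardWindow[1L] - standardWindow[2L] &
                     spec@mz <= standardWindow[1L] + standardWindow[2L]))
    stdInt <- correctIntensity(raw, sigma, n, spacing = dmz)
  }
  new("SpeciesTable", entries = entries, noiseSigma = sigma,
      standardIntensity = stdInt,
      ambiguous = w[ambiguous, , drop = FALSE])
}

#' Total corrected intensity per stoichiometry
#'
#' Sums a species table over the full K+/NH4+ adduct ladder and all monitored
#' charge states, returning one intensity per ligand count (the I(M), I(ML),
#' I(ML2) entering the concentration conversion).
#'
#' @param table A \linkS4class{SpeciesTable}.
#' @param ligandCounts Stoichiometries to report (default 0:2).
#' @return Named numeric vector ("0", "1", "2", ...).
#' @export
stoichiometryIntensities <- function(table, ligandCounts = 0:2) {
  stopifnot(is(table, "SpeciesTable"))
  e <- table@entries
  vapply(ligandCounts, function(lc)
    sum(e$intensity[e$ligand_count == lc]), numeric(1)) |>
    stats::setNames(as.character(ligandCounts))
}

#' Write / read a species table as CSV
#'
#' Serializes the entries with columns ligand_count, k_count, nh4_count, z,
#' intensity; noise sigma and internal-standard intensity are stored in
#' comment headers.
#'
#' @param table A \linkS4class{SpeciesTable}.
#' @param path CSV path.
#' @return \code{path} (write) or a \linkS4class{SpeciesTable} (read).
#' @export
writeSpeciesTable <- function(table, path) {
  stopifnot(is(table, "SpeciesTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# noise_sigma: %.10g", table@noiseSigma),
               sprintf("# standard_intensity: %.10g",
                       table@standardIntensity)), con)
  utils::write.csv(table@entries, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpeciesTable
#' @export
readSpeciesTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  getNum <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*: *", "", ln[1L])) else 0
  }
  df <- utils::read.csv(path, comment.char = "#")
  new("SpeciesTable", entries = df, noiseSigma = getNum("noise_sigma"),
      standardIntensity = getNum("standard_intensity"),
      ambiguous = data.frame())
}
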