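#' Construct a K+ adduct profile
#'
#' @param counts Non-negative intensities for n = 0, 1, ..., n_max K+
#'   adducts (in order; length >= 2).
#' @param ligandCount Stoichiometry context (0 = M, 1 = ML, 2 = ML2).
#' @return An \linkS4class{AdductProfile}.
#' @export
adductProfile <- function(counts, ligandCount = 0L) {
  new("AdductProfile", counts = as.numeric(counts),
      ligandCount = as.integer(ligandCount))
}

#' Extract an adduct profile from a species table
#'
#' Sums the adduct-resolved entries of one stoichiometry over charge states
#' and NH4+ counts, returning the K+ ladder.
#'
#' @param table A \linkS4class{SpeciesTable}.
#' @param ligandCount Stoichiometry to extract.
#' @param nMax Ladder length (default 6).
#' @return An \linkS4class{AdductProfile}.
#' @export
adductProfileFromTable <- function(table, ligandCount = 0L, nMax = 6L) {
  stopifnot(is(table, "SpeciesTable"))
  e <- table@entries[table@entries$ligand_count == ligandCount, ]
  counts <- vapply(0:nMax, function(n)
    sum(e$intensity[e$k_count == n]), numeric(1))
  adductProfile(counts, ligandCount)
}

## Candidate-specific channels: interior strict local maxima at n >= 1
## (n = 0 is never a candidate: zero specific K+ is not a structural site).
## The channel above n_max is treated as zero.
.candidateSpecific <- function(counts) {
  n <- length(counts)
  padded <- c(counts, 0)
  which(vapply(2:n, function(i)
    counts[i] > padded[i - 1L] && counts[i] > padded[i + 1L],
    logical(1))) # index into counts[2..n]; adduct number = index
}

#' Fit the nonspecific Poisson adduct background
#'
#' Nonspecific electrospray K+ adducts follow an approximately Poisson
#' distribution over the adduct number n. The mean and amplitude are fitted
#' by maximum likelihood on the profile with candidate-specific channels
#' (interior local maxima) treated as missing, so a large specific spike does
#' not bias the background estimate.
#'
#' @param profile An \linkS4class{AdductProfile}.
#' @param mask Integer adduct numbers to exclude from the fit; defaults to
#'   the detected candidate-specific channels.
#' @return A list: \code{lambda} (Poisson mean), \code{scale} (total
#'   background intensity), \code{predicted} (background prediction per
#'   channel), \code{mask}. \code{lambda} is NA when fewer than 3 channels
#'   remain (degenerate profile).
#' @export
fitPoissonBackground <- function(profile, mask = NULL) {
  stopifnot(is(profile, "AdductProfile"))
  counts <- profile@counts
  nMax <- length(counts) - 1L
  if (is.null(mask)) mask <- .candidateSpecific(counts)
  use <- setdiff(0:nMax, mask)
  cu <- counts[use + 1L]
  if (length(use) < 3L || sum(cu) <= 0)
    return(list(lambda = NA_real_, scale = NA_real_,
                predicted = rep(NA_real_, nMax + 1L), mask = mask))
  ## conditional multinomial ML over the unmasked channels
  negll <- function(lambda) {
    lp <- stats::dpois(use, lambda, log = TRUE)
    -sum(cu * (lp - log(sum(exp(lp)))))
  }
  opt <- stats::optimize(negll, interval = c(1e-8, 20))
  lambda <- opt$minimum
  pUse <- stats::dpois(use, lambda)
  scale <- sum(cu) / sum(pUse)
  predicted <- scale * stats::dpois(0:nMax, lambda)
  list(lambda = lambda, scale = scale, predicted = predicted, mask = mask)
}

#' Call specific K+ adducts and count G-quartets
#'
#' An adduct with n K+ is specific when it is significantly more populated
#' than its n - 1 and n + 1 neighbours: quantified as (i) counts[n] >
#' \code{minExcess} x max(neighbours) and (ii) counts[n] exceeding the fitted
#' Poisson background prediction by more than \code{nSigma} background
#' standard deviations (the residual sd of the masked background fit, which
#' keeps the call invariant under rescaling of the profile). n specific K+
#' between consecutive quartets imply n + 1 quartets.
#'
#' @param profile An \linkS4class{AdductProfile}.
#' @param minExcess Ratio threshold to both neighbours (default 1.5).
#' @param nSigma Background significance threshold (default 3).
#' @return A \linkS4class{SpecificityCall}. With no specific adduct the
#'   quartet count is undetermined (NA).
#' @examples
#' ## ladder dominated by 2 K+ with absent 0 and 1 K+ -> 3 quartets
#' callSpecific(adductProfile(c(0, 0, 100, 12, 2, 0, 0)))
#' @export
callSpecific <- function(profile, minExcess = 1.5, nSigma = 3) {
  stopifnot(is(profile, "AdductProfile"))
  counts <- profile@counts
  nMax <- length(counts) - 1L
  if (sum(counts) <= 0) {
    return(new("SpecificityCall", specificN = integer(0),
               lambda = NA_real_, scale = NA_real_,
               quartetCount = NA_integer_, minExcess = minExcess))
  }
  cand <- .candidateSpecific(counts)
  bg <- fitPoissonBackground(profile, mask = cand)
  padded <- c(counts, 0)
  specific <- integer(0)
  if (length(cand)) {
    if (!is.na(bg$lambda)) {
      use <- setdiff(0:nMax, cand)
      resid <- counts[use + 1L] - bg$predicted[use + 1L]
      sdBg <- stats::sd(resid)
      if (!is.finite(sdBg)) sdBg <- 0
      excess <- counts[cand + 1L] - bg$predicted[cand + 1L]
    } else {
      ## degenerate background: fall back to the neighbour test alone
      sdBg <- 0
      excess <- counts[cand + 1L]
    }
    neighMax <- pmax(counts[cand], padded[cand + 2L])
    ok <- counts[cand + 1L] > minExcess * neighMax & excess > nSigma * sdBg
    specific <- cand[ok]
  }
  qc <- if (length(specific)) max(specific) + 1L else NA_integer_
  new("SpecificityCall", specificN = as.integer(specific),
      lambda = if (is.na(bg$lambda)) NA_real_ else bg$lambda,
      scale = if (is.na(bg$scale)) NA_real_ else bg$scale,
      quartetCount = qc, minExcess = minExcess)
}

#' Export specificity calls as JSON
#'
#' One entry per stoichiometry with the specific-adduct set, Poisson
#' background parameters, quartet count and the thresholds used.
#'
#' @param calls Named list of \linkS4class{SpecificityCall} (names = "M",
#'   "ML", "ML2", ...).
#' @param path Output JSON path (NULL returns the list only).
#' @return Invisibly, the JSON-ready list.
#' @export
exportAdductCalls <- function(calls, path = NULL) {
  out <- lapply(calls, function(cl) {
    list(specific_n = as.integer(cl@specificN),
         lambda_nonspecific = cl@lambda,
         quartet_count = if (is.na(cl@quartetCount)) "undetermined"
                         else cl@quartetCount,
         min_excess = cl@minExcess)
  })
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(out)
}
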