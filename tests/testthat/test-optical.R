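test_that("molar ellipticity conversion follows the 32980 c l rule", {
  c0 <- 1e-5; l0 <- 0.2
  ## unit case: theta = 32980 c l gives delta-epsilon = 1
  sp <- cdSpectrum(c(260, 295), c(32980 * c0 * l0, 0), c0, l0)
  expect_equal(molarEllipticity(sp), c(1, 0))
  ## direct evaluation: theta = 10 mdeg at 10 uM, 0.2 cm
  sp2 <- cdSpectrum(260, 10, c0, l0)
  expect_equal(molarEllipticity(sp2), 10 / (32980 * 1e-5 * 0.2))
  ## linear in theta, inverse-linear in c and l
  set.seed(31)
  for (i in 1:20) {
    th <- runif(1, -20, 20); cc <- runif(1, 1e-6, 1e-4)
    ll <- runif(1, 0.1, 1); k <- runif(1, 0.5, 3)
    base <- molarEllipticity(cdSpectrum(260, th, cc, ll))
    expect_equal(molarEllipticity(cdSpectrum(260, k * th, cc, ll)),
                 k * base)
    expect_equal(molarEllipticity(cdSpectrum(260, th, k * cc, ll)),
                 base / k)
    expect_equal(molarEllipticity(cdSpectrum(260, th, cc, k * ll)),
                 base / k)
  }
  expect_error(cdSpectrum(260, 1, -1e-5, 0.2), "> 0")
})

test_that("baselines fit exactly on linear flanks and reject bad windows", {
  temp <- seq(10, 90, by = 0.5)
  A <- ifelse(temp < 50, 0.8 - 3e-4 * temp, 0.25 + 2e-4 * temp)
  cv <- meltingCurve(temp, A, wavelength = 295)
  bl <- fitBaselines(cv, lowWindow = c(10, 30), highWindow = c(70, 90))
  expect_equal(bl$folded, c(0.8, -3e-4), tolerance = 1e-9)
  expect_equal(bl$unfolded, c(0.25, 2e-4), tolerance = 1e-9)
  expect_error(fitBaselines(cv, c(10, 50), c(45, 90)), "overlap")
  expect_error(fitBaselines(cv, c(10, 11), c(70, 90)), "5 points")
  ## windows inside the transition: poor-fit warning
  sm <- simulateMelting(simConfig(meltingTm = 55, meltingEnthalpy = 300))
  expect_warning(fitBaselines(sm$curve, lowWindow = c(50, 54),
                              highWindow = c(56, 60)),
                 "inside the transition")
})

test_that("baselines recover the generator coefficients within 1%", {
  cfg <- simConfig(meltingTm = 55, meltingEnthalpy = 300)
  sm <- simulateMelting(cfg, tempRange = c(5, 95))
  ## window fits approximate the baselines where they are evaluated
  blW <- fitBaselines(sm$curve)
  atT <- function(co, t) co[1] + co[2] * t
  expect_equal(atT(blW$folded, 10), atT(cfg$baselineFolded, 10),
               tolerance = 0.01)
  expect_equal(atT(blW$unfolded, 90), atT(cfg$baselineUnfolded, 90),
               tolerance = 0.01)
  ## the two-state refinement recovers the coefficients themselves
  bl <- refineBaselinesTwoState(sm$curve, blW)
  expect_equal(bl$folded, cfg$baselineFolded, tolerance = 0.01)
  expect_equal(bl$unfolded, cfg$baselineUnfolded, tolerance = 0.01)
})

test_that("folded fraction reproduces the two-state construction", {
  temp <- seq(10, 90, by = 1)
  L0 <- 0.25 + 2e-4 * temp
  L1 <- 0.8 - 3e-4 * temp
  bl <- list(unfolded = c(0.25, 2e-4), folded = c(0.8, -3e-4))
  ## A = L0 everywhere -> theta = 0; A = L1 -> theta = 1; midpoint -> 0.5
  for (case in list(list(A = L0, th = 0), list(A = L1, th = 1),
                    list(A = (L0 + L1) / 2, th = 0.5))) {
    ffc <- foldedFraction(meltingCurve(temp, case$A), bl)
    expect_equal(ffc@theta, rep(case$th, length(temp)), tolerance = 1e-12)
  }
  ## values outside [0, 1] are preserved, not clipped
  ffc2 <- foldedFraction(meltingCurve(temp, L1 + 0.05), bl)
  expect_true(any(ffc2@theta > 1))
  ## coinciding baselines are rejected
  expect_error(foldedFraction(meltingCurve(temp, L0),
                              list(unfolded = c(0.25, 2e-4),
                                   folded = c(0.25, 2e-4))), "coincide")
  ## exact generator theta is recovered when baselines are exact
  cfg <- simConfig(meltingTm = 55, meltingEnthalpy = 250)
  sm <- simulateMelting(cfg)
  ffc3 <- foldedFraction(sm$curve, list(unfolded = cfg$baselineUnfolded,
                                        folded = cfg$baselineFolded))
  expect_equal(ffc3@theta, sm$thetaTrue, tolerance = 1e-10)
})

test_that("Tm is recovered within 0.2 degC from synthetic curves", {
  for (tmTrue in c(45, 55, 68)) {
    cfg <- simConfig(meltingTm = tmTrue, meltingEnthalpy = 250)
    sm <- simulateMelting(cfg, tempRange = c(10, 90))
    bl <- refineBaselinesTwoState(sm$curve)
    mr <- meltingTemperature(foldedFraction(sm$curve, bl))
    expect_lt(abs(meltingTm(mr) - tmTrue), 0.2)
  }
  ## the refinement matters near the scan edge; plain window baselines
  ## still suffice in the middle of the scan
  sm <- simulateMelting(simConfig(meltingTm = 50, meltingEnthalpy = 250))
  mr <- meltingTemperature(foldedFraction(sm$curve, fitBaselines(sm$curve)))
  expect_lt(abs(meltingTm(mr) - 50), 0.2)
})

test_that("Tm is invariant under affine rescaling of the absorbance axis", {
  cfg <- simConfig(meltingTm = 58, meltingEnthalpy = 250)
  sm <- simulateMelting(cfg)
  tm1 <- meltingTm(meltingTemperature(
    foldedFraction(sm$curve, fitBaselines(sm$curve))))
  scaled <- meltingCurve(sm$curve@temperature,
                         3.2 * sm$curve@absorbance + 0.7)
  tm2 <- meltingTm(meltingTemperature(
    foldedFraction(scaled, fitBaselines(scaled))))
  expect_equal(tm2, tm1, tolerance = 1e-6)
})

test_that("curves never reaching 0.5 are undetermined with range report", {
  temp <- seq(10, 90, by = 1)
  ffc <- new("FoldedFractionCurve", temperature = temp,
             theta = seq(0.9, 0.7, length.out = length(temp)),
             baselineUnfolded = c(0, 0), baselineFolded = c(1, 0),
             direction = "heating")
  mr <- meltingTemperature(ffc)
  expect_true(is.na(meltingTm(mr)))
  expect_equal(mr@thetaRange, c(0.7, 0.9))
})

test_that("delta-Tm and hysteresis behave on constructed pairs", {
  mk <- function(tm) {
    cfg <- simConfig(meltingTm = tm, meltingEnthalpy = 250)
    sm <- simulateMelting(cfg)
    bl <- refineBaselinesTwoState(sm$curve)
    meltingTemperature(foldedFraction(sm$curve, bl))
  }
  ref <- mk(50)
  expect_equal(deltaTm(ref, ref), 0)
  ## injected +10 degC shift recovered within 0.3 degC
  expect_equal(deltaTm(mk(60), ref), 10, tolerance = 0.3 / 10)
  und <- new("MeltingResult", tm = NA_real_, thetaRange = c(0.6, 0.9),
             multipleCrossings = FALSE)
  expect_true(is.na(deltaTm(mk(60), und)))
  ## reversible synthetic curve: zero hysteresis
  cfg <- simConfig(meltingTm = 55, meltingEnthalpy = 250)
  heat <- simulateMelting(cfg, direction = "heating")
  cool <- simulateMelting(cfg, direction = "cooling")
  tmH <- meltingTemperature(foldedFraction(heat$curve,
                                           fitBaselines(heat$curve)))
  tmC <- meltingTemperature(foldedFraction(cool$curve,
                                           fitBaselines(cool$curve)))
  expect_lt(hysteresis(tmH, tmC), 1e-6)
})

test_that("335 nm reference subtraction removes additive drift", {
  cfg <- simConfig(meltingTm = 55, meltingEnthalpy = 250)
  sm <- simulateMelting(cfg)
  drift <- 0.02 + 1e-3 * sm$curve@temperature
  drifted <- meltingCurve(sm$curve@temperature,
                          sm$curve@absorbance + drift, 295)
  refCurve <- meltingCurve(sm$curve@temperature, drift, 335)
  corrected <- subtractReference(drifted, refCurve)
  expect_equal(corrected@absorbance, sm$curve@absorbance, tolerance = 1e-12)
  expect_error(subtractReference(drifted, drifted), "335")
})

test_that("melting and CD files round-trip through CSV", {
  cfg <- simConfig(meltingTm = 52, meltingEnthalpy = 250)
  heat <- simulateMelting(cfg)$curve
  path <- withr::local_tempfile(fileext = ".csv")
  writeMeltingCurves(list(heat), path)
  back <- readMeltingCurves(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]@absorbance, heat@absorbance, tolerance = 1e-9)
  cd <- simulateCD("parallel", conc = 1e-5, pathLength = 0.2,
                   cfg = simConfig(seed = 2))
  cdPath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength = cd@wavelength, mdeg = cd@ellipticity),
            cdPath, row.names = FALSE)
  cdBack <- readCDSpectrum(cdPath, conc = 1e-5, pathLength = 0.2)
  expect_equal(molarEllipticity(cdBack), molarEllipticity(cd),
               tolerance = 1e-6)
})
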