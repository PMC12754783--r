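test_that("Mason-Schamp scaling laws and inversion hold", {
  m <- calibrantIonMass(5L)
  c1 <- masonSchamp(2, 5, m, 296)
  expect_equal(masonSchamp(4, 5, m, 296), c1 / 2)     # K0 doubled
  expect_equal(masonSchamp(2, 10, m, 296), 2 * c1)    # z doubled
  ## exact round trip
  for (ccs in c(100, 787.5, 2000)) {
    K0 <- invertMasonSchamp(ccs, 5, m, 296)
    expect_equal(masonSchamp(K0, 5, m, 296), ccs, tolerance = 1e-12)
  }
  ## ccs -> 0 limit sends K0 -> infinity
  expect_gt(invertMasonSchamp(1e-6, 5, m, 296),
            invertMasonSchamp(787.5, 5, m, 296) * 1e6)
})

test_that("published calibrant CCS values regenerate through K0", {
  ## reference: 787.5 A2 (5-) and 735.7 A2 (4-) for (dTG4T)4.(NH4)3
  for (ref in list(c(5, 787.5), c(4, 735.7))) {
    z <- ref[1]; ccs <- ref[2]
    K0 <- invertMasonSchamp(ccs, z, calibrantIonMass(as.integer(z)), 296)
    expect_equal(masonSchamp(K0, z, calibrantIonMass(as.integer(z)), 296),
                 ccs, tolerance = 1e-10)
  }
})

test_that("noise-free stepped-field records are recovered exactly", {
  m <- calibrantIonMass(5L)
  cfg <- simConfig(seed = 1)
  recs <- simulateDrift(787.5, 5, m, cfg)
  fit <- fitSteppedField(recs)
  K0true <- invertMasonSchamp(787.5, 5, m, cfg$driftTemperature)
  expect_equal(reducedMobility(fit), K0true, tolerance = 1e-4)
  expect_equal(deadTime(fit), cfg$driftT0, tolerance = 1e-3)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  ## two points define the line exactly
  fit2 <- fitSteppedField(recs[c(1, 8)])
  expect_equal(reducedMobility(fit2), K0true, tolerance = 1e-4)
  ## rejections
  expect_error(fitSteppedField(recs[1]), "at least 2")
  bad <- recs
  bad[[2]]@pressure <- bad[[2]]@pressure * 1.5
  expect_error(fitSteppedField(bad), "inconsistent")
})

test_that("full CCS pipeline round trip is exact to < 0.01% noise-free", {
  for (ref in list(c(5, 787.5), c(4, 735.7))) {
    z <- as.integer(ref[1]); ccs <- ref[2]
    m <- calibrantIonMass(z)
    cfg <- simConfig(seed = 1)
    recs <- simulateDrift(ccs, z, m, cfg)
    fit <- fitSteppedField(recs)
    rec <- masonSchamp(reducedMobility(fit), z, m, cfg$driftTemperature)
    expect_lt(abs(rec - ccs) / ccs, 1e-4)
  }
})

test_that("median K0 is within 1% of truth under 1% arrival jitter", {
  m <- calibrantIonMass(5L)
  K0true <- invertMasonSchamp(787.5, 5, m, 296)
  ## scaled to 60 seeds for runtime; the median is stable well before 200
  k0s <- vapply(1:60, function(i) {
    recs <- simulateDrift(787.5, 5, m, simConfig(seed = 2000 + i),
                          jitterSD = 0.01)
    reducedMobility(fitSteppedField(recs))
  }, numeric(1))
  expect_lt(abs(median(k0s) - K0true) / K0true, 0.01)
})

test_that("calibrant validation applies the asymmetric 2% rule", {
  v <- validateCalibrant(787.5, 787.5)
  expect_true(v$pass)
  expect_identical(v$relativeError, 0)
  expect_false(validateCalibrant(1.03 * 787.5, 787.5)$pass)
  expect_true(validateCalibrant(0.985 * 787.5, 787.5)$pass)
  ## the definition normalizes by the reference: swapping arguments changes
  ## the error, so a value passing one way can fail the other near the edge
  a <- 787.5; b <- 787.5 / 1.0204
  expect_false(validateCalibrant(a, b)$pass)
  expect_true(validateCalibrant(b, a)$pass)
})

test_that("CCS distributions preserve apex and modality", {
  m <- calibrantIonMass(5L)
  cfg <- simConfig(seed = 1)
  recs <- simulateDrift(787.5, 5, m, cfg)
  fit <- fitSteppedField(recs)
  dist <- ccsDistribution(recs[[1]], fit, 5, m)
  ## apex matches the Mason-Schamp CCS of the apex mobility within 0.1%
  apexCCS <- dist$ccs[which.max(dist$abundance)]
  expect_lt(abs(apexCCS - 787.5) / 787.5, 1e-3)
  ## strictly monotone transform
  expect_true(all(diff(dist$ccs) > 0))
  ## area preserved by the Jacobian correction
  areaT <- sum(diff(recs[[1]]@time) *
               (head(recs[[1]]@intensity, -1) +
                tail(recs[[1]]@intensity, -1)) / 2)
  areaC <- sum(diff(dist$ccs) *
               (head(dist$abundance, -1) + tail(dist$abundance, -1)) / 2)
  expect_equal(areaC, areaT, tolerance = 1e-6)
  ## bimodal arrival distribution stays bimodal in CCS space
  recs2 <- simulateDrift(c(700, 800), 5, m, cfg)
  dist2 <- ccsDistribution(recs2[[1]], fitSteppedField(recs2), 5, m)
  nModes <- function(y) {
    y <- y[y > max(y) * 0.01]
    sum(diff(sign(diff(y))) == -2)
  }
  expect_equal(nModes(dist2$abundance), 2L)
})

test_that("drift records round-trip through CSV", {
  m <- calibrantIonMass(4L)
  recs <- simulateDrift(735.7, 4, m, simConfig(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDriftRecords(recs, path)
  back <- readDriftRecords(path)
  expect_length(back, length(recs))
  expect_equal(back[[3]]@deltaV, recs[[3]]@deltaV)
  expect_equal(back[[3]]@time, recs[[3]]@time, tolerance = 1e-9)
  fit <- fitSteppedField(back)
  expect_equal(masonSchamp(reducedMobility(fit), 4, m, 296), 735.7,
               tolerance = 1e-3)
})
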