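test_that("spectrum invariants are enforced on construction and read", {
  expect_error(massSpectrum(numeric(0), numeric(0)), "empty")
  expect_error(massSpectrum(c(1, 3, 2), c(1, 1, 1)), "increasing")
  expect_error(massSpectrum(c(1, 2), c(1, -1)), ">= 0")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("100.0 5", "100.5 7", "101.0 3"), path)
  sp <- readSpectrum(path)
  expect_length(mzValues(sp), 3L)
  writeLines(c("101 5", "100 7"), path)
  expect_error(readSpectrum(path), "increasing")
})

test_that("two-column tables round-trip through write and read", {
  sp <- massSpectrum(seq(100, 110, by = 0.1), runif(101))
  path <- withr::local_tempfile(fileext = ".txt")
  writeSpectrumTable(sp, path)
  sp2 <- readSpectrum(path, format = "table")
  expect_equal(mzValues(sp2), mzValues(sp), tolerance = 1e-12)
})

test_that("synthetic mzML round-trips bit-identically in m/z", {
  sim <- simulateSpectrum(bindingSample(10, 20), 1.5, 22, fixtureOligo(),
                          fixtureLigand(), simConfig(seed = 3))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(sim$spectrum, path)
  back <- readSpectrum(path)
  expect_identical(mzValues(back), mzValues(sim$spectrum))
  expect_identical(intensityValues(back), intensityValues(sim$spectrum))
})

test_that("window integration matches closed-form areas", {
  ## flat intensity 1 over a 2 Th window integrates to 2
  sp <- massSpectrum(seq(99, 103, by = 0.01), rep(1, 401))
  expect_equal(integrateWindow(sp, 101, 1), 2, tolerance = 1e-9)
  ## window fully outside the range: 0 with a warning
  expect_warning(out <- integrateWindow(sp, 200, 1), "outside")
  expect_identical(out, 0)
  ## Gaussian fully inside the window recovers its analytic area within 1%
  area <- 37.5
  sigma <- 0.2
  g <- massSpectrum(seq(95, 105, by = 0.01),
                    area * dnorm(seq(95, 105, by = 0.01), 100, sigma))
  expect_equal(integrateWindow(g, 100, 1.5), area, tolerance = 0.01)
  ## additivity over disjoint windows
  left <- integrateWindow(g, 99.25, 0.75)
  right <- integrateWindow(g, 100.75, 0.75)
  expect_equal(left + right, integrateWindow(g, 100, 1.5),
               tolerance = 1e-6)
})

test_that("noise estimation matches the known simulated sigma", {
  sp <- massSpectrum(seq(100, 110, by = 0.01), rep(2, 1001))
  expect_identical(estimateNoise(sp, c(101, 109)), 0)
  set.seed(11)
  noisy <- massSpectrum(seq(100, 110, by = 0.01),
                        abs(rnorm(1001, 50, 5)))
  est <- estimateNoise(noisy, c(100, 110))
  expect_lt(abs(est - 5) / 5, 0.2)
  ## too few points and species overlap are rejected
  expect_error(estimateNoise(sp, c(100.0, 100.05)), "10 points")
  win <- data.frame(center = 105, half_width = 1)
  expect_error(estimateNoise(sp, c(104.5, 108), windows = win), "overlap")
})

test_that("3-sigma correction is a clamped subtraction", {
  expect_identical(correctIntensity(100, 0, 50), 100)
  expect_equal(correctIntensity(100, 10 / (3 * sqrt(25)), 25), 90)
  expect_identical(correctIntensity(5, 10, 100), 0)
  ## monotone non-decreasing in raw, non-increasing in sigma
  set.seed(2)
  for (i in 1:20) {
    raw <- runif(1, 0, 100); sg <- runif(1, 0, 5); n <- sample(1:100, 1)
    expect_gte(correctIntensity(raw + 1, sg, n),
               correctIntensity(raw, sg, n))
    expect_lte(correctIntensity(raw, sg + 1, n),
               correctIntensity(raw, sg, n))
  }
})

test_that("species tables recover generator ground truth", {
  g4 <- fixtureOligo()
  lg <- fixtureLigand()
  ## noise-free: ledger areas within 1%
  sim <- simulateSpectrum(bindingSample(10, 20), 1.5, 22, g4, lg,
                          simConfig(seed = 5))
  w <- speciesWindows(g4, lg)
  tb <- buildSpeciesTable(sim$spectrum, w)
  I <- stoichiometryIntensities(tb)
  truth <- vapply(0:2, function(lc)
    sum(sim$ledger$area[sim$ledger$ligand_count == lc]), numeric(1))
  expect_equal(unname(I / sum(I)), truth / sum(truth), tolerance = 0.01)
  ## spectrum with only M: ML and ML2 integrate to zero
  simM <- simulateSpectrum(bindingSample(10, 0), 1.5, 22, g4, lg,
                           simConfig(seed = 5))
  tbM <- buildSpeciesTable(simM$spectrum, w)
  IM <- stoichiometryIntensities(tbM)
  expect_gt(IM[["0"]], 0)
  expect_equal(unname(IM[c("1", "2")]), c(0, 0), tolerance = 1e-6)
})

test_that("relative abundances are recovered within 2% at SNR >= 50", {
  g4 <- fixtureOligo()
  lg <- fixtureLigand()
  ## peak amplitude ~ area/(sigma sqrt(2 pi)); pick noise for SNR ~ 60
  sim <- simulateSpectrum(bindingSample(10, 20), 1.5, 22, g4, lg,
                          simConfig(seed = 9, noiseSigma = 3))
  w <- speciesWindows(g4, lg)
  sigma <- estimateNoise(sim$spectrum, c(min(mzValues(sim$spectrum)),
                                         min(sim$ledger$mz) - 5))
  tb <- buildSpeciesTable(sim$spectrum, w, sigma = sigma)
  I <- stoichiometryIntensities(tb)
  truth <- vapply(0:2, function(lc)
    sum(sim$ledger$area[sim$ledger$ligand_count == lc]), numeric(1))
  expect_equal(unname(I / sum(I)), truth / sum(truth), tolerance = 0.02)
})

test_that("colliding windows of different stoichiometry are excluded", {
  g4 <- fixtureOligo()
  sp <- massSpectrum(seq(1000, 2000, by = 0.05), rep(1, 20001))
  w <- data.frame(ligand_count = c(0L, 1L), k_count = 0L, nh4_count = 0L,
                  z = 5L, center = c(1500, 1500.5), half_width = 1)
  expect_message(tb <- buildSpeciesTable(sp, w), "ambiguous")
  expect_equal(nrow(speciesEntries(tb)), 0L)
  expect_equal(nrow(tb@ambiguous), 2L)
})

test_that("species tables round-trip through CSV", {
  tb <- equalResponseTable(10, 20, 1.5, 22)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpeciesTable(tb, path)
  tb2 <- readSpeciesTable(path)
  expect_equal(speciesEntries(tb2)$intensity, speciesEntries(tb)$intensity,
               tolerance = 1e-9)
  expect_equal(standardIntensity(tb2), 400)
})
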