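test_that("response drift analysis recovers constructed drifts", {
  ## constant ratio: all correction factors are 1, drift 0
  sim <- simulateTitration(10, NULL, 2, 30, simConfig(seed = 1))
  rd <- responseDrift(sim$series)
  expect_equal(rd$factors, rep(1, 7), tolerance = 1e-9)
  expect_equal(rd$drift, 0, tolerance = 1e-9)
  ## ratio halving linearly by the last point: last correction factor 2
  grid <- c(0, 5, 10, 15, 20, 30, 40)
  sim2 <- simulateTitration(10, grid, 2, 30, simConfig(seed = 1),
                            driftPerUM = -0.5 / 40)
  rd2 <- responseDrift(sim2$series)
  expect_equal(rd2$factors[7], 2, tolerance = 1e-6)
  ## injected 20% linear drift recovered within 10%
  sim3 <- simulateTitration(10, grid, 2, 30, simConfig(seed = 1),
                            driftPerUM = -0.2 / 40)
  rd3 <- responseDrift(sim3$series)
  expect_equal(rd3$drift, -0.2 / 40, tolerance = 0.1)
})

test_that("model intensities are responses times concentrations", {
  s <- bindingSample(10, 20)
  st <- solveEquilibrium(s, 1.5, 22)
  mi <- modelIntensities(s, 1.5, 22, 1, 1)
  expect_equal(unname(mi), c(st@freeM, st@ML, st@ML2))
  mi0 <- modelIntensities(s, 1.5, 22, 0, 1)
  expect_identical(unname(mi0["ML"]), 0)
  ## predicted fraction bound is monotone in L0
  fb <- vapply(seq(0, 40, by = 2), function(l0) {
    m <- modelIntensities(bindingSample(10, l0), 0.54, 200, 1, 1)
    (m["ML"] + m["ML2"]) / sum(m)
  }, numeric(1))
  expect_true(all(diff(fb) >= -1e-12))
})

test_that("noise-free 7-point series is refit within 1%", {
  sim <- simulateTitration(10, NULL, KD1 = 0.54, KD2 = 200,
                           cfg = simConfig(seed = 1))
  fit <- fitTitration(sim$series)
  expect_true(fit@converged)
  expect_equal(kd1(fit), 0.54, tolerance = 0.01)
  expect_equal(kd2(fit), 200, tolerance = 0.01)
  expect_equal(fit@rML, 1, tolerance = 0.01)
})

test_that("free response factors are identified from noise-free data", {
  sim <- simulateTitration(10, NULL, KD1 = 2, KD2 = 30,
                           cfg = simConfig(seed = 1,
                                           response = c(rM = 1, rML = 1.4,
                                                        rML2 = 0.7)))
  fit <- fitTitration(sim$series)
  expect_equal(kd1(fit), 2, tolerance = 0.02)
  expect_equal(kd2(fit), 30, tolerance = 0.02)
  expect_equal(fit@rML, 1.4, tolerance = 0.02)
  expect_equal(fit@rML2, 0.7, tolerance = 0.02)
})

test_that("refitting its own model is a fixed point with ~zero residual", {
  sim <- simulateTitration(10, NULL, 0.54, 200, simConfig(seed = 1))
  fit <- fitTitration(sim$series)
  expect_lt(fit@residualNorm, 1e-6)
})

test_that("an all-free-DNA series is censored above", {
  grid <- c(0, 5, 10, 20, 40)
  tables <- lapply(grid, function(l0) {
    new("SpeciesTable",
        entries = data.frame(ligand_count = 0:2, k_count = 0L,
                             nh4_count = 0L, z = 0L,
                             intensity = c(1000, 0, 0)),
        noiseSigma = 0, standardIntensity = 400, ambiguous = data.frame())
  })
  fit <- fitTitration(titrationSeries(grid, tables, 10))
  expect_identical(fit@censor, "above")
  expect_true(is.na(kd1(fit)))
})

test_that("the fit is invariant under permutation of the points", {
  sim <- simulateTitration(10, NULL, 1.2, 15, simConfig(seed = 4))
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  shuffled <- titrationSeries(sim$series@L0[perm],
                              sim$series@tables[perm], 10)
  f1 <- fitTitration(sim$series)
  f2 <- fitTitration(shuffled)
  expect_equal(kd1(f2), kd1(f1), tolerance = 1e-6)
  expect_equal(kd2(f2), kd2(f1), tolerance = 1e-6)
})

test_that("median KD1 over noisy replicates stays within 15% of truth", {
  ## 5% multiplicative noise, seeded replicates (scaled to 40 for runtime;
  ## the estimator is assessed by the median, which stabilizes quickly)
  kds <- vapply(1:40, function(i) {
    sim <- simulateTitration(10, NULL, 0.54, 200,
                             simConfig(seed = 1000 + i, noiseSigma = 0.05))
    kd1(fitTitration(sim$series))
  }, numeric(1))
  expect_lt(abs(median(kds) - 0.54) / 0.54, 0.15)
})

test_that("series invariants and directory round trip hold", {
  expect_error(titrationSeries(c(0, 5), list(), 10), "one SpeciesTable")
  sim <- simulateTitration(10, NULL, 2, 30, simConfig(seed = 2))
  dir <- withr::local_tempdir()
  files <- sprintf("p%d.csv", seq_along(sim$series@L0))
  for (i in seq_along(files))
    writeSpeciesTable(sim$series@tables[[i]], file.path(dir, files[i]))
  write.csv(data.frame(L0 = sim$series@L0, file = files),
            file.path(dir, "series.csv"), row.names = FALSE)
  back <- readTitrationDir(dir, M0 = 10)
  fit <- fitTitration(back)
  expect_equal(kd1(fit), 2, tolerance = 0.01)
})
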