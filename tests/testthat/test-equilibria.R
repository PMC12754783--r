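test_that("intensities convert to concentrations that sum to M0", {
  s <- bindingSample(10, 20)
  expect_equal(unname(concentrationsFromIntensities(c(1, 1, 0), s)),
               c(5, 5, 0))
  expect_equal(unname(concentrationsFromIntensities(c(7, 0, 0), s)),
               c(10, 0, 0))
  expect_equal(unname(concentrationsFromIntensities(c(2, 1, 1), s)),
               c(5, 2.5, 2.5))
  expect_warning(out <- concentrationsFromIntensities(c(0, 0, 0), s),
                 "undetermined")
  expect_true(all(is.na(out)))
})

test_that("free ligand by difference censors at zero", {
  expect_equal(as.numeric(freeLigand(bindingSample(10, 20), 0, 0)), 20)
  L <- freeLigand(bindingSample(10, 20), 5, 2)
  expect_equal(as.numeric(L), 11)
  expect_false(attr(L, "censored"))
  Lc <- freeLigand(bindingSample(10, 20), 10, 6)
  expect_identical(as.numeric(Lc), 0)
  expect_true(attr(Lc, "censored"))
})

test_that("fraction bound behaves on boundary cases", {
  expect_identical(fractionBound(10, 0, 0), 0)
  expect_identical(fractionBound(0, 4, 1), 1)
  expect_equal(fractionBound(3, 3, 3), 2 / 3)
  expect_warning(expect_true(is.na(fractionBound(0, 0, 0))))
  expect_error(fractionBound(-1, 0, 0))
})

test_that("cooperativity classification uses the statistical factor 4", {
  expect_identical(classifyCooperativity(1.5, 22), "negative")
  expect_identical(classifyCooperativity(75, 40), "positive")
  expect_identical(classifyCooperativity(2, 8), "non-cooperative")
  expect_identical(classifyCooperativity(2, 8 * (1 + 1e-3)), "negative")
  expect_identical(classifyCooperativity(2, 8 * (1 - 1e-3)), "positive")
  expect_identical(classifyCooperativity(1, 4, KD1Censor = "above"),
                   "undetermined")
})

test_that("two identical independent sites give KD2/KD1 = 4 exactly", {
  ## microscopic site constant kd; macroscopic constants from site occupancy
  ## enumeration: ML has 2 configurations, so KD1 = kd/2 and KD2 = 2 kd
  kd <- 3.7
  KD1 <- kd / 2
  KD2 <- 2 * kd
  expect_identical(KD2 / KD1, 4)
  expect_identical(classifyCooperativity(KD1, KD2), "non-cooperative")
  ## the same holds through the forward solver: simulate the independent-site
  ## model and re-derive the macroscopic constants at equilibrium
  st <- solveEquilibrium(bindingSample(10, 20), KD1, KD2)
  br <- kdSinglePoint(st@freeM, st@ML, st@ML2,
                      freeLigand(bindingSample(10, 20), st@ML, st@ML2))
  expect_equal(kd2(br) / kd1(br), 4, tolerance = 1e-9)
  expect_identical(cooperativity(br), "non-cooperative")
})

test_that("single-point KDs recover Fig.-3-style parameters by round trip", {
  s <- bindingSample(10, 20)
  for (kds in list(c(1.5, 22), c(75, 40))) {
    st <- solveEquilibrium(s, kds[1], kds[2])
    br <- kdSinglePoint(st@freeM, st@ML, st@ML2,
                        freeLigand(s, st@ML, st@ML2))
    expect_equal(kd1(br), kds[1], tolerance = 1e-8)
    expect_equal(kd2(br), kds[2], tolerance = 1e-8)
  }
})

test_that("single-point estimator censors unobserved species", {
  ## equal M and ML at free L = 3: KD1 = 3
  br <- kdSinglePoint(2, 2, 1, structure(3, censored = FALSE))
  expect_equal(kd1(br), 3)
  ## no 2:1 complex: KD2 censored above
  br2 <- kdSinglePoint(5, 2, 0, structure(10, censored = FALSE))
  expect_identical(br2@KD2Censor, "above")
  expect_identical(cooperativity(br2), "undetermined")
  ## censored free ligand: everything undetermined
  br3 <- kdSinglePoint(5, 2, 1, structure(0, censored = TRUE))
  expect_identical(br3@KD1Censor, "undetermined")
  expect_error(kdSinglePoint(-1, 2, 1, 3))
})

test_that("the forward solver matches an exhaustive grid search", {
  s <- bindingSample(10, 20)
  st <- solveEquilibrium(s, 1.5, 22)
  ## independent oracle: enumerate free L, refine to 1e-6 uM resolution
  gFun <- function(L) {
    den <- 1 + L / 1.5 + L * L / (1.5 * 22)
    M <- 10 / den
    ML <- M * L / 1.5
    ML2 <- ML * L / 22
    L + ML + 2 * ML2 - 20
  }
  coarse <- seq(0, 20, by = 1e-3)
  Lc <- coarse[which.min(abs(gFun(coarse)))]
  fine <- seq(max(0, Lc - 2e-3), min(20, Lc + 2e-3), by = 1e-6)
  Lstar <- fine[which.min(abs(gFun(fine)))]
  expect_equal(st@freeL, Lstar, tolerance = 1e-5)
})

test_that("solver limits: no ligand and vanishing affinity", {
  st0 <- solveEquilibrium(bindingSample(10, 0), 1, 10)
  expect_identical(st0@freeM, 10)
  expect_identical(st0@ML + st0@ML2, 0)
  stw <- solveEquilibrium(bindingSample(10, 20), 1e9, 1e9)
  expect_lt(stw@ML + stw@ML2, 1e-6)
})

test_that("round trip and mass balances hold over random parameter tuples", {
  set.seed(123)
  for (i in 1:200) {
    M0 <- runif(1, 1, 50)
    L0 <- runif(1, 0.5, 100)
    K1 <- 10^runif(1, -2, 2)
    K2 <- 10^runif(1, -2, 2)
    s <- bindingSample(M0, L0)
    st <- solveEquilibrium(s, K1, K2)
    ## conservation to 1e-9 relative
    expect_lt(abs(st@freeM + st@ML + st@ML2 - M0) / M0, 1e-9)
    expect_lt(abs(st@freeL + st@ML + 2 * st@ML2 - L0) / L0, 1e-9)
    ## kd_single_point o solve_equilibrium is the identity to 1e-6 relative
    br <- kdSinglePoint(st@freeM, st@ML, st@ML2,
                        freeLigand(s, st@ML, st@ML2))
    expect_lt(abs(kd1(br) - K1) / K1, 1e-6)
    expect_lt(abs(kd2(br) - K2) / K2, 1e-6)
  }
})

test_that("bound fraction is monotone non-decreasing in total ligand", {
  fb <- vapply(seq(0, 80, by = 4), function(l0) {
    st <- solveEquilibrium(bindingSample(10, l0), 2, 30)
    fractionBound(st@freeM, st@ML, st@ML2)
  }, numeric(1))
  expect_true(all(diff(fb) >= -1e-12))
})

test_that("panel screening assembles the heatmap with absent cells", {
  tb <- equalResponseTable(10, 20, 1.5, 22)
  cells <- list(
    list(dna = "5YEY", ligand = "QQPQ", table = tb,
         sample = bindingSample(10, 20)),
    list(dna = "5YEY", ligand = "QPPQ",
         table = equalResponseTable(10, 20, 75, 40),
         sample = bindingSample(10, 20)),
    list(dna = "T24", ligand = "QQPQ",
         table = new("SpeciesTable",
                     entries = data.frame(ligand_count = 0:2, k_count = 0L,
                                          nh4_count = 0L, z = 0L,
                                          intensity = 0),
                     noiseSigma = 0, standardIntensity = 0,
                     ambiguous = data.frame()),
         sample = bindingSample(10, 20)))
  sc <- screenPanel(cells)
  expect_equal(dim(sc$fractionBound), c(2L, 2L))
  st <- solveEquilibrium(bindingSample(10, 20), 1.5, 22)
  expect_equal(sc$fractionBound["5YEY", "QQPQ"],
               fractionBound(st@freeM, st@ML, st@ML2), tolerance = 1e-9)
  expect_true(is.na(sc$fractionBound["T24", "QQPQ"]))
  expect_true(is.na(sc$fractionBound["T24", "QPPQ"]))
  ## single sample reduces to fraction_bound
  one <- screenPanel(cells[1])
  expect_equal(dim(one$fractionBound), c(1L, 1L))
  ## export with censoring metadata
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  meta <- exportScreen(sc, csvPath = csv, jsonPath = json)
  expect_true(file.exists(json) && file.exists(csv))
  expect_true(meta[["T24|QQPQ"]]$absent)
})
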