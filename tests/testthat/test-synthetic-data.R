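test_that("sampled concentrations respect the configured bounds", {
  cfg <- tinyConfig(n = 500, seed = 21)
  conc <- sampleConcentrations(cfg)
  b <- contentRanges()
  for (k in 1:5) {
    expect_gte(min(conc[, k]), b[k, "min"])
    expect_lte(max(conc[, k]), b[k, "max"])
  }
  ## moisture specifically stays within its mass-fraction window
  expect_true(all(conc[, "moisture"] >= 0.057 &
                    conc[, "moisture"] <= 0.085))
})

test_that("the embedded cross-analyte correlation is recovered", {
  cfg <- SyntheticConfig(nSamples = 2000, seed = 33)
  conc <- sampleConcentrations(cfg)
  r <- pearsonMatrix(conc)["cryptotanshinone", "tanshinone_IIA"]
  expect_lt(abs(r - 0.64), 0.05)
  ## the other pairs stay weakly correlated
  off <- pearsonMatrix(conc); diag(off) <- 0
  off["cryptotanshinone", "tanshinone_IIA"] <- 0
  off["tanshinone_IIA", "cryptotanshinone"] <- 0
  expect_lt(max(abs(off)), 0.2)
})

test_that("concentration sampling is deterministic under the seed", {
  a <- sampleConcentrations(tinyConfig(n = 50, seed = 5))
  b <- sampleConcentrations(tinyConfig(n = 50, seed = 5))
  d <- sampleConcentrations(tinyConfig(n = 50, seed = 6))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("the forward model inverts through the calibration chain", {
  cfg <- tinyConfig(n = 5, seed = 9, noiseSd = 0, scatterAmplitude = 0)
  wl <- BandAxis()@wavelengths
  E <- componentSpectra(wl)
  conc <- contentRanges()[, "mean"]
  set.seed(9)
  rc <- renderCube(conc, E, cfg)
  refl <- calibrateReflectance(rc$raw, rc$refs)
  ## foreground reflectance is spatially constant at zero noise/field
  lab <- maskLabels(rc$truth)
  fgSpec <- meanSpectrum(refl, rc$truth, "all")
  fgPix <- which(lab > 0)[1]
  expect_equal(unname(fgSpec),
               cubeData(refl)[cbind(arrayInd(fgPix, dim(lab))[1],
                                    arrayInd(fgPix, dim(lab))[2],
                                    seq_along(wl))],
               tolerance = 1e-6)
  ## absorbance is linear in concentration: A(2c) - A(c) == A(c) - A(0)
  set.seed(9); rc2 <- renderCube(2 * conc, E, cfg)
  set.seed(9); rc0 <- renderCube(0 * conc, E, cfg)
  A <- function(r) log10(1 / pmax(
    meanSpectrum(calibrateReflectance(r$raw, r$refs), r$truth, "all"),
    1e-4))
  expect_equal(A(rc2) - A(rc), A(rc) - A(rc0), tolerance = 1e-6)
})

test_that("raising a concentration darkens its peak band", {
  cfg <- tinyConfig(n = 5, seed = 10, noiseSd = 0)
  wl <- BandAxis()@wavelengths
  E <- componentSpectra(wl)
  conc <- contentRanges()[, "mean"]
  for (k in c(1, 3, 5)) {
    peak <- which.max(E[, k])
    conc2 <- conc; conc2[k] <- 2 * conc[k]
    set.seed(1); r1 <- renderCube(conc, E, cfg)
    set.seed(1); r2 <- renderCube(conc2, E, cfg)
    m1 <- meanSpectrum(calibrateReflectance(r1$raw, r1$refs),
                       r1$truth, "all")[peak]
    m2 <- meanSpectrum(calibrateReflectance(r2$raw, r2$refs),
                       r2$truth, "all")[peak]
    expect_lt(m2, m1)
  }
})

test_that("the truth mask always carries the 6x5 segment grid", {
  cfg <- tinyConfig(n = 5, seed = 11)
  E <- componentSpectra(BandAxis()@wavelengths)
  set.seed(11)
  rc <- renderCube(contentRanges()[, "mean"], E, cfg)
  expect_equal(nSegments(rc$truth), 30L)
  ## and the recovered mask agrees with it at zero noise
  cfg0 <- tinyConfig(n = 5, seed = 11, noiseSd = 0)
  set.seed(11)
  rc0 <- renderCube(contentRanges()[, "mean"], E, cfg0)
  refl <- calibrateReflectance(rc0$raw, rc0$refs)
  m <- buildMask(refl, 850, minArea = 25)
  agree <- mean((maskLabels(m) > 0) == (maskLabels(rc0$truth) > 0))
  expect_gte(agree, 0.99)
})

test_that("generated datasets carry 128-band spectra and patches", {
  ds <- generateDataset(tinyConfig(n = 6, seed = 12))
  ss <- ds$samples
  expect_identical(dim(spectraMatrix(ss)), c(128L, 6L))
  expect_length(patches(ss), 6)
  expect_identical(dim(patches(ss)[[1]]), c(8L, 8L, 128L))
  expect_identical(dim(concentrations(ss)), c(6L, 5L))
  expect_length(ds$truth$masks, 6)
})

test_that("regeneration with the same seed is bit-identical", {
  a <- generateDataset(tinyConfig(n = 5, seed = 13))
  b <- generateDataset(tinyConfig(n = 5, seed = 13))
  expect_identical(spectraMatrix(a$samples), spectraMatrix(b$samples))
  expect_identical(patches(a$samples), patches(b$samples))
  expect_identical(a$truth$concentrations, b$truth$concentrations)
})

test_that("mean spectra track the dominant analyte monotonically", {
  cfg <- tinyConfig(n = 15, seed = 14, noiseSd = 0,
                    scatterAmplitude = 0)
  ds <- generateDataset(cfg, keepPatches = FALSE)
  E <- ds$truth$endmembers
  conc <- ds$truth$concentrations
  peak <- which.max(E[, "salvianolic_acid_B"])
  absb <- log10(1 / pmax(spectraMatrix(ds$samples)[peak, ], 1e-4))
  rho <- cor(conc[, "salvianolic_acid_B"], absb, method = "spearman")
  expect_gte(abs(rho), 0.9)
})

test_that("PLSR is exact on noiseless synthetic absorbance spectra", {
  cfg <- tinyConfig(n = 30, seed = 15, noiseSd = 0,
                    scatterAmplitude = 0)
  ds <- generateDataset(cfg, keepPatches = FALSE)
  A <- log10(1 / pmax(t(spectraMatrix(ds$samples)), 1e-4))
  Y <- concentrations(ds$samples)
  m <- suppressWarnings(plsrFit(A, Y, 6))
  p <- plsrPredict(m, A)
  for (j in 1:5) expect_gte(rSquared(Y[, j], p[, j]), 0.999)
})
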