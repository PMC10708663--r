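test_that("ENVI round trips reproduce the cube bit-exactly", {
  for (mode in c("raw", "reflectance", "absorbance")) {
    cube <- smallCube(4, 4, 3, mode = mode)
    if (mode == "raw")
      cube@data <- round(cube@data * 256)      # integral counts
    path <- file.path(withr::local_tempdir(), "cube.raw")
    writeCube(cube, path)
    back <- readCube(path)
    expect_identical(cubeData(back), cubeData(cube))
    expect_equal(wavelengths(back), wavelengths(cube))
    expect_identical(cubeMode(back), mode)
  }
  ## float64 dialect round-trips arbitrary doubles
  cube <- HyperspectralCube(array(rnorm(24), c(2, 4, 3)),
                            BandAxis(n = 3), mode = "absorbance")
  path <- file.path(withr::local_tempdir(), "cube64.raw")
  writeCube(cube, path, dtype = 5)
  expect_identical(cubeData(readCube(path)), cubeData(cube))
})

test_that("malformed or inconsistent headers are rejected", {
  cube <- smallCube(4, 4, 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cube.raw")
  writeCube(cube, path)

  ## header declares more bands than the file holds
  hdr <- readLines(paste0(path, ".hdr"))
  hdr2 <- sub("^bands = 3", "bands = 4", hdr)
  hdr2 <- sub("wavelength = \\{ 500, 510, 520 \\}",
              "wavelength = { 500, 510, 520, 530 }", hdr2)
  writeLines(hdr2, paste0(path, ".hdr"))
  expect_error(readCube(path), "consistency")

  ## wavelength list inconsistent with band count
  hdr3 <- sub("wavelength = \\{ 500, 510, 520 \\}",
              "wavelength = { 500, 510 }", hdr)
  writeLines(hdr3, paste0(path, ".hdr"))
  expect_error(readCube(path), "consistency")

  ## missing magic
  writeLines(hdr[-1], paste0(path, ".hdr"))
  expect_error(readCube(path), "malformed")
})

test_that("generator cubes read back with the 128-band camera axis", {
  cfg <- tinyConfig(n = 5, seed = 7)
  E <- componentSpectra(BandAxis()@wavelengths)
  set.seed(7)
  rc <- renderCube(contentRanges()[, "mean"], E, cfg)
  path <- file.path(withr::local_tempdir(), "plate.raw")
  writeCube(rc$raw, path, dtype = 5)
  back <- readCube(path)
  wl <- wavelengths(back)
  expect_length(wl, 128)
  expect_gte(min(wl), 380)
  expect_lte(max(wl), 1064)
})

test_that("reflectance calibration follows (I - D) / (W - D)", {
  dims <- c(3, 3, 4)
  refs <- ReferenceFrames(white = rep(90, 4), dark = rep(10, 4))
  mk <- function(v) HyperspectralCube(array(v, dims), BandAxis(n = 4),
                                      mode = "raw")
  expect_equal(cubeData(calibrateReflectance(mk(90), refs)),
               array(1, dims))
  expect_equal(cubeData(calibrateReflectance(mk(10), refs)),
               array(0, dims))
  expect_equal(cubeData(calibrateReflectance(mk(50), refs)),
               array(0.5, dims))
  ## mode and degenerate-reference contracts
  expect_error(calibrateReflectance(smallCube(), refs), "mode")
  bad <- ReferenceFrames(white = rep(10, 4), dark = rep(10, 4))
  expect_error(calibrateReflectance(mk(50), bad), "calibration error")
})

test_that("white reference against itself is identically 1", {
  set.seed(3)
  W <- array(runif(36, 400, 900), c(3, 3, 4))
  D <- array(runif(36, 50, 99), c(3, 3, 4))
  refs <- ReferenceFrames(white = W, dark = D)
  raw <- HyperspectralCube(W, BandAxis(n = 4), mode = "raw")
  expect_equal(cubeData(calibrateReflectance(raw, refs)),
               array(1, c(3, 3, 4)))
})

test_that("absorbance transform is log10(1/R) with a floor", {
  mk <- function(v) HyperspectralCube(array(v, c(2, 2, 2)),
                                      BandAxis(n = 2),
                                      mode = "reflectance")
  expect_equal(cubeData(toAbsorbance(mk(1))), array(0, c(2, 2, 2)))
  expect_equal(cubeData(toAbsorbance(mk(0.1))), array(1, c(2, 2, 2)))
  expect_equal(cubeData(toAbsorbance(mk(0.01))), array(2, c(2, 2, 2)))
  ## floor prevents infinities
  expect_true(all(is.finite(cubeData(toAbsorbance(mk(0))))))
  expect_error(toAbsorbance(smallCube(mode = "raw")), "mode")
})

test_that("calibration then absorbance is monotone decreasing in counts", {
  set.seed(9)
  dims <- c(4, 4, 5)
  refs <- ReferenceFrames(white = rep(800, 5), dark = rep(100, 5))
  for (rep_i in 1:5) {
    counts <- array(runif(prod(dims), 150, 700), dims)
    bump <- counts + array(runif(prod(dims), 1, 20), dims)
    a1 <- cubeData(toAbsorbance(calibrateReflectance(
      HyperspectralCube(counts, BandAxis(n = 5), mode = "raw"), refs)))
    a2 <- cubeData(toAbsorbance(calibrateReflectance(
      HyperspectralCube(bump, BandAxis(n = 5), mode = "raw"), refs)))
    expect_true(all(a2 <= a1 + 1e-12))
  }
})

test_that("BandAxis enforces its invariants", {
  expect_error(BandAxis(c(500, 400)), "increasing")
  expect_error(BandAxis(500), "2 wavelengths")
  ax <- BandAxis()
  expect_length(wavelengths(ax), 128)
  expect_equal(wavelengths(ax)[2] - wavelengths(ax)[1], 5.38)
  ## band-count mismatch in the cube
  expect_error(HyperspectralCube(array(1, c(2, 2, 3)), BandAxis(n = 4)),
               "wavelength count")
})
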