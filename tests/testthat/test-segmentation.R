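## A reflectance plate built directly from a label image: foreground
## discs dark (0.2), plate bright (0.9).
maskCube <- function(lab, nb = 4, fgVal = 0.2, bgVal = 0.9) {
  arr <- array(rep(ifelse(lab > 0, fgVal, bgVal), nb),
               c(nrow(lab), ncol(lab), nb))
  HyperspectralCube(arr, BandAxis(n = nb, start = 800, step = 20),
                    mode = "reflectance")
}

test_that("the rendered 6x5 plate grid yields 30 labelled segments", {
  cfg <- tinyConfig(n = 5, seed = 2)
  E <- componentSpectra(BandAxis()@wavelengths)
  set.seed(2)
  rc <- renderCube(contentRanges()[, "mean"], E, cfg)
  refl <- calibrateReflectance(rc$raw, rc$refs)
  mask <- buildMask(refl, bandNm = 850, minArea = 25)
  expect_equal(nSegments(mask), 30L)
  expect_equal(nSegments(rc$truth), 30L)
  ## labels are contiguous 1..30
  expect_setequal(unique(as.vector(maskLabels(mask)[maskLabels(mask) > 0])),
                  1:30)
})

test_that("degenerate plates: all background and uniform foreground", {
  lab <- matrix(0L, 20, 20)
  cube <- maskCube(lab)                    # uniformly bright plate
  expect_warning(m0 <- buildMask(cube, 850, minArea = 5, threshold = 0.5),
                 "empty")
  expect_equal(nSegments(m0), 0L)

  uni <- maskCube(matrix(1L, 20, 20))      # uniformly dark foreground
  m1 <- buildMask(uni, 850, minArea = 5)
  expect_equal(nSegments(m1), 1L)
  expect_true(all(maskLabels(m1) == 1L))
})

test_that("mean spectra follow the arithmetic of masked means", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L; lab[7:9, 6:9] <- 2L
  cube <- maskCube(lab, nb = 3)
  mask <- new("SegmentMask", labels = lab, nSegments = 2L,
              bandUsed = 800)
  ## constant ROI -> constant spectrum
  expect_equal(unname(meanSpectrum(cube, mask, 1)), rep(0.2, 3))

  ## two-pixel ROI averaging
  arr <- array(0.9, c(2, 2, 2)); arr[1, 1, ] <- 0.2; arr[1, 2, ] <- 0.4
  c2 <- HyperspectralCube(arr, BandAxis(n = 2), mode = "reflectance")
  m2 <- new("SegmentMask",
            labels = matrix(c(1L, 0L, 1L, 0L), 2, 2),
            nSegments = 1L, bandUsed = 500)
  expect_equal(unname(meanSpectrum(c2, m2, 1)), c(0.3, 0.3))

  ## union mean = pixel-count-weighted mean of per-segment means
  set.seed(4)
  cube@data <- array(runif(300), c(10, 10, 3))
  all_ <- meanSpectrum(cube, mask, "all")
  s1 <- meanSpectrum(cube, mask, 1); s2 <- meanSpectrum(cube, mask, 2)
  n1 <- sum(lab == 1); n2 <- sum(lab == 2)
  expect_equal(all_, (n1 * s1 + n2 * s2) / (n1 + n2))

  expect_error(meanSpectrum(cube, mask, 7), "empty selection")
})

test_that("segment label permutation leaves the spectrum set unchanged", {
  lab <- matrix(0L, 12, 12)
  lab[2:4, 2:4] <- 1L; lab[2:4, 8:10] <- 2L; lab[8:10, 5:7] <- 3L
  set.seed(5)
  cube <- HyperspectralCube(array(runif(12 * 12 * 3), c(12, 12, 3)),
                            BandAxis(n = 3), mode = "reflectance")
  mask <- new("SegmentMask", labels = lab, nSegments = 3L, bandUsed = 500)
  perm <- c(3L, 1L, 2L)
  lab2 <- lab; lab2[lab > 0] <- perm[lab[lab > 0]]
  mask2 <- new("SegmentMask", labels = lab2, nSegments = 3L,
               bandUsed = 500)
  sp1 <- lapply(1:3, function(k) unname(meanSpectrum(cube, mask, k)))
  sp2 <- lapply(1:3, function(k) unname(meanSpectrum(cube, mask2, k)))
  ## same multiset of spectra
  ord1 <- order(vapply(sp1, sum, numeric(1)))
  ord2 <- order(vapply(sp2, sum, numeric(1)))
  expect_equal(sp1[ord1], sp2[ord2])
})

test_that("re-thresholding a mask's own foreground reproduces it", {
  cfg <- tinyConfig(n = 5, seed = 6)
  E <- componentSpectra(BandAxis()@wavelengths)
  set.seed(6)
  rc <- renderCube(contentRanges()[, "mean"], E, cfg)
  refl <- calibrateReflectance(rc$raw, rc$refs)
  m1 <- buildMask(refl, 850, minArea = 25)
  binary <- maskCube(maskLabels(m1), nb = 3)
  m2 <- buildMask(binary, 850, minArea = 25, threshold = 0.5)
  expect_identical(maskLabels(m2), maskLabels(m1))
})

test_that("sample tables round-trip through CSV", {
  ds <- generateDataset(tinyConfig(n = 6, seed = 3),
                        keepPatches = FALSE)
  path <- file.path(withr::local_tempdir(), "samples.csv")
  writeSampleTable(ds$samples, path)
  back <- readSampleTable(path)
  expect_equal(spectraMatrix(back), spectraMatrix(ds$samples),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(concentrations(back), concentrations(ds$samples),
               ignore_attr = TRUE, tolerance = 1e-12)
})
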