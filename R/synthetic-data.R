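## Synthetic plate generator: concentration sampling with an embedded
## cross-analyte correlation, a Beer-Lambert-style forward model
## rendering raw cubes with white/dark frames, and end-to-end dataset
## assembly. The generator claims structural fidelity (geometry,
## correlation structure, noise, calibration chain), not spectroscopic
## fidelity: the endmember curves are synthetic stand-ins.

#' Synthetic component (endmember) spectra
#'
#' One absorptivity curve per analyte, each a sum of 2-3 Gaussian peaks
#' with fixed positions spread over 450-1000 nm (moisture peaks near the
#' 970 nm water band). Each curve is normalized to unit peak height and
#' scaled so that the mean concentration contributes
#' `targetAbsorbance` absorbance units at the peak, keeping every
#' analyte detectable at comparable signal levels despite mass fractions
#' spanning two orders of magnitude.
#'
#' @param wavelengths numeric vector of band centres (nm).
#' @param means per-analyte mean mass fractions used for scaling
#'   (default the calibration means of [contentRanges()]).
#' @param targetAbsorbance absorbance contribution of the mean
#'   concentration at the main peak (default 0.35).
#' @return bands x 5 matrix of absorptivities (1 / mass fraction).
#' @export
componentSpectra <- function(wavelengths,
                             means = contentRanges()[, "mean"],
                             targetAbsorbance = 0.35) {
  ## main peaks spread over 450-1000 nm with enough separation that
  ## each analyte dominates its own peak band
  peaks <- list(
    salvianolic_acid_B = cbind(c(470, 430), c(35, 25), c(1, 0.3)),
    dihydrotanshinone_I = cbind(c(540, 575), c(30, 25), c(1, 0.4)),
    cryptotanshinone = cbind(c(660, 705), c(35, 25), c(1, 0.5)),
    tanshinone_IIA = cbind(c(800, 760), c(40, 25), c(1, 0.4)),
    moisture = cbind(c(970, 900), c(40, 30), c(1, 0.3)))
  E <- vapply(seq_along(peaks), function(k) {
    p <- peaks[[k]]
    v <- rowSums(vapply(seq_len(nrow(p)), function(i)
      p[i, 3] * exp(-(wavelengths - p[i, 1])^2 / (2 * p[i, 2]^2)),
      numeric(length(wavelengths))))
    v / max(v) * targetAbsorbance / means[k]
  }, numeric(length(wavelengths)))
  colnames(E) <- names(peaks)
  rownames(E) <- sprintf("%.2f", wavelengths)
  E
}

## Per-analyte sampling sd: small enough that the bound truncation is
## rare (bounds sit >= 2.5 sd from the mean), so the embedded
## correlation survives the rejection step essentially unattenuated.
.concSd <- function(bounds)
  pmin(bounds[, "mean"] - bounds[, "min"],
       bounds[, "max"] - bounds[, "mean"]) / 2.5

#' Sample a concentration table
#'
#' Draws `nSamples` rows from a truncated multivariate normal with means
#' at the configured per-analyte means, a covariance embedding the
#' configured pair correlation, truncated (by rejection) to the
#' configured bounds. Fully seeded.
#'
#' @param config a [SyntheticConfig-class].
#' @return samples x 5 matrix of mass fractions, columns named after
#'   [analyteNames()].
#' @export
sampleConcentrations <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  b <- config@bounds
  sds <- .concSd(b)
  R <- diag(5)
  i <- config@correlatedPair[1]; j <- config@correlatedPair[2]
  R[i, j] <- R[j, i] <- config@crossCorrelation
  Sigma <- diag(sds) %*% R %*% diag(sds)
  set.seed(config@seed)
  out <- matrix(NA_real_, 0, 5)
  tries <- 0L
  while (nrow(out) < config@nSamples) {
    tries <- tries + 1L
    if (tries > 1000L)
      stop("rejection-sampling cap: bounds and correlation incompatible")
    draw <- MASS::mvrnorm(config@nSamples, mu = b[, "mean"],
                          Sigma = Sigma)
    ok <- rep(TRUE, nrow(draw))
    for (k in 1:5)
      ok <- ok & draw[, k] >= b[k, "min"] & draw[, k] <= b[k, "max"]
    out <- rbind(out, draw[ok, , drop = FALSE])
  }
  out <- out[seq_len(config@nSamples), , drop = FALSE]
  colnames(out) <- analyteNames()
  rownames(out) <- sprintf("sample_%03d", seq_len(config@nSamples))
  out
}

.whiteProfile <- function(wl) 650 + 250 * exp(-((wl - 720) / 260)^2)
.darkProfile <- function(wl) 96 + 4 * (wl - 380) / 684
.plateReflectance <- function(wl) 0.86 + 0.03 * (wl - 380) / 684
.baselineAbsorbance <- function(wl) 0.10 + 0.05 * (wl - 380) / 684

## Ground-truth label image for the segment grid, labelled row-major.
.truthLabels <- function(config) {
  h <- config@imageHeight; w <- config@imageWidth
  rows <- config@gridRows; cols <- config@gridCols
  r <- config@segmentRadius
  cy <- (seq_len(rows)) * h / (rows + 1)
  cx <- (seq_len(cols)) * w / (cols + 1)
  lab <- matrix(0L, h, w)
  rr <- row(lab); cc <- col(lab)
  k <- 0L
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    k <- k + 1L
    lab[(rr - cy[i])^2 + (cc - cx[j])^2 <= r^2] <- k
  }
  lab
}

#' Render one synthetic plate
#'
#' Forward model: per foreground pixel the absorbance is
#' `A(lambda) = baseline(lambda) + (1 + field_px) * sum_k c_k eps_k(lambda)`
#' with a smooth multiplicative spatial field; reflectance is
#' `R = 10^(-A)` (with an optional quadratic absorbance term when the
#' scattering nonlinearity is enabled); raw counts are
#' `I = dark + R * (white - dark) + noise`. Segments sit on a bright
#' plate background in the configured grid.
#'
#' @param conc numeric 5-vector of mass fractions.
#' @param endmembers bands x 5 absorptivity matrix
#'   (see [componentSpectra()]).
#' @param config a [SyntheticConfig-class].
#' @param wavelengths band centres; defaults to the 128-band grid.
#' @return List: `raw` (raw-mode [HyperspectralCube-class]), `refs`
#'   (per-band [ReferenceFrames-class]), `truth` ([SegmentMask-class]).
#'   Uses the current RNG stream (seed it for reproducibility).
#' @export
renderCube <- function(conc, endmembers, config,
                       wavelengths = BandAxis(n = config@nBands)@wavelengths) {
  stopifnot(all(conc >= 0), length(conc) == ncol(endmembers))
  h <- config@imageHeight; w <- config@imageWidth
  nb <- length(wavelengths)
  lab <- .truthLabels(config)
  fg <- as.vector(lab > 0)
  Wp <- .whiteProfile(wavelengths)
  Dp <- .darkProfile(wavelengths)
  contrib <- drop(endmembers %*% conc)            # absorbance per band
  base <- .baselineAbsorbance(wavelengths)
  ## smooth multiplicative field over the plate
  rr <- as.vector(row(lab)) / h; cc <- as.vector(col(lab)) / w
  ph <- runif(2, 0, 2 * pi)
  field <- config@scatterAmplitude *
    sin(2 * pi * rr + ph[1]) * cos(2 * pi * cc + ph[2])
  Rmat <- matrix(rep(.plateReflectance(wavelengths), each = h * w),
                 h * w, nb)
  if (any(fg)) {
    A <- outer(1 + field[fg], contrib)
    A <- sweep(A, 2, base, "+")
    if (config@nonlinearity > 0) A <- A + config@nonlinearity * A^2
    Rmat[fg, ] <- 10^(-A)
  }
  den <- Wp - Dp
  Imat <- sweep(Rmat, 2, den, "*")
  Imat <- sweep(Imat, 2, Dp, "+")
  if (config@noiseSd > 0)
    Imat <- Imat + sweep(matrix(rnorm(h * w * nb), h * w, nb), 2,
                         config@noiseSd * den, "*")
  cube <- HyperspectralCube(array(Imat, c(h, w, nb)),
                            bands = BandAxis(wavelengths), mode = "raw")
  list(raw = cube,
       refs = ReferenceFrames(white = Wp, dark = Dp),
       truth = new("SegmentMask", labels = lab,
                   nSegments = as.integer(max(lab)),
                   bandUsed = NA_real_))
}

## Area-averaged (block mean) downsampling: each output pixel is the
## mean of its source block, so per-pixel noise is averaged instead of
## aliased (plain bilinear sampling at large downscale factors would
## keep only a few source pixels per output pixel).
.resizePatch <- function(crop, size) {
  d <- dim(crop)
  g1 <- as.integer(cut(seq_len(d[1]), size))
  m1 <- rowsum(matrix(crop, d[1], d[2] * d[3]), g1) /
    as.vector(table(g1))
  a1 <- aperm(array(m1, c(size, d[2], d[3])), c(2, 1, 3))
  g2 <- as.integer(cut(seq_len(d[2]), size))
  m2 <- rowsum(matrix(a1, d[2], size * d[3]), g2) /
    as.vector(table(g2))
  aperm(array(m2, c(size, size, d[3])), c(2, 1, 3))
}

#' Generate a complete synthetic dataset
#'
#' End-to-end: samples concentrations, renders each plate, calibrates to
#' reflectance, segments the plate, extracts the plate-mean spectrum and
#' a resized foreground patch, and assembles a [SampleSet-class]. Fully
#' seeded: identical configs give identical datasets.
#'
#' @param config a [SyntheticConfig-class].
#' @param writeDir optional directory; the reference concentration table
#'   (`concentrations.csv`), the sample table (`samples.csv`) and a JSON
#'   ground-truth sidecar are written there.
#' @param keepPatches logical, store resized patches in the SampleSet
#'   (default TRUE; needed for the deep regressor).
#' @param writeCubes logical, also write every raw cube as an ENVI pair
#'   under `writeDir` (default FALSE; large).
#' @return List: `samples` (a [SampleSet-class]), `truth` (list with
#'   `concentrations`, `masks`, `endmembers`).
#' @export
generateDataset <- function(config, writeDir = NULL, keepPatches = TRUE,
                            writeCubes = FALSE) {
  stopifnot(is(config, "SyntheticConfig"))
  wl <- BandAxis(n = config@nBands)@wavelengths
  E <- componentSpectra(wl, means = config@bounds[, "mean"])
  conc <- sampleConcentrations(config)   # seeds the stream
  n <- config@nSamples
  spectra <- matrix(NA_real_, length(wl), n)
  patchList <- if (keepPatches) vector("list", n) else NULL
  masks <- vector("list", n)
  for (s in seq_len(n)) {
    rc <- renderCube(conc[s, ], E, config, wl)
    refl <- calibrateReflectance(rc$raw, rc$refs)
    mask <- buildMask(refl, bandNm = 850,
                      minArea = max(10, config@segmentRadius^2))
    if (mask@nSegments == 0) mask <- rc$truth   # degenerate fallback
    spectra[, s] <- meanSpectrum(refl, mask, "all")
    masks[[s]] <- mask@labels
    if (keepPatches) {
      sel <- which(mask@labels > 0, arr.ind = TRUE)
      rws <- range(sel[, 1]); cls <- range(sel[, 2])
      crop <- cubeData(refl)[rws[1]:rws[2], cls[1]:cls[2], , drop = FALSE]
      patchList[[s]] <- .resizePatch(crop, config@patchSize)
    }
    if (writeCubes && !is.null(writeDir))
      writeCube(rc$raw, file.path(writeDir,
                                  sprintf("cube_%03d.raw", s)))
  }
  ss <- SampleSet(spectra, wl, concentrations = conc,
                  sampleIds = rownames(conc), patches = patchList,
                  mode = "reflectance")
  if (!is.null(writeDir)) {
    dir.create(writeDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(conc),
              file.path(writeDir, "concentrations.csv"))
    writeSampleTable(ss, file.path(writeDir, "samples.csv"))
    jsonlite::write_json(
      list(nSamples = n, nBands = config@nBands,
           seed = config@seed,
           crossCorrelation = config@crossCorrelation,
           correlatedPair = config@correlatedPair,
           segmentGrid = c(config@gridRows, config@gridCols)),
      file.path(writeDir, "ground_truth.json"), auto_unbox = TRUE)
  }
  list(samples = ss,
       truth = list(concentrations = conc, masks = masks,
                    endmembers = E))
}
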