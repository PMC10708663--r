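#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats sd cor rnorm runif predict coef kmeans quantile median
#' @importFrom utils read.csv write.csv modifyList head tail
#' @exportMethod predict
NULL

## Analyte panel: four marker metabolites of Salvia miltiorrhiza plus
## moisture, all expressed as mass fractions.
.ANALYTES <- c("salvianolic_acid_B", "dihydrotanshinone_I",
               "cryptotanshinone", "tanshinone_IIA", "moisture")

#' Names of the five quality attributes
#'
#' The package quantifies four marker metabolites of *Salvia miltiorrhiza*
#' (salvianolic acid B, dihydrotanshinone I, cryptotanshinone,
#' tanshinone IIA) together with moisture content, all as mass fractions.
#'
#' @return Character vector of length 5.
#' @export
analyteNames <- function() .ANALYTES

#' Reference content ranges of the five quality attributes
#'
#' Calibration-set minimum, maximum and mean mass fraction for each
#' attribute, as determined by the reference assays (HPLC-DAD for the
#' metabolites, rapid moisture analysis for moisture). These ranges
#' parameterize the synthetic concentration sampler and the RER metric.
#'
#' @param set `"calibration"` (default) or `"test"`.
#' @return A 5 x 3 numeric matrix with columns `min`, `max`, `mean` and
#'   one row per analyte.
#' @export
contentRanges <- function(set = c("calibration", "test")) {
  set <- match.arg(set)
  cal <- cbind(min  = c(0.223, 0.001, 0.005, 0.009, 0.057),
               max  = c(2.064, 0.064, 0.184, 0.136, 0.085),
               mean = c(1.231, 0.007, 0.031, 0.053, 0.071))
  tst <- cbind(min  = c(0.333, 0.002, 0.008, 0.012, 0.059),
               max  = c(1.733, 0.014, 0.048, 0.083, 0.082),
               mean = c(1.118, 0.006, 0.027, 0.049, 0.069))
  out <- if (set == "calibration") cal else tst
  rownames(out) <- .ANALYTES
  out
}

## ---------------------------------------------------------------------------
## BandAxis

#' BandAxis: spectral band centres of a hyperspectral cube
#'
#' Holds the ordered band-centre wavelengths (nm), the nominal sampling
#' interval and the instrument spectral resolution. The default axis is the
#' camera grid used throughout the package: 128 bands from 380 nm at
#' 5.38 nm sampling (resolution 10 nm is metadata only; the data grid
#' follows the sampling interval).
#'
#' @slot wavelengths numeric, strictly increasing band centres in nm.
#' @slot samplingInterval numeric(1), nominal spacing in nm.
#' @slot resolution numeric(1), instrument spectral resolution in nm.
#' @exportClass BandAxis
setClass("BandAxis",
         representation(wavelengths = "numeric",
                        samplingInterval = "numeric",
                        resolution = "numeric"))

setValidity("BandAxis", function(object) {
  w <- object@wavelengths
  if (length(w) < 2) return("need at least 2 wavelengths")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  TRUE
})

#' Construct a BandAxis
#'
#' @param wavelengths numeric vector of band centres (nm). If missing, a
#'   linear grid `start + (0:(n-1)) * step` is built.
#' @param n number of bands for the linear grid (default 128).
#' @param start first band centre in nm (default 380).
#' @param step sampling interval in nm (default 5.38).
#' @param resolution instrument spectral resolution in nm (default 10).
#' @return A [BandAxis-class] object.
#' @examples
#' ax <- BandAxis()
#' length(wavelengths(ax))  # 128
#' @export
BandAxis <- function(wavelengths = NULL, n = 128L, start = 380,
                     step = 5.38, resolution = 10) {
  if (is.null(wavelengths))
    wavelengths <- start + (seq_len(n) - 1) * step
  new("BandAxis", wavelengths = as.numeric(wavelengths),
      samplingInterval = if (length(wavelengths) > 1)
        stats::median(diff(wavelengths)) else step,
      resolution = resolution)
}

#' @rdname BandAxis
#' @param x a `BandAxis` or `HyperspectralCube`.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname BandAxis
#' @export
setMethod("wavelengths", "BandAxis", function(x) x@wavelengths)

setMethod("show", "BandAxis", function(object) {
  w <- object@wavelengths
  cat(sprintf("BandAxis: %d bands, %.2f-%.2f nm (sampling %.2f nm, resolution %.1f nm)\n",
              length(w), min(w), max(w), object@samplingInterval,
              object@resolution))
})

## ---------------------------------------------------------------------------
## HyperspectralCube

#' HyperspectralCube: a spatial x spectral data cube
#'
#' A 3-D array indexed (row, col, band) holding raw detector counts,
#' relative reflectance or absorbance, together with its [BandAxis-class].
#' Row 0 of the acquisition is row 1 here (R is 1-based); coordinates are
#' (row, col) with row 1 at the image top.
#'
#' @slot data numeric 3-D array, dim = (height, width, bands).
#' @slot bands a [BandAxis-class].
#' @slot mode one of `"raw"`, `"reflectance"`, `"absorbance"`.
#' @exportClass HyperspectralCube
setClass("HyperspectralCube",
         representation(data = "array", bands = "BandAxis",
                        mode = "character"))

setValidity("HyperspectralCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-D array (row, col, band)")
  if (d[3] != length(object@bands@wavelengths))
    return(sprintf("band dimension (%d) != wavelength count (%d)",
                   d[3], length(object@bands@wavelengths)))
  if (!object@mode %in% c("raw", "reflectance", "absorbance"))
    return("mode must be raw, reflectance or absorbance")
  if (object@mode == "reflectance") {
    v <- object@data
    if (any(!is.finite(v)) || any(v < 0))
      return("reflectance values must be finite and >= 0")
  }
  TRUE
})

#' Construct a HyperspectralCube
#'
#' @param data 3-D numeric array (row, col, band).
#' @param bands a [BandAxis-class]; defaults to the 128-band camera grid
#'   when the band dimension is 128, otherwise a linear axis is built.
#' @param mode `"raw"`, `"reflectance"` or `"absorbance"`.
#' @return A [HyperspectralCube-class].
#' @export
HyperspectralCube <- function(data, bands = NULL, mode = "raw") {
  d <- dim(data)
  if (is.null(bands)) bands <- BandAxis(n = d[3])
  new("HyperspectralCube", data = data, bands = bands, mode = mode)
}

#' @rdname HyperspectralCube
#' @param x a `HyperspectralCube`.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))
#' @rdname HyperspectralCube
#' @export
setMethod("cubeData", "HyperspectralCube", function(x) x@data)

#' @rdname HyperspectralCube
#' @export
setGeneric("cubeMode", function(x) standardGeneric("cubeMode"))
#' @rdname HyperspectralCube
#' @export
setMethod("cubeMode", "HyperspectralCube", function(x) x@mode)

#' @rdname HyperspectralCube
#' @export
setMethod("wavelengths", "HyperspectralCube",
          function(x) x@bands@wavelengths)

#' @rdname HyperspectralCube
#' @export
setGeneric("bandAxis", function(x) standardGeneric("bandAxis"))
#' @rdname HyperspectralCube
#' @export
setMethod("bandAxis", "HyperspectralCube", function(x) x@bands)

setMethod("dim", "HyperspectralCube", function(x) dim(x@data))

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperspectralCube: %d x %d px, %d bands, mode=%s\n",
              d[1], d[2], d[3], object@mode))
  show(object@bands)
})

## ---------------------------------------------------------------------------
## ReferenceFrames

#' ReferenceFrames: white and dark calibration frames
#'
#' White-reference (whiteboard) and dark-current (lens cap) frames used to
#' convert raw counts to relative reflectance. Each frame is either a 3-D
#' array matching the cube shape or a per-band vector broadcast over all
#' pixels.
#'
#' @slot white numeric array or per-band vector.
#' @slot dark numeric array or per-band vector.
#' @exportClass ReferenceFrames
setClass("ReferenceFrames",
         representation(white = "ANY", dark = "ANY"))

#' @rdname ReferenceFrames-class
#' @param white,dark 3-D arrays (row, col, band) or numeric per-band vectors.
#' @return A [ReferenceFrames-class].
#' @export
ReferenceFrames <- function(white, dark) {
  new("ReferenceFrames", white = white, dark = dark)
}

setMethod("show", "ReferenceFrames", function(object) {
  fmt <- function(x) if (is.null(dim(x)))
    sprintf("per-band vector [%d]", length(x))
  else paste(dim(x), collapse = " x ")
  cat("ReferenceFrames: white", fmt(object@white),
      "| dark", fmt(object@dark), "\n")
})

## ---------------------------------------------------------------------------
## SegmentMask

#' SegmentMask: labelled foreground segments of a plate image
#'
#' @slot labels integer matrix; 0 = background, k = segment k. Labels are
#'   contiguous 1..nSegments in row-major discovery order.
#' @slot nSegments integer(1).
#' @slot bandUsed numeric(1), wavelength (nm) used for thresholding.
#' @exportClass SegmentMask
setClass("SegmentMask",
         representation(labels = "matrix", nSegments = "integer",
                        bandUsed = "numeric"))

setValidity("SegmentMask", function(object) {
  lab <- object@labels
  n <- object@nSegments
  u <- sort(unique(as.integer(lab[lab > 0])))
  if (n > 0 && !identical(u, seq_len(n)))
    return("labels must be contiguous 1..nSegments")
  if (n == 0 && length(u) > 0) return("nSegments = 0 but labels present")
  TRUE
})

#' @rdname SegmentMask-class
#' @param x a `SegmentMask`.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname SegmentMask-class
#' @export
setMethod("nSegments", "SegmentMask", function(x) x@nSegments)

#' @rdname SegmentMask-class
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname SegmentMask-class
#' @export
setMethod("maskLabels", "SegmentMask", function(x) x@labels)

setMethod("show", "SegmentMask", function(object) {
  cat(sprintf("SegmentMask: %d segments on %d x %d px (threshold band %.1f nm)\n",
              object@nSegments, nrow(object@labels), ncol(object@labels),
              object@bandUsed))
})

## ---------------------------------------------------------------------------
## SampleSet (SummarizedExperiment subclass)

#' SampleSet: per-sample mean spectra, concentrations and patches
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' `"spectra"` is a bands x samples matrix of mean spectra; `rowData`
#' carries the wavelength of each band, `colData` the five reference
#' concentrations per sample. Optional per-sample cube patches for the
#' deep regressor live in `metadata(x)$patches` (a list of
#' height x width x bands arrays).
#'
#' @exportClass SampleSet
setClass("SampleSet", contains = "SummarizedExperiment")

setValidity("SampleSet", function(object) {
  if (!"spectra" %in% SummarizedExperiment::assayNames(object))
    return("assay 'spectra' is required")
  cd <- SummarizedExperiment::colData(object)
  an <- intersect(.ANALYTES, colnames(cd))
  if (length(an) > 0) {
    conc <- as.matrix(as.data.frame(cd[, an, drop = FALSE]))
    if (any(conc < 0)) return("concentrations must be >= 0")
  }
  TRUE
})

#' Construct a SampleSet
#'
#' @param spectra bands x samples numeric matrix of mean spectra.
#' @param wavelengths numeric vector of band centres (nm).
#' @param concentrations optional samples x 5 matrix/data.frame of
#'   reference mass fractions (columns named after [analyteNames()]).
#' @param sampleIds optional character vector of sample identifiers.
#' @param patches optional list (one per sample) of cube patches
#'   (height x width x bands arrays).
#' @param mode spectral mode of the spectra (`"reflectance"` or
#'   `"absorbance"`).
#' @return A [SampleSet-class].
#' @export
SampleSet <- function(spectra, wavelengths,
                      concentrations = NULL, sampleIds = NULL,
                      patches = NULL, mode = "reflectance") {
  n <- ncol(spectra)
  if (is.null(sampleIds)) sampleIds <- sprintf("sample_%03d", seq_len(n))
  colnames(spectra) <- sampleIds
  rownames(spectra) <- sprintf("band_%.2fnm", wavelengths)
  cd <- S4Vectors::DataFrame(sample_id = sampleIds)
  if (!is.null(concentrations)) {
    conc <- as.data.frame(concentrations)
    colnames(conc) <- .ANALYTES[seq_len(ncol(conc))]
    cd <- cbind(cd, S4Vectors::DataFrame(conc))
  }
  rownames(cd) <- sampleIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = spectra),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths),
    colData = cd,
    metadata = list(patches = patches, mode = mode))
  new("SampleSet", se)
}

#' @rdname SampleSet
#' @param x a `SampleSet`.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))
#' @rdname SampleSet
#' @export
setMethod("spectraMatrix", "SampleSet", function(x)
  SummarizedExperiment::assay(x, "spectra"))

#' @rdname SampleSet
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
#' @rdname SampleSet
#' @export
setMethod("concentrations", "SampleSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  an <- intersect(.ANALYTES, colnames(cd))
  if (length(an) == 0) return(NULL)
  m <- as.matrix(as.data.frame(cd[, an, drop = FALSE]))
  rownames(m) <- cd$sample_id
  m
})

#' @rdname SampleSet
#' @export
setGeneric("patches", function(x) standardGeneric("patches"))
#' @rdname SampleSet
#' @export
setMethod("patches", "SampleSet", function(x)
  S4Vectors::metadata(x)$patches)

#' @rdname SampleSet
#' @export
setMethod("wavelengths", "SampleSet", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

## ---------------------------------------------------------------------------
## SelectionResult

#' SelectionResult: outcome of a wavelength-selection run
#'
#' @slot method `"CARS"`, `"SPA"` or `"UVE"`.
#' @slot selected integer vector of selected band indices (1-based,
#'   unique, within the band count).
#' @slot history per-iteration record (data.frame; content depends on the
#'   method: kept fraction and RMSECV for CARS, chain order for SPA,
#'   stability statistics for UVE).
#' @slot seed integer seed used for the stochastic parts.
#' @exportClass SelectionResult
setClass("SelectionResult",
         representation(method = "character", selected = "integer",
                        history = "data.frame", seed = "integer"))

setValidity("SelectionResult", function(object) {
  s <- object@selected
  if (anyDuplicated(s)) return("selected indices must be unique")
  if (length(s) && any(s < 1)) return("indices must be >= 1")
  TRUE
})

#' @rdname SelectionResult-class
#' @param x a `SelectionResult`.
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))
#' @rdname SelectionResult-class
#' @export
setMethod("selectedBands", "SelectionResult", function(x) x@selected)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d bands selected (seed %d)\n",
              object@method, length(object@selected), object@seed))
})

## ---------------------------------------------------------------------------
## ArchitectureSpec / TrainConfig

#' ArchitectureSpec: declarative description of the SE-ResNet regressor
#'
#' The network is a residual network with squeeze-and-excitation (SE)
#' channel recalibration in every bottleneck block: a 7x7/stride-2 stem
#' convolution with batch normalization, a 3x3/stride-2 max-pool, four
#' SE-residual stages, global average pooling and a two-layer fully
#' connected head ending in one output per analyte. The reference profile
#' uses stage block counts (3, 4, 23, 3), stage widths
#' (256, 512, 1024, 2048) and a 2048 -> 256 -> 5 head.
#'
#' @slot stemChannels integer(1), stem output channels.
#' @slot stemKernel,stemStride,stemPad integer(1) stem convolution geometry.
#' @slot poolKernel,poolStride,poolPad integer(1) max-pool geometry. The
#'   instrument-software description prints pool padding 3; a 3x3 window
#'   with padding 3 is geometrically degenerate, so the default is the
#'   standard padding 1 (override via `poolPad`).
#' @slot stageBlocks integer(4), SE-residual blocks per stage.
#' @slot stageChannels integer(4), output channels per stage.
#' @slot reduction integer(1), SE bottleneck reduction ratio.
#' @slot headWidths integer vector, fully connected widths; the last entry
#'   is the number of analytes.
#' @slot inputShape integer(3): patch height, width, spectral channels.
#' @exportClass ArchitectureSpec
setClass("ArchitectureSpec",
         representation(stemChannels = "integer", stemKernel = "integer",
                        stemStride = "integer", stemPad = "integer",
                        poolKernel = "integer", poolStride = "integer",
                        poolPad = "integer",
                        stageBlocks = "integer", stageChannels = "integer",
                        reduction = "integer", headWidths = "integer",
                        inputShape = "integer"))

setValidity("ArchitectureSpec", function(object) {
  if (length(object@stageBlocks) != 4) return("stageBlocks must have 4 entries")
  if (length(object@stageChannels) != 4) return("stageChannels must have 4 entries")
  if (any(object@stageChannels %% object@reduction != 0))
    return("reduction must divide every stage channel count")
  if (object@headWidths[1] != object@stageChannels[4])
    return("head input width must equal the final stage channel count")
  TRUE
})

#' Construct an ArchitectureSpec
#'
#' @param stageBlocks integer(4), blocks per SE-residual stage
#'   (default `c(3, 4, 23, 3)`).
#' @param stageChannels integer(4), output channels per stage
#'   (default `c(256, 512, 1024, 2048)`).
#' @param stemChannels stem output channels (default 64).
#' @param reduction SE reduction ratio (default 16).
#' @param headWidths fully connected widths including the output layer
#'   (default `c(2048, 256, 5)`).
#' @param inputShape integer(3): input patch height, width and spectral
#'   channel count (default `c(64, 64, 128)`).
#' @param poolPad max-pool padding (default 1; see
#'   [ArchitectureSpec-class]).
#' @return An [ArchitectureSpec-class].
#' @examples
#' spec <- ArchitectureSpec()
#' sum(spec@stageBlocks)  # 33 SE-residual blocks
#' @export
ArchitectureSpec <- function(stageBlocks = c(3L, 4L, 23L, 3L),
                             stageChannels = c(256L, 512L, 1024L, 2048L),
                             stemChannels = 64L, reduction = 16L,
                             headWidths = c(2048L, 256L, 5L),
                             inputShape = c(64L, 64L, 128L),
                             poolPad = 1L) {
  new("ArchitectureSpec",
      stemChannels = as.integer(stemChannels), stemKernel = 7L,
      stemStride = 2L, stemPad = 3L,
      poolKernel = 3L, poolStride = 2L, poolPad = as.integer(poolPad),
      stageBlocks = as.integer(stageBlocks),
      stageChannels = as.integer(stageChannels),
      reduction = as.integer(reduction),
      headWidths = as.integer(headWidths),
      inputShape = as.integer(inputShape))
}

#' Desk-scale ArchitectureSpec
#'
#' A reduced-depth profile (stage blocks 1,1,2,1; stage widths
#' 64/128/256/512; 8x8 input patches) for CPU-scale experiments and the
#' package's simulation studies. The regression head is 512 -> 64 -> 5.
#'
#' @param inputShape integer(3), default `c(8, 8, 128)`.
#' @return An [ArchitectureSpec-class].
#' @export
deskArchitectureSpec <- function(inputShape = c(8L, 8L, 128L)) {
  ArchitectureSpec(stageBlocks = c(1L, 1L, 2L, 1L),
                   stageChannels = c(64L, 128L, 256L, 512L),
                   stemChannels = 32L, reduction = 16L,
                   headWidths = c(512L, 64L, 5L),
                   inputShape = as.integer(inputShape))
}

setMethod("show", "ArchitectureSpec", function(object) {
  cat("ArchitectureSpec\n")
  cat(sprintf("  stem: %dx%d/%d pad %d -> %d ch; maxpool %dx%d/%d pad %d\n",
              object@stemKernel, object@stemKernel, object@stemStride,
              object@stemPad, object@stemChannels, object@poolKernel,
              object@poolKernel, object@poolStride, object@poolPad))
  cat(sprintf("  stages: blocks (%s), channels (%s), SE reduction %d\n",
              paste(object@stageBlocks, collapse = ","),
              paste(object@stageChannels, collapse = ","),
              object@reduction))
  cat(sprintf("  head: %s; input %s\n",
              paste(object@headWidths, collapse = " -> "),
              paste(object@inputShape, collapse = " x ")))
})

#' TrainConfig: training protocol for the SE-ResNet regressor
#'
#' @slot loss character, loss name (`"mse"` on z-scored targets).
#' @slot optimizer character (`"adam"`).
#' @slot learningRate numeric(1), initial Adam step size.
#' @slot lrSchedule `"cosine"` (default; the rate anneals to ~0 over the
#'   epochs, which settles the final minimization) or `"constant"`.
#' @slot epochs integer(1).
#' @slot batchSize integer(1).
#' @slot seed integer(1); fixes initialization and batch shuffling.
#' @slot augNoise numeric(1), sd of Gaussian noise added to the
#'   (normalized) input patches each step — a regularizer against
#'   memorizing per-sample noise (0 disables).
#' @slot weightDecay numeric(1), decoupled weight decay applied to
#'   convolution/dense weight matrices (not biases or batch-norm
#'   parameters).
#' @slot valFraction numeric(1), fraction of records held out for
#'   early-stopping monitoring (0 disables).
#' @slot patience integer(1), early-stopping patience in epochs
#'   (ignored when valFraction = 0).
#' @exportClass TrainConfig
setClass("TrainConfig",
         representation(loss = "character", optimizer = "character",
                        learningRate = "numeric", lrSchedule = "character",
                        epochs = "integer",
                        batchSize = "integer", seed = "integer",
                        augNoise = "numeric", weightDecay = "numeric",
                        valFraction = "numeric", patience = "integer"))

#' @rdname TrainConfig-class
#' @param learningRate,lrSchedule,epochs,batchSize,seed,augNoise,weightDecay,valFraction,patience
#'   see slots.
#' @return A [TrainConfig-class].
#' @export
TrainConfig <- function(learningRate = 2e-3, epochs = 120L,
                        batchSize = 32L, seed = 1L,
                        lrSchedule = c("cosine", "constant"),
                        augNoise = 0, weightDecay = 0,
                        valFraction = 0, patience = 20L) {
  stopifnot(epochs >= 1)
  new("TrainConfig", loss = "mse", optimizer = "adam",
      learningRate = learningRate,
      lrSchedule = match.arg(lrSchedule), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      augNoise = augNoise, weightDecay = weightDecay,
      valFraction = valFraction, patience = as.integer(patience))
}

## ---------------------------------------------------------------------------
## SyntheticConfig

#' SyntheticConfig: parameters of the synthetic plate generator
#'
#' Controls the forward model used to render synthetic hyperspectral
#' plates: number of samples, per-analyte concentration bounds and means
#' (defaulting to the reference calibration ranges, see [contentRanges()]),
#' the embedded cross-analyte correlation (default 0.64 between
#' cryptotanshinone and tanshinone IIA), reflectance noise, plate geometry
#' (a 5-row x 6-column grid of circular segments) and the RNG seed.
#'
#' @slot nSamples integer(1).
#' @slot bounds 5 x 3 matrix (`min`, `max`, `mean`) of mass fractions.
#' @slot crossCorrelation numeric(1) in (-1, 1).
#' @slot correlatedPair integer(2), analyte indices sharing the
#'   correlation.
#' @slot noiseSd numeric(1), sd of additive reflectance noise.
#' @slot scatterAmplitude numeric(1), amplitude of the multiplicative
#'   spatial scattering field (0 disables).
#' @slot nonlinearity numeric(1), strength of the optional multiplicative
#'   scattering nonlinearity emulating the non-bilinear reflectance
#'   regime (0 = off, linear in absorbance).
#' @slot gridRows,gridCols integer(1), segment grid layout.
#' @slot segmentRadius integer(1), segment radius in px.
#' @slot imageHeight,imageWidth integer(1), plate image size in px.
#' @slot patchSize integer(1), spatial size of the resized cube patch
#'   stored per sample for the deep regressor.
#' @slot nBands integer(1), spectral bands.
#' @slot seed integer(1).
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
         representation(nSamples = "integer", bounds = "matrix",
                        crossCorrelation = "numeric",
                        correlatedPair = "integer",
                        noiseSd = "numeric", scatterAmplitude = "numeric",
                        nonlinearity = "numeric",
                        gridRows = "integer", gridCols = "integer",
                        segmentRadius = "integer",
                        imageHeight = "integer", imageWidth = "integer",
                        patchSize = "integer", nBands = "integer",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  b <- object@bounds
  if (any(b[, "min"] >= b[, "max"])) return("bounds must satisfy min < max")
  if (abs(object@crossCorrelation) >= 1)
    return("|crossCorrelation| must be < 1")
  if (object@nSamples < 5) return("nSamples must be >= 5")
  TRUE
})

#' Construct a SyntheticConfig
#'
#' @param nSamples number of plates/samples (default 187).
#' @param bounds 5 x 3 matrix of per-analyte `min`, `max`, `mean`
#'   (default [contentRanges()]).
#' @param crossCorrelation embedded Pearson correlation between the
#'   analytes in `correlatedPair` (default 0.64).
#' @param correlatedPair analyte index pair (default cryptotanshinone and
#'   tanshinone IIA, i.e. `c(3, 4)`).
#' @param noiseSd reflectance noise sd (default 0.01).
#' @param scatterAmplitude multiplicative spatial field amplitude
#'   (default 0.05).
#' @param nonlinearity optional scattering nonlinearity strength
#'   (default 0, linear in absorbance).
#' @param gridRows,gridCols segment layout (default 5 x 6).
#' @param segmentRadius segment radius in px (default 5).
#' @param imageHeight,imageWidth plate size in px (default 80 x 96; a
#'   down-scaled rendering of the acquisition geometry — pass 703 x 800
#'   with radius ~45 for full scale).
#' @param patchSize resized patch edge length for the deep model
#'   (default 8; the bilinear resize also averages away most per-pixel
#'   noise).
#' @param nBands spectral bands (default 128).
#' @param seed RNG seed (default 1).
#' @return A [SyntheticConfig-class].
#' @export
SyntheticConfig <- function(nSamples = 187L, bounds = contentRanges(),
                            crossCorrelation = 0.64,
                            correlatedPair = c(3L, 4L),
                            noiseSd = 0.01, scatterAmplitude = 0.05,
                            nonlinearity = 0,
                            gridRows = 5L, gridCols = 6L,
                            segmentRadius = 5L,
                            imageHeight = 80L, imageWidth = 96L,
                            patchSize = 8L, nBands = 128L, seed = 1L) {
  new("SyntheticConfig", nSamples = as.integer(nSamples), bounds = bounds,
      crossCorrelation = crossCorrelation,
      correlatedPair = as.integer(correlatedPair),
      noiseSd = noiseSd, scatterAmplitude = scatterAmplitude,
      nonlinearity = nonlinearity,
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      segmentRadius = as.integer(segmentRadius),
      imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth),
      patchSize = as.integer(patchSize), nBands = as.integer(nBands),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d samples, %d bands, plate %dx%d px, ",
                     "%dx%d segments (r=%d px)\n"),
              object@nSamples, object@nBands, object@imageHeight,
              object@imageWidth, object@gridRows, object@gridCols,
              object@segmentRadius))
  cat(sprintf("  correlation %.2f between analytes %d and %d; noise sd %.3g; seed %d\n",
              object@crossCorrelation, object@correlatedPair[1],
              object@correlatedPair[2], object@noiseSd, object@seed))
})

## ---------------------------------------------------------------------------
## MetricsReport

#' MetricsReport: per-analyte calibration and prediction metrics
#'
#' One row per analyte with RMSEC/RMSECV/RMSEP, Rc2/Rcv2/Rp2, RPD (with
#' its qualitative category) and RER, mirroring the standard comparison
#' table layout of multivariate calibration studies.
#'
#' @slot table data.frame, one row per analyte.
#' @slot model character, model label.
#' @exportClass MetricsReport
setClass("MetricsReport",
         representation(table = "data.frame", model = "character"))

#' @rdname MetricsReport-class
#' @param x a `MetricsReport`.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
#' @rdname MetricsReport-class
#' @export
setMethod("metricsTable", "MetricsReport", function(x) x@table)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s)\n", object@model))
  print(object@table, digits = 4, row.names = FALSE)
})
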