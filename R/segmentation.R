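## Foreground segmentation of plate images and mean-spectrum extraction.

## Relabel a label matrix so labels are contiguous 1..n in row-major
## discovery order (row 1 at the top, scanning left to right).
.relabelRowMajor <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(list(labels = lab, n = 0L))
  h <- nrow(lab); w <- ncol(lab)
  rowIdx <- row(lab); colIdx <- col(lab)
  firstSeen <- vapply(ids, function(k) {
    sel <- lab == k
    min((rowIdx[sel] - 1) * w + colIdx[sel])
  }, numeric(1))
  ord <- ids[order(firstSeen)]
  out <- matrix(0L, h, w)
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  list(labels = out, n = length(ord))
}

#' Build a foreground mask for plant segments on the plate
#'
#' Thresholds the band nearest `bandNm` (plant tissue is darker than the
#' bright plate, so foreground = below threshold), applies a binary
#' opening to suppress speckle, labels connected components, and drops
#' components smaller than `minArea` pixels. The threshold defaults to
#' Otsu's method on the chosen band; pass `threshold` for a fixed cut.
#' Labels are contiguous `1..nSegments` in row-major discovery order.
#'
#' @param cube a reflectance-mode [HyperspectralCube-class].
#' @param bandNm wavelength (nm) used for thresholding; default 850
#'   (NIR, where tissue/plate contrast is strongest).
#' @param minArea minimum component area in px (default 50).
#' @param threshold optional fixed reflectance threshold overriding Otsu.
#' @param opening size of the square opening structuring element
#'   (default 3; 0 disables).
#' @return A [SegmentMask-class]. A cube with no foreground yields
#'   `nSegments = 0` with a warning.
#' @export
buildMask <- function(cube, bandNm = 850, minArea = 50, threshold = NULL,
                      opening = 3) {
  stopifnot(is(cube, "HyperspectralCube"))
  if (cube@mode != "reflectance")
    stop("buildMask expects a reflectance-mode cube")
  wl <- cube@bands@wavelengths
  if (bandNm < min(wl) - 50 || bandNm > max(wl) + 50)
    stop("bandNm outside the band axis range")
  bi <- which.min(abs(wl - bandNm))
  img <- cube@data[, , bi]
  if (is.null(threshold)) {
    rng <- range(img)
    if (diff(rng) < 1e-12) {
      ## constant frame: treat everything as foreground
      fg <- matrix(TRUE, nrow(img), ncol(img))
    } else {
      sc <- (img - rng[1]) / diff(rng)
      th <- EBImage::otsu(EBImage::Image(sc))
      fg <- sc < th
    }
  } else {
    fg <- img < threshold
  }
  if (opening >= 2 && any(fg) && !all(fg)) {
    brush <- EBImage::makeBrush(opening, shape = "box")
    fg <- EBImage::opening(fg * 1, brush) > 0.5
  }
  if (!any(fg)) {
    warning("empty mask: no foreground pixels")
    return(new("SegmentMask", labels = matrix(0L, nrow(img), ncol(img)),
               nSegments = 0L, bandUsed = wl[bi]))
  }
  lab <- EBImage::bwlabel(fg * 1)
  lab <- matrix(as.integer(round(lab)), nrow(img), ncol(img))
  if (minArea > 1) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= minArea)
    lab[!(lab %in% keep)] <- 0L
  }
  rl <- .relabelRowMajor(lab)
  if (rl$n == 0) warning("empty mask: all components below minArea")
  new("SegmentMask", labels = rl$labels, nSegments = as.integer(rl$n),
      bandUsed = wl[bi])
}

#' Mean spectrum over a segment (or all foreground)
#'
#' Arithmetic mean over the masked pixels, per band.
#'
#' @param cube a [HyperspectralCube-class].
#' @param mask a [SegmentMask-class] matching the cube's spatial size.
#' @param segment a segment id, or `"all"` for the union of all
#'   foreground pixels.
#' @return Numeric vector over bands, named by wavelength.
#' @export
meanSpectrum <- function(cube, mask, segment = "all") {
  stopifnot(is(cube, "HyperspectralCube"), is(mask, "SegmentMask"))
  d <- dim(cube@data)
  if (!all(dim(mask@labels) == d[1:2]))
    stop("mask and cube spatial sizes differ")
  sel <- if (identical(segment, "all")) mask@labels > 0
  else mask@labels == as.integer(segment)
  if (!any(sel)) stop("empty selection: segment ", segment,
                      " has no pixels")
  m <- matrix(cube@data, d[1] * d[2], d[3])
  sp <- colMeans(m[as.vector(sel), , drop = FALSE])
  names(sp) <- sprintf("%.2f", cube@bands@wavelengths)
  sp
}

#' Per-segment mean spectra
#'
#' @param cube a [HyperspectralCube-class].
#' @param mask a [SegmentMask-class].
#' @return bands x segments matrix of mean spectra.
#' @export
segmentSpectra <- function(cube, mask) {
  stopifnot(mask@nSegments >= 1)
  vapply(seq_len(mask@nSegments),
         function(k) meanSpectrum(cube, mask, k),
         numeric(dim(cube@data)[3]))
}

#' Write / read a sample table (spectra + concentrations) as CSV
#'
#' Columns: `sample_id`, one column per analyte, then one column per band
#' named by wavelength (`band_<nm>`).
#'
#' @param x a [SampleSet-class].
#' @param path CSV path.
#' @return `path` invisibly (`writeSampleTable`); a [SampleSet-class]
#'   (`readSampleTable`).
#' @export
writeSampleTable <- function(x, path) {
  sp <- t(spectraMatrix(x))
  colnames(sp) <- sprintf("band_%.2f", wavelengths(x))
  conc <- concentrations(x)
  df <- data.frame(sample_id = colnames(spectraMatrix(x)),
                   check.names = FALSE)
  if (!is.null(conc)) df <- cbind(df, as.data.frame(conc))
  df <- cbind(df, as.data.frame(sp))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleTable
#' @export
readSampleTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  bandCols <- grep("^band_", colnames(df), value = TRUE)
  wl <- as.numeric(sub("^band_", "", bandCols))
  analytes <- intersect(analyteNames(), colnames(df))
  SampleSet(spectra = t(as.matrix(df[, bandCols])), wavelengths = wl,
            concentrations = if (length(analytes))
              as.matrix(df[, analytes]) else NULL,
            sampleIds = as.character(df$sample_id))
}
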