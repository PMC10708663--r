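## Radiometric core: ENVI I/O, reflectance calibration, absorbance.

.ENVI_DTYPES <- list(`4` = list(what = "numeric", size = 4L),
                     `5` = list(what = "numeric", size = 8L),
                     `12` = list(what = "integer", size = 2L))

.dtypeForMode <- function(mode) switch(mode, raw = 12L, 4L)

#' Write a HyperspectralCube as an ENVI raster
#'
#' Writes a band-sequential (BSQ), little-endian binary at `path` and a
#' text header at `<path>.hdr` carrying geometry, wavelengths (nm) and the
#' cube mode. Raw cubes are stored as unsigned 16-bit integers, calibrated
#' cubes as 32-bit floats (override via `dtype`; use 5 for 64-bit floats).
#'
#' @param cube a [HyperspectralCube-class].
#' @param path data-file path (header written alongside as `<path>.hdr`).
#' @param dtype ENVI data-type code: 4 (float32), 5 (float64) or
#'   12 (uint16). Default depends on `cube` mode.
#' @return `path`, invisibly.
#' @export
writeCube <- function(cube, path, dtype = NULL) {
  stopifnot(is(cube, "HyperspectralCube"))
  d <- dim(cube@data)
  if (is.null(dtype)) dtype <- .dtypeForMode(cube@mode)
  dtype <- as.integer(dtype)
  spec <- .ENVI_DTYPES[[as.character(dtype)]]
  if (is.null(spec)) stop("unsupported ENVI data type: ", dtype)
  hdr <- c("ENVI",
           "file type = ENVI Standard",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           sprintf("data type = %d", dtype),
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           sprintf("mode = %s", cube@mode),
           sprintf("sampling interval = %.6g", cube@bands@samplingInterval),
           sprintf("spectral resolution = %.6g", cube@bands@resolution),
           sprintf("wavelength = { %s }",
                   paste(format(cube@bands@wavelengths, trim = TRUE,
                                digits = 10), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    plane <- t(cube@data[, , b])          # BSQ: samples vary fastest
    if (spec$what == "integer") {
      v <- as.integer(round(plane))
      if (any(v < 0 | v > 65535)) stop("uint16 overflow while writing raw cube")
      writeBin(v, con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(plane), con, size = spec$size, endian = "little")
    }
  }
  invisible(path)
}

.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("malformed header: missing ENVI magic")
  getField <- function(name, required = TRUE) {
    m <- regmatches(txt, regexpr(
      paste0("(?mi)^", name, "\\s*=\\s*([^\\n{]+)$"), txt, perl = TRUE))
    if (length(m) == 0) {
      if (required) stop("malformed header: missing field '", name, "'")
      return(NULL)
    }
    trimws(sub(paste0("(?i)^", name, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  wl <- regmatches(txt, regexpr("(?si)wavelength\\s*=\\s*\\{[^}]*\\}",
                                txt, perl = TRUE))
  wavelengths <- NULL
  if (length(wl)) {
    nums <- gsub("(?si).*\\{|\\}.*", "", wl, perl = TRUE)
    wavelengths <- as.numeric(strsplit(nums, "[,\\s]+")[[1]] |>
                                (\(x) x[nzchar(x)])())
  }
  list(samples = as.integer(getField("samples")),
       lines = as.integer(getField("lines")),
       bands = as.integer(getField("bands")),
       dtype = as.integer(getField("data type")),
       interleave = tolower(getField("interleave")),
       mode = getField("mode", required = FALSE) %||% "raw",
       sampling = as.numeric(getField("sampling interval",
                                      required = FALSE) %||% NA),
       resolution = as.numeric(getField("spectral resolution",
                                        required = FALSE) %||% 10),
       wavelengths = wavelengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a HyperspectralCube from an ENVI raster
#'
#' @param path data-file path; the header is looked up at `<path>.hdr`.
#' @param dialect format tag; only `"envi"` is supported.
#' @return A [HyperspectralCube-class] with populated band axis; `mode`
#'   is taken from the header, defaulting to `"raw"`.
#' @export
readCube <- function(path, dialect = "envi") {
  dialect <- match.arg(dialect, "envi")
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(path)) stop("cube file not found: ", path)
  if (!file.exists(hdrPath)) stop("header not found: ", hdrPath)
  h <- .parseEnviHeader(hdrPath)
  if (h$interleave != "bsq") stop("unsupported interleave: ", h$interleave)
  spec <- .ENVI_DTYPES[[as.character(h$dtype)]]
  if (is.null(spec)) stop("unsupported ENVI data type: ", h$dtype)
  if (!is.null(h$wavelengths) && length(h$wavelengths) != h$bands)
    stop("consistency error: header declares ", h$bands,
         " bands but lists ", length(h$wavelengths), " wavelengths")
  nval <- h$samples * h$lines * h$bands
  expectBytes <- nval * spec$size
  if (file.info(path)$size != expectBytes)
    stop("consistency error: expected ", expectBytes, " bytes (",
         h$bands, " bands) but file holds ", file.info(path)$size)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- if (spec$what == "integer")
    readBin(con, integer(), n = nval, size = 2L, signed = FALSE,
            endian = "little")
  else readBin(con, numeric(), n = nval, size = spec$size,
               endian = "little")
  ## BSQ, samples fastest: dims read back as (samples, lines, bands)
  arr <- aperm(array(as.numeric(raw), c(h$samples, h$lines, h$bands)),
               c(2, 1, 3))
  bands <- if (!is.null(h$wavelengths))
    BandAxis(h$wavelengths, resolution = h$resolution)
  else BandAxis(n = h$bands)
  HyperspectralCube(arr, bands = bands, mode = h$mode)
}

.broadcastRef <- function(ref, dims, what) {
  if (is.null(dim(ref))) {
    if (length(ref) != dims[3])
      stop(what, " frame: per-band vector length ", length(ref),
           " does not match ", dims[3], " bands")
    return(array(rep(ref, each = dims[1] * dims[2]), dims))
  }
  if (length(dim(ref)) == 3 && all(dim(ref) == dims)) return(ref)
  stop(what, " frame shape is not broadcastable against the cube")
}

#' Calibrate raw counts to relative reflectance
#'
#' Applies the standard white/dark two-point calibration
#' `R = (I - dark) / (white - dark)` element-wise; the denominator is
#' floored at `epsilon` and the result clipped to `clip` to tolerate
#' specular pixels.
#'
#' @param raw a raw-mode [HyperspectralCube-class].
#' @param refs a [ReferenceFrames-class] (3-D frames or per-band vectors).
#' @param epsilon denominator floor (default 1e-6).
#' @param clip length-2 output clip range (default `c(0, 1.5)`).
#' @return A reflectance-mode [HyperspectralCube-class].
#' @examples
#' cube <- HyperspectralCube(array(50, c(2, 2, 3)), BandAxis(n = 3))
#' refs <- ReferenceFrames(white = rep(90, 3), dark = rep(10, 3))
#' range(cubeData(calibrateReflectance(cube, refs)))  # 0.5
#' @export
calibrateReflectance <- function(raw, refs, epsilon = 1e-6,
                                 clip = c(0, 1.5)) {
  stopifnot(is(raw, "HyperspectralCube"), is(refs, "ReferenceFrames"))
  if (raw@mode != "raw")
    stop("mode error: calibrateReflectance expects a raw-mode cube, got ",
         raw@mode)
  dims <- dim(raw@data)
  W <- .broadcastRef(refs@white, dims, "white")
  D <- .broadcastRef(refs@dark, dims, "dark")
  den <- W - D
  if (any(den <= 0))
    stop("calibration error: white <= dark at ", sum(den <= 0), " positions")
  R <- (raw@data - D) / pmax(den, epsilon)
  R <- pmin(pmax(R, clip[1]), clip[2])
  new("HyperspectralCube", data = R, bands = raw@bands,
      mode = "reflectance")
}

#' Convert reflectance to absorbance
#'
#' `A = log10(1 / max(R, floor))`; the floor avoids infinities at
#' near-zero reflectance.
#'
#' @param refl a reflectance-mode [HyperspectralCube-class].
#' @param floor reflectance floor before the log (default 1e-4).
#' @return An absorbance-mode [HyperspectralCube-class].
#' @export
toAbsorbance <- function(refl, floor = 1e-4) {
  stopifnot(is(refl, "HyperspectralCube"))
  if (refl@mode != "reflectance")
    stop("mode error: toAbsorbance expects a reflectance cube, got ",
         refl@mode)
  A <- log10(1 / pmax(refl@data, floor))
  new("HyperspectralCube", data = A, bands = refl@bands,
      mode = "absorbance")
}
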