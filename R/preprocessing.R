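## Spectral preprocessing: Savitzky-Golay filtering, standardization,
## and declarative preprocessing chains.

#' Savitzky-Golay filtering of a spectrum
#'
#' Local least-squares polynomial smoothing / differentiation. Length is
#' preserved; edges use the off-centre rows of the projection matrix,
#' i.e. polynomial extrapolation, so polynomials up to `polyorder` are
#' reproduced (or differentiated) exactly everywhere.
#'
#' @param x numeric vector (one spectrum) or samples x bands matrix
#'   (filtered along bands).
#' @param window odd window length > `polyorder` (default 11).
#' @param polyorder polynomial order (default 2).
#' @param derivOrder derivative order, `<= polyorder` (default 0).
#' @param delta band spacing used to scale derivatives (default 1).
#' @return Filtered vector/matrix of the same shape.
#' @export
sgFilter <- function(x, window = 11, polyorder = 2, derivOrder = 0,
                     delta = 1) {
  if (window %% 2 != 1 || window <= polyorder)
    stop("parameter error: window must be odd and > polyorder")
  if (derivOrder > polyorder)
    stop("parameter error: derivOrder must be <= polyorder")
  f <- function(v) signal::sgolayfilt(v, p = polyorder, n = window,
                                      m = derivOrder, ts = delta)
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

#' Column-wise standardization with reusable statistics
#'
#' Centres each column to zero mean and scales to unit sample (n-1)
#' standard deviation. Fitted statistics can be re-applied to new data
#' (and inverted).
#'
#' @param x samples x variables matrix.
#' @param stats optional fitted statistics (list with `center`, `scale`)
#'   from a previous call; when supplied they are applied instead of
#'   refitted.
#' @param epsilon floor for zero-variance scales (default 1e-12; floored
#'   columns trigger a warning).
#' @return List with `x` (standardized matrix) and `stats`.
#' @export
standardize <- function(x, stats = NULL, epsilon = 1e-12) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    if (nrow(x) < 2) stop("need >= 2 samples to fit standardization")
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    if (any(scale < epsilon)) {
      warning(sum(scale < epsilon), " zero-variance column(s); scale floored")
      scale <- pmax(scale, epsilon)
    }
    stats <- list(center = center, scale = scale)
  }
  z <- sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
  list(x = z, stats = stats)
}

#' Invert a fitted standardization
#'
#' @param z standardized matrix.
#' @param stats statistics from [standardize()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(z, stats) {
  sweep(sweep(as.matrix(z), 2, stats$scale, "*"), 2, stats$center, "+")
}

#' Declarative preprocessing chain
#'
#' A `PreprocSpec` is an ordered list of steps applied to a
#' samples x bands matrix of reflectance spectra. Supported steps:
#' `sg_smooth(window, polyorder)`, `sg_derivative(window, polyorder,
#' deriv)`, `absorbance`, `standardize`. The default chain is empty:
#' with these data, raw spectra feed the calibration models unless
#' preprocessing is explicitly requested.
#'
#' @param steps list of steps; each step is a character name or a named
#'   list `list(name = "sg_smooth", window = 11, polyorder = 2)`.
#' @return An object of class `PreprocSpec`.
#' @export
preprocSpec <- function(steps = list()) {
  norm <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(name = s)
    s$name <- match.arg(s$name, c("sg_smooth", "sg_derivative",
                                  "absorbance", "standardize"))
    if (s$name %in% c("sg_smooth", "sg_derivative")) {
      s$window <- s$window %||% 11
      s$polyorder <- s$polyorder %||% 2
      s$deriv <- if (s$name == "sg_derivative") s$deriv %||% 1 else 0
      if (s$window %% 2 != 1 || s$window <= s$polyorder)
        stop("parameter error: window must be odd and > polyorder")
      if (s$deriv > s$polyorder)
        stop("parameter error: deriv must be <= polyorder")
    }
    s
  })
  structure(list(steps = norm), class = "PreprocSpec")
}

#' Apply a preprocessing chain
#'
#' @param x samples x bands matrix (reflectance unless the chain starts
#'   elsewhere).
#' @param spec a [preprocSpec()].
#' @param stats optional fitted statistics (from a previous call) for the
#'   `standardize` step, so test data reuse calibration statistics.
#' @param delta band spacing for derivative scaling (default 1).
#' @return List with `x` (processed matrix) and `stats` (fitted
#'   standardization statistics, if any).
#' @export
applyPreproc <- function(x, spec, stats = NULL, delta = 1) {
  stopifnot(inherits(spec, "PreprocSpec"))
  x <- as.matrix(x)
  outStats <- stats
  for (s in spec$steps) {
    x <- switch(s$name,
      sg_smooth = sgFilter(x, s$window, s$polyorder, 0, delta),
      sg_derivative = sgFilter(x, s$window, s$polyorder, s$deriv, delta),
      absorbance = log10(1 / pmax(x, 1e-4)),
      standardize = {
        r <- standardize(x, stats = outStats)
        outStats <- r$stats
        r$x
      })
  }
  list(x = x, stats = outStats)
}
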