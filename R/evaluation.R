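## Sample-set partitioning (Kennard-Stone), the RMSE/R2/RPD/RER metric
## suite, Pearson correlation, cross-validation, and report assembly.

#' SplitResult: a calibration/test partition
#'
#' @slot calibration integer ids (selection order of the Kennard-Stone
#'   walk).
#' @slot test integer ids (remainder, ascending).
#' @slot ratio numeric, calibration fraction.
#' @slot distanceMetric character.
#' @exportClass SplitResult
setClass("SplitResult",
         representation(calibration = "integer", test = "integer",
                        ratio = "numeric", distanceMetric = "character"))

setValidity("SplitResult", function(object) {
  if (length(intersect(object@calibration, object@test)) > 0)
    return("calibration and test sets must be disjoint")
  TRUE
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d test (ratio %.2f, %s)\n",
              length(object@calibration), length(object@test),
              object@ratio, object@distanceMetric))
})

#' Kennard-Stone calibration/test split
#'
#' Deterministic max-min-distance partitioning: the two most distant
#' samples (Euclidean) seed the calibration set; each further step adds
#' the sample maximizing its minimum distance to the already-selected
#' set, until `floor(n * ratio)` samples are selected. The remainder is
#' the test set. Ties break to the lowest sample index.
#'
#' @param features samples x dims matrix (finite values).
#' @param ratio calibration fraction (default 4/5, i.e. a 4:1 split).
#' @return A [SplitResult-class].
#' @examples
#' s <- kennardStoneSplit(matrix(c(0, 1, 2, 3, 10)), ratio = 4/5)
#' s@calibration  # 1 5 4 2 (values 0, 10, 3, 1)
#' @export
kennardStoneSplit <- function(features, ratio = 4 / 5) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 5) stop("Kennard-Stone needs at least 5 samples")
  if (any(!is.finite(X))) stop("features must be finite")
  nCal <- floor(n * ratio)
  D <- as.matrix(stats::dist(X))
  ## seed pair: maximal distance, ties to lowest (row, col) index
  m <- which(D == max(D), arr.ind = TRUE)
  m <- m[m[, 1] < m[, 2], , drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  sel <- as.integer(m[1, ])
  minDist <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < nCal) {
    minDist[sel] <- -Inf
    cand <- which.max(minDist)     # first max = lowest index
    sel <- c(sel, as.integer(cand))
    minDist <- pmin(minDist, D[, cand])
  }
  new("SplitResult", calibration = sel,
      test = setdiff(seq_len(n), sel), ratio = ratio,
      distanceMetric = "euclidean")
}

#' Root mean square error
#'
#' `sqrt(sum((chat - c)^2) / n)`.
#'
#' @param actual measured values.
#' @param predicted model estimates (same length).
#' @return Non-negative scalar.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("length mismatch between actual and predicted")
  sqrt(mean((predicted - actual)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((chat - c)^2) / sum((c - cbar)^2)` with `cbar` the mean of
#' the measured values.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
rSquared <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("length mismatch between actual and predicted")
  if (length(actual) < 2) stop("R2 needs n >= 2")
  ss <- sum((actual - mean(actual))^2)
  if (ss < 1e-300) stop("undefined R2: measured values have zero variance")
  1 - sum((predicted - actual)^2) / ss
}

#' Residual prediction deviation (RPD) and its qualitative category
#'
#' `RPD = DPcal / RMSEP` where `DPcal` is the sample (n-1) standard
#' deviation of the calibration reference values.
#'
#' @param calibrationRefs calibration-set reference values (length >= 2).
#' @param rmsep prediction RMSE (> 0).
#' @return Scalar RPD.
#' @export
rpd <- function(calibrationRefs, rmsep) {
  if (rmsep <= 0) stop("rmsep must be > 0")
  if (length(calibrationRefs) < 2) stop("need >= 2 calibration refs")
  sd(calibrationRefs) / rmsep
}

#' @rdname rpd
#' @param x an RPD value.
#' @return `rpdCategory`: one of the five interpretation bands
#'   (below 1.5: limited utility; 1.5-2.0: distinguishes high from low;
#'   2.0-2.5: approximate prediction; 2.5-3.0: good prediction;
#'   above 3: excellent).
#' @export
rpdCategory <- function(x) {
  cut(x, c(-Inf, 1.5, 2.0, 2.5, 3.0, Inf),
      labels = c("limited utility (<1.5)",
                 "distinguishes high from low (1.5-2.0)",
                 "approximate prediction (2.0-2.5)",
                 "good prediction (2.5-3.0)",
                 "excellent (>3)"),
      right = TRUE) |> as.character()
}

#' Relative error range (RER)
#'
#' `(Ymax - Ymin) / RMSEP`, with the extrema taken from the
#' calibration-set reference values.
#'
#' @param yMax,yMin calibration-set extrema of the attribute.
#' @param rmsep prediction RMSE (non-zero).
#' @return Scalar RER.
#' @examples
#' rer(2.064, 0.223, 0.017)  # 108.294
#' @export
rer <- function(yMax, yMin, rmsep) {
  if (rmsep == 0) stop("rmsep must be non-zero")
  (yMax - yMin) / rmsep
}

#' Pearson correlation matrix between analytes
#'
#' @param concentrations samples x analytes matrix (>= 3 samples, no
#'   zero-variance column).
#' @return Symmetric analytes x analytes matrix with unit diagonal.
#' @export
pearsonMatrix <- function(concentrations) {
  m <- as.matrix(concentrations)
  if (nrow(m) < 3) stop("need >= 3 samples")
  v <- apply(m, 2, sd)
  if (any(v < 1e-300))
    stop("undefined correlation: zero-variance analyte(s): ",
         paste(colnames(m)[v < 1e-300], collapse = ", "))
  cor(m)
}

#' Seeded k-fold cross-validation of an arbitrary model factory
#'
#' Partitions the rows into `folds` seeded folds, fits
#' `factory(X[train], Y[train])` per fold, pools the out-of-fold
#' predictions, and computes RMSECV and Rcv2 once on the pooled vector,
#' per target.
#'
#' @param factory function `(X, Y) -> model`; the model must respond to
#'   `predict(model, X)` (a model that is itself a function is called
#'   directly on the new data).
#' @param X,Y data matrices (rows aligned).
#' @param folds number of folds (`folds = nrow(X)` gives leave-one-out).
#' @param seed fold-assignment seed.
#' @return List with `rmsecv`, `rcv2` (vectors per target), `predictions`
#'   (pooled out-of-fold matrix) and `foldSizes`.
#' @export
crossValidate <- function(factory, X, Y, folds = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fold <- .foldAssign(nrow(X), folds, seed)
  pred <- matrix(NA_real_, nrow(X), ncol(Y))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    if (sum(!tr) < 1) stop("fold with no samples")
    m <- factory(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    pred[!tr, ] <- if (is.function(m)) as.matrix(m(X[!tr, , drop = FALSE]))
    else as.matrix(predict(m, X[!tr, , drop = FALSE]))
  }
  list(rmsecv = vapply(seq_len(ncol(Y)),
                       function(j) rmse(Y[, j], pred[, j]), numeric(1)),
       rcv2 = vapply(seq_len(ncol(Y)),
                     function(j) rSquared(Y[, j], pred[, j]), numeric(1)),
       predictions = pred,
       foldSizes = as.integer(table(fold)))
}

#' Assemble a per-analyte MetricsReport
#'
#' Computes RMSEC/Rc2 on the calibration set, RMSEP/Rp2 on the test set,
#' RPD and RER from the calibration reference values, and (optionally)
#' RMSECV/Rcv2 via [crossValidate()] on the calibration set.
#'
#' @param Ycal,YcalHat calibration reference values and fitted values
#'   (samples x analytes).
#' @param Ytest,YtestHat test reference values and predictions.
#' @param cvFactory optional model factory for cross-validation metrics.
#' @param Xcal calibration features (needed when `cvFactory` is given).
#' @param folds,seed CV controls.
#' @param model model label for the report.
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(Ycal, YcalHat, Ytest, YtestHat,
                          cvFactory = NULL, Xcal = NULL, folds = 5,
                          seed = 1, model = "model") {
  Ycal <- as.matrix(Ycal); YcalHat <- as.matrix(YcalHat)
  Ytest <- as.matrix(Ytest); YtestHat <- as.matrix(YtestHat)
  q <- ncol(Ycal)
  nm <- colnames(Ycal) %||% paste0("target_", seq_len(q))
  cv <- if (!is.null(cvFactory))
    crossValidate(cvFactory, Xcal, Ycal, folds, seed) else NULL
  rows <- lapply(seq_len(q), function(j) {
    rmsep <- rmse(Ytest[, j], YtestHat[, j])
    rpdj <- if (rmsep > 0) rpd(Ycal[, j], rmsep) else Inf
    data.frame(
      analyte = nm[j],
      Rc2 = rSquared(Ycal[, j], YcalHat[, j]),
      RMSEC = rmse(Ycal[, j], YcalHat[, j]),
      Rcv2 = if (is.null(cv)) NA_real_ else cv$rcv2[j],
      RMSECV = if (is.null(cv)) NA_real_ else cv$rmsecv[j],
      Rp2 = rSquared(Ytest[, j], YtestHat[, j]),
      RMSEP = rmsep,
      RPD = rpdj,
      RER = if (rmsep > 0) rer(max(Ycal[, j]), min(Ycal[, j]), rmsep)
      else Inf,
      rpd_category = rpdCategory(rpdj))
  })
  new("MetricsReport", table = do.call(rbind, rows), model = model)
}

#' Write a MetricsReport as CSV and JSON
#'
#' @param report a [MetricsReport-class].
#' @param path output path without extension; `<path>.csv` and
#'   `<path>.json` are written.
#' @return `path` invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  write.csv(metricsTable(report), paste0(path, ".csv"),
            row.names = FALSE)
  jsonlite::write_json(list(model = report@model,
                            metrics = metricsTable(report)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
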