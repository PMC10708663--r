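## NIPALS partial least squares regression (PLS2). This engine is shared
## by the PLSR baseline and the CARS/UVE wavelength selectors so that
## regression-coefficient conventions are identical everywhere.

#' PLSRModel: NIPALS partial least squares regression model
#'
#' @slot nComponents integer(1), latent variables used.
#' @slot weights,loadings,scores NIPALS W, P, T matrices.
#' @slot yLoadings Y-loading matrix C.
#' @slot coefficients bands x targets regression coefficient matrix (on
#'   centred data).
#' @slot xCenter,yCenter column means used for centring.
#' @slot xScale optional column scales (1s when unscaled).
#' @exportClass PLSRModel
setClass("PLSRModel",
         representation(nComponents = "integer", weights = "matrix",
                        loadings = "matrix", scores = "matrix",
                        yLoadings = "matrix", coefficients = "matrix",
                        xCenter = "numeric", yCenter = "numeric",
                        xScale = "numeric"))

#' Fit a PLSR model by NIPALS
#'
#' @param X samples x bands matrix.
#' @param Y samples x targets matrix (or vector).
#' @param nComponents number of latent variables; capped at the data rank
#'   (with a warning) if too large.
#' @param scale logical, scale X columns to unit variance (default FALSE;
#'   centring is always applied).
#' @param tol NIPALS convergence tolerance.
#' @return A [PLSRModel-class].
#' @examples
#' X <- matrix(rnorm(60), 20, 3); Y <- X %*% c(1, -2, 0.5)
#' m <- plsrFit(X, Y, 3)
#' max(abs(plsrPredict(m, X) - Y)) < 1e-8
#' @export
plsrFit <- function(X, Y, nComponents, scale = FALSE, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  nComponents <- as.integer(nComponents)
  maxA <- min(n - 1L, p)
  if (nComponents > maxA) {
    warning("nComponents capped at ", maxA)
    nComponents <- maxA
  }
  xCenter <- colMeans(X); yCenter <- colMeans(Y)
  xScale <- if (scale) pmax(apply(X, 2, sd), 1e-12) else rep(1, p)
  E <- sweep(sweep(X, 2, xCenter), 2, xScale, "/")
  F <- sweep(Y, 2, yCenter)
  W <- matrix(0, p, nComponents); P <- matrix(0, p, nComponents)
  Tm <- matrix(0, n, nComponents); C <- matrix(0, q, nComponents)
  a <- 0L
  for (k in seq_len(nComponents)) {
    u <- F[, which.max(apply(F, 2, function(v) sum(v^2)))]
    if (sum(u^2) < tol) break
    tOld <- rep(Inf, n)
    for (it in seq_len(200)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- E %*% w
      cc <- crossprod(F, tt) / sum(tt^2)
      if (q == 1) { u <- F[, 1]; }
      else u <- F %*% cc / sum(cc^2)
      if (sqrt(sum((tt - tOld)^2)) < tol * sqrt(sum(tt^2))) break
      tOld <- tt
    }
    if (nw < tol || sum(tt^2) < tol) break
    p_ <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(p_)
    F <- F - tt %*% t(cc)
    a <- k
    W[, k] <- w; P[, k] <- p_; Tm[, k] <- tt; C[, k] <- cc
  }
  if (a == 0L) {
    ## degenerate (e.g. constant Y): intercept-only model predicting the
    ## target mean
    warning("PLSR: no usable latent variable; intercept-only model")
    return(new("PLSRModel", nComponents = 0L,
               weights = matrix(0, p, 0), loadings = matrix(0, p, 0),
               scores = matrix(0, n, 0), yLoadings = matrix(0, q, 0),
               coefficients = matrix(0, p, q), xCenter = xCenter,
               yCenter = yCenter, xScale = xScale))
  }
  if (a < nComponents)
    warning("PLSR: rank limited to ", a, " components")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; C <- C[, seq_len(a), drop = FALSE]
  ## B on the centred/scaled scale: B = W (P'W)^-1 C'
  B <- W %*% solve(crossprod(P, W), t(C))
  B <- B / xScale
  rownames(B) <- colnames(X)
  new("PLSRModel", nComponents = a, weights = W, loadings = P,
      scores = Tm, yLoadings = C, coefficients = B,
      xCenter = xCenter, yCenter = yCenter, xScale = xScale)
}

#' Predict from a PLSR model
#'
#' @param model a [PLSRModel-class].
#' @param X samples x bands matrix.
#' @return samples x targets matrix of predictions.
#' @export
plsrPredict <- function(model, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, model@xCenter) %*% model@coefficients, 2,
        model@yCenter, "+")
}

#' @describeIn plsrFit regression coefficients (bands x targets, centred
#'   convention).
#' @export
plsrCoef <- function(model) model@coefficients

setMethod("predict", "PLSRModel",
          function(object, newdata, ...) plsrPredict(object, newdata))

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d latent variables, %d bands, %d target(s)\n",
              object@nComponents, nrow(object@coefficients),
              ncol(object@coefficients)))
})

## Seeded k-fold assignment shared by CV helpers.
.foldAssign <- function(n, folds, seed) {
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Cross-validated RMSE for PLSR over a component range
#'
#' Seeded k-fold cross-validation; out-of-fold predictions are pooled and
#' RMSE computed once per component count (averaged over targets).
#'
#' @param X,Y data matrices.
#' @param nCompMax largest component count tried.
#' @param folds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return List with `rmsecv` (vector over 1..nCompMax) and `best`: the
#'   smallest component count whose RMSECV is within 2% of the minimum
#'   (a parsimony rule guarding against overfitted latent variables).
#' @export
plsrCV <- function(X, Y, nCompMax = 15, folds = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  nCompMax <- min(nCompMax, ncol(X), n - ceiling(n / folds) - 1)
  nCompMax <- max(nCompMax, 1)
  fold <- .foldAssign(n, folds, seed)
  pred <- array(NA_real_, c(n, ncol(Y), nCompMax))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    m <- suppressWarnings(plsrFit(X[tr, , drop = FALSE],
                                  Y[tr, , drop = FALSE], nCompMax))
    Xc <- sweep(X[!tr, , drop = FALSE], 2, m@xCenter)
    ## predictions for every component count from one fit
    W <- m@weights; P <- m@loadings; C <- m@yLoadings
    for (a in seq_len(nCompMax)) {
      aa <- min(a, m@nComponents)
      Ba <- W[, 1:aa, drop = FALSE] %*%
        solve(crossprod(P[, 1:aa, drop = FALSE], W[, 1:aa, drop = FALSE]),
              t(C[, 1:aa, drop = FALSE]))
      pred[!tr, , a] <- sweep(sweep(Xc, 2, m@xScale, "/") %*% Ba, 2,
                              m@yCenter, "+")
    }
  }
  rmsecv <- vapply(seq_len(nCompMax),
                   function(a) sqrt(mean((pred[, , a] - Y)^2)),
                   numeric(1))
  list(rmsecv = rmsecv,
       best = which(rmsecv <= min(rmsecv) * 1.02)[1])
}
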