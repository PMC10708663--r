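## Wavelength-subset selection: CARS, SPA, UVE. All three share the
## in-package NIPALS PLS engine; ranking ties break to the lower band
## index so runs are deterministic under a fixed seed.

## Exponentially decreasing fraction (EDF) of retained variables for
## CARS: r_i = a exp(-k i) with r_1 = 1 and r_N = 2/p.
.carsEDF <- function(nRuns, p) {
  a <- (p / 2)^(1 / (nRuns - 1))
  k <- log(p / 2) / (nRuns - 1)
  a * exp(-k * seq_len(nRuns))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection: each Monte-Carlo run fits PLS on a
#' random subsample, ranks variables by the absolute regression
#' coefficient, enforces an exponentially decreasing retained fraction
#' (from 1 down to `2/p`), then performs adaptive reweighted sampling
#' among the survivors. Each run's subset is scored by cross-validated
#' RMSE; the subset with minimal RMSECV wins.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param nRuns Monte-Carlo runs (default 50).
#' @param cvFolds CV folds for run scoring (default 5).
#' @param sampleRatio Monte-Carlo subsample fraction (default 0.8).
#' @param nComponents PLS components per fit (default `min(10, ...)`).
#' @param seed RNG seed (fixes subsampling and reweighted sampling).
#' @return A [SelectionResult-class]; history columns: `run`,
#'   `keptFraction`, `nKept`, `rmsecv`.
#' @export
carsSelect <- function(X, y, nRuns = 50, cvFolds = 5, sampleRatio = 0.8,
                       nComponents = NULL, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nRuns >= 2, n >= cvFolds, p >= 2)
  if (is.null(nComponents))
    nComponents <- max(1, min(10, p - 1, n - 2))
  edf <- .carsEDF(nRuns, p)
  set.seed(seed)
  retained <- seq_len(p)
  best <- list(rmsecv = Inf, subset = retained)
  hist <- data.frame(run = seq_len(nRuns), keptFraction = edf,
                     nKept = NA_integer_, rmsecv = NA_real_)
  for (i in seq_len(nRuns)) {
    m <- max(2, ceiling(sampleRatio * n))
    idx <- sample(n, m)
    fit <- suppressWarnings(
      plsrFit(X[idx, retained, drop = FALSE], y[idx],
              min(nComponents, length(retained), m - 2)))
    b <- abs(drop(plsrCoef(fit)))
    nKeep <- max(2, round(edf[i] * p))
    nKeep <- min(nKeep, length(retained))
    ## rank by |b|, ties to the lower band index
    ord <- order(-b, seq_along(b))
    survivors <- retained[ord[seq_len(nKeep)]]
    bSurv <- b[ord[seq_len(nKeep)]]
    ## adaptive reweighted sampling among survivors
    if (sum(bSurv) > 0 && nKeep > 2) {
      pick <- sample(seq_along(survivors), nKeep, replace = TRUE,
                     prob = bSurv / sum(bSurv))
      newRet <- sort(unique(survivors[pick]))
      if (length(newRet) < 2)
        newRet <- sort(survivors[order(-bSurv)[1:2]])
    } else newRet <- sort(survivors)
    retained <- newRet
    cv <- plsrCV(X[, retained, drop = FALSE], matrix(y),
                 nCompMax = min(nComponents, length(retained)),
                 folds = min(cvFolds, n), seed = seed + i)
    hist$nKept[i] <- length(retained)
    hist$rmsecv[i] <- min(cv$rmsecv)
    if (min(cv$rmsecv) < best$rmsecv)
      best <- list(rmsecv = min(cv$rmsecv), subset = retained)
  }
  new("SelectionResult", method = "CARS",
      selected = as.integer(sort(best$subset)), history = hist,
      seed = as.integer(seed))
}

#' Successive projections algorithm (SPA)
#'
#' Forward selection of minimally collinear wavelengths: starting from
#' one column, the band whose column has maximal norm after projection
#' onto the orthogonal complement of the already-selected columns is
#' appended, up to `kMax`. When `y` is supplied the final subset size is
#' chosen by cross-validated RMSE of least squares on the first
#' `1..kMax` chain members; otherwise the full chain is returned.
#'
#' @param X samples x bands matrix.
#' @param kMax maximal chain length (`<= min(samples - 1, bands)`).
#' @param start starting band index, or `"scan"` to try every start and
#'   keep the chain with the best validation RMSE (requires `y`), or
#'   `NULL` (default) to start from the maximum-norm column.
#' @param y optional response vector enabling validation-based choice of
#'   the subset size.
#' @param folds,seed CV controls for the validation step.
#' @return A [SelectionResult-class]; `history` records the chain order.
#' @export
spaSelect <- function(X, kMax, start = NULL, y = NULL, folds = 5,
                      seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ## the projection chain exists up to rank min(n, p); the validation
  ## regression additionally needs a residual degree of freedom
  kCap <- if (is.null(y)) min(n, p) else min(n - 1, p)
  if (kMax > kCap)
    stop("kMax must be <= ", kCap,
         " (min of samples and bands, minus 1 when validating)")
  chainFrom <- function(s0) {
    sel <- integer(0)
    R <- X                      # residual columns
    norms <- colSums(R^2)
    cur <- s0
    for (k in seq_len(kMax)) {
      sel <- c(sel, cur)
      v <- R[, cur]
      nv2 <- sum(v^2)
      if (nv2 < 1e-12) { sel <- sel[-length(sel)]; break }
      R <- R - v %*% (crossprod(v, R) / nv2)
      R[, sel] <- 0
      if (k == kMax) break
      norms <- colSums(R^2)
      if (max(norms) < 1e-12) {
        warning("SPA chain stopped early: residual rank exhausted")
        break
      }
      cur <- which.max(norms)   # first max = lowest index on ties
    }
    sel
  }
  scoreChain <- function(sel) {
    if (is.null(y) || length(sel) == 0) return(list(k = length(sel), rmse = NA))
    fold <- .foldAssign(n, min(folds, n), seed)
    rmses <- vapply(seq_along(sel), function(k) {
      idx <- sel[seq_len(k)]
      pr <- rep(NA_real_, n)
      for (f in seq_len(max(fold))) {
        tr <- fold != f
        cf <- stats::lm.fit(cbind(1, X[tr, idx, drop = FALSE]), y[tr])$coefficients
        cf[is.na(cf)] <- 0
        pr[!tr] <- cbind(1, X[!tr, idx, drop = FALSE]) %*% cf
      }
      sqrt(mean((pr - y)^2))
    }, numeric(1))
    list(k = which.min(rmses), rmse = min(rmses))
  }
  starts <- if (identical(start, "scan")) seq_len(p)
  else if (is.null(start)) which.max(colSums(X^2))
  else as.integer(start)
  bestChain <- NULL; bestScore <- Inf
  for (s0 in starts) {
    ch <- chainFrom(s0)
    sc <- scoreChain(ch)
    val <- if (is.na(sc$rmse)) 0 else sc$rmse
    cand <- if (!is.null(y)) ch[seq_len(sc$k)] else ch
    better <- is.null(bestChain) || val < bestScore - 1e-12 ||
      (abs(val - bestScore) <= 1e-12 && length(cand) < length(bestChain))
    if (better) {
      bestChain <- cand
      bestScore <- val
    }
  }
  new("SelectionResult", method = "SPA",
      selected = as.integer(bestChain),
      history = data.frame(order = seq_along(bestChain),
                           band = bestChain),
      seed = as.integer(seed))
}

#' Uninformative variable elimination (UVE)
#'
#' Appends `p` small-amplitude uniform noise columns, computes
#' leave-one-out PLS regression coefficients, and eliminates every real
#' variable whose stability `c_j = mean(b_j)/sd(b_j)` does not exceed
#' (in absolute value) the largest absolute stability among the noise
#' columns.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param nComponents PLS components (`samples >= nComponents + 2`).
#' @param seed RNG seed for the noise columns.
#' @param noiseAmplitude relative noise amplitude (default 1e-10).
#' @return A [SelectionResult-class]; history columns: `band`,
#'   `stability`, `isNoise`, `retained`.
#' @export
uveSelect <- function(X, y, nComponents = 2, seed = 1,
                      noiseAmplitude = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= nComponents + 2)
  set.seed(seed)
  scale0 <- max(abs(X))
  N <- matrix(runif(n * p), n, p) * noiseAmplitude * scale0
  Z <- cbind(X, N)
  B <- matrix(NA_real_, n, 2 * p)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(plsrFit(Z[-i, , drop = FALSE], y[-i],
                                    nComponents))
    B[i, ] <- drop(plsrCoef(fit))
  }
  mu <- colMeans(B)
  sdv <- apply(B, 2, sd)
  stab <- numeric(2 * p)
  zero <- sdv < 1e-300
  if (any(zero)) warning(sum(zero), " coefficient(s) with zero variance; ",
                         "stability set to 0 (eliminated)")
  stab[!zero] <- mu[!zero] / sdv[!zero]
  cutoff <- max(abs(stab[(p + 1):(2 * p)]))
  keep <- which(abs(stab[seq_len(p)]) > cutoff)
  new("SelectionResult", method = "UVE", selected = as.integer(keep),
      history = data.frame(band = seq_len(2 * p), stability = stab,
                           isNoise = rep(c(FALSE, TRUE), each = p),
                           retained = c(seq_len(p) %in% keep,
                                        rep(FALSE, p))),
      seed = as.integer(seed))
}
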