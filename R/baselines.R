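## Baseline regressors: epsilon-SVR with RBF kernel (via e1071) and a
## radial basis function network (k-means centres + ridge output layer).
## Both standardize each target independently and inverse-transform at
## prediction, so the evaluation layer sees original concentration units.

#' SVMRModel: per-target epsilon-SVR with RBF kernel
#'
#' One support-vector regression per target, trained on the same spectra.
#'
#' @slot fits list of `e1071::svm` fits (one per target).
#' @slot yStats target standardization statistics.
#' @slot hyper list of hyperparameters (C, gamma, epsilon) per target.
#' @exportClass SVMRModel
setClass("SVMRModel",
         representation(fits = "list", yStats = "list", hyper = "list"))

#' Fit epsilon-SVR models (one per target)
#'
#' Vapnik epsilon-insensitive loss with an RBF kernel. When `tune = TRUE`
#' a small log-spaced grid over (C, gamma, epsilon) is searched by
#' seeded k-fold cross-validation, independently per target.
#'
#' @param X samples x bands matrix.
#' @param Y samples x targets matrix (or vector).
#' @param C,gamma,epsilon hyperparameters (scalars; `gamma` defaults to
#'   `1/ncol(X)`).
#' @param tune logical, grid-search hyperparameters (default FALSE).
#' @param folds,seed CV controls used when tuning.
#' @return An [SVMRModel-class].
#' @export
svmrFit <- function(X, Y, C = 10, gamma = NULL, epsilon = 0.1,
                    tune = FALSE, folds = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(C > 0, epsilon > 0)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  ys <- standardize(Y)
  fits <- list(); hyper <- list()
  for (j in seq_len(ncol(Y))) {
    yj <- ys$x[, j]
    if (sd(yj) < 1e-8) {
      ## degenerate (constant) target: constant model in z-space
      fits[[j]] <- list(constant = mean(yj))
      hyper[[j]] <- list(C = C, gamma = gamma, epsilon = epsilon)
      next
    }
    if (tune) {
      grid <- expand.grid(C = 10^(0:3), gamma = gamma * 10^(-1:1),
                          epsilon = c(0.01, 0.1))
      fold <- .foldAssign(nrow(X), min(folds, nrow(X)), seed)
      errs <- apply(grid, 1, function(g) {
        pr <- rep(NA_real_, nrow(X))
        for (f in seq_len(max(fold))) {
          tr <- fold != f
          m <- e1071::svm(X[tr, , drop = FALSE], yj[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = g["C"], gamma = g["gamma"],
                          epsilon = g["epsilon"], scale = FALSE)
          pr[!tr] <- predict(m, X[!tr, , drop = FALSE])
        }
        sqrt(mean((pr - yj)^2))
      })
      g <- grid[which.min(errs), ]
      hyper[[j]] <- as.list(g)
    } else {
      hyper[[j]] <- list(C = C, gamma = gamma, epsilon = epsilon)
    }
    fits[[j]] <- e1071::svm(X, yj, type = "eps-regression",
                            kernel = "radial", cost = hyper[[j]]$C,
                            gamma = hyper[[j]]$gamma,
                            epsilon = hyper[[j]]$epsilon, scale = FALSE)
  }
  new("SVMRModel", fits = fits, yStats = ys$stats, hyper = hyper)
}

#' Predict from an SVMRModel
#'
#' @param model an [SVMRModel-class].
#' @param X samples x bands matrix.
#' @return samples x targets matrix in original units.
#' @export
svmrPredict <- function(model, X) {
  X <- as.matrix(X)
  Z <- vapply(model@fits, function(f) {
    if (!is.null(f$constant)) rep(f$constant, nrow(X))
    else as.numeric(predict(f, X))
  }, numeric(nrow(X)))
  unstandardize(matrix(Z, nrow(X)), model@yStats)
}

setMethod("predict", "SVMRModel",
          function(object, newdata, ...) svmrPredict(object, newdata))

setMethod("show", "SVMRModel", function(object) {
  cat(sprintf("SVMRModel: %d target(s), RBF kernel\n",
              length(object@fits)))
})

## ---------------------------------------------------------------------------

#' RBFNNModel: radial basis function network regressor
#'
#' Three layers: inputs, Gaussian hidden units (each with a centre `c_j`
#' and width `r_j`, activation `exp(-d^2 / (2 r_j^2))` of the Euclidean
#' distance `d` to the centre), and a linear output layer fitted by
#' ridge-regularized least squares.
#'
#' @slot centers hidden-unit centres (centres x bands).
#' @slot widths positive widths, one per centre.
#' @slot weights (centres + 1) x targets output weights (first row =
#'   bias).
#' @slot yStats target standardization statistics.
#' @exportClass RBFNNModel
setClass("RBFNNModel",
         representation(centers = "matrix", widths = "numeric",
                        weights = "matrix", yStats = "list"))

.rbfDesign <- function(X, centers, widths) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) -
    2 * tcrossprod(X, centers)
  d2[d2 < 0] <- 0
  exp(-sweep(d2, 2, 2 * widths^2, "/"))
}

#' Fit an RBF network
#'
#' Centres are placed by seeded k-means (or at all training points when
#' `nCenters == nrow(X)`); widths default to the mean distance to the two
#' nearest other centres; output weights solve a ridge least-squares
#' problem on the Gaussian design matrix.
#'
#' @param X samples x bands matrix.
#' @param Y samples x targets matrix (or vector).
#' @param nCenters number of hidden units (`<= nrow(X)`).
#' @param widthRule `"knn2"` (default) or a fixed positive number.
#' @param ridge ridge penalty (default 1e-8).
#' @param seed k-means seed.
#' @return An [RBFNNModel-class].
#' @export
rbfnnFit <- function(X, Y, nCenters, widthRule = "knn2", ridge = 1e-8,
                     seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nCenters <= nrow(X), nCenters >= 1)
  ys <- standardize(Y)
  if (nCenters == nrow(X)) {
    centers <- X
  } else {
    set.seed(seed)
    centers <- kmeans(X, centers = nCenters, nstart = 5,
                      iter.max = 50)$centers
  }
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  widths <- if (identical(widthRule, "knn2")) {
    if (nrow(centers) < 3) rep(max(apply(X, 2, sd)) + 1e-6, nrow(centers))
    else apply(D, 1, function(r) mean(sort(r)[1:2]))
  } else rep(as.numeric(widthRule), nrow(centers))
  widths <- pmax(widths, 1e-8)   # duplicate centres: width floored
  Phi <- cbind(1, .rbfDesign(X, centers, widths))
  A <- crossprod(Phi) + diag(ridge, ncol(Phi))
  Wout <- solve(A, crossprod(Phi, ys$x))
  new("RBFNNModel", centers = centers, widths = widths,
      weights = Wout, yStats = ys$stats)
}

#' Predict from an RBFNNModel
#'
#' @param model an [RBFNNModel-class].
#' @param X samples x bands matrix.
#' @return samples x targets matrix in original units.
#' @export
rbfnnPredict <- function(model, X) {
  Phi <- cbind(1, .rbfDesign(as.matrix(X), model@centers, model@widths))
  unstandardize(Phi %*% model@weights, model@yStats)
}

setMethod("predict", "RBFNNModel",
          function(object, newdata, ...) rbfnnPredict(object, newdata))

setMethod("show", "RBFNNModel", function(object) {
  cat(sprintf("RBFNNModel: %d Gaussian unit(s), %d target(s)\n",
              nrow(object@centers), ncol(object@weights)))
})
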