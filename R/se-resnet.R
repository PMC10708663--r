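## The SE-ResNet regressor: stem convolution + batch norm + max-pool,
## four stages of SE-residual bottleneck blocks, global average pooling
## and a two-layer fully connected head with one output per analyte.

#' Channel convolution of a multi-channel map
#'
#' Computes `u_c = v_c * X = sum_s v_c^s * x^s`: each output channel is
#' the sum over input channels of 2-D spatial cross-correlations of the
#' kernel's per-channel slices with the corresponding input channels.
#'
#' @param X input map, array (H, W, C_in).
#' @param V kernel set, array (k, k, C_in, C_out).
#' @param stride spatial stride (default 1).
#' @param pad spatial zero-padding (default `floor(k/2)`, preserving the
#'   map size at stride 1 for odd kernels).
#' @return Array (H', W', C_out).
#' @export
channelConvolution <- function(X, V, stride = 1, pad = NULL) {
  stopifnot(length(dim(X)) == 3, length(dim(V)) == 4)
  if (dim(X)[3] != dim(V)[3])
    stop("shape error: kernel expects ", dim(V)[3], " input channels, got ",
         dim(X)[3])
  k <- dim(V)[1]
  if (is.null(pad)) pad <- k %/% 2
  cin <- dim(V)[3]; cout <- dim(V)[4]
  layer <- list(kind = "conv",
                par = list(W = matrix(aperm(V, c(3, 1, 2, 4)),
                                      k * k * cin, cout),
                           b = numeric(cout)),
                cfg = list(k = as.integer(k), stride = as.integer(stride),
                           pad = as.integer(pad), cin = cin, cout = cout))
  x4 <- array(X, c(1, dim(X)))
  y <- .convF(layer, x4)$y
  array(y, dim(y)[2:4])
}

#' Squeeze-and-excitation recalibration of a feature map
#'
#' Squeeze: per-channel global average. Excitation: a two-layer
#' bottleneck (C -> C/reduction -> C) with ReLU then sigmoid, yielding
#' per-channel gates in (0, 1). The map is rescaled channel-wise by the
#' gates. Supply `weights` to use fixed excitation parameters, or
#' `excitation` to pin the gates directly (e.g. all ones for the SE
#' ablation).
#'
#' @param U feature map, array (H, W, C).
#' @param reduction bottleneck reduction ratio (must divide C).
#' @param weights optional list (`W1`, `b1`, `W2`, `b2`).
#' @param excitation optional numeric C vector of fixed gates.
#' @param seed seed for random weights when none are given.
#' @return List with `output` (H, W, C), `squeeze` (length C) and
#'   `excitation` (length C).
#' @export
seRecalibrate <- function(U, reduction = 16, weights = NULL,
                          excitation = NULL, seed = 1) {
  stopifnot(length(dim(U)) == 3)
  C <- dim(U)[3]
  if (C %% reduction != 0) stop("reduction must divide the channel count")
  if (is.null(weights)) {
    set.seed(seed)
    layer <- .seLayer(C, as.integer(reduction))
  } else {
    layer <- list(par = weights,
                  cfg = list(C = C, reduction = reduction, pinned = NULL))
  }
  if (!is.null(excitation)) layer$cfg$pinned <- excitation
  x4 <- array(U, c(1, dim(U)))
  r <- .seF(layer, x4)
  sq <- .gapF(x4)$y[1, ]
  exc <- if (!is.null(excitation)) excitation else r$cache$z[1, ]
  list(output = array(r$y, dim(U)), squeeze = sq, excitation = exc)
}

#' Build an SE-ResNet regression model
#'
#' Instantiates the network described by an [ArchitectureSpec-class]:
#' 7x7/stride-2 stem convolution + batch norm + ReLU, 3x3/stride-2
#' max-pool, four SE-residual bottleneck stages, global average pooling
#' and the fully connected head. Initialization (He) is seeded.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param seed initialization seed.
#' @param seEnabled logical; `FALSE` pins every excitation gate to 1,
#'   turning the network into a plain residual network (SE ablation).
#' @return An object of class `SEResNet` (list with the layer tree, the
#'   spec and bookkeeping).
#' @examples
#' m <- buildModel(deskArchitectureSpec(), seed = 1)
#' nParams(m) > 1e5
#' @export
buildModel <- function(spec, seed = 1, seEnabled = TRUE) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  set.seed(seed)
  cin <- spec@inputShape[3]
  layers <- list(
    stem = .convLayer(spec@stemKernel, cin, spec@stemChannels,
                      stride = spec@stemStride, pad = spec@stemPad),
    stemBn = .bnLayer(spec@stemChannels))
  stages <- list()
  prev <- spec@stemChannels
  for (s in 1:4) {
    blocks <- list()
    for (b in seq_len(spec@stageBlocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blk <- .blockLayer(prev, spec@stageChannels[s], stride,
                         spec@reduction)
      if (!seEnabled)
        blk$se$cfg$pinned <- rep(1, spec@stageChannels[s])
      blocks[[paste0("b", b)]] <- blk
      prev <- spec@stageChannels[s]
    }
    stages[[paste0("s", s)]] <- blocks
  }
  layers$stages <- stages
  stopifnot(prev == spec@headWidths[1])  # head width matches final stage
  layers$fc1 <- .denseLayer(spec@headWidths[1], spec@headWidths[2])
  layers$fc2 <- .denseLayer(spec@headWidths[2], spec@headWidths[3])
  structure(list(spec = spec, layers = layers,
                 poolCfg = list(k = spec@poolKernel,
                                stride = spec@poolStride,
                                pad = spec@poolPad),
                 yStats = NULL, history = NULL, trained = FALSE,
                 seed = as.integer(seed)),
            class = "SEResNet")
}

#' Number of trainable parameters of an SEResNet
#'
#' @param model an object from [buildModel()].
#' @return Integer parameter count (convolution, batch-norm, SE and
#'   dense weights).
#' @export
nParams <- function(model) .countTree(model$layers)

#' @export
print.SEResNet <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("SEResNet: stages (%s), channels (%s), %s head, %d params%s\n",
              paste(sp@stageBlocks, collapse = ","),
              paste(sp@stageChannels, collapse = ","),
              paste(sp@headWidths, collapse = "->"), nParams(x),
              if (x$trained) " [trained]" else ""))
  invisible(x)
}

## Full forward pass. Returns the head output (N x targets), caches for
## backward, and the (BN-stat-updated) layer tree.
.netForward <- function(model, x, train = FALSE) {
  L <- model$layers
  caches <- list()
  st <- .convF(L$stem, x); caches$stem <- st$cache
  bn <- .bnF(L$stemBn, st$y, train); L$stemBn <- bn$layer
  caches$stemBn <- bn$cache
  a <- pmax(bn$y, 0); caches$stemMask <- bn$y > 0
  pl <- .poolF(model$poolCfg, a); caches$pool <- pl$cache
  h <- pl$y
  caches$stages <- list()
  for (s in names(L$stages)) {
    caches$stages[[s]] <- list()
    for (b in names(L$stages[[s]])) {
      r <- .blockF(L$stages[[s]][[b]], h, train)
      L$stages[[s]][[b]] <- r$layer
      caches$stages[[s]][[b]] <- r$cache
      h <- r$y
    }
  }
  g <- .gapF(h); caches$gap <- g$cache
  f1 <- .denseF(L$fc1, g$y); caches$fc1 <- f1$cache
  a1 <- pmax(f1$y, 0); caches$fc1Mask <- f1$y > 0
  f2 <- .denseF(L$fc2, a1); caches$fc2 <- f2$cache
  model$layers <- L
  list(out = f2$y, caches = caches, model = model)
}

.netBackward <- function(model, caches, dout) {
  L <- model$layers
  g <- list()
  f2 <- .denseB(L$fc2, caches$fc2, dout); g$fc2 <- f2$grads
  da1 <- f2$dx * caches$fc1Mask
  f1 <- .denseB(L$fc1, caches$fc1, da1); g$fc1 <- f1$grads
  dh <- .gapB(caches$gap, f1$dx)
  g$stages <- list()
  for (s in rev(names(L$stages))) {
    g$stages[[s]] <- list()
    for (b in rev(names(L$stages[[s]]))) {
      r <- .blockB(L$stages[[s]][[b]], caches$stages[[s]][[b]], dh)
      g$stages[[s]][[b]] <- r$grads
      dh <- r$dx
    }
  }
  dp <- .poolB(model$poolCfg, caches$pool, dh)
  da <- dp * caches$stemMask
  bn <- .bnB(L$stemBn, caches$stemBn, da); g$stemBn <- bn$grads
  ## the stem is the input layer: its input gradient is never consumed
  st <- .convB(L$stem, caches$stem, bn$dx, needDx = FALSE)
  g$stem <- st$grads
  g
}

.stackPatches <- function(patchList) {
  d <- dim(patchList[[1]])
  x <- array(0, c(length(patchList), d))
  for (i in seq_along(patchList)) x[i, , , ] <- patchList[[i]]
  x
}

#' Train an SE-ResNet regressor
#'
#' Minimizes mean squared error on z-scored targets with Adam. Batches
#' are reshuffled every epoch from the seeded RNG stream, so identical
#' seeds and data give identical loss histories. When
#' `config@valFraction > 0` a tail fraction of the records monitors
#' validation RMSE for early stopping (best weights restored).
#'
#' @param model an untrained model from [buildModel()].
#' @param x a [SampleSet-class] with patches, or a list of patch arrays.
#' @param y samples x targets matrix of concentrations (taken from the
#'   SampleSet when `x` is one).
#' @param config a [TrainConfig-class].
#' @return The trained model; `$history` holds a data.frame with
#'   per-epoch training loss (standardized scale) and validation RMSE.
#' @export
trainModel <- function(model, x, y = NULL, config = TrainConfig()) {
  stopifnot(inherits(model, "SEResNet"), is(config, "TrainConfig"))
  if (is(x, "SampleSet")) {
    y <- concentrations(x)
    x <- patches(x)
  }
  if (length(x) < 2) stop("need >= 2 records")
  X <- .stackPatches(x)
  Y <- as.matrix(y)
  stopifnot(nrow(Y) == dim(X)[1])
  if (!all(dim(X)[2:4] == model$spec@inputShape))
    stop("shape error: patches are ", paste(dim(X)[2:4], collapse = "x"),
         " but the spec expects ",
         paste(model$spec@inputShape, collapse = "x"))
  ys <- standardize(Y)
  Yz <- ys$x
  n <- nrow(Yz)
  ## input normalization: centre per feature (pixel x channel) across
  ## the training samples to remove the static plate/segment geometry,
  ## then scale per spectral channel by the pooled deviation sd. The
  ## per-feature centre exposes the small between-sample signal; the
  ## per-channel scale brings it to O(1) without amplifying
  ## signal-free background pixels to unit variance.
  dX <- dim(X)
  xm <- matrix(X, dX[1], prod(dX[2:4]))
  ctr <- colMeans(xm)
  xm <- sweep(xm, 2, ctr)
  chOf <- rep(seq_len(dX[4]), each = dX[2] * dX[3])
  chSd <- sqrt(tapply(colMeans(xm^2), chOf, mean))
  scl <- pmax(chSd[chOf], 1e-8)
  xStats <- list(center = ctr, scale = scl)
  X <- array(sweep(xm, 2, scl, "/"), dX)
  model$xStats <- xStats
  set.seed(config@seed)
  nVal <- floor(config@valFraction * n)
  valIdx <- if (nVal >= 1) sample(n, nVal) else integer(0)
  trIdx <- setdiff(seq_len(n), valIdx)
  state <- list()
  tAdam <- 0L
  hist <- data.frame(epoch = seq_len(config@epochs), loss = NA_real_,
                     valRmse = NA_real_)
  best <- list(rmse = Inf, layers = NULL, wait = 0L)
  for (ep in seq_len(config@epochs)) {
    lrEp <- if (identical(config@lrSchedule, "cosine"))
      config@learningRate * 0.5 *
        (1 + cos(pi * (ep - 1) / config@epochs))
    else config@learningRate
    ord <- sample(trIdx)
    bs <- config@batchSize
    losses <- c(); sizes <- c()
    for (start in seq(1, length(ord), by = bs)) {
      idx <- ord[start:min(start + bs - 1, length(ord))]
      xb <- X[idx, , , , drop = FALSE]
      if (config@augNoise > 0)
        xb <- xb + array(rnorm(length(xb), 0, config@augNoise), dim(xb))
      yb <- Yz[idx, , drop = FALSE]
      fw <- .netForward(model, xb, train = TRUE)
      model <- fw$model
      resid <- fw$out - yb
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep,
             " (exploding gradients; lower the learning rate)")
      dout <- 2 * resid / length(resid)
      grads <- .netBackward(model, fw$caches, dout)
      tAdam <- tAdam + 1L
      up <- .adamTree(model$layers, grads, state, lrEp,
                      0.9, 0.999, 1e-8, tAdam, config@weightDecay)
      model$layers <- up$node
      state <- up$st
      losses <- c(losses, loss); sizes <- c(sizes, length(idx))
    }
    hist$loss[ep] <- sum(losses * sizes) / sum(sizes)
    if (length(valIdx) > 0) {
      pv <- .netPredictZ(model, X[valIdx, , , , drop = FALSE])
      vr <- sqrt(mean((pv - Yz[valIdx, , drop = FALSE])^2))
      hist$valRmse[ep] <- vr
      if (vr < best$rmse - 1e-6) {
        best <- list(rmse = vr, layers = model$layers, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= config@patience) {
          hist <- hist[seq_len(ep), ]
          break
        }
      }
    }
  }
  if (!is.null(best$layers)) model$layers <- best$layers
  model <- .refreshBN(model, X[trIdx, , , , drop = FALSE])
  model$yStats <- ys$stats
  model$history <- hist
  model$trained <- TRUE
  model
}

## Set every batch-norm momentum in the tree to `val`.
.setBNMomentum <- function(node, val) {
  if (!is.list(node)) return(node)
  if (identical(node$kind, "bn")) {
    node$cfg$momentum <- val
    return(node)
  }
  for (nm in names(node))
    if (is.list(node[[nm]])) node[[nm]] <- .setBNMomentum(node[[nm]], val)
  node
}

## After optimization, replace the EMA batch-norm statistics by
## statistics recomputed over the training set (momentum 1/t implements
## a cumulative average over refresh batches; with a single full batch
## the statistics are the exact population moments). The EMA both lags
## the converged weights and — when refreshed in small batches —
## misses the between-batch-mean variance, which biases eval-mode
## activations precisely when between-sample structure is strong.
.refreshBN <- function(model, X, batchSize = 256L) {
  n <- dim(X)[1]
  starts <- seq(1, n, by = batchSize)
  for (t in seq_along(starts)) {
    idx <- starts[t]:min(starts[t] + batchSize - 1, n)
    model$layers <- .setBNMomentum(model$layers, 1 / t)
    fw <- .netForward(model, X[idx, , , , drop = FALSE], train = TRUE)
    model <- fw$model
  }
  model$layers <- .setBNMomentum(model$layers, 0.1)
  model
}

.netPredictZ <- function(model, X, batchSize = 32) {
  n <- dim(X)[1]
  out <- NULL
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    fw <- .netForward(model, X[idx, , , , drop = FALSE], train = FALSE)
    out <- rbind(out, fw$out)
  }
  out
}

#' Train an ensemble of SE-ResNet regressors
#'
#' Trains `nModels` networks that differ only in their initialization
#' and batch-shuffling seeds (derived from `config@seed`) and predicts
#' with the average of the member predictions. With small calibration
#' sets the dominant error of a single network is stochastic training
#' variance — member residuals are nearly uncorrelated across seeds —
#' so the seed-ensemble average removes most of it (a standard deep
#' ensemble).
#'
#' @param spec an [ArchitectureSpec-class] shared by all members.
#' @param x,y training data as in [trainModel()].
#' @param config a [TrainConfig-class]; member `i` uses seed
#'   `config@seed + (i - 1)`.
#' @param nModels ensemble size (default 4).
#' @return An object of class `SEResNetEnsemble`.
#' @export
trainEnsemble <- function(spec, x, y = NULL, config = TrainConfig(),
                          nModels = 4) {
  if (is(x, "SampleSet")) {
    y <- concentrations(x)
    x <- patches(x)
  }
  members <- vector("list", nModels)
  for (i in seq_len(nModels)) {
    cfg <- config
    cfg@seed <- config@seed + i - 1L
    m <- buildModel(spec, seed = cfg@seed)
    members[[i]] <- trainModel(m, x, y, cfg)
  }
  structure(list(members = members, spec = spec),
            class = "SEResNetEnsemble")
}

#' @export
print.SEResNetEnsemble <- function(x, ...) {
  cat(sprintf("SEResNetEnsemble: %d members\n", length(x$members)))
  print(x$members[[1]])
  invisible(x)
}

#' @rdname trainEnsemble
#' @param object a trained ensemble.
#' @param newdata patches as in [predict.SEResNet()].
#' @param ... passed to the member predict method.
#' @exportS3Method stats::predict
#' @export
predict.SEResNetEnsemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, predict, newdata = newdata, ...)
  Reduce(`+`, preds) / length(preds)
}

#' Predict concentrations with a trained SE-ResNet
#'
#' @param object a trained model from [trainModel()].
#' @param newdata a [SampleSet-class] with patches, or a list of patch
#'   arrays.
#' @param batchSize forward-pass batch size (default 32).
#' @param ... ignored.
#' @return samples x targets matrix in original concentration units,
#'   rows in input order.
#' @exportS3Method stats::predict
#' @export
predict.SEResNet <- function(object, newdata, batchSize = 32, ...) {
  if (!object$trained) stop("model is not trained")
  if (is(newdata, "SampleSet")) newdata <- patches(newdata)
  if (is.array(newdata) && length(dim(newdata)) == 3)
    newdata <- list(newdata)
  X <- .stackPatches(newdata)
  if (!all(dim(X)[2:4] == object$spec@inputShape))
    stop("shape error: patches are ", paste(dim(X)[2:4], collapse = "x"),
         " but the model expects ",
         paste(object$spec@inputShape, collapse = "x"))
  if (!is.null(object$xStats)) {
    xm <- matrix(X, dim(X)[1], prod(dim(X)[2:4]))
    X <- array(sweep(sweep(xm, 2, object$xStats$center), 2,
                     object$xStats$scale, "/"), dim(X))
  }
  z <- .netPredictZ(object, X, batchSize)
  unstandardize(z, object$yStats)
}
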