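test_that("channel convolution implements the summed 2-D convolution", {
  set.seed(1)
  X1 <- array(rnorm(25), c(5, 5, 1))
  ## single channel, 1x1 kernel of value a: pure scalar multiply
  V <- array(2.5, c(1, 1, 1, 1))
  expect_equal(channelConvolution(X1, V), 2.5 * X1)
  ## two channels with unit 1x1 kernels: channel-wise sum
  X2 <- array(rnorm(50), c(5, 5, 2))
  Vsum <- array(1, c(1, 1, 2, 1))
  expect_equal(drop(channelConvolution(X2, Vsum)),
               X2[, , 1] + X2[, , 2])
  ## spatial delta kernel per channel: again the channel sum
  Vd <- array(0, c(3, 3, 2, 1)); Vd[2, 2, , 1] <- 1
  expect_equal(drop(channelConvolution(X2, Vd)),
               X2[, , 1] + X2[, , 2])
  expect_error(channelConvolution(X1, Vsum), "shape error")
})

test_that("SE recalibration squeezes, gates in (0,1), and can be pinned", {
  set.seed(2)
  U <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  ## pinned all-ones excitation: identity
  r1 <- seRecalibrate(U, reduction = 4, excitation = rep(1, 8))
  expect_equal(r1$output, U)
  ## squeeze of a constant channel is that constant
  U2 <- U; U2[, , 3] <- 0.7
  r2 <- seRecalibrate(U2, reduction = 4, seed = 5)
  expect_equal(r2$squeeze[3], 0.7)
  ## excitation strictly inside (0, 1) for finite inputs
  expect_true(all(r2$excitation > 0 & r2$excitation < 1))
  expect_error(seRecalibrate(U, reduction = 3), "reduction")
})

test_that("the default architecture matches the published configuration", {
  spec <- ArchitectureSpec()
  expect_identical(spec@stageBlocks, c(3L, 4L, 23L, 3L))
  expect_identical(sum(spec@stageBlocks), 33L)
  expect_identical(spec@headWidths, c(2048L, 256L, 5L))
  ## invalid specs are rejected with the violated invariant
  expect_error(ArchitectureSpec(headWidths = c(1024L, 256L, 5L)),
               "head input width")
  expect_error(ArchitectureSpec(reduction = 13L), "reduction")
})

test_that("built models run forward with a 5-wide output", {
  m <- buildModel(tinySpec(), seed = 1)
  set.seed(3)
  x <- lapply(1:2, function(i) array(rnorm(9 * 9 * 3), c(9, 9, 3)))
  m$trained <- TRUE
  m$yStats <- list(center = rep(0, 5), scale = rep(1, 5))
  out <- predict(m, x)
  expect_identical(dim(out), c(2L, 5L))
  out1 <- predict(m, x[[1]])
  expect_identical(dim(out1), c(1L, 5L))
  ## parameter count is invariant across seeds
  expect_identical(nParams(buildModel(tinySpec(), seed = 1)),
                   nParams(buildModel(tinySpec(), seed = 99)))
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("hsiQuant")
  netF <- get(".netForward", ns); netB <- get(".netBackward", ns)
  m <- buildModel(tinySpec(), seed = 3)
  set.seed(7)
  x <- array(rnorm(2 * 9 * 9 * 3), c(2, 9, 9, 3))
  y <- matrix(rnorm(10), 2, 5)
  fw <- netF(m, x, train = TRUE)
  dout <- 2 * (fw$out - y) / length(fw$out)
  gr <- netB(fw$model, fw$caches, dout)
  lossAt <- function(model) mean((netF(model, x, train = TRUE)$out - y)^2)
  checks <- list(
    list(path = c("stem"), nm = "W", i = 5),
    list(path = c("stemBn"), nm = "gamma", i = 2),
    list(path = c("stages", "s1", "b1", "conv2"), nm = "W", i = 10),
    list(path = c("stages", "s2", "b1", "se"), nm = "W1", i = 3),
    list(path = c("stages", "s3", "b1", "short", "conv"), nm = "W", i = 2),
    list(path = c("fc1"), nm = "W", i = 7))
  eps <- 1e-5
  for (ch in checks) {
    perturb <- function(v) {
      mm <- m
      node <- mm$layers
      expr <- Reduce(function(acc, p) acc[[p]], ch$path, node)
      expr$par[[ch$nm]][ch$i] <- expr$par[[ch$nm]][ch$i] + v
      ## write back along the path
      assignPath <- function(node, path, value) {
        if (length(path) == 0) return(value)
        node[[path[1]]] <- assignPath(node[[path[1]]], path[-1], value)
        node
      }
      mm$layers <- assignPath(mm$layers, ch$path, expr)
      lossAt(mm)
    }
    num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    ana <- Reduce(function(acc, p) acc[[p]], ch$path, gr)[[ch$nm]][ch$i]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("training is deterministic and overfits a toy set", {
  toy <- toyGeneratorSet(n = 8, seed = 5)
  cfgShort <- TrainConfig(epochs = 10, batchSize = 4, seed = 11)
  m1 <- trainModel(buildModel(toySpec(), seed = 4), toy$patches,
                   toy$Y, cfgShort)
  m2 <- trainModel(buildModel(toySpec(), seed = 4), toy$patches,
                   toy$Y, cfgShort)
  expect_identical(m1$history, m2$history)

  ## longer run: optimization sanity (overfit) on the toy set
  cfgLong <- TrainConfig(learningRate = 2e-3, epochs = 150,
                         batchSize = 8, seed = 11)
  m <- trainModel(buildModel(toySpec(), seed = 4), toy$patches,
                  toy$Y, cfgLong)
  expect_lt(tail(m$history$loss, 1), 1e-2)
  ## moving-average loss (window 20) is non-increasing
  ma <- stats::filter(m$history$loss, rep(1 / 20, 20), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-3 * ma[1]))
  ## predictions on the training set recover the targets
  p <- predict(m, toy$patches)
  for (j in 1:5)
    expect_gte(rSquared(toy$Y[, j], p[, j]), 0.99)
  ## standardize/inverse round trip
  s <- standardize(toy$Y)
  expect_lt(max(abs(unstandardize(s$x, s$stats) - toy$Y)), 1e-10)
})

test_that("pinning every excitation to 1 changes the computation", {
  mSE <- buildModel(tinySpec(), seed = 6, seEnabled = TRUE)
  mPlain <- buildModel(tinySpec(), seed = 6, seEnabled = FALSE)
  ns <- asNamespace("hsiQuant")
  netF <- get(".netForward", ns)
  set.seed(8)
  x <- array(rnorm(9 * 9 * 3), c(1, 9, 9, 3))
  outSE <- netF(mSE, x, train = FALSE)$out
  outPlain <- netF(mPlain, x, train = FALSE)$out
  ## identical weights, but the gated path differs from the plain one
  expect_gt(max(abs(outSE - outPlain)), 1e-8)
})

test_that("shape mismatches are reported at the model boundary", {
  m <- buildModel(tinySpec(), seed = 1)
  bad <- list(array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  expect_error(trainModel(m, bad, matrix(rnorm(5), 1, 5),
                          TrainConfig(epochs = 1)), "2 records")
  bad2 <- lapply(1:3, function(i) array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  expect_error(trainModel(m, bad2, matrix(rnorm(15), 3, 5),
                          TrainConfig(epochs = 1)), "shape error")
})
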