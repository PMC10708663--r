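## Simulated spectra with two informative bands for selector oracles.
twoBandSim <- function(n, p, informative = c(10, 60), noise = 0.05,
                       seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, informative[1]] - 0.8 * X[, informative[2]] +
    rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("CARS retention schedule hits the 2/p endpoint", {
  sim <- twoBandSim(40, 128, noise = 0.1, seed = 2)
  res <- carsSelect(sim$X, sim$y, nRuns = 50, cvFolds = 4,
                    nComponents = 3, seed = 1)
  h <- res@history
  expect_equal(h$keptFraction[1], 1, tolerance = 1e-12)
  expect_equal(h$keptFraction[50], 2 / 128, tolerance = 1e-12)
  ## kept fraction is non-increasing
  expect_true(all(diff(h$keptFraction) <= 1e-12))
  expect_true(length(selectedBands(res)) >= 2)
})

test_that("CARS recovers strongly informative bands across seeds", {
  hits <- 0L
  for (s in 1:10) {
    sim <- twoBandSim(500, 64, informative = c(10, 60), noise = 0.05,
                      seed = 100 + s)
    res <- carsSelect(sim$X, sim$y, nRuns = 30, cvFolds = 4,
                      nComponents = 3, seed = s)
    if (all(c(10, 60) %in% selectedBands(res))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("CARS respects the two-variable floor", {
  set.seed(5)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- X %*% c(1, 1) + rnorm(60, sd = 0.05)
  res <- carsSelect(X, y, nRuns = 10, cvFolds = 3, nComponents = 1,
                    seed = 1)
  expect_setequal(selectedBands(res), 1:2)
})

test_that("CARS is bit-reproducible under a fixed seed", {
  sim <- twoBandSim(80, 20, informative = c(3, 15), seed = 3)
  r1 <- carsSelect(sim$X, sim$y, nRuns = 12, cvFolds = 4, seed = 7)
  r2 <- carsSelect(sim$X, sim$y, nRuns = 12, cvFolds = 4, seed = 7)
  expect_identical(selectedBands(r1), selectedBands(r2))
  expect_identical(r1@history, r2@history)
})

test_that("SPA follows the hand-traced projection chain", {
  ## identity columns: chain from column 1 is 1, 2, 3 (ties to lowest)
  res <- spaSelect(diag(3), kMax = 3, start = 1)
  expect_identical(selectedBands(res), c(1L, 2L, 3L))
  ## a duplicated column is never selected twice
  X <- cbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  r2 <- spaSelect(X, kMax = 2, start = 1)
  expect_false(2L %in% selectedBands(r2))
  ## kMax = 1 returns the start column alone
  expect_identical(selectedBands(spaSelect(diag(3), kMax = 1, start = 2)),
                   2L)
  expect_error(spaSelect(diag(3), kMax = 4), "kMax")
})

test_that("SPA scan picks the spanning column first for orthonormal X", {
  set.seed(6)
  Q <- qr.Q(qr(matrix(rnorm(48), 8, 6)))
  y <- Q[, 4]
  res <- spaSelect(Q, kMax = 3, start = "scan", y = y, folds = 4,
                   seed = 1)
  expect_equal(selectedBands(res)[1], 4L)
})

test_that("UVE eliminates noise replicas and keeps informative bands", {
  set.seed(7)
  n <- 300
  X <- cbind(matrix(rnorm(n * 2), n, 2),           # informative
             matrix(rnorm(n * 18), n, 18))         # pure noise
  y <- X[, 1] + 0.8 * X[, 2] + rnorm(n, sd = 0.05)
  res <- uveSelect(X, y, nComponents = 2, seed = 1)
  expect_true(all(c(1, 2) %in% selectedBands(res)))
  eliminatedNoise <- sum(!(3:20 %in% selectedBands(res)))
  expect_gte(eliminatedNoise / 18, 0.9)
})

test_that("UVE treats zero-variance coefficients as uninformative", {
  set.seed(8)
  X <- cbind(matrix(rnorm(40 * 3), 40, 3), rep(5, 40))
  y <- X[, 1] + rnorm(40, sd = 0.05)
  expect_warning(res <- uveSelect(X, y, nComponents = 2, seed = 1),
                 "zero variance")
  expect_false(4L %in% selectedBands(res))
  expect_true(1L %in% selectedBands(res))
})

test_that("refitting on a selected subset uses only subset bands", {
  sim <- twoBandSim(100, 20, informative = c(3, 15), seed = 9)
  for (res in list(
    carsSelect(sim$X, sim$y, nRuns = 10, cvFolds = 4, seed = 1),
    spaSelect(sim$X, kMax = 5, y = sim$y, seed = 1),
    uveSelect(sim$X, sim$y, nComponents = 2, seed = 1))) {
    sel <- selectedBands(res)
    expect_true(length(sel) >= 1 && all(sel >= 1 & sel <= 20))
    expect_false(anyDuplicated(sel) > 0)
    m <- suppressWarnings(plsrFit(sim$X[, sel, drop = FALSE], sim$y,
                                  min(3, length(sel))))
    ## coefficient support is exactly the subset
    expect_equal(nrow(plsrCoef(m)), length(sel))
  }
})
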