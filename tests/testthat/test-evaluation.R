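test_that("Kennard-Stone reproduces the hand-traced selection", {
  s <- kennardStoneSplit(matrix(c(0, 1, 2, 3, 10)), ratio = 4 / 5)
  ## values 0 and 10 seed; then 3 (max-min), then 1 (tie to lowest index)
  expect_identical(s@calibration, c(1L, 5L, 4L, 2L))
  expect_identical(s@test, 3L)
  expect_error(kennardStoneSplit(matrix(1:4), 4 / 5), "at least 5")
  expect_error(kennardStoneSplit(matrix(c(1, NA, 2, 3, 4))), "finite")
})

test_that("a 4:1 split of 187 samples gives 149 + 38", {
  set.seed(1)
  X <- matrix(rnorm(187 * 10), 187, 10)
  s <- kennardStoneSplit(X, ratio = 4 / 5)
  expect_length(s@calibration, 149)
  expect_length(s@test, 38)
})

test_that("calibration and test sets are disjoint and exhaustive", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(6:60, 1)
    s <- kennardStoneSplit(matrix(rnorm(n * 3), n, 3))
    expect_length(intersect(s@calibration, s@test), 0)
    expect_setequal(c(s@calibration, s@test), seq_len(n))
    expect_length(s@calibration, floor(n * 4 / 5))
  }
})

test_that("rmse follows its defining arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(1, 4), 3)
  expect_error(rmse(1:3, 1:2), "length mismatch")
})

test_that("rSquared follows the measured-deviation convention", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rSquared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(rSquared(rep(2, 3), c(1, 2, 3)), "zero variance")
})

test_that("metric implementations agree with brute-force loops", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    a <- rnorm(n); p <- rnorm(n)
    sse <- 0; sst <- 0; ab <- mean(a)
    for (k in seq_len(n)) {
      sse <- sse + (p[k] - a[k])^2
      sst <- sst + (a[k] - ab)^2
    }
    expect_equal(rmse(a, p), sqrt(sse / n), tolerance = 1e-12)
    expect_equal(rSquared(a, p), 1 - sse / sst, tolerance = 1e-12)
  }
})

test_that("RPD and its interpretation bands behave as defined", {
  expect_equal(rpd(c(1, 2, 3), 1), 1)
  expect_match(rpdCategory(1), "limited utility")
  expect_equal(rpd(c(1, 2, 3), 0.5), 2)
  expect_match(rpdCategory(6.324), "excellent")
  expect_match(rpdCategory(1.7), "high from low")
  expect_match(rpdCategory(2.2), "approximate")
  expect_match(rpdCategory(2.7), "good")
  expect_error(rpd(c(1, 2, 3), 0), "rmsep")
})

test_that("RER divides the calibration range by RMSEP", {
  expect_equal(rer(2, 1, 0.5), 2)
  expect_equal(rer(3, 3, 0.1), 0)
  expect_error(rer(2, 1, 0), "non-zero")
})

test_that("Pearson matrices are symmetric with unit diagonal", {
  set.seed(3)
  x <- rnorm(50)
  m <- pearsonMatrix(cbind(a = x, b = -x, c = rnorm(50)))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], -1)
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(m, t(m))
  expect_error(pearsonMatrix(cbind(x, rep(1, 50))), "zero-variance")
  expect_error(pearsonMatrix(matrix(1:4, 2)), "3 samples")
})

test_that("cross-validation pools out-of-fold predictions", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Y <- X %*% matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2)
  ## perfect factory: the identity oracle as a function model
  oracle <- function(Xtr, Ytr) {
    B <- stats::lm.fit(Xtr, Ytr)$coefficients
    function(Xnew) Xnew %*% B
  }
  cv <- crossValidate(oracle, X, Y, folds = 5, seed = 1)
  expect_true(all(cv$rmsecv < 1e-8))
  expect_true(all(cv$rcv2 > 1 - 1e-10))

  ## leave-one-out: every fold has one sample
  cvLoo <- crossValidate(oracle, X, Y, folds = 40, seed = 1)
  expect_true(all(cvLoo$foldSizes == 1L))

  ## a constant predictor cannot beat the mean on varying targets
  constFactory <- function(Xtr, Ytr)
    function(Xnew) matrix(7, nrow(Xnew), ncol(Ytr))
  cvC <- crossValidate(constFactory, X, Y, folds = 5, seed = 1)
  expect_true(all(cvC$rcv2 <= 0))
})

test_that("metrics reports carry the full per-analyte table", {
  set.seed(5)
  Ycal <- matrix(rnorm(60), 30, 2,
                 dimnames = list(NULL, c("a", "b")))
  Ytst <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  rep_ <- metricsReport(Ycal, Ycal + rnorm(60, sd = 0.1),
                        Ytst, Ytst + rnorm(20, sd = 0.2),
                        model = "toy")
  tb <- metricsTable(rep_)
  expect_identical(nrow(tb), 2L)
  expect_true(all(c("Rc2", "RMSEC", "Rp2", "RMSEP", "RPD", "RER",
                    "rpd_category") %in% colnames(tb)))
  expect_true(all(tb$RMSEC >= 0 & tb$RMSEP >= 0))
  expect_true(all(tb$Rc2 <= 1 & tb$Rp2 <= 1))
  ## RER/RPD consistency with their definitions
  expect_equal(tb$RER[1],
               (max(Ycal[, 1]) - min(Ycal[, 1])) / tb$RMSEP[1])
  expect_equal(tb$RPD[1], sd(Ycal[, 1]) / tb$RMSEP[1])
})
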