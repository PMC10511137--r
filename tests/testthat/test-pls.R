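test_that("full-rank PLS1 equals the ordinary least squares fit", {
  set.seed(10)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rep(c(1, -1), each = 5)
  m <- fitPLSDA(X, y, ncomp = 5)
  # normal-equations oracle
  Xc <- cbind(1, X)
  bOLS <- solve(crossprod(Xc), crossprod(Xc, y))
  expect_equal(m@coefficients, bOLS[-1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(m@intercept, bOLS[1], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a single informative column separates the classes completely", {
  set.seed(11)
  y <- rep(c(1, -1), 10)
  X <- cbind(sig = y * 2, matrix(rnorm(20 * 3, 0, 0.01), 20, 3))
  m <- fitPLSDA(X, y, ncomp = 1)
  expect_gt(m@coefficients[1], 0)
  sc <- scores(scoreSeeds(m, X))
  expect_gt(min(sc[y == 1]), max(sc[y == -1]))
})

test_that("permuted labels have no cross-validated skill", {
  set.seed(12)
  X <- matrix(rnorm(100 * 20), 100, 20)
  y <- sample(rep(c(1, -1), 50))
  mse <- nirsort:::.cvMSE(X, y, maxComp = 5, folds = 5, seed = 1)
  expect_gt(min(mse), 0.9 * var(y))   # no better than predicting the mean
})

test_that("SPRC is the coefficient on standardized units", {
  set.seed(13)
  X <- scale(matrix(rnorm(40 * 6), 40, 6))
  y <- rep(c(1, -1), 20)           # sd-1-ish dummy
  m <- fitPLSDA(X, y, ncomp = 3)
  expect_equal(m@sprc, m@coefficients * apply(X, 2, sd) / sd(y),
               ignore_attr = TRUE)
  # at full rank (where the fit is scale-equivariant) rescaling one
  # column's units leaves every SPRC unchanged
  mf <- fitPLSDA(X, y, ncomp = 6)
  X2 <- X; X2[, 3] <- X2[, 3] * 100
  m2 <- fitPLSDA(X2, y, ncomp = 6)
  expect_equal(m2@sprc, mf@sprc, tolerance = 1e-8)
  # single-predictor SPRC equals the Pearson correlation with y
  x1 <- rnorm(40)
  ms <- fitPLSDA(matrix(x1, ncol = 1), y, ncomp = 1)
  expect_equal(ms@sprc[1], cor(x1, y), tolerance = 1e-10)
})

test_that("VIP collapses to |w| for one component and is normalized", {
  set.seed(14)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- X[, 1] - X[, 5] + rnorm(30, 0, 0.5)
  y <- ifelse(y > median(y), 1, -1)
  m1 <- fitPLSDA(X, y, ncomp = 1)
  w <- abs(m1@weights[, 1])
  expect_equal(m1@vip / max(m1@vip), w / max(w), tolerance = 1e-10)
  for (k in 1:4) {
    m <- fitPLSDA(X, y, ncomp = k)
    expect_equal(mean(m@vip^2), 1, tolerance = 1e-8)
  }
})

test_that("VIP ranks planted informative bands on top", {
  ds <- generateSyntheticDataset(syntheticSpectraSpec(nSeeds = 150), seed = 15)
  truth <- S4Vectors::metadata(ds)$truth
  m <- fitPLSDA(makeVariant(ds, 1), ncomp = 5)
  top <- order(m@vip, decreasing = TRUE)[1:15]
  expect_true(all(vapply(truth$informativeBands,
                         function(b) any(abs(top - b) <= 1), TRUE)))
  # SPRC and VIP orderings agree on a one-component model
  m1 <- fitPLSDA(makeVariant(ds, 1), ncomp = 1)
  expect_gt(cor(abs(m1@sprc), m1@vip, method = "spearman"), 0.9)
})

test_that("PLS1 agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(16)
  X <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(NULL, paste0("b", 1:12)))
  y <- rep(c(1, -1), 25)
  m <- fitPLSDA(X, y, ncomp = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(scores(scoreSeeds(m, X)), pref, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate fits are refused", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fitPLSDA(X, rep(1, 10)), "degenerate")
  expect_error(fitPLSDA(X, c(1, rep(-1, 9))), "2 seeds per class")
})

test_that("adaptive lasso equals soft-thresholding on an orthonormal design", {
  set.seed(17)
  n <- 64; p <- 8
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), center = TRUE,
                     scale = FALSE)))   # orthonormal, zero-mean columns
  X <- Q * sqrt(n)                      # crossprod(X)/n = I
  bTrue <- c(3, -2, 1.5, 0, 0, 0.8, 0, 0)
  y <- drop(X %*% bTrue) + rnorm(n, 0, 0.2)
  y <- y - mean(y)
  beta <- rep(1, p)                     # uniform weights: plain lasso
  path <- adaptiveLassoPath(X, y, beta, nlambda = 40)
  fit <- path$path
  proj <- drop(crossprod(X, y)) / n
  picks <- unique(round(seq(2, length(fit$lambda), length.out = 4)))
  for (j in picks) {
    lam <- fit$lambda[j]
    oracle <- sign(proj) * pmax(abs(proj) - lam, 0) /
      (colSums(X^2) / n)
    expect_equal(as.numeric(fit$beta[, j]), oracle, tolerance = 1e-4)
  }
})

test_that("lasso path endpoints span empty to full support", {
  set.seed(18)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(60, 0, 0.1)
  beta <- rnorm(10)
  path <- adaptiveLassoPath(X, y, beta, nlambda = 100, lambdaMinRatio = 1e-6)
  sizes <- lengths(path$supports)
  expect_gte(min(sizes), 1)
  expect_equal(max(sizes), 10)
  # strongest-SPRC variable enters the path first
  beta2 <- c(100, rep(1, 9))
  y2 <- drop(X %*% c(0.5, rep(0.3, 9))) + rnorm(60, 0, 0.1)
  p2 <- adaptiveLassoPath(X, y2, beta2)
  expect_true(1 %in% p2$supports[[1]])
  # zero-SPRC variables are hard-excluded
  beta3 <- beta; beta3[4] <- 0
  p3 <- adaptiveLassoPath(X, y, beta3)
  expect_identical(p3$excluded, 4L)
  expect_false(any(vapply(p3$supports, function(s) 4L %in% s, TRUE)))
  expect_error(adaptiveLassoPath(X, y, rep(0, 10)), "all SPRC")
})

test_that("model JSON serialization round-trips scoring exactly", {
  ds <- generateSyntheticDataset(syntheticSpectraSpec(nSeeds = 60), seed = 19)
  xv <- makeVariant(ds, 2)
  m <- fitPLSDA(xv, ncomp = 3, support = seq(5, 195, by = 10))
  f <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(m, f)
  m2 <- readModelJSON(f)
  expect_equal(scores(scoreSeeds(m2, xv)), scores(scoreSeeds(m, xv)))
  expect_identical(m2@support, m@support)
  expect_equal(m2@vip, m@vip)
  expect_identical(m2@preprocess$index, 2L)
  # scoring refuses mismatched preprocessing
  expect_error(scoreSeeds(m, makeVariant(ds, 3)), "mismatch")
})

test_that("scoring is affine and duplicate rows tie", {
  set.seed(20)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep(c(1, -1), 15)
  m <- fitPLSDA(X, y, ncomp = 2)
  x0 <- matrix(0, 2, 6); x1 <- matrix(rnorm(6), 2, 6, byrow = TRUE)
  s0 <- scores(scoreSeeds(m, x0)); s1 <- scores(scoreSeeds(m, x1))
  expect_equal(s1[1], s1[2])                       # duplicates tie
  s2 <- scores(scoreSeeds(m, 2 * x1))
  expect_equal(s2 - s0, 2 * (s1 - s0), tolerance = 1e-10)  # linearity
})
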