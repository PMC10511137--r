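## PLS1 (NIPALS) regression of the +/-1 class dummy on spectra.
## Written in-package because the discriminant pipeline needs the
## per-component weights, scores and explained y-variance for SPRC and VIP;
## cross-checked against an independent PLS implementation in the test
## suite. X is column-centered (optionally scaled); y is centered.

.pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  W <- matrix(0, p, ncomp)          # normalized weights
  P <- matrix(0, p, ncomp)          # x loadings
  q <- numeric(ncomp)               # y loadings
  Tn2 <- numeric(ncomp)             # ||t_a||^2
  Xr <- X; yr <- y
  a <- 0L
  for (i in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break           # nothing left to extract
    w <- w / nw
    t <- Xr %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pa <- crossprod(Xr, t) / tt
    qa <- sum(yr * t) / tt
    Xr <- Xr - t %*% t(pa)
    yr <- yr - qa * t
    a <- i
    W[, i] <- w; P[, i] <- pa; q[i] <- qa; Tn2[i] <- tt
  }
  if (a == 0L) stop("no PLS component could be extracted (X'y is zero)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]; Tn2 <- Tn2[seq_len(a)]
  # regression coefficients at each number of components
  Rmat <- W %*% solve(crossprod(P, W))          # p x a
  B <- sapply(seq_len(a), function(k)
    Rmat[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
  B <- matrix(B, nrow = ncol(X))
  list(ncomp = a, W = W, P = P, q = q, Tn2 = Tn2, B = B)
}

.cvMSE <- function(X, y, maxComp, folds, seed) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  maxComp <- min(maxComp, n - ceiling(n / folds) - 1L, ncol(X))
  err <- matrix(NA_real_, folds, maxComp)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) next
    mx <- colMeans(X[tr, , drop = FALSE]); my <- mean(y[tr])
    fit <- .pls1(sweep(X[tr, , drop = FALSE], 2L, mx), y[tr] - my,
                 maxComp)
    Xc <- sweep(X[!tr, , drop = FALSE], 2L, mx)
    for (k in seq_len(fit$ncomp))
      err[f, k] <- mean((y[!tr] - (my + Xc %*% fit$B[, k]))^2)
  }
  colMeans(err, na.rm = TRUE)
}

#' Fit a PLS-DA discriminant model
#'
#' Partial least squares regression of the +/-1 eligibility dummy on the
#' (column-centered) spectra; the continuous prediction is the discriminant
#' score. When `ncomp = "auto"` the latent-variable count minimizing the
#' cross-validated mean squared error is used (10-fold by default, capped at
#' `maxComp`).
#'
#' @param x a labelled [SpectraSet-class], or a seeds x bands matrix.
#' @param labels +1 / -1 labels; taken from `x` when it is a SpectraSet.
#' @param ncomp latent-variable count, or "auto".
#' @param support integer indices of the wavebands to fit on (default all).
#' @param maxComp cap on the latent-variable count.
#' @param scale also scale columns to unit variance before fitting (the
#'   default centers only).
#' @param folds,seed cross-validation protocol for `ncomp = "auto"`.
#' @return a [PLSDAModel-class] with SPRC and VIP filled in.
#' @export
fitPLSDA <- function(x, labels = NULL, ncomp = "auto", support = NULL,
                     maxComp = 20L, scale = FALSE, folds = 10L, seed = 1L) {
  if (is(x, "SpectraSet")) {
    if (is.null(labels)) labels <- seedLabels(x)
    wl <- wavelengths(x)
    pp <- preprocessSpec(x)
    X <- spectraMatrix(x)
  } else {
    X <- as.matrix(x)
    wl <- if (!is.null(colnames(X))) suppressWarnings(as.numeric(colnames(X)))
          else seq_len(ncol(X))
    if (anyNA(wl)) wl <- seq_len(ncol(X))
    pp <- variantSpec(1L)
  }
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("all seeds must be labelled for fitting")
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: both classes are required")
  if (any(table(labels) < 2L)) stop("at least 2 seeds per class required")
  if (is.null(support)) support <- seq_len(ncol(X))
  support <- sort(as.integer(support))
  X <- X[, support, drop = FALSE]
  y <- as.numeric(labels)
  sdx <- apply(X, 2L, stats::sd)
  if (any(sdx == 0)) {
    warning(sprintf("%d zero-variance waveband(s) excluded", sum(sdx == 0)))
    keep <- sdx > 0
    support <- support[keep]; X <- X[, keep, drop = FALSE]; sdx <- sdx[keep]
  }
  if (identical(ncomp, "auto")) {
    mse <- .cvMSE(X, y, maxComp, folds, seed)
    ncomp <- which.min(mse)
  }
  ncomp <- as.integer(ncomp)
  mx <- colMeans(X); my <- mean(y)
  scl <- if (scale) sdx else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, mx), 2L, scl, "/")
  fit <- .pls1(Xc, y - my, ncomp)
  bScaled <- fit$B[, fit$ncomp]
  b <- bScaled / scl                       # coefficients on original units
  intercept <- my - sum(mx * b)
  sprc <- b * sdx / stats::sd(y)
  ssY <- fit$q^2 * fit$Tn2                 # y-SS explained per component
  p <- length(support)
  vip <- sqrt(p * as.vector(fit$W^2 %*% ssY) / sum(ssY))
  new("PLSDAModel", ncomp = fit$ncomp, support = support,
      wavelengths = wl[support], coefficients = as.numeric(b),
      intercept = intercept, xMeans = mx, xScales = scl, weights = fit$W,
      xLoadings = fit$P, yLoadings = fit$q, ssY = ssY,
      sprc = as.numeric(sprc), vip = vip, preprocess = pp,
      meta = list(n = nrow(X), nEligible = sum(labels == 1L),
                  scale = scale, cvFolds = folds, cvSeed = seed))
}

#' @describeIn scoreSeeds score a SpectraSet; errors if its preprocessing
#'   provenance differs from the model's (spectra are never silently
#'   re-transformed).
#' @export
setMethod("scoreSeeds", signature("PLSDAModel", "SpectraSet"),
          function(model, x, ...) {
  ppx <- preprocessSpec(x); ppm <- preprocessSpec(model)
  if (!is.null(ppx$index) && ppx$index != ppm$index)
    stop(sprintf("preprocess mismatch: model expects variant X%d, got X%d",
                 ppm$index, ppx$index))
  wl <- wavelengths(x)
  idx <- .matchWavelengths(model@wavelengths, wl)
  if (anyNA(idx)) stop("input does not cover the model's waveband support")
  m <- spectraMatrix(x)[, idx, drop = FALSE]
  ScoredBatch(drop(m %*% model@coefficients) + model@intercept,
              seedLabels(x), seedIds(x))
})

## nearest-match within a tolerance; wavelengths survive text serialization
.matchWavelengths <- function(target, wl, tol = 1e-6) {
  vapply(target, function(t) {
    i <- which.min(abs(wl - t))
    if (abs(wl[i] - t) <= tol) i else NA_integer_
  }, 0L)
}

#' @describeIn scoreSeeds score a bare matrix whose columns are (or contain,
#'   by wavelength name) the model support.
#' @export
setMethod("scoreSeeds", signature("PLSDAModel", "matrix"),
          function(model, x, ...) {
  if (ncol(x) != length(model@support)) {
    idx <- .matchWavelengths(model@wavelengths,
                             suppressWarnings(as.numeric(colnames(x))))
    if (anyNA(idx)) stop("matrix does not cover the model's waveband support")
    x <- x[, idx, drop = FALSE]
  }
  ScoredBatch(drop(x %*% model@coefficients) + model@intercept)
})
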