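## Adaptive-lasso waveband preselection. The per-variable penalty weight is
## 1/|SPRC| from a full PLS-DA fit, so wavebands the full model deems
## important are penalized less and enter the solution path earlier.
## Wavebands with SPRC exactly 0 are hard-excluded (infinite penalty).

#' Adaptive-lasso solution path over wavebands
#'
#' L1-penalized least squares of the +/-1 dummy on the spectra with
#' per-variable penalty weight `1/|beta|`, realized through
#' [glmnet::glmnet()]'s `penalty.factor` over a decreasing lambda grid from
#' the empty-support lambda down to `lambdaMinRatio` of it. Returns the
#' distinct non-empty supports appearing along the path, ordered by size.
#'
#' @param X seeds x bands matrix (one preprocessing variant).
#' @param y +/-1 labels (numeric).
#' @param beta SPRC per column of `X` (penalty weights are `1/|beta|`).
#' @param nlambda lambda grid size.
#' @param lambdaMinRatio smallest lambda as a fraction of lambda-max.
#' @return list with `supports` (list of integer index vectors, size
#'   ascending), `lambda` (grid), `path` (the glmnet fit), `excluded`
#'   (indices dropped for zero SPRC).
#' @export
adaptiveLassoPath <- function(X, y, beta, nlambda = 100L,
                              lambdaMinRatio = 1e-4) {
  if (ncol(X) != length(beta)) stop("one SPRC per column of X required")
  excluded <- which(beta == 0 | !is.finite(beta))
  keep <- setdiff(seq_len(ncol(X)), excluded)
  if (!length(keep)) stop("all SPRCs are zero; no waveband can be selected")
  pf <- 1 / abs(beta[keep])
  fit <- glmnet::glmnet(X[, keep, drop = FALSE], as.numeric(y),
                        family = "gaussian", alpha = 1,
                        penalty.factor = pf, standardize = FALSE,
                        nlambda = nlambda,
                        lambda.min.ratio = lambdaMinRatio)
  nz <- apply(fit$beta != 0, 2L, which)
  supports <- unique(lapply(nz[lengths(nz) > 0L],
                            function(i) sort(keep[i])))
  supports <- supports[order(lengths(supports))]
  list(supports = supports, lambda = fit$lambda, path = fit,
       excluded = excluded)
}
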