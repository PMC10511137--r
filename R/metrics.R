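## Sorting-performance metrics for eligible-seed sorting.
##
## A sorter recovers every seed whose discriminant score is >= the lower
## score threshold (LST). Sweeping the LST over all achieved scores yields
## precision P (eligibility rate after sorting), recall R (recovery rate of
## eligible seeds), accuracy A, and relative precision
## rP = (P - iP)/(1 - iP) when P > iP, else 0 -- precision rescaled so that
## 0 means no improvement over the initial eligibility rate iP and 1 means
## a pure recovered batch.

.checkLabelled <- function(x) {
  if (!length(x@scores)) stop("empty batch")
  if (anyNA(x@labels)) stop("batch must be fully labelled")
  if (length(unique(x@labels)) < 2L)
    stop("degenerate batch: both classes must be present")
}

#' Relative precision
#'
#' `rP = (P - iP) / (1 - iP)` when `P > iP`, else 0: precision rescaled to
#' the closed interval from "no enrichment" (0) to "pure batch" (1), making
#' sorting performance comparable across batches with different initial
#' eligibility rates.
#'
#' @param P precision (eligibility rate after sorting), in \[0, 1\].
#' @param iP initial precision, in (0, 1).
#' @return rP, same length as `P`.
#' @examples
#' relativePrecision(0.903, 0.8)  # 0.515
#' @export
relativePrecision <- function(P, iP) {
  if (any(iP >= 1) || any(iP <= 0)) stop("iP must lie strictly inside (0, 1)")
  ifelse(P > iP, (P - iP) / (1 - iP), 0)
}

#' @describeIn sortingCurve one row per distinct achieved score threshold
#'   `t` (descending): `recovery` = fraction of all seeds with score >= t,
#'   `P`, `R`, `A`, and `rP`. At the loosest threshold recovery = 1, P = iP,
#'   R = 1.
#' @export
setMethod("sortingCurve", "ScoredBatch", function(x, ...) {
  .checkLabelled(x)
  o <- order(x@scores, decreasing = TRUE)
  s <- x@scores[o]
  pos <- x@labels[o] == 1L
  N <- length(s)
  npos <- sum(pos)
  iP <- npos / N
  cumTP <- cumsum(pos)
  keep <- which(!duplicated(s, fromLast = TRUE))  # last index per tie group
  k <- keep
  tp <- cumTP[keep]
  P <- tp / k
  R <- tp / npos
  A <- (tp + (N - npos) - (k - tp)) / N
  data.frame(threshold = s[keep], recovery = k / N, P = P, R = R, A = A,
             rP = relativePrecision(P, iP))
})

#' @describeIn standardCondition recovers the top `k = round(iP * N)` seeds
#'   by score; `sLST` is the k-th highest score (the lowest score of seeds to
#'   be recovered). Ties at sLST are all recovered, re-expanding `k`
#'   (reported as `k`). Returns `list(sLST, sP, sR, sA, k)`; `sP == sR`
#'   exactly whenever `iP * N` is integral and no ties re-expand the cut.
#' @export
setMethod("standardCondition", "ScoredBatch", function(x, ...) {
  .checkLabelled(x)
  N <- length(x@scores)
  iP <- initialPrecision(x)
  k0 <- round(iP * N)
  if (k0 < 1L || k0 >= N)
    stop("degenerate standard condition: round(iP * N) must lie in [1, N-1]")
  srt <- sort(x@scores, decreasing = TRUE)
  sLST <- srt[k0]
  rec <- x@scores >= sLST
  k <- sum(rec)
  tp <- sum(rec & x@labels == 1L)
  list(sLST = sLST, sP = tp / k, sR = tp / sum(x@labels == 1L),
       sA = (tp + sum(!rec & x@labels == -1L)) / N, k = k)
})

#' Area under a curve by trapezoid (or step) integration
#'
#' Points are sorted by `x`; the curve is extended to `x = 0` carrying the
#' value at the smallest achieved `x`, so areas over recall are integrals
#' over \[0, max(R)\] (max(R) = 1 for a full sorting curve).
#'
#' @param x abscissa (recall), in \[0, 1\].
#' @param y ordinate (P, rP, ...).
#' @param method "trapezoid" (default) or "step" (right-step, the
#'   average-precision convention).
#' @return the area, a scalar.
#' @export
curveAUC <- function(x, y, method = c("trapezoid", "step")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (x[1L] > 0) { x <- c(0, x); y <- c(y[1L], y) }
  if (method == "trapezoid")
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  else
    sum(diff(x) * utils::tail(y, -1L))
}

#' Precision-recall and relative-precision-recall curves
#'
#' @param curve a sorting curve from [sortingCurve()].
#' @return list with `pr` and `rpr` data.frames (`R` ascending, plus the
#'   `P` / `rP` ordinate).
#' @export
prCurves <- function(curve) {
  o <- order(curve$R)
  list(pr = data.frame(R = curve$R[o], P = curve$P[o]),
       rpr = data.frame(R = curve$R[o], rP = curve$rP[o]))
}

#' Maximum achievable accuracy over all thresholds
#'
#' @param x a [ScoredBatch-class] or a sorting-curve data.frame. The
#'   all-rejected operating point (accuracy `1 - iP`) is included, so Amax
#'   is never below `max(iP, 1 - iP)`.
#' @export
accuracyMax <- function(x) {
  curve <- if (is(x, "ScoredBatch")) sortingCurve(x) else x
  iP <- curve$P[which.max(curve$recovery)]
  max(max(curve$A), 1 - iP)
}

#' @describeIn standardSummary one-row data.frame with the Table-style
#'   metric layout: `iP`, `sLST`, `sP`, `sA`, `Amax`, `AUC_PR`, `AUC_rPR`.
#' @param auc integration rule passed to [curveAUC()].
#' @export
setMethod("standardSummary", "ScoredBatch",
          function(x, auc = c("trapezoid", "step"), ...) {
  auc <- match.arg(auc)
  sc <- standardCondition(x)
  curve <- sortingCurve(x)
  data.frame(iP = initialPrecision(x), sLST = sc$sLST, sP = sc$sP,
             sA = sc$sA, Amax = accuracyMax(curve),
             AUC_PR = curveAUC(curve$R, curve$P, auc),
             AUC_rPR = curveAUC(curve$R, curve$rP, auc))
})

#' Format a metric summary the way the field's tables print it
#'
#' Percentages to one decimal, scores and AUCs to four.
#' @param s one or more rows from [standardSummary()].
#' @return data.frame of formatted strings.
#' @export
formatSummary <- function(s) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  data.frame(iP = pct(s$iP), sLST = sprintf("%.4f", s$sLST), sP = pct(s$sP),
             sA = pct(s$sA), Amax = pct(s$Amax),
             AUC_PR = sprintf("%.4f", s$AUC_PR),
             AUC_rPR = sprintf("%.4f", s$AUC_rPR))
}

#' Standardize discriminant scores against a calibration batch
#'
#' Converts raw scores to `z = (y - sLST(calib)) / s(calib)` where `s` is
#' the standard deviation of the calibration scores and sLST their standard
#' threshold. A standardized score of 0 therefore means "exactly at the
#' standard cut of the calibration batch", making scores from different
#' models (or testing occasions) comparable and ready for unification.
#'
#' @param scores numeric scores to convert.
#' @param calib a labelled [ScoredBatch-class] used to estimate sLST and the
#'   score sd (typically the model's outer-CV validation scores).
#' @return standardized scores, same length as `scores`.
#' @export
standardizeScores <- function(scores, calib) {
  s <- stats::sd(calib@scores)
  if (!is.finite(s) || s == 0) stop("calibration scores have zero sd")
  (scores - standardCondition(calib)$sLST) / s
}

#' Unify standardized scores from several per-trait models
#'
#' The representative score of a seed is its lowest standardized score over
#' the models: when several quality traits are required, rejection is
#' preferred over acceptance in case of doubt. The result can be treated
#' like any other discriminant score.
#'
#' @param zList list of equal-length standardized score vectors.
#' @return numeric vector `u`, the elementwise minimum.
#' @export
unifyScores <- function(zList) {
  if (!length(zList)) stop("at least one score vector required")
  n <- lengths(zList)
  if (length(unique(n)) != 1L) stop("score vectors differ in length")
  do.call(pmin, zList)
}
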