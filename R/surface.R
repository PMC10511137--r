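## Two-model ("successive") sorting: a seed is recovered when its score from
## model 1 is >= LST1 AND its score from model 2 is >= LST2. Precision,
## recall and relative precision of the recovered set against the joint
## (fully-eligible) labels become surfaces over the two thresholds.

#' Sorting surface for successive two-model discrimination
#'
#' Evaluates P, R and rP of the jointly recovered set over a grid of
#' threshold pairs. Grid thresholds are placed at score quantiles of each
#' model (plus a below-minimum anchor so each axis reaches recall 1), so the
#' per-model marginal recalls `R1`, `R2` cover their full range. Volumes
#' under the P and rP surfaces over the (R1, R2) unit square are computed by
#' 2-d trapezoid, with the surfaces extended to zero recall carrying their
#' edge values (the same convention as [curveAUC()]).
#'
#' @param batch1,batch2 [ScoredBatch-class] objects scoring the same seeds,
#'   aligned by position (seed ids must agree).
#' @param labels joint full-eligibility labels, +1 / -1; defaults to the
#'   labels carried by `batch1`.
#' @param grid number of thresholds per axis (default 201).
#' @return list with `lst1`, `lst2` (descending threshold grids), `R1`,
#'   `R2` (marginal recall grids, ascending), matrices `P`, `R`, `rP`
#'   (rows follow `lst1`, columns `lst2`), `iP`, `volumePR`, `volumeRPR`.
#'   At the loosest corner P equals iP and R equals 1.
#' @export
successiveSurface <- function(batch1, batch2, labels = NULL, grid = 201L) {
  s1 <- scores(batch1); s2 <- scores(batch2)
  if (length(s1) != length(s2))
    stop("batches are misaligned: different seed counts")
  if (!identical(seedIds(batch1), seedIds(batch2)))
    stop("batches are misaligned: seed ids differ")
  if (is.null(labels)) labels <- seedLabels(batch1)
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("joint eligibility labels are required")
  pos <- labels == 1L
  npos <- sum(pos)
  iP <- npos / length(s1)
  if (iP <= 0 || iP >= 1) stop("both classes required in the joint labels")
  thr <- function(s) {       # descending thresholds, last one recovers all
    q <- unique(stats::quantile(s, probs = seq(1, 0, length.out = grid),
                                type = 1L, names = FALSE))
    c(sort(q, decreasing = TRUE), min(s) - 1)
  }
  t1 <- thr(s1); t2 <- thr(s2)
  n1 <- length(t1); n2 <- length(t2)
  Pm <- matrix(0, n1, n2); Rm <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    in1 <- s1 >= t1[i]
    sel2 <- s2[in1]; selPos <- pos[in1]
    nrec <- vapply(t2, function(t) sum(sel2 >= t), 0L)
    tp <- vapply(t2, function(t) sum(selPos & sel2 >= t), 0L)
    Pm[i, ] <- ifelse(nrec > 0L, tp / nrec, 1)
    Rm[i, ] <- tp / npos
  }
  rPm <- matrix(relativePrecision(as.vector(Pm), iP), n1, n2)
  R1 <- vapply(t1, function(t) sum(pos & s1 >= t), 0L) / npos  # ascending
  R2 <- vapply(t2, function(t) sum(pos & s2 >= t), 0L) / npos
  vol <- function(Z) {
    x <- R1; y <- R2
    if (x[1L] > 0) { x <- c(0, x); Z <- rbind(Z[1L, ], Z) }
    if (y[1L] > 0) { y <- c(0, y); Z <- cbind(Z[, 1L], Z) }
    cellMean <- (Z[-1L, -1L] + Z[-nrow(Z), -1L] + Z[-1L, -ncol(Z)] +
                 Z[-nrow(Z), -ncol(Z)]) / 4
    sum(outer(diff(x), diff(y)) * cellMean)
  }
  list(lst1 = t1, lst2 = t2, R1 = R1, R2 = R2, P = Pm, R = Rm, rP = rPm,
       iP = iP, volumePR = vol(Pm), volumeRPR = vol(rPm))
}
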