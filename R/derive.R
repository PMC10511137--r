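## Candidate-model derivation: for each explanatory-variable variant and
## each direction of the mutual outer cross-validation (train on capture 1,
## validate on capture 2, and vice versa), fit a full PLS-DA on the training
## capture, take its SPRCs as adaptive-lasso penalty weights, walk the lasso
## path, refit PLS-DA on every distinct support, and score the held-out
## capture. The whole derivation runs inside the training capture so the
## validation scores are leak-free: no seed is ever scored by a model whose
## waveband selection or coefficients saw that seed's capture.

.outerFolds <- function(capture, seed) {
  caps <- sort(unique(capture))
  if (length(caps) == 2L)
    return(list(capture == caps[1L], capture == caps[2L]))
  warning("single capture: falling back to seeded 2-fold seed-level CV")
  set.seed(seed)
  f <- sample(rep(1:2, length.out = length(capture)))
  list(f == 1L, f == 2L)
}

#' Derive candidate sparse discriminant models
#'
#' Runs the four-step derivation per explanatory-variable variant and per
#' outer-CV direction: (1) the variant spectra of the training capture, (2)
#' full PLS-DA and its SPRCs, (3) adaptive lasso with penalty weights
#' 1/|SPRC|, (4) PLS-DA refit on every distinct support along the path. Each
#' candidate is summarized ([standardSummary()]) from its held-out capture
#' scores, so duplicate-capture structure is required (a single capture
#' falls back to a seeded 2-fold seed split, with a warning).
#'
#' @param x a labelled raw-reflectance [SpectraSet-class] with a capture
#'   column.
#' @param variants which of the twelve variants to derive on.
#' @param maxComp latent-variable cap for the auto component selection.
#' @param folds inner CV folds for the component selection.
#' @param seed RNG seed controlling all fold assignments.
#' @param nlambda,lambdaMinRatio lasso path grid.
#' @param maxSupports at most this many path supports per variant and
#'   direction are refitted (evenly thinned by size when exceeded).
#' @param includeFull also evaluate the non-sparse full-support parent model.
#' @return a [CandidateSet-class] ranked by (sP, AUC-rPR, fewer bands).
#'   Each candidate's `meta$trainFold` records which outer fold trained it.
#' @export
deriveCandidates <- function(x, variants = 1:12, maxComp = 20L, folds = 10L,
                             seed = 1L, nlambda = 100L,
                             lambdaMinRatio = 1e-4, maxSupports = 30L,
                             includeFull = TRUE) {
  y <- seedLabels(x)
  if (anyNA(y)) stop("all seeds must be labelled")
  ids <- seedIds(x)
  outer <- .outerFolds(captureIds(x), seed)
  models <- list(); rows <- list()
  for (v in variants) {
    xv <- makeVariant(x, v)
    Xm <- spectraMatrix(xv)
    for (f in seq_along(outer)) {
      tr <- outer[[f]]; te <- !tr
      if (!any(te) || !any(tr)) next
      full <- fitPLSDA(Xm[tr, , drop = FALSE], y[tr], ncomp = "auto",
                       maxComp = maxComp, folds = folds, seed = seed + f)
      full@preprocess <- preprocessSpec(xv)
      path <- adaptiveLassoPath(Xm[tr, , drop = FALSE], y[tr], full@sprc,
                                nlambda = nlambda,
                                lambdaMinRatio = lambdaMinRatio)
      sup <- path$supports
      if (length(sup) > maxSupports)
        sup <- sup[unique(round(seq(1L, length(sup),
                                    length.out = maxSupports)))]
      cands <- lapply(sup, function(s)
        fitPLSDA(Xm[tr, , drop = FALSE], y[tr], ncomp = "auto", support = s,
                 maxComp = maxComp, folds = folds, seed = seed + f))
      if (includeFull) cands <- c(cands, list(full))
      for (cand in cands) {
        cand@preprocess <- preprocessSpec(xv)
        cand@meta$trainFold <- f
        cand@meta$variant <- v
        val <- scoreSeeds(cand, Xm[te, , drop = FALSE])
        val@labels <- as.integer(y[te]); val@seedIds <- ids[te]
        validObject(val)
        sm <- standardSummary(val)
        models[[length(models) + 1L]] <- cand
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(variant = v, fold = f,
                           nBands = length(cand@support)), sm)
      }
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  new("CandidateSet", candidates = models, summaries = summaries,
      ranking = .rankSummaries(summaries))
}

## primary key sP (desc), tie-break AUC-rPR (desc), then fewer bands
.rankSummaries <- function(s)
  as.integer(order(-s$sP, -s$AUC_rPR, s$nBands))

#' Rank candidates by repeated re-evaluation
#'
#' Re-evaluates every candidate `iterations` times with resampled inner
#' cross-validation fold assignments (a fresh seed per iteration, derived
#' from `seed`): the candidate's support and training capture stay fixed,
#' its coefficients are refit under the new component selection, and the
#' held-out capture is re-scored. Each iteration is ranked by (sP, AUC-rPR,
#' fewer bands) and iterations are aggregated by median rank, so candidates
#' that are frequently high-ranked come first. With `iterations = 1` this
#' equals a single-pass sort of the stored summaries.
#'
#' @param candset a [CandidateSet-class] from [deriveCandidates()].
#' @param x the labelled [SpectraSet-class] the set was derived from (raw
#'   reflectance); required when `iterations > 1`.
#' @param iterations resampling repetitions.
#' @param seed RNG seed; results are deterministic given it.
#' @param maxComp,folds evaluation protocol, as in [deriveCandidates()].
#' @return the [CandidateSet-class] with its ranking replaced.
#' @export
rankCandidates <- function(candset, x = NULL, iterations = 1L, seed = 1L,
                           maxComp = 20L, folds = 10L) {
  if (iterations <= 1L) {
    candset@ranking <- .rankSummaries(candset@summaries)
    return(candset)
  }
  if (is.null(x)) stop("x is required when iterations > 1")
  y <- seedLabels(x); ids <- seedIds(x)
  outer <- .outerFolds(captureIds(x), seed)
  nc <- length(candset@candidates)
  varCache <- new.env()
  rankMat <- matrix(NA_real_, iterations, nc)
  for (it in seq_len(iterations)) {
    itSeed <- seed + 1000L * it
    rows <- lapply(seq_len(nc), function(i) {
      m <- candset@candidates[[i]]
      key <- paste0("X", m@preprocess$index)
      if (is.null(varCache[[key]]))
        varCache[[key]] <- spectraMatrix(makeVariant(x, m@preprocess$index))
      Xm <- varCache[[key]]
      tr <- outer[[m@meta$trainFold]]; te <- !tr
      refit <- fitPLSDA(Xm[tr, , drop = FALSE], y[tr], ncomp = "auto",
                        support = m@support, maxComp = maxComp,
                        folds = folds, seed = itSeed + m@meta$trainFold)
      val <- scoreSeeds(refit, Xm[te, , drop = FALSE])
      val@labels <- as.integer(y[te]); val@seedIds <- ids[te]
      cbind(data.frame(variant = m@meta$variant, nBands = length(m@support)),
            standardSummary(val))
    })
    s <- do.call(rbind, rows)
    rankMat[it, .rankSummaries(s)] <- seq_len(nc)
  }
  med <- apply(rankMat, 2L, stats::median)
  candset@ranking <- as.integer(order(med, candset@summaries$nBands))
  candset
}

#' Serialize a fitted model to JSON
#'
#' Single-file JSON with the preprocessing spec, support wavelengths (nm),
#' coefficients, intercept, latent-variable count, SPRC, VIP and training
#' metadata; round-trip stable through [readModelJSON()].
#'
#' @param model a [PLSDAModel-class].
#' @param path output file.
#' @export
writeModelJSON <- function(model, path) {
  obj <- list(format = "nirsort-model", version = 1L,
              preprocess = model@preprocess, ncomp = model@ncomp,
              support = model@support, wavelengths = model@wavelengths,
              coefficients = model@coefficients, intercept = model@intercept,
              xMeans = model@xMeans, xScales = model@xScales,
              weights = model@weights, xLoadings = model@xLoadings,
              yLoadings = model@yLoadings, ssY = model@ssY,
              sprc = model@sprc, vip = model@vip, meta = model@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nirsort-model"))
    stop("not a serialized discriminant model: ", path)
  asMat <- function(m, p) matrix(unlist(m), nrow = p)
  p <- length(obj$support)
  pp <- obj$preprocess
  pp$index <- as.integer(pp$index)
  new("PLSDAModel", ncomp = as.integer(obj$ncomp),
      support = as.integer(obj$support), wavelengths = obj$wavelengths,
      coefficients = obj$coefficients, intercept = obj$intercept,
      xMeans = obj$xMeans, xScales = obj$xScales,
      weights = asMat(obj$weights, p), xLoadings = asMat(obj$xLoadings, p),
      yLoadings = as.numeric(obj$yLoadings), ssY = as.numeric(obj$ssY),
      sprc = obj$sprc, vip = obj$vip, preprocess = pp,
      meta = as.list(obj$meta))
}
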