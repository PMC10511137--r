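#' @describeIn SpectraSet wavelength axis in nm.
#' @export
setMethod("wavelengths", "SpectraSet",
          function(x, ...) rowData(x)$wavelength)

#' @describeIn HyperCube wavelength axis in nm.
#' @export
setMethod("wavelengths", "HyperCube", function(x, ...) x@wavelengths)

#' @describeIn SpectraSet spectra as a seeds x wavebands matrix.
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x, ...) {
  m <- t(assay(x, "spectra"))
  rownames(m) <- colData(x)$seed_id
  colnames(m) <- as.character(rowData(x)$wavelength)
  m
})

#' @describeIn SpectraSet eligibility labels (+1 / -1 / NA), one per seed.
#' @export
setMethod("seedLabels", "SpectraSet", function(x, ...) colData(x)$label)

#' @describeIn SpectraSet seed identifiers.
#' @export
setMethod("seedIds", "SpectraSet", function(x, ...) colData(x)$seed_id)

#' @describeIn ScoredBatch seed identifiers.
#' @export
setMethod("seedIds", "ScoredBatch", function(x, ...) x@seedIds)

#' @describeIn SpectraSet capture identifier per seed row.
#' @export
setMethod("captureIds", "SpectraSet", function(x, ...) colData(x)$capture)

#' @describeIn SpectraSet preprocessing provenance ([variantSpec()] list).
#' @export
setMethod("preprocessSpec", "SpectraSet",
          function(x, ...) S4Vectors::metadata(x)$preprocess)

#' @describeIn PLSDAModel preprocessing variant the model expects.
#' @export
setMethod("preprocessSpec", "PLSDAModel", function(x, ...) x@preprocess)

#' @describeIn ScoredBatch discriminant scores.
#' @export
setMethod("scores", "ScoredBatch", function(x, ...) x@scores)

#' @describeIn ScoredBatch eligibility labels.
#' @export
setMethod("seedLabels", "ScoredBatch", function(x, ...) x@labels)

#' @describeIn ScoredBatch eligible fraction of the labelled seeds.
#' @export
setMethod("initialPrecision", "ScoredBatch", function(x, ...) {
  lb <- x@labels[!is.na(x@labels)]
  if (!length(lb)) stop("batch carries no labels")
  mean(lb == 1L)
})

#' Number of latent variables of a fitted model
#' @param model a [PLSDAModel-class].
#' @export
nComponents <- function(model) model@ncomp

#' Retained waveband support of a fitted model
#' @param model a [PLSDAModel-class].
#' @param wavelength return nm instead of indices.
#' @export
modelSupport <- function(model, wavelength = FALSE)
  if (wavelength) model@wavelengths else model@support

#' Standardized partial regression coefficients of a fitted model
#' @param model a [PLSDAModel-class].
#' @export
modelSPRC <- function(model) model@sprc

#' Variable importance in projection of a fitted model
#' @param model a [PLSDAModel-class].
#' @export
modelVIP <- function(model) model@vip

#' @describeIn CandidateSet per-candidate validation metrics.
#' @param x a [CandidateSet-class].
#' @export
candidateSummaries <- function(x) x@summaries

#' @describeIn CandidateSet candidate models, in derivation order.
#' @export
candidateModels <- function(x) x@candidates

#' @describeIn CandidateSet ranking permutation, best candidate first.
#' @export
candidateRanking <- function(x) x@ranking

setMethod("show", "SpectraSet", function(object) {
  pp <- preprocessSpec(object)
  cat(sprintf("SpectraSet: %d seeds x %d wavebands (%.0f-%.0f nm)\n",
              ncol(object), nrow(object), min(wavelengths(object)),
              max(wavelengths(object))))
  cat(sprintf("  variant X%d (base=%s, SG=%s, SNV=%s)\n", pp$index, pp$base,
              pp$sg, pp$snv))
  lb <- seedLabels(object)
  if (any(!is.na(lb)))
    cat(sprintf("  labels: %d eligible / %d ineligible / %d unknown\n",
                sum(lb == 1L, na.rm = TRUE), sum(lb == -1L, na.rm = TRUE),
                sum(is.na(lb))))
  cat(sprintf("  captures: %s\n",
              paste(unique(captureIds(object)), collapse = ", ")))
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf(
    "PLSDAModel: %d latent variables, %d wavebands (variant X%d)\n",
    object@ncomp, length(object@support), object@preprocess$index))
})

setMethod("show", "ScoredBatch", function(object) {
  cat(sprintf("ScoredBatch: %d seeds, score range [%.4g, %.4g]\n",
              length(object@scores), min(object@scores),
              max(object@scores)))
  if (any(!is.na(object@labels)))
    cat(sprintf("  iP = %.3f\n", initialPrecision(object)))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidates\n", length(object@candidates)))
  if (length(object@ranking)) {
    best <- object@summaries[object@ranking[1L], , drop = FALSE]
    cat(sprintf("  top-ranked: variant X%d, %d bands, sP=%.3f, AUC-rPR=%.4f\n",
                best$variant, best$nBands, best$sP, best$AUC_rPR))
  }
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube (%s): %d lines x %d samples x %d bands (%.0f-%.0f nm)\n",
              object@kind, d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
})
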