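#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Container for per-seed reflectance (or transformed) spectra
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with
#' wavebands as rows (features) and seeds as columns (samples). The single
#' assay `"spectra"` holds one spectrum per seed; `rowData` carries the
#' wavelength axis in nm; `colData` carries the seed identifier, the
#' eligibility label (+1 eligible, -1 ineligible, `NA` unknown) and the
#' capture identifier (trays are imaged twice, rotated 180 degrees, so each
#' physical seed may appear once per capture). The preprocessing provenance
#' (which of the twelve explanatory-variable variants the matrix represents)
#' lives in `metadata(x)$preprocess`.
#'
#' @seealso [SpectraSet()] constructor, [makeVariant()], [readSpectraTable()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  wl <- rowData(object)$wavelength
  if (is.null(wl))
    return("rowData must contain a 'wavelength' column (nm)")
  if (anyNA(wl) || any(!is.finite(wl)))
    msg <- c(msg, "wavelengths must be finite")
  if (length(wl) > 1L && any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!"spectra" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'spectra' is required")
  cd <- colData(object)
  if (!is.null(cd$label)) {
    bad <- !(cd$label %in% c(-1L, 1L) | is.na(cd$label))
    if (any(bad)) msg <- c(msg, "labels must be +1, -1 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param spectra numeric matrix of spectra, one seed per row, one waveband
#'   per column (the user-facing orientation; stored transposed).
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, one per column of `spectra`.
#' @param labels optional eligibility labels, +1 / -1 / NA, one per seed.
#' @param seedIds optional seed identifiers; defaults to `seed_1 ...`.
#' @param capture optional capture identifiers (e.g. 1 and 2 for the two
#'   rotated tray images); defaults to 1.
#' @param preprocess provenance list as returned by [variantSpec()];
#'   defaults to variant 1 (raw reflectance).
#' @return a [SpectraSet-class] object.
#' @examples
#' x <- SpectraSet(matrix(runif(10), 2, 5), wavelengths = seq(1000, 1400, 100))
#' wavelengths(x)
#' @export
SpectraSet <- function(spectra, wavelengths, labels = NULL, seedIds = NULL,
                       capture = NULL, preprocess = variantSpec(1L)) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("ncol(spectra) must equal length(wavelengths)")
  n <- nrow(spectra)
  if (is.null(seedIds)) seedIds <- paste0("seed_", seq_len(n))
  if (is.null(capture)) capture <- rep(1L, n)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  a <- t(spectra)
  dimnames(a) <- list(NULL, NULL)
  se <- SummarizedExperiment(
    assays = SimpleList(spectra = a),
    rowData = DataFrame(wavelength = as.numeric(wavelengths)),
    colData = DataFrame(seed_id = as.character(seedIds),
                        label = labels,
                        capture = as.integer(capture)))
  S4Vectors::metadata(se)$preprocess <- preprocess
  new("SpectraSet", se)
}

#' Fitted (sparse) PLS-DA discriminant model
#'
#' Stores everything needed to score new seeds and to interpret the model:
#' the retained waveband support, regression coefficients on that support,
#' per-component weights/loadings for VIP, the standardized partial
#' regression coefficients (SPRC) and VIP per retained waveband, and the
#' preprocessing variant the model expects its input in.
#'
#' @slot ncomp number of latent variables.
#' @slot support integer indices of the retained wavebands within the
#'   training waveband axis.
#' @slot wavelengths nm of the retained wavebands.
#' @slot coefficients raw regression coefficients, one per retained band.
#' @slot intercept scalar intercept of the discriminant score.
#' @slot xMeans training column means of the retained bands.
#' @slot xScales training column scales (all 1 unless scaling was requested).
#' @slot weights p x a matrix of normalized PLS weight vectors.
#' @slot xLoadings p x a matrix of X loadings.
#' @slot yLoadings per-component y loadings.
#' @slot ssY per-component explained y sum of squares (drives VIP).
#' @slot sprc standardized partial regression coefficients per retained band.
#' @slot vip variable importance in projection per retained band.
#' @slot preprocess provenance list ([variantSpec()]) of the expected input.
#' @slot meta free-form training metadata (sample sizes, CV choice, seed).
#' @export
setClass("PLSDAModel",
  representation(ncomp = "integer", support = "integer",
                 wavelengths = "numeric", coefficients = "numeric",
                 intercept = "numeric", xMeans = "numeric",
                 xScales = "numeric", weights = "matrix",
                 xLoadings = "matrix", yLoadings = "numeric",
                 ssY = "numeric", sprc = "numeric", vip = "numeric",
                 preprocess = "list", meta = "list"))

setValidity("PLSDAModel", function(object) {
  msg <- character()
  p <- length(object@support)
  if (length(object@coefficients) != p)
    msg <- c(msg, "one coefficient per retained waveband required")
  if (length(object@wavelengths) != p)
    msg <- c(msg, "one wavelength per retained waveband required")
  if (object@ncomp < 1L) msg <- c(msg, "ncomp must be >= 1")
  if (length(object@vip) && any(object@vip < 0))
    msg <- c(msg, "VIP must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Discriminant scores for a batch of seeds
#'
#' Holds the continuous discriminant score of each seed and, when known, its
#' eligibility label. All sorting metrics ([sortingCurve()],
#' [standardCondition()], [standardSummary()]) consume this class.
#'
#' @slot scores numeric discriminant scores, higher = more likely eligible.
#' @slot labels integer +1 / -1 labels, or NA for prediction-only batches.
#' @slot seedIds character seed identifiers.
#' @export
setClass("ScoredBatch",
  representation(scores = "numeric", labels = "integer",
                 seedIds = "character"))

setValidity("ScoredBatch", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(object@labels) != n) msg <- c(msg, "one label slot per score")
  if (!all(object@labels %in% c(-1L, 1L) | is.na(object@labels)))
    msg <- c(msg, "labels must be +1, -1 or NA")
  if (length(object@seedIds) != n) msg <- c(msg, "one id per score")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoredBatch
#'
#' @param scores numeric discriminant scores.
#' @param labels +1 / -1 eligibility labels, or NULL when unknown.
#' @param seedIds optional identifiers.
#' @return a [ScoredBatch-class] object.
#' @examples
#' b <- ScoredBatch(c(5, 4, 3, 2, 1), c(1, 1, 1, -1, -1))
#' initialPrecision(b)
#' @export
ScoredBatch <- function(scores, labels = NULL, seedIds = NULL) {
  n <- length(scores)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  if (is.null(seedIds)) seedIds <- paste0("seed_", seq_len(n))
  new("ScoredBatch", scores = as.numeric(scores),
      labels = as.integer(labels), seedIds = as.character(seedIds))
}

#' Set of candidate discriminant models with validation metrics
#'
#' @slot candidates list of [PLSDAModel-class] objects.
#' @slot summaries data.frame of per-candidate validation metrics (one row
#'   per candidate: variant, nBands, iP, sLST, sP, sA, Amax, AUC_PR,
#'   AUC_rPR).
#' @slot ranking integer permutation of the candidates, best first.
#' @export
setClass("CandidateSet",
  representation(candidates = "list", summaries = "data.frame",
                 ranking = "integer"))

setValidity("CandidateSet", function(object) {
  msg <- character()
  k <- length(object@candidates)
  if (nrow(object@summaries) != k)
    msg <- c(msg, "one summary row per candidate required")
  if (length(object@ranking) &&
      !identical(sort(object@ranking), seq_len(k)))
    msg <- c(msg, "ranking must be a permutation of the candidates")
  if (length(msg)) msg else TRUE
})

#' In-memory hyperspectral cube
#'
#' A lines x samples x bands array of raw counts or calibrated reflectance,
#' with its wavelength axis. Sizes are arbitrary; the reference push-broom
#' instrument produces 320-sample lines with 256 bands.
#'
#' @slot data numeric array, dim = c(lines, samples, bands).
#' @slot wavelengths nm per band.
#' @slot kind "raw" (sensor counts) or "reflectance" (calibrated).
#' @export
setClass("HyperCube",
  representation(data = "array", wavelengths = "numeric",
                 kind = "character"))

setValidity("HyperCube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
  else if (d[3] != length(object@wavelengths))
    msg <- c(msg, "band count must match the wavelength list")
  if (!object@kind %in% c("raw", "reflectance"))
    msg <- c(msg, "kind must be 'raw' or 'reflectance'")
  if (length(msg)) msg else TRUE
})

#' Construct a HyperCube
#'
#' @param data lines x samples x bands array.
#' @param wavelengths nm per band.
#' @param kind "raw" or "reflectance".
#' @return a [HyperCube-class] object.
#' @export
HyperCube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      kind = kind)
}
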