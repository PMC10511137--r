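#' @rdname SpectraSet
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("wavelengths", function(x, ...) standardGeneric("wavelengths"))

#' @rdname SpectraSet
#' @export
setGeneric("spectraMatrix", function(x, ...) standardGeneric("spectraMatrix"))

#' @rdname SpectraSet
#' @export
setGeneric("seedLabels", function(x, ...) standardGeneric("seedLabels"))

#' @rdname SpectraSet
#' @export
setGeneric("seedIds", function(x, ...) standardGeneric("seedIds"))

#' @rdname SpectraSet
#' @export
setGeneric("captureIds", function(x, ...) standardGeneric("captureIds"))

#' @rdname SpectraSet
#' @export
setGeneric("preprocessSpec", function(x, ...) standardGeneric("preprocessSpec"))

#' Discriminant scores of an object
#' @param x an object holding scores.
#' @param ... further arguments for methods.
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' Score seeds with a fitted discriminant model
#'
#' @param model a [PLSDAModel-class].
#' @param x a [SpectraSet-class] (its preprocessing provenance must match the
#'   model's) or a bare numeric matrix covering the model support.
#' @param ... further arguments for methods.
#' @return a [ScoredBatch-class]; labels are carried over when `x` has them.
#' @export
setGeneric("scoreSeeds", function(model, x, ...) standardGeneric("scoreSeeds"))

#' Sorting curve of a scored batch
#'
#' Precision, recall, accuracy and relative precision as functions of the
#' lower score threshold (LST); see [sortingCurve,ScoredBatch-method].
#' @param x a [ScoredBatch-class] with labels.
#' @param ... further arguments for methods.
#' @export
setGeneric("sortingCurve", function(x, ...) standardGeneric("sortingCurve"))

#' Standard sorting condition of a scored batch
#'
#' The operating point where the seed recovery rate equals the initial
#' eligibility rate iP; see [standardCondition,ScoredBatch-method].
#' @param x a [ScoredBatch-class] with labels.
#' @param ... further arguments for methods.
#' @export
setGeneric("standardCondition",
           function(x, ...) standardGeneric("standardCondition"))

#' Full metric summary of a scored batch
#'
#' iP, sLST, sP, sA, Amax, AUC-PR and AUC-rPR in one row; see
#' [standardSummary,ScoredBatch-method].
#' @param x a [ScoredBatch-class] with labels.
#' @param ... further arguments for methods.
#' @export
setGeneric("standardSummary",
           function(x, ...) standardGeneric("standardSummary"))

#' Initial precision (eligibility rate before sorting) of a batch
#' @param x a [ScoredBatch-class] with labels.
#' @param ... further arguments for methods.
#' @export
setGeneric("initialPrecision",
           function(x, ...) standardGeneric("initialPrecision"))
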