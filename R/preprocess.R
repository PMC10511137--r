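## Chemometric preprocessing: the twelve explanatory-variable variants
## X1..X12 = {R, 1/R, -log10 R} x {none, SG, SNV, SG+SNV}.

.BASES <- c("reflectance", "reciprocal", "pseudo_absorbance")

#' Decode a preprocessing variant index
#'
#' The twelve candidate explanatory-variable spectra are indexed in three
#' blocks of four by base transform: X1-X4 raw reflectance R, X5-X8
#' reciprocal 1/R, X9-X12 pseudo-absorbance -log10(R); within each block the
#' order is plain, +SG, +SNV, +SG+SNV. X1 is raw reflectance.
#'
#' @param index integer 1-12.
#' @return list with `index`, `base`, `sg`, `snv` and `order` ("sg_first",
#'   recorded so the SG/SNV composition order is explicit provenance).
#' @examples
#' variantSpec(6)   # reciprocal + SG
#' @export
variantSpec <- function(index) {
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L || index > 12L)
    stop("variant index must be a single integer in 1..12")
  base <- .BASES[(index - 1L) %/% 4L + 1L]
  slot <- (index - 1L) %% 4L   # 0 plain, 1 sg, 2 snv, 3 sg+snv
  list(index = index, base = base,
       sg = slot %in% c(1L, 3L), snv = slot %in% c(2L, 3L),
       order = "sg_first")
}

#' Encode (base, sg, snv) as a variant index
#'
#' Inverse of [variantSpec()].
#' @param base one of `"reflectance"`, `"reciprocal"`, `"pseudo_absorbance"`.
#' @param sg logical, Savitzky-Golay smoothing applied.
#' @param snv logical, standard normal variate transform applied.
#' @export
variantIndex <- function(base, sg, snv) {
  b <- match(match.arg(base, .BASES), .BASES)
  slot <- if (!sg && !snv) 0L else if (sg && !snv) 1L else
    if (!sg && snv) 2L else 3L
  as.integer(4L * (b - 1L) + slot + 1L)
}

#' Base transform of a reflectance spectrum
#'
#' Identity, elementwise reciprocal 1/R, or pseudo-absorbance -log10(R).
#' Reflectance is clipped from below at `clip` before reciprocal/log (a
#' warning reports how many values were clipped); values that are still
#' non-positive are a domain error naming the offending band.
#'
#' @param values numeric reflectance vector or seeds x bands matrix.
#' @param base transform kind.
#' @param clip lower clip applied before reciprocal / log.
#' @return transformed values, same shape as the input.
#' @examples
#' baseTransform(c(0.5, 0.25), "reciprocal")      # 2, 4
#' baseTransform(c(1, 0.1), "pseudo_absorbance")  # 0, 1
#' @export
baseTransform <- function(values, base = .BASES, clip = 1e-6) {
  base <- match.arg(base)
  if (base == "reflectance") return(values)
  bad <- which(values <= 0)
  if (length(bad)) {
    idx <- if (is.matrix(values)) unique(col(values)[bad]) else bad
    stop(sprintf("non-positive reflectance at band(s) %s; cannot apply %s",
                 paste(utils::head(idx, 5L), collapse = ", "), base))
  }
  nclip <- sum(values < clip)
  if (nclip > 0) {
    warning(sprintf("%d reflectance value(s) clipped to %g before %s",
                    nclip, clip, base))
    values <- pmax(values, clip)
  }
  switch(base, reciprocal = 1 / values, pseudo_absorbance = -log10(values))
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing (zeroth derivative), default
#' window 5 and order 3. The first and last `(window - 1)/2` bands are
#' smoothed with the filter's least-squares endpoint fits, so the output
#' length equals the input length and any polynomial of degree <= `order`
#' passes through unchanged everywhere (not only at interior points).
#'
#' @param values numeric vector or seeds x bands matrix (filtered per row).
#' @param window odd filter length.
#' @param order polynomial order, < window.
#' @return smoothed values, same shape.
#' @export
sgFilter <- function(values, window = 5L, order = 3L) {
  if (is.matrix(values))
    return(t(apply(values, 1L, sgFilter, window = window, order = order)))
  n <- length(values)
  if (n < window)
    stop(sprintf("spectrum has %d bands; at least %d required", n, window))
  as.numeric(signal::sgolayfilt(values, p = order, n = window))
}

#' Standard normal variate transform
#'
#' Per-spectrum standardization: subtract the spectrum mean and divide by
#' its standard deviation, computed over the (already range-restricted)
#' bands. Output has mean 0 and sd 1.
#'
#' @param values numeric vector or seeds x bands matrix (per row).
#' @return standardized values, same shape.
#' @export
snvTransform <- function(values) {
  if (is.matrix(values)) {
    m <- rowMeans(values)
    s <- apply(values, 1L, stats::sd)
    if (any(s == 0)) stop("degenerate (zero-variance) spectrum; SNV undefined")
    return((values - m) / s)
  }
  s <- stats::sd(values)
  if (is.na(s) || s == 0) stop("degenerate (zero-variance) spectrum; SNV undefined")
  (values - mean(values)) / s
}

#' Restrict a SpectraSet to the valid spectral range
#'
#' @param x a [SpectraSet-class].
#' @param range closed wavelength interval in nm, default 980-2200 (which
#'   carries 201 bands on the reference 6.1 nm-pitch grid; other grids are
#'   accepted with a warning when the count differs from 201).
#' @export
restrictRange <- function(x, range = c(980, 2200)) {
  wl <- wavelengths(x)
  keep <- wl >= range[1] & wl <= range[2]
  if (!any(keep)) stop("no wavebands inside the valid range")
  out <- x[keep, ]
  if (sum(keep) != 201L && abs(mean(diff(wl)) - 6.1) < 0.2)
    warning(sprintf("valid range carries %d bands (201 expected on the reference grid)",
                    sum(keep)))
  out
}

#' Build one explanatory-variable variant
#'
#' Applies, in order: the base transform, Savitzky-Golay smoothing when
#' flagged, restriction to the valid range, and SNV when flagged. SG before
#' SNV is the default composition order (denoise, then baseline-correct);
#' set `sgFirst = FALSE` to flip it, in which case SNV is computed on the
#' range-restricted unsmoothed bands first.
#'
#' @param x a raw-reflectance [SpectraSet-class] (variant 1).
#' @param spec variant spec from [variantSpec()], or an index 1-12.
#' @param range valid range passed to [restrictRange()].
#' @param sgFirst apply SG before SNV when both are flagged.
#' @param window,order Savitzky-Golay parameters.
#' @return a [SpectraSet-class] carrying the variant's provenance.
#' @export
makeVariant <- function(x, spec, range = c(980, 2200), sgFirst = TRUE,
                        window = 5L, order = 3L) {
  if (is.numeric(spec)) spec <- variantSpec(spec)
  m <- spectraMatrix(x)
  m <- baseTransform(m, spec$base)
  apply_sg <- function(mm) sgFilter(mm, window = window, order = order)
  if (spec$sg && sgFirst) m <- apply_sg(m)
  tmp <- SpectraSet(m, wavelengths(x), seedLabels(x), seedIds(x),
                    captureIds(x))
  tmp <- restrictRange(tmp, range)
  m <- spectraMatrix(tmp)
  if (spec$snv) m <- snvTransform(m)
  if (spec$sg && !sgFirst) m <- apply_sg(m)
  spec$order <- if (sgFirst) "sg_first" else "snv_first"
  SpectraSet(m, wavelengths(tmp), seedLabels(x), seedIds(x), captureIds(x),
             preprocess = spec)
}

#' Build all twelve explanatory-variable variants
#'
#' @inheritParams makeVariant
#' @param indices which variants to build (default all twelve).
#' @return named list `X1` ... `X12` of [SpectraSet-class] objects.
#' @export
makeAllVariants <- function(x, indices = 1:12, range = c(980, 2200),
                            sgFirst = TRUE) {
  out <- lapply(indices, function(i)
    makeVariant(x, variantSpec(i), range = range, sgFirst = sgFirst))
  names(out) <- paste0("X", indices)
  out
}
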