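## Delimited-text I/O for per-seed labelled spectra tables.
## Layout: seed_id, label, capture, then one column per waveband named by
## its wavelength in nm.

#' Write a SpectraSet as a delimited text table
#'
#' @param x a [SpectraSet-class].
#' @param path output file.
#' @param sep field separator ("," for CSV, "\\t" for TSV).
#' @param digits significant digits written; round-trips bit-exactly for the
#'   precision written.
#' @export
writeSpectraTable <- function(x, path, sep = ",", digits = 10L) {
  m <- spectraMatrix(x)
  df <- data.frame(seed_id = seedIds(x), label = seedLabels(x),
                   capture = captureIds(x),
                   signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:3)] <- format(wavelengths(x), trim = TRUE, digits = 12)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-seed spectra table
#'
#' Expects a header row with `seed_id`, `label`, `capture` (label/capture
#' optional) followed by wavelength column names in nm.
#'
#' @param path input file.
#' @param sep field separator; guessed from the extension when NULL.
#' @param preprocess provenance to attach (default raw reflectance).
#' @return a [SpectraSet-class].
#' @export
readSpectraTable <- function(path, sep = NULL, preprocess = variantSpec(1L)) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"seed_id" %in% names(df)) stop("spectra table lacks a seed_id column")
  meta <- intersect(c("seed_id", "label", "capture"), names(df))
  wlcols <- setdiff(names(df), meta)
  wl <- suppressWarnings(as.numeric(wlcols))
  if (anyNA(wl)) stop("non-numeric wavelength column name(s): ",
                      paste(wlcols[is.na(wl)], collapse = ", "))
  m <- as.matrix(df[, wlcols, drop = FALSE])
  if (anyNA(m)) stop("missing values in spectra table")
  SpectraSet(m, wl,
             labels = if ("label" %in% meta) df$label else NULL,
             seedIds = df$seed_id,
             capture = if ("capture" %in% meta) df$capture else NULL,
             preprocess = preprocess)
}
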