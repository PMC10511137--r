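## ENVI-dialect hyperspectral cube I/O, reflectance calibration, seed
## segmentation and per-seed spectrum extraction.

.ENVI_TYPES <- list(`1` = list(what = "integer", size = 1L, signed = FALSE),
                    `2` = list(what = "integer", size = 2L, signed = TRUE),
                    `3` = list(what = "integer", size = 4L, signed = TRUE),
                    `4` = list(what = "numeric", size = 4L, signed = TRUE),
                    `5` = list(what = "numeric", size = 8L, signed = TRUE),
                    `12` = list(what = "integer", size = 2L, signed = FALSE))

.parseENVIHeader <- function(header) {
  txt <- readLines(header, warn = FALSE)
  if (!length(txt) || !grepl("^\\s*ENVI", txt[1L]))
    stop("not an ENVI header: ", header)
  fields <- list()
  buf <- ""
  for (ln in txt[-1L]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    nOpen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nClose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nOpen > nClose) next              # { ... } block spans lines
    if (!grepl("=", buf, fixed = TRUE)) { buf <- ""; next }
    kv <- regmatches(buf, regexec("^([^=]+?)\\s*=\\s*(.*)$", buf))[[1L]]
    key <- tolower(trimws(kv[2L])); val <- trimws(kv[3L])
    if (startsWith(val, "{"))
      val <- trimws(strsplit(gsub("[{}]", "", val), ",")[[1L]])
    fields[[key]] <- val
    buf <- ""
  }
  fields
}

#' Read an ENVI-style hyperspectral cube
#'
#' Accepts BSQ, BIL and BIP interleaves; the in-memory layout is always
#' (line, sample, band). The header must declare `samples`, `lines`,
#' `bands`, `data type`, `interleave` and a `wavelength` list.
#'
#' @param path binary cube file.
#' @param header header file; defaults to `path` + ".hdr".
#' @param kind "raw" or "reflectance" tag for the result.
#' @return a [HyperCube-class].
#' @export
readENVI <- function(path, header = paste0(path, ".hdr"),
                     kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  h <- .parseENVIHeader(header)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header lacks field(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(h$wavelength)) stop("ENVI header lacks wavelengths")
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  wl <- as.numeric(h$wavelength)
  if (length(wl) != nb) stop("wavelength list does not match band count")
  tp <- .ENVI_TYPES[[h[["data type"]]]]
  if (is.null(tp)) stop("unsupported ENVI data type: ", h[["data type"]])
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1")
    "big" else "little"
  nvals <- ns * nl * nb
  if (file.info(path)$size < nvals * tp$size)
    stop(sprintf("cube file truncated: %d bytes expected, %d found",
                 nvals * tp$size, file.info(path)$size))
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, tp$what, n = nvals, size = tp$size, signed = tp$signed,
               endian = endian)
  il <- tolower(h$interleave)
  a <- switch(il,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", il))
  HyperCube(a, wl, kind)
}

#' Write a HyperCube in the ENVI dialect
#'
#' @param cube a [HyperCube-class].
#' @param path binary cube file to write; the header goes to `path` + ".hdr".
#' @param interleave "bsq", "bil" or "bip".
#' @param dataType ENVI data-type code (4 = float32, 5 = float64).
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                      dataType = 4L) {
  interleave <- match.arg(interleave)
  tp <- .ENVI_TYPES[[as.character(dataType)]]
  if (is.null(tp)) stop("unsupported ENVI data type: ", dataType)
  d <- dim(cube@data)
  a <- switch(interleave,
    bsq = aperm(cube@data, c(2L, 1L, 3L)),
    bil = aperm(cube@data, c(2L, 3L, 1L)),
    bip = aperm(cube@data, c(3L, 2L, 1L)))
  con <- file(path, "wb")
  writeBin(if (tp$what == "integer") as.integer(a) else as.numeric(a),
           con, size = tp$size, endian = "little")
  close(con)
  hdr <- c("ENVI",
           paste0("samples = ", d[2L]), paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]), "header offset = 0",
           paste0("data type = ", dataType),
           paste0("interleave = ", interleave), "byte order = 0",
           paste0("wavelength = {",
                  paste(format(cube@wavelengths, trim = TRUE, digits = 10),
                        collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Calibrate raw counts to absolute reflectance
#'
#' Per-pixel-per-band linear interpolation between a darkfield image (0%
#' reflectance) and an image of a diffuse reflectance standard:
#' `reflectance = whiteReflectance * (raw - dark) / (white - dark)`, clipped
#' to `[0, clipMax]` (specular glints exceed 1; clipping is reported).
#'
#' @param raw a raw-counts [HyperCube-class].
#' @param dark,white reference images: arrays broadcastable to the cube
#'   (full lines x samples x bands arrays, samples x bands matrices for a
#'   push-broom column profile, or scalars).
#' @param whiteReflectance nominal reflectance of the standard (0.99).
#' @param clipMax upper reflectance clip.
#' @return a reflectance [HyperCube-class].
#' @export
calibrateReflectance <- function(raw, dark, white, whiteReflectance = 0.99,
                                 clipMax = 1.2) {
  if (raw@kind != "raw") stop("cube is already calibrated")
  d <- dim(raw@data)
  expand <- function(r) {
    if (is.array(r) && length(dim(r)) == 3L) return(r)
    if (is.matrix(r))   # samples x bands profile, constant over lines
      return(aperm(array(rep(r, each = d[1L]), d), c(1L, 2L, 3L)))
    array(r, d)
  }
  dk <- expand(dark); wh <- expand(white)
  den <- wh - dk
  if (any(den <= 0))
    stop("calibration error: white <= dark at some pixel/band")
  refl <- whiteReflectance * (raw@data - dk) / den
  nclip <- sum(refl > clipMax)
  if (nclip > 0)
    message(sprintf("%d reflectance value(s) clipped to %.2f", nclip, clipMax))
  refl[refl < 0] <- 0
  refl[refl > clipMax] <- clipMax
  HyperCube(refl, raw@wavelengths, "reflectance")
}

#' Segment seed-occupied pixels
#'
#' Foreground = pixels whose mean reflectance over a band window exceeds a
#' threshold (Otsu on the mean image by default) against the matt-black
#' tray; 4-connected components with at least `minArea` pixels become seed
#' regions, ordered row-major by centroid.
#'
#' @param cube a reflectance [HyperCube-class].
#' @param bandWindow wavelength interval (nm) averaged for the foreground
#'   image; default the full range.
#' @param threshold "otsu" or a numeric reflectance cutoff.
#' @param minArea minimum region area in pixels.
#' @param minContrast minimum spread of the mean-reflectance image for Otsu
#'   thresholding to be attempted; a flatter image (a tray with no seeds,
#'   where Otsu would threshold pure noise) yields zero regions.
#' @return list with `regions` (data.frame: id, centroid_line,
#'   centroid_sample, area; 0-based coordinates) and `labels` (lines x
#'   samples integer matrix, 0 = background). No foreground yields zero
#'   regions, not an error.
#' @export
segmentSeeds <- function(cube, bandWindow = NULL, threshold = "otsu",
                         minArea = 20L, minContrast = 0.05) {
  if (cube@kind != "reflectance") stop("cube must be calibrated first")
  wl <- cube@wavelengths
  bands <- if (is.null(bandWindow)) seq_along(wl)
           else which(wl >= bandWindow[1L] & wl <= bandWindow[2L])
  if (!length(bands)) stop("band window selects no bands")
  img <- apply(cube@data[, , bands, drop = FALSE], c(1L, 2L), mean)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) < minContrast) Inf
    else EBImage::otsu(EBImage::Image((img - rng[1L]) / diff(rng)),
                       range = c(0, 1)) * diff(rng) + rng[1L]
  } else as.numeric(threshold)
  mask <- img > thr
  empty <- list(regions = data.frame(id = integer(), centroid_line = numeric(),
                                     centroid_sample = numeric(),
                                     area = integer()),
                labels = matrix(0L, nrow(img), ncol(img)))
  if (!any(mask)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  tab <- tabulate(lab)
  keepIds <- which(tab >= minArea)
  if (!length(keepIds)) return(empty)
  lab[!(lab %in% keepIds)] <- 0L
  cl <- vapply(keepIds, function(i) mean(row(lab)[lab == i]) - 1, 0)
  cs <- vapply(keepIds, function(i) mean(col(lab)[lab == i]) - 1, 0)
  o <- order(round(cl), cs)   # row-major by centroid
  newLab <- matrix(0L, nrow(lab), ncol(lab))
  for (j in seq_along(o)) newLab[lab == keepIds[o[j]]] <- j
  list(regions = data.frame(id = seq_along(o), centroid_line = cl[o],
                            centroid_sample = cs[o],
                            area = as.integer(tab[keepIds][o])),
       labels = newLab)
}

#' Extract per-seed mean spectra from a cube
#'
#' One spectrum per region: the unweighted mean over the region's pixels,
#' band by band.
#'
#' @param cube a reflectance [HyperCube-class].
#' @param segmentation result of [segmentSeeds()] (or a compatible list with
#'   a `labels` matrix and `regions` table).
#' @return a raw-reflectance [SpectraSet-class], rows ordered like the
#'   regions.
#' @export
extractSeedSpectra <- function(cube, segmentation) {
  lab <- segmentation$labels
  ids <- segmentation$regions$id
  if (!length(ids)) stop("no regions to extract")
  d <- dim(cube@data)
  flat <- matrix(cube@data, d[1L] * d[2L], d[3L])
  m <- t(vapply(ids, function(i) {
    px <- which(lab == i)
    if (!length(px)) stop("empty region: ", i)
    colMeans(flat[px, , drop = FALSE])
  }, numeric(d[3L])))
  SpectraSet(m, cube@wavelengths, seedIds = paste0("region_", ids))
}

#' Render a pseudo-color discriminant score map
#'
#' Paints every seed region with a color mapped from its relative score
#' (rank-scaled by default, so the palette spans the batch); the background
#' is the grayscale mean-reflectance image.
#'
#' @param cube a reflectance [HyperCube-class].
#' @param segmentation result of [segmentSeeds()].
#' @param scores one score per region.
#' @param palette color vector, low to high.
#' @param rankScale map by rank (default) or by linear score value.
#' @param file optional PNG path to write.
#' @return invisibly, a lines x samples x 3 RGB array in \[0, 1\].
#' @export
renderScoreMap <- function(cube, segmentation, scores,
                           palette = grDevices::hcl.colors(256L, "viridis"),
                           rankScale = TRUE, file = NULL) {
  regions <- segmentation$regions
  if (length(scores) != nrow(regions))
    stop("one score per region required")
  img <- apply(cube@data, c(1L, 2L), mean)
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1L]) / diff(rng) else img * 0
  out <- array(g, c(dim(g), 3L))
  if (nrow(regions)) {
    rel <- if (length(scores) == 1L || diff(range(scores)) == 0)
      rep(0.5, length(scores))
    else if (rankScale) (rank(scores) - 1) / (length(scores) - 1)
    else (scores - min(scores)) / diff(range(scores))
    cidx <- 1L + round(rel * (length(palette) - 1L))
    rgb <- grDevices::col2rgb(palette[cidx]) / 255
    for (j in seq_len(nrow(regions))) {
      px <- which(segmentation$labels == regions$id[j])
      npx <- length(g)
      out[px] <- rgb[1L, j]
      out[px + npx] <- rgb[2L, j]
      out[px + 2L * npx] <- rgb[3L, j]
    }
  }
  if (!is.null(file)) png::writePNG(out, file)
  invisible(out)
}
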