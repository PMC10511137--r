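## Simulation module: (a) hypothetical class-conditional normal score models
## with an analytic oracle for the standard condition; (b) synthetic labelled
## seed spectra with planted informative wavebands, paired duplicate
## captures, and optional hypercubes, all with known ground truth.

#' Hypothetical discriminant model and seed batch specification
#'
#' The canonical thought-experiment setup: a discriminant model scores
#' eligible seeds as draws from Normal(muOk, sigma) and ineligible seeds
#' from Normal(muNg, sigma). The named presets are NP (near-perfect, means
#' +/-1), MP (medium, +/-0.2) and PP (poor, +/-0.05), all with sd 0.25
#' (the dispersion parameter is a standard deviation). Batch sizes default
#' to the canonical 65,535-seed batches: 52,428/13,107 at iP = 0.8 and
#' 39,321/26,214 at iP = 0.6.
#'
#' @param name "NP", "MP" or "PP" (or "custom" with explicit means).
#' @param iP initial eligibility rate selecting the preset batch (0.8 or
#'   0.6), ignored when `nOk`/`nNg` are given.
#' @param muOk,muNg class score means; preset by `name` unless given.
#' @param sigma class score sd.
#' @param nOk,nNg class counts.
#' @return a `hypotheticalModel` spec (list).
#' @examples
#' hypotheticalModel("MP", iP = 0.8)
#' @export
hypotheticalModel <- function(name = c("NP", "MP", "PP", "custom"), iP = 0.8,
                              muOk = NULL, muNg = NULL, sigma = 0.25,
                              nOk = NULL, nNg = NULL) {
  name <- match.arg(name)
  mus <- switch(name, NP = c(1, -1), MP = c(0.2, -0.2), PP = c(0.05, -0.05),
                custom = c(NA, NA))
  if (is.null(muOk)) muOk <- mus[1L]
  if (is.null(muNg)) muNg <- mus[2L]
  if (anyNA(c(muOk, muNg))) stop("custom models need muOk and muNg")
  if (is.null(nOk) || is.null(nNg)) {
    if (isTRUE(all.equal(iP, 0.8))) { nOk <- 52428L; nNg <- 13107L }
    else if (isTRUE(all.equal(iP, 0.6))) { nOk <- 39321L; nNg <- 26214L }
    else { nOk <- round(iP * 65535); nNg <- 65535L - nOk }
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (nOk + nNg <= 0) stop("batch must contain seeds")
  structure(list(name = name, muOk = muOk, muNg = muNg, sigma = sigma,
                 nOk = as.integer(nOk), nNg = as.integer(nNg),
                 iP = nOk / (nOk + nNg)),
            class = "hypotheticalModel")
}

#' Simulate discriminant scores from a hypothetical model
#'
#' @param spec a [hypotheticalModel()] spec.
#' @param seed RNG seed; the draw is deterministic given it.
#' @return a labelled [ScoredBatch-class] with `nOk + nNg` seeds.
#' @export
simulateHypotheticalScores <- function(spec, seed = 1L) {
  set.seed(seed)
  sc <- c(stats::rnorm(spec$nOk, spec$muOk, spec$sigma),
          stats::rnorm(spec$nNg, spec$muNg, spec$sigma))
  ScoredBatch(sc, c(rep(1L, spec$nOk), rep(-1L, spec$nNg)))
}

#' Analytic standard condition for normal class-conditional scores
#'
#' Independent oracle for the simulated standard condition: sLST solves
#' `iP * S_ok(t) + (1 - iP) * S_ng(t) = iP` (S = normal survival function),
#' i.e. the threshold recovering exactly the fraction iP of all seeds, by
#' bracketed root-finding; then `sP = S_ok(sLST)`.
#'
#' @param spec a [hypotheticalModel()] spec.
#' @param tol root-finding tolerance.
#' @return list with `sLST` and `sP`.
#' @export
analyticStandardCondition <- function(spec, tol = 1e-10) {
  iP <- spec$iP
  f <- function(t)
    iP * stats::pnorm(t, spec$muOk, spec$sigma, lower.tail = FALSE) +
    (1 - iP) * stats::pnorm(t, spec$muNg, spec$sigma, lower.tail = FALSE) - iP
  lo <- min(spec$muOk, spec$muNg) - 12 * spec$sigma
  hi <- max(spec$muOk, spec$muNg) + 12 * spec$sigma
  if (f(lo) * f(hi) > 0) stop("no root in bracket")
  t <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  list(sLST = t,
       sP = stats::pnorm(t, spec$muOk, spec$sigma, lower.tail = FALSE))
}

#' The six canonical thought-experiment rows
#'
#' NP/MP/PP applied to the 80%- and 60%-iP batches, in table order.
#' @return list of six [hypotheticalModel()] specs.
#' @export
hypotheticalGrid <- function() {
  out <- list()
  for (ip in c(0.8, 0.6))
    for (nm in c("NP", "MP", "PP"))
      out[[paste0(nm, "_iP", 100 * ip)]] <- hypotheticalModel(nm, iP = ip)
  out
}

#' Specification for synthetic labelled seed spectra
#'
#' Emulates the structure of per-seed NIR reflectance data: a smooth shared
#' base curve, per-seed baseline variation (offset and slope, as scatter and
#' tilt differences between seeds produce), class-dependent Gaussian
#' absorption dips at a handful of informative wavebands (ineligible seeds
#' absorb `effectSize` more deeply), iid measurement noise, and a second
#' duplicate capture of every seed perturbed by capture-level noise. It does
#' not emulate crop-specific waveforms, detector nonlinearity, or spatial
#' within-seed heterogeneity.
#'
#' @param nSeeds number of physical seeds.
#' @param iP eligible fraction; assignment is stratified so the realized
#'   fraction is `round(iP * nSeeds) / nSeeds` exactly.
#' @param wavelengths band grid in nm (default 201 bands, 980-2200).
#' @param informativeBands indices of the planted class-informative bands
#'   (defaults near 1200, 1730 and 1920 nm, the classic CH2/protein
#'   absorption regions).
#' @param effectSize extra absorption depth (reflectance units) of
#'   ineligible seeds at the informative bands.
#' @param featureSd width (in bands) of each Gaussian dip.
#' @param noiseSd iid per-band measurement noise sd.
#' @param baselineSd sd of the per-seed additive baseline offset.
#' @param slopeSd sd of the per-seed baseline slope (per full range).
#' @param captureNoiseSd sd of the capture-level perturbation.
#' @return a `syntheticSpectraSpec` list.
#' @export
syntheticSpectraSpec <- function(nSeeds = 400L, iP = 0.8,
                                 wavelengths = seq(980, 2200,
                                                   length.out = 201L),
                                 informativeBands = NULL,
                                 effectSize = 0.03, featureSd = 1.5,
                                 noiseSd = 0.01, baselineSd = 0.02,
                                 slopeSd = 0.01, captureNoiseSd = 0.005) {
  if (iP <= 0 || iP >= 1) stop("iP must lie strictly inside (0, 1)")
  if (is.null(informativeBands))
    informativeBands <- vapply(c(1200, 1730, 1920),
                               function(t) which.min(abs(wavelengths - t)),
                               0L)
  if (any(informativeBands < 1L | informativeBands > length(wavelengths)))
    stop("informative bands outside the wavelength grid")
  structure(list(nSeeds = as.integer(nSeeds), iP = iP,
                 wavelengths = wavelengths,
                 informativeBands = as.integer(informativeBands),
                 effectSize = effectSize, featureSd = featureSd,
                 noiseSd = noiseSd, baselineSd = baselineSd,
                 slopeSd = slopeSd, captureNoiseSd = captureNoiseSd),
            class = "syntheticSpectraSpec")
}

.baseCurve <- function(wl) {
  u <- (wl - min(wl)) / diff(range(wl))
  0.45 + 0.15 * sin(2.2 * pi * u + 0.4) * exp(-u) +
    0.10 * exp(-((u - 0.65) / 0.18)^2)
}

#' Generate a synthetic labelled spectra dataset with paired captures
#'
#' @param spec a [syntheticSpectraSpec()].
#' @param seed RNG seed.
#' @return a raw-reflectance [SpectraSet-class] with `2 * nSeeds` columns
#'   (each physical seed appears once per capture, same label and id);
#'   `metadata(x)$truth` records the planted ground truth.
#' @export
generateSyntheticDataset <- function(spec, seed = 1L) {
  set.seed(seed)
  n <- spec$nSeeds
  wl <- spec$wavelengths
  p <- length(wl)
  nOk <- round(spec$iP * n)
  labels <- c(rep(1L, nOk), rep(-1L, n - nOk))
  base <- .baseCurve(wl)
  dip <- matrix(0, 1L, p)
  for (b in spec$informativeBands)
    dip <- dip + exp(-((seq_len(p) - b) / spec$featureSd)^2 / 2)
  u <- (wl - min(wl)) / diff(range(wl))
  perSeed <- matrix(rep(base, each = n), n, p)
  perSeed <- perSeed + stats::rnorm(n, 0, spec$baselineSd) +
    outer(stats::rnorm(n, 0, spec$slopeSd), u - 0.5)
  perSeed <- perSeed - (labels == -1L) %o% drop(dip * spec$effectSize)
  capture1 <- perSeed + matrix(stats::rnorm(n * p, 0, spec$noiseSd), n, p) +
    stats::rnorm(n, 0, spec$captureNoiseSd)
  capture2 <- perSeed + matrix(stats::rnorm(n * p, 0, spec$noiseSd), n, p) +
    stats::rnorm(n, 0, spec$captureNoiseSd)
  m <- rbind(capture1, capture2)
  m[m < 1e-4] <- 1e-4
  ids <- paste0("seed_", seq_len(n))
  x <- SpectraSet(m, wl, labels = c(labels, labels),
                  seedIds = c(ids, ids), capture = rep(1:2, each = n))
  S4Vectors::metadata(x)$truth <-
    list(informativeBands = spec$informativeBands,
         effectSize = spec$effectSize, seed = seed,
         perSeedClean = perSeed)
  x
}

#' Fraction of planted bands recovered by a model support
#'
#' A planted band counts as recovered when the support contains it or an
#' immediate neighbour (adjacent bands carry most of a narrow Gaussian
#' feature's signal and are statistically interchangeable with its centre).
#'
#' @param support integer waveband indices of a sparse model.
#' @param planted integer indices of the planted informative bands.
#' @param tol neighbourhood half-width in bands (default 1).
#' @return fraction in \[0, 1\].
#' @export
bandRecovery <- function(support, planted, tol = 1L) {
  if (!length(planted)) stop("no planted bands given")
  hits <- vapply(planted, function(b) any(abs(support - b) <= tol), TRUE)
  mean(hits)
}

#' Generate a synthetic hyperspectral cube with planted seeds
#'
#' Lays elliptical seed regions on a dark-background cube in a rows x cols
#' tray grid; each region's pixels carry that seed's spectrum plus pixel
#' noise. Ground truth (regions, labels, per-seed spectra) is returned for
#' segmentation and extraction tests.
#'
#' @param spec a [syntheticSpectraSpec()]; `nSeeds` seeds are placed.
#' @param layout c(rows, cols) of the tray grid; must fit `nSeeds`.
#' @param cellPx pixel pitch of the grid cells.
#' @param radius semi-axes in pixels, c(a, b); must fit inside a cell.
#' @param background background reflectance of the matt-black tray.
#' @param pixelNoiseSd per-pixel noise sd.
#' @param seed RNG seed.
#' @return list with `cube` ([HyperCube-class], reflectance), `regions`
#'   (truth data.frame: id, centroid_line, centroid_sample, area, label),
#'   `labels` (truth label matrix) and `spectra` (the per-seed clean
#'   spectra, seeds x bands).
#' @export
generateSyntheticCube <- function(spec, layout = NULL, cellPx = 16L,
                                  radius = c(5, 4), background = 0.02,
                                  pixelNoiseSd = 0.005, seed = 1L) {
  n <- spec$nSeeds
  if (is.null(layout)) {
    cols <- max(1L, ceiling(sqrt(n))); layout <- c(ceiling(n / cols), cols)
  }
  if (prod(layout) < n) stop("layout does not fit the seed count")
  if (2 * max(radius) + 2 > cellPx)
    stop("seeds overlap: radius too large for the cell pitch")
  if (n > 0L) {
    ds <- generateSyntheticDataset(spec, seed = seed)
    keep <- captureIds(ds) == 1L
    spectra <- spectraMatrix(ds)[keep, , drop = FALSE]
    seedLab <- seedLabels(ds)[keep]
    wl <- wavelengths(ds)
  } else {
    wl <- spec$wavelengths
    spectra <- matrix(numeric(0), 0L, length(wl))
    seedLab <- integer(0)
  }
  p <- length(wl)
  nl <- layout[1L] * cellPx; nsamp <- layout[2L] * cellPx
  set.seed(seed + 1L)
  cube <- array(background, c(nl, nsamp, p)) +
    array(stats::rnorm(nl * nsamp * p, 0, pixelNoiseSd), c(nl, nsamp, p))
  labMat <- matrix(0L, nl, nsamp)
  rows <- integer(0); cols <- integer(0)
  regions <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% layout[2L]; cc <- (i - 1L) %% layout[2L]
    cy <- r * cellPx + cellPx / 2; cx <- cc * cellPx + cellPx / 2
    yy <- row(labMat); xx <- col(labMat)
    px <- which(((yy - cy) / radius[1L])^2 + ((xx - cx) / radius[2L])^2 <= 1)
    labMat[px] <- i
    npix <- nl * nsamp
    for (b in seq_len(p))
      cube[px + (b - 1L) * npix] <- spectra[i, b] +
        stats::rnorm(length(px), 0, pixelNoiseSd)
    regions[[i]] <- data.frame(id = i, centroid_line = mean(yy[px]) - 1,
                               centroid_sample = mean(xx[px]) - 1,
                               area = length(px), label = seedLab[i])
  }
  cube[cube < 0] <- 0
  regTab <- if (n > 0L) do.call(rbind, regions) else
    data.frame(id = integer(), centroid_line = numeric(),
               centroid_sample = numeric(), area = integer(),
               label = integer())
  list(cube = HyperCube(cube, wl, "reflectance"), regions = regTab,
       labels = labMat, spectra = spectra)
}
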