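cubeFixture <- function() {
  a <- array(seq_len(2 * 3 * 4) / 10, c(2, 3, 4))
  HyperCube(a, c(1000, 1100, 1200, 1300), "reflectance")
}

test_that("ENVI cubes round-trip through every interleave", {
  cube <- cubeFixture()
  for (il in c("bsq", "bil", "bip")) {
    f <- withr::local_tempfile(fileext = paste0(".", il))
    writeENVI(cube, f, interleave = il, dataType = 5)
    back <- readENVI(f, kind = "reflectance")
    expect_equal(back@data, cube@data, info = il)
    expect_equal(back@wavelengths, cube@wavelengths)
  }
})

test_that("malformed cubes are refused with format errors", {
  cube <- cubeFixture()
  f <- withr::local_tempfile(fileext = ".bsq")
  writeENVI(cube, f, dataType = 5)
  # truncation
  writeBin(readBin(f, "raw", 100), f)
  expect_error(readENVI(f), "truncated")
  # missing wavelengths
  f2 <- withr::local_tempfile(fileext = ".bsq")
  writeENVI(cube, f2, dataType = 5)
  hdr <- readLines(paste0(f2, ".hdr"))
  writeLines(hdr[!grepl("wavelength", hdr)], paste0(f2, ".hdr"))
  expect_error(readENVI(f2), "wavelength")
  # not a header at all
  f3 <- withr::local_tempfile()
  writeLines("garbage", f3)
  expect_error(readENVI(f2, header = f3), "not an ENVI header")
})

test_that("reflectance calibration is anchored linear interpolation", {
  wl <- c(1000, 1100)
  mk <- function(v) HyperCube(array(v, c(3, 4, 2)), wl, "raw")
  dark <- 100; white <- 900
  expect_equal(calibrateReflectance(mk(100), dark, white)@data,
               array(0, c(3, 4, 2)))
  expect_equal(calibrateReflectance(mk(900), dark, white)@data,
               array(0.99, c(3, 4, 2)))
  expect_equal(calibrateReflectance(mk(500), dark, white)@data,
               array(0.495, c(3, 4, 2)))
  # per-pixel references and clipping
  darkA <- array(runif(24, 0, 50), c(3, 4, 2))
  whiteA <- darkA + 800
  out <- calibrateReflectance(mk(500), darkA, whiteA)
  expect_equal(out@data, 0.99 * (500 - darkA) / 800)
  expect_error(calibrateReflectance(mk(500), darkA, darkA), "calibration")
  expect_error(calibrateReflectance(out, dark, white), "already calibrated")
  glint <- suppressMessages(calibrateReflectance(mk(5000), dark, white))
  expect_lte(max(glint@data), 1.2)
})

test_that("segmentation recovers planted regions with correct centroids", {
  gen <- generateSyntheticCube(syntheticSpectraSpec(nSeeds = 12),
                               layout = c(3, 4), seed = 30)
  seg <- segmentSeeds(gen$cube, minArea = 10)
  expect_equal(nrow(seg$regions), 12)
  expect_lt(max(abs(seg$regions$centroid_line - gen$regions$centroid_line)), 1)
  expect_lt(max(abs(seg$regions$centroid_sample -
                    gen$regions$centroid_sample)), 1)
  # regions partition the foreground: disjoint, union equals the mask
  expect_true(all(sort(unique(as.vector(seg$labels))) ==
                  c(0, seq_len(nrow(seg$regions)))))
})

test_that("segmentation handles empty and sub-minimum foreground", {
  dark <- HyperCube(array(0.02, c(8, 8, 3)), c(1000, 1100, 1200),
                    "reflectance")
  seg <- segmentSeeds(dark, minArea = 5)
  expect_identical(nrow(seg$regions), 0L)
  # one bright disc below the area threshold is excluded
  a <- array(0.02, c(16, 16, 3))
  a[8:9, 8:9, ] <- 0.8
  seg2 <- segmentSeeds(HyperCube(a, c(1000, 1100, 1200), "reflectance"),
                       minArea = 20)
  expect_identical(nrow(seg2$regions), 0L)
  seg3 <- segmentSeeds(HyperCube(a, c(1000, 1100, 1200), "reflectance"),
                       minArea = 4)
  expect_identical(nrow(seg3$regions), 1L)
})

test_that("extraction averages the seed-occupied pixels exactly", {
  a <- array(0.02, c(10, 10, 3))
  s1 <- c(0.5, 0.6, 0.7); s2 <- c(0.3, 0.4, 0.5)
  for (b in 1:3) { a[2:3, 2:3, b] <- s1[b]; a[7, 7:8, b] <- s2[b] }
  cube <- HyperCube(a, c(1000, 1100, 1200), "reflectance")
  seg <- segmentSeeds(cube, minArea = 2)
  sp <- extractSeedSpectra(cube, seg)
  expect_equal(unname(spectraMatrix(sp)), rbind(s1, s2), ignore_attr = TRUE)
  # mean of two pixels with different spectra
  a[7, 7, ] <- c(0.2, 0.2, 0.2); a[7, 8, ] <- c(0.4, 0.6, 0.8)
  cube2 <- HyperCube(a, c(1000, 1100, 1200), "reflectance")
  sp2 <- extractSeedSpectra(cube2, seg)
  expect_equal(unname(spectraMatrix(sp2)[2, ]), c(0.3, 0.4, 0.5))
})

test_that("extraction recovers planted spectra within noise tolerance", {
  spec <- syntheticSpectraSpec(nSeeds = 9)
  gen <- generateSyntheticCube(spec, layout = c(3, 3), pixelNoiseSd = 0.01,
                               seed = 31)
  seg <- segmentSeeds(gen$cube, minArea = 10)
  sp <- extractSeedSpectra(gen$cube, seg)
  tol <- 3 * 0.01 / sqrt(min(gen$regions$area))
  expect_lt(max(abs(spectraMatrix(sp) - gen$spectra)), tol + 0.01 * 3 / 8)
  expect_equal(nrow(spectraMatrix(sp)), 9)
})

test_that("score maps color regions by score and leave background intact", {
  gen <- generateSyntheticCube(syntheticSpectraSpec(nSeeds = 4),
                               layout = c(2, 2), seed = 32)
  seg <- segmentSeeds(gen$cube, minArea = 10)
  img <- renderScoreMap(gen$cube, seg, c(-2, -1, 1, 2))
  lo <- which(seg$labels == 1)[1]; hi <- which(seg$labels == 4)[1]
  npx <- prod(dim(seg$labels))
  colAt <- function(px) c(img[px], img[px + npx], img[px + 2 * npx])
  expect_false(isTRUE(all.equal(colAt(lo), colAt(hi))))
  # equal scores paint identical colors
  img2 <- renderScoreMap(gen$cube, seg, rep(1, 4))
  expect_equal(colAt2 <- c(img2[lo], img2[lo + npx], img2[lo + 2 * npx]),
               c(img2[hi], img2[hi + npx], img2[hi + 2 * npx]))
  # colored area equals the segmentation mask: background stays grayscale
  bg <- which(seg$labels == 0)
  expect_equal(img[bg], img[bg + npx])
  expect_equal(img[bg], img[bg + 2 * npx])
  expect_error(renderScoreMap(gen$cube, seg, 1:3), "one score per region")
})
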