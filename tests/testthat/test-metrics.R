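test_that("sorting curve matches hand enumeration on a 5-seed batch", {
  curve <- sortingCurve(tinyBatch())
  row <- curve[curve$threshold == 3, ]
  expect_equal(row$recovery, 0.6)
  expect_equal(row$P, 1)
  expect_equal(row$R, 1)
  expect_equal(row$A, 1)
  # loosest threshold: everything recovered
  last <- curve[nrow(curve), ]
  expect_equal(last$recovery, 1)
  expect_equal(last$P, 0.6)
  expect_equal(last$R, 1)
  expect_equal(last$rP, 0)
})

test_that("anti-correlated scores give zero relative precision", {
  b <- ScoredBatch(5:1, c(-1, -1, -1, 1, 1))
  curve <- sortingCurve(b)
  above <- curve$recovery <= 0.5
  expect_true(all(curve$P[above] <= initialPrecision(b)))
  expect_true(all(curve$rP[above] == 0))
})

test_that("relative precision follows its defining arithmetic", {
  expect_equal(relativePrecision(0.903, 0.8), 0.515)
  expect_equal(relativePrecision(0.8, 0.8), 0)
  expect_equal(relativePrecision(0.5, 0.8), 0)
  expect_equal(relativePrecision(1, 0.37), 1)
  expect_error(relativePrecision(0.9, 1), "strictly inside")
})

test_that("standard condition recovers the top round(iP*N) seeds", {
  sc <- standardCondition(tinyBatch())
  expect_equal(sc$k, 3)
  expect_equal(sc$sLST, 3)
  expect_equal(sc$sP, 1)
  expect_equal(sc$sR, 1)
  expect_equal(sc$sA, 1)
  one <- ScoredBatch(c(2, 1), c(1L, -1L))
  expect_equal(standardCondition(one)$sP, 1)
  expect_error(standardCondition(ScoredBatch(1:3, c(1L, 1L, 1L))),
               "degenerate")
})

test_that("sP equals sR whenever iP * N is integral", {
  for (s in 1:20) {
    b <- randomBatch(n = 200, iP = 0.8, seed = s)
    sc <- standardCondition(b)
    expect_identical(sc$sP, sc$sR)
  }
})

test_that("rP <= P pointwise and AUC-rPR <= AUC-PR on random batches", {
  for (s in 1:20) {
    b <- randomBatch(n = 150, iP = 0.6, seed = s, informative = (s %% 2 == 0))
    curve <- sortingCurve(b)
    expect_true(all(curve$rP <= curve$P))
    expect_lte(curveAUC(curve$R, curve$rP), curveAUC(curve$R, curve$P))
    s0 <- standardSummary(b)
    expect_gte(s0$Amax, s0$sA)
    expect_gte(s0$Amax, max(s0$iP, 1 - s0$iP))
  }
})

test_that("label permutation drives AUC-PR to iP and AUC-rPR to zero", {
  set.seed(99)
  n <- 10000
  labels <- c(rep(1L, 7000), rep(-1L, 3000))
  b <- ScoredBatch(rnorm(n), labels)   # scores independent of labels
  s <- standardSummary(b)
  expect_equal(s$AUC_PR, 0.7, tolerance = 0.02)
  expect_lt(s$AUC_rPR, 0.05)
  curve <- sortingCurve(b)
  expect_lt(median(curve$rP), 0.05)
})

test_that("curve AUC integrates trapezoids with endpoint extension", {
  expect_equal(curveAUC(c(0.2, 0.6, 1), c(0.5, 0.5, 0.5)), 0.5)
  # unordered input is sorted internally
  expect_equal(curveAUC(c(1, 0.2, 0.6), c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(curveAUC(c(0, 1), c(1, 0)), 0.5)
  expect_equal(curveAUC(c(0, 1), c(1, 0), method = "step"), 0)
  pr <- prCurves(sortingCurve(tinyBatch()))
  expect_equal(pr$rpr$rP,
               relativePrecision(pr$pr$P, 0.6))
})

test_that("metrics are rank statistics: monotone score maps change nothing", {
  b <- randomBatch(n = 120, iP = 0.75, seed = 5)
  s1 <- standardSummary(b)
  b2 <- ScoredBatch(exp(2 * scores(b)) + 1, seedLabels(b))
  s2 <- standardSummary(b2)
  expect_equal(s1[c("sP", "sA", "Amax", "AUC_PR", "AUC_rPR")],
               s2[c("sP", "sA", "Amax", "AUC_PR", "AUC_rPR")])
})

test_that("score standardization anchors the standard cut at zero", {
  b <- randomBatch(n = 400, iP = 0.8, seed = 8)
  z <- standardizeScores(scores(b), b)
  sc <- standardCondition(b)
  expect_equal(standardizeScores(sc$sLST, b), 0)
  # affine rescaling of scores and calibration leaves z unchanged
  b2 <- ScoredBatch(3 * scores(b) + 7, seedLabels(b))
  expect_equal(standardizeScores(3 * scores(b) + 7, b2), z)
  # by construction about iP of seeds sit at or above z = 0
  expect_equal(mean(z >= 0), initialPrecision(b), tolerance = 0.01)
  expect_error(standardizeScores(1, ScoredBatch(rep(1, 5), rep(1L, 5))),
               "zero sd")
})

test_that("unified scores take the per-seed minimum", {
  z <- rnorm(10)
  expect_identical(unifyScores(list(z)), z)
  z2 <- z; z2[4] <- -5
  u <- unifyScores(list(z, z2))
  expect_equal(u[4], -5)
  expect_equal(u[-4], pmin(z, z2)[-4])
  expect_error(unifyScores(list(z, rnorm(9))), "length")
  expect_error(unifyScores(list()), "at least one")
})

test_that("unification beats either single-trait model on joint eligibility", {
  # two independent traits; each model scores only its own trait
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    okA <- rbinom(n, 1, 0.9); okB <- rbinom(n, 1, 0.85)
    joint <- ifelse(okA & okB, 1L, -1L)
    if (length(unique(joint)) < 2) return(NA)
    scA <- rnorm(n, 0.4 * okA, 0.25); scB <- rnorm(n, 0.4 * okB, 0.25)
    bA <- ScoredBatch(scA, joint); bB <- ScoredBatch(scB, joint)
    u <- unifyScores(list(standardizeScores(scA, bA),
                          standardizeScores(scB, bB)))
    sPu <- standardCondition(ScoredBatch(u, joint))$sP
    sPu >= max(standardCondition(bA)$sP, standardCondition(bB)$sP)
  }, TRUE)
  expect_true(median(wins, na.rm = TRUE) == 1)
})

test_that("successive surface anchors and marginals are consistent", {
  set.seed(21)
  n <- 300
  okA <- rbinom(n, 1, 0.9); okB <- rbinom(n, 1, 0.85)
  joint <- ifelse(okA & okB, 1L, -1L)
  scA <- rnorm(n, 0.5 * okA, 0.3); scB <- rnorm(n, 0.5 * okB, 0.3)
  b1 <- ScoredBatch(scA, joint); b2 <- ScoredBatch(scB, joint)
  surf <- successiveSurface(b1, b2, grid = 41)
  iP <- mean(joint == 1)
  # loosest corner: everything recovered
  expect_equal(surf$P[length(surf$lst1), length(surf$lst2)], iP)
  expect_equal(surf$R[length(surf$lst1), length(surf$lst2)], 1)
  # with model 2's threshold below all scores, the cross-section is the
  # single-model sorting curve of model 1
  crossP <- surf$P[, length(surf$lst2)]
  curve1 <- sortingCurve(b1)
  at <- vapply(surf$lst1, function(t) {
    i <- which(curve1$threshold <= t)[1]
    if (is.na(i)) utils::tail(curve1$P, 1) else curve1$P[i]
  }, 0)
  expect_equal(crossP, at, tolerance = 1e-12)
  expect_error(successiveSurface(b1, ScoredBatch(scB[-1], joint[-1])),
               "misaligned")
})

test_that("surface volumes converge under grid refinement", {
  set.seed(22)
  n <- 500
  okA <- rbinom(n, 1, 0.9); okB <- rbinom(n, 1, 0.85)
  joint <- ifelse(okA & okB, 1L, -1L)
  b1 <- ScoredBatch(rnorm(n, 0.5 * okA, 0.3), joint)
  b2 <- ScoredBatch(rnorm(n, 0.5 * okB, 0.3), joint)
  coarse <- successiveSurface(b1, b2, grid = 21)
  fine <- successiveSurface(b1, b2, grid = 201)
  expect_lt(abs(coarse$volumeRPR - fine$volumeRPR), 0.05)
  expect_lt(abs(coarse$volumePR - fine$volumePR), 0.05)
  expect_true(fine$volumePR <= 1 && fine$volumePR >= 0)
})

test_that("summaries format the way the field's tables print", {
  s <- standardSummary(tinyBatch())
  f <- formatSummary(s)
  expect_match(f$sP, "^100.0%$")
  expect_match(f$AUC_PR, "^1.0000$")
})
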