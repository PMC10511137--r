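# Shared fixtures, generated in code.

# The hand-enumerable 5-seed batch: scores 5..1, first three eligible.
tinyBatch <- function() ScoredBatch(c(5, 4, 3, 2, 1), c(1, 1, 1, -1, -1))

# Small raw-reflectance SpectraSet on the reference 201-band grid.
toySpectra <- function(n = 8, seed = 1) {
  set.seed(seed)
  wl <- seq(980, 2200, length.out = 201)
  m <- matrix(runif(n * 201, 0.2, 0.8), n, 201)
  SpectraSet(m, wl, labels = rep(c(1L, -1L), length.out = n))
}

# A random labelled batch whose iP * N is integral.
randomBatch <- function(n = 200, iP = 0.75, seed = 1, informative = TRUE) {
  set.seed(seed)
  k <- round(iP * n)
  labels <- c(rep(1L, k), rep(-1L, n - k))
  mu <- if (informative) 0.5 * labels else 0
  ScoredBatch(rnorm(n, mu, 1), labels)
}
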