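---
title: "Evaluating seed-sorting discriminants: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating seed-sorting discriminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsort)
```

## The task and the model

A seed sorter recovers every seed whose discriminant score ŷ is at or above
a lower score threshold (LST) and discards the rest. `nirsort` builds the
scores from per-seed NIR reflectance spectra by PLS-DA: a partial least
squares regression of the eligibility dummy **y** (+1 eligible, −1
ineligible) on the column-centered spectra matrix, whose continuous
prediction is the score. PLS-DA is used rather than a classifier with a
hard decision boundary because the score itself is the product: sorting
strength is adjusted after the fact by moving the LST.

Spectra enter the model in one of twelve candidate forms X1–X12, the cross
of three base transforms (reflectance *R*; reciprocal 1/*R*;
pseudo-absorbance −log₁₀ *R*, log base 10 by spectroscopic convention) with
optional Savitzky–Golay (SG) smoothing and optional standard normal variate
(SNV) correction. Indices run in blocks of four per base — plain, +SG,
+SNV, +SG+SNV — with bases ordered *R* (X1–X4), 1/*R* (X5–X8), −log₁₀ *R*
(X9–X12); this is the only ordering consistent with every published
description of the variants we model the workflow on. Which variant
discriminates best is an empirical matter and differs by crop and trait, so
all twelve are candidate inputs to model derivation.

Two composition details are genuinely open and resolved as follows:

* **SG before SNV** when both are flagged (denoise first, then
  baseline-correct). The order is recorded in each dataset's provenance and
  `makeVariant(sgFirst = FALSE)` flips it.
* **SG edge handling.** The filter (window 5, order 3, zeroth derivative)
  uses least-squares polynomial endpoint fits rather than mirror padding:
  mirror padding preserves length but breaks the filter's defining property
  that polynomials up to the fit order pass through unchanged (a mirrored
  cubic is no longer a cubic at the fold). With endpoint fits the property
  holds at every band, which is also what the exactness tests assert.

SNV is computed over the valid spectral range only — 980–2,200 nm, which
carries 201 wavebands on the reference 6.1 nm-pitch grid; other grids are
accepted with a warning when the count differs.

## Sparse derivation

Full-spectrum PLS-DA models spread small coefficients over hundreds of
collinear wavebands and are hard to interpret. Derivation therefore runs in
four steps per variant: (1) build the variant spectra; (2) fit a full
PLS-DA and take its standardized partial regression coefficients (SPRC),
β<sub>j</sub> = b<sub>j</sub>·sd(x<sub>j</sub>)/sd(y); (3) run an adaptive
lasso of **y** on the spectra with per-variable penalty weight
1/|β<sub>j</sub>| (wavebands with β<sub>j</sub> = 0 are hard-excluded —
infinite penalty), collecting every distinct support along a 100-point
log-spaced λ path from the empty-support λ down to 10⁻⁴ of it; (4) refit
PLS-DA on each support. Variable importance in projection (VIP) is carried
on every fitted model for interpretation; mean(VIP²) = 1 by construction.

The latent-variable count is chosen by 10-fold cross-validation minimizing
the mean squared error of the score, capped at 20 components (the cap and
fold count are arguments; the refit tests in this package run with a cap of
10 and 5 folds, which is ample at a few hundred seeds).

**Validation is capture-based.** Trays are imaged twice, rotated 180°, so
every physical seed has two spectra. The entire derivation — full fit,
SPRC, lasso path, refits — runs inside one capture, and each resulting
candidate is scored on the other capture; both directions run ("mutual
outer cross-validation"). Running waveband selection on pooled captures
instead would leak: the two captures share each seed's true spectrum, so
bands selected for chance label correlations on pooled data keep their
apparent skill on the held-out capture (we measured a median selected-best
AUC-rPR of ~0.3 on zero-effect data under pooled selection, versus ~0.04
with capture-internal derivation). When only one capture exists the
package falls back to a seeded two-fold seed-level split, with a warning.

Candidates are ranked by standard precision, tie-broken by AUC-rPR and then
by parsimony (fewer wavebands). Because a single cross-validation
realization is noisy, `rankCandidates(iterations = k)` re-evaluates every
candidate under resampled inner folds and aggregates by median rank —
"frequently high-ranked" candidates come first. The resampling protocol is
one admissible reading of iterative derivation; it is deterministic given
its seed.

## Sorting metrics

All metrics are rank statistics of the scores (any monotone transform of ŷ
leaves them unchanged):

* **Standard condition.** With iP the initial eligibility rate and N seeds,
  recover the top k = round(iP·N) scores. The threshold sLST is the k-th
  highest score (ties at sLST are all recovered and k re-expands). At this
  operating point precision equals recall — exactly so whenever iP·N is
  integral — which makes sP = sR a natural single-number ranking criterion
  regardless of the model.
* **Relative precision** rP = (P − iP)/(1 − iP) if P > iP, else 0. It maps
  "no enrichment" to 0 and "pure batch" to 1, so performance is comparable
  across batches with different iP. The rPR curve (rP against recall R) and
  its area AUC-rPR are the model-selection criteria least confounded by iP;
  AUC-rPR ≤ AUC-PR always.
* **Amax**, the maximum accuracy over thresholds, is reported to check how
  far the standard condition sits from the accuracy optimum; the
  all-rejected operating point is included, so Amax ≥ max(iP, 1 − iP).

**Integration rule.** Curve areas use the trapezoid over the achieved
(R, value) points, extending the curve to R = 0 with the value at the
smallest achieved recall. A right-step (average-precision) rule is
available (`curveAUC(method = "step")`); at the batch sizes used here the
two differ by less than 10⁻⁴.

**Multi-trait evaluation.** When full eligibility needs several traits
(e.g. germinability and hybrid haplotype), three routes are supported:
successive per-trait thresholds (a 2-d surface of P/R/rP over the two LSTs,
with volumes over the marginal-recall square by 2-d trapezoid), one
directly trained joint model, or score unification: each model's scores are
standardized as ẑ = (ŷ − sLST(ŷ<sub>p</sub>))/s(ŷ<sub>p</sub>) against a
calibration batch ŷ<sub>p</sub>, and a seed's unified score is û = min ẑ
over models — rejection is preferred over acceptance in case of doubt. The
calibration subset is deliberately an argument: the natural default is the
model's outer-CV validation scores, but the definition is not pinned down
by the workflow we model, so the choice is explicit and recorded.

## The simulation module

Two generators drive validation:

* **Hypothetical score models.** Class-conditional normals: eligible scores
  ~ N(μ_ok, σ), ineligible ~ N(μ_ng, σ), σ = 0.25 read as a *standard
  deviation* (the variance reading misses the published standard precisions
  by over two points; the analytic oracle below confirms the SD reading).
  Presets: near-perfect (±1), medium (±0.2), poor (±0.05), on canonical
  batches of 52,428/13,107 (iP 80 %) and 39,321/26,214 (iP 60 %). The
  analytic oracle solves iP·S_ok(t) + (1−iP)·S_ng(t) = iP for sLST by
  bracketed root-finding (tolerance 10⁻¹⁰) and sets sP = S_ok(sLST),
  independently of the empirical machinery it checks.
* **Synthetic spectra.** A smooth shared base curve; per-seed baseline
  offset (sd 0.02) and slope (sd 0.01), emulating scatter and tilt
  variation between seeds; Gaussian absorption dips (sd 1.5 bands) at three
  informative bands near 1,200, 1,730 and 1,920 nm — the classic CH₂ and
  protein absorption regions — deepened by `effectSize` (default 0.03
  reflectance units) in ineligible seeds; iid noise (sd 0.01, so the
  default effect-to-noise ratio is 3); and two captures per seed differing
  by capture-level noise (sd 0.005). Labels are stratified so the realized
  eligible fraction is exact. Defaults were chosen once as a realistic
  mid-difficulty regime and are not tuned per test. The generator emulates
  the *structure* of seed spectra data, not crop-specific waveforms,
  detector nonlinearity, or within-seed spatial heterogeneity — so passing
  tests demonstrate the pipeline's correctness and its behavior under known
  ground truth, not field performance on any particular crop.

A property worth knowing when interpreting null results: per-seed baselines
are shared between the duplicate captures, so seed-level chance
correlations with the labels survive capture-based validation. On
zero-effect data with baselines on, the best of ~30 candidates therefore
shows a small but nonzero AUC-rPR (median ≈ 0.12 at 400 seeds) even though
no label signal exists; with pure iid noise the median is ≈ 0.04. The same
caveat applies to the real paired-capture design.

## Numerical and degenerate-input choices

* Reflectance is clipped to ≥ 10⁻⁶ before reciprocal/log (with a warning);
  non-positive reflectance is a domain error naming the band.
* Zero-variance wavebands are excluded from fits with a warning
  (SPRC undefined there); zero-variance spectra make SNV a
  degenerate-spectrum error.
* Calibration requires white > dark per pixel/band; reflectance is clipped
  to [0, 1.2] (specular glints), and clipping is reported.
* Segmentation thresholds the mean-reflectance image by Otsu, requires a
  minimum image contrast of 0.05 reflectance (a flatter image — a tray with
  no seeds — yields zero regions rather than thresholded noise), uses
  4-connected components, area ≥ 20 px at the reference ~90 ppi scale, and
  orders regions row-major by centroid for determinism.
* The standard condition requires 1 ≤ round(iP·N) ≤ N−1; ties at sLST
  re-expand the recovered set, honouring "the lowest score of seeds to be
  recovered".
* Ranking ties are broken by fewer wavebands, then derivation order.

## Problem sizes used in the automated checks

The test suite reproduces the six-row thought experiment at the full
canonical batch size (65,535 scores, five seeded replicates, ensemble mean
compared because single-replicate noise in the poor model's AUC-rPR — SD ≈
0.007 — is of the same order as the comparison band); end-to-end waveband
recovery runs 20 replicates of 400 seeds × 201 bands with derivation on the
raw-reflectance variant. One caveat is recorded honestly rather than
papered over: the near-perfect model's sLST is an order statistic falling
in the density gap between the two class distributions, where its sampling
SD is ≈ 0.03 and even the analytic iP-quantile differs from any single
simulated realization; published single-realization values of that quantity
are not reproducible to ±0.005 by any estimator, and the corresponding
check is expected to fail. All other quantities reproduce within their
stated bands.

## Known limitations

* PLS-DA is fit center-only by default (`scale = TRUE` is available); with
  fewer components than the rank, coefficients are not scale-equivariant,
  which is inherent to PLS.
* The adaptive-lasso path inherits glmnet's internal rescaling of penalty
  weights (weights are normalized to sum to the variable count); supports
  along the path are unaffected.
* `vignettes` are source-only; figures are intentionally absent.
* Real-crop performance (which cultivars discriminate well, which variant
  X wins, absolute sP levels) cannot be inferred from the synthetic
  generator; it requires real labelled spectra supplied by the user as a
  spectra table.
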