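---
title: "Methods: multimodal seed classification with ORBMO-tuned random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal seed classification with ORBMO-tuned random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic fixtures
can and cannot demonstrate.

## The problem and the pipeline

Seed varieties of the same species often differ subtly in shape,
surface texture and biochemistry. The package classifies seeds by
fusing two measurement modalities: morphology from RGB board images and
reflectance over 350–2500 nm. The pipeline is

1. segment individual seeds and compute 34 morphological descriptors;
2. crop spectra to 400–2400 nm and correct them (Savitzky–Golay
   smoothing, multiplicative scatter correction);
3. select characteristic wavelengths (SPA or CARS) and morphological
   features (RFE or SFM) on the *training split only*;
4. z-score and concatenate the two blocks;
5. tune a random forest with the improved Red-Billed Blue Magpie
   Optimizer and evaluate on the held-out split.

## Seed imaging

Segmentation follows the conventional contour route: grayscale
(Rec. 601 weights), Gaussian blur (σ = 1 px), Otsu threshold,
morphological opening (disc radius 2 px), connected components,
boundary tracing, per-component minimum axis-aligned bounding
rectangle expanded by `margin_px = 15` px and clipped to the image.
Components below `min_area = 200` px² are dropped; regions touching
the image border are kept but flagged. All defaults are configurable
(`segmentation_config()`).

Descriptor choices that were open and how they were fixed:

* **Perimeter.** The 8-connected boundary chain with √2-weighted
  diagonal steps systematically overestimates smooth boundaries by
  8/(π(1+√2)) ≈ 1.055, which would push a disk's circularity to ~0.91.
  The chain length is therefore scaled by Kulpa's classical correction
  π(1+√2)/8, after which a rasterized disk reports C ≈ 1.01.
* **Axes.** L and W are the major/minor axis lengths of the moment
  ellipse (4·√eigenvalue of the second-order central-moment matrix),
  the standard regionprops convention. A mask with zero minor axis
  (single-pixel-wide line) raises a degenerate-region error.
* **Rectangularity.** R = A divided by the area of the *oriented*
  minimum-area rectangle (rotating calipers over the convex hull of
  pixel-square corners, so an axis-aligned w×h rectangle gives exactly
  R = 1).
* **Dispersion.** "e" is implemented as compactness S²/A, the usual
  reading of dispersion in seed morphometrics; it is the reciprocal of
  circularity up to the 4π factor.
* **Hu moments.** Log-scaled as h ← −sign(h)·log10(|h| + 1e−30) so the
  seven invariants are on comparable magnitudes after normalization.
* **GLCM.** Computed on the masked crop quantized to 32 grey levels,
  distance 1, the four angles {0°, 45°, 90°, 135°} symmetrized,
  normalized and averaged. Pairs are counted only when both pixels are
  inside the mask, so background never contaminates the statistics. A
  constant crop has zero variance; its correlation is defined as 0 and
  logged. Energy is defined as √ASM.
* **LBP.** Rotation-invariant uniform coding, 8 neighbours at radius 1
  (bit set when neighbour ≥ centre): uniform patterns (≤ 2 circular
  transitions) bin by their count of ones (bins 0–8), non-uniform
  patterns go to bin 9 — exactly ten bins. Centres must lie in the
  mask; the histogram is normalized (sums to 1 within 1e−9).

The full vector is always 34 values in a fixed documented order
(`morph_feature_names()`).

## Spectral preprocessing

Cropping keeps wavelengths in [400, 2400] nm inclusive — a 1 nm grid
from 350–2500 yields 2001 retained points (the count is reported, not
hard-coded). Savitzky–Golay defaults to window 21 points, polynomial
order 3, derivative 0; the filter reproduces polynomials up to its
order exactly, including at the edges. MSC regresses each spectrum on
the global mean spectrum by OLS and inverts the fitted gain/offset;
rows with |b| < 1e−12 are left unchanged with a warning. The reference
is the global (not per-class) mean: a per-class reference would leak
label information into a transform that is also applied to test data.
The combined method applies smoothing first, then scatter correction.

## Wavelength selection

**SPA.** Projection chains start from up to 50 evenly spaced columns;
each chain appends the column with maximal residual norm after
projecting out the span of the chosen ones, stopping early when the
residuals drop below 1e−12 (rank deficiency). Chains run on the
*mean-centered* matrix on its physical reflectance scale:
unit-variance autoscaling was tried and rejected because it inflates
pure-noise bands to the same norm as structured ones, which makes the
chains prefer noise (planted-band recovery collapsed from 10/10 to
1/10 seeds). Chain prefixes of every length are scored by the
validation RMSE of a multi-response ridge model (λ = 1e−6) on a fixed
seeded 70/30 row split; the argmin subset is returned, ties toward
fewer bands.

**CARS.** Fifty Monte-Carlo runs by default. Each run fits PLS2 (an
internal SIMPLS; no lightweight PLS package is available, and the
implementation is cross-checked in the tests against both the
full-rank OLS identity and an independent PLS implementation) on 80 %
of the rows, weights each retained band by |B|·sd(column) — the
coefficient of the standardized predictor, since raw coefficients on
unscaled spectra reward low-variance columns — and retains
⌈r_i·p⌉ bands with r_i = a·e^(−k·i), a = (p/2)^{1/(N−1)},
k = ln(p/2)/(N−1), so r₁ = 1 and r_N = 2/p. The forced top-weight cut
is followed by the competitive reweighted draw (m_i weighted draws,
unique survivors); a degenerate draw falls back to the two top-weight
bands so the run can still be scored. Five-fold RMSECV (same fold
assignment across runs, for comparability) selects the returned run;
ties break toward the smaller subset, then the earlier run. Labels
enter both selectors as one-hot indicator responses, the standard
chemometric device for classification with regression-native
selectors.

## Feature selection, split and fusion

RFE fits one-vs-rest linear SVMs (C = 1) on the standardized table,
sums absolute coefficients as importances, removes one feature per
iteration (ties: lower column index first), and returns the subset
maximizing 5-fold stratified CV accuracy (ties: smaller subset), or
the top-k of the ranking when a size is forced. SFM normalizes
random-forest impurity importances to sum 1 (200 trees) and keeps
those at or above the mean (or a numeric threshold); if nothing
clears it, the single top feature is kept with a warning.

The train/test split is stratified 7:3 with largest-remainder
rounding, so 260 samples split 182/78 exactly (equal per-class
remainders are resolved in class order). Fusion z-scores every column
with statistics computed on the training rows only and concatenates
the morphological block ahead of the spectral block; the
dimensionality reduction of each modality is reported as
100·(1 − kept/original).

## The optimizer

The base dynamics are defined explicitly so the package is
self-contained: per individual, with probability 1 − t/T an
exploration move x′ = x + U(0,1)·(x̄_q − x) toward the mean of a random
subgroup (small, 2–5, or large, 10–20, with probability ½ each), else
a food-guided exploitation move x′ = x_food + CF·U(0,1)·(x̄_q − x) with
CF = (1 − t/T)^{2t/T}. New positions are clipped to the box and kept
only if they improve that individual ("food storage"); the best-so-far
archive is strictly elitist.

The three mechanisms:

* **Circle chaotic initialization.** Per dimension the chosen map is
  iterated from a seeded start with a 100-step burn-in; the improved
  variant (factor 2.75, a = 0.6, b = 0.3) is empirically more uniform
  than the standard one (χ² on 20 bins over 10⁴ iterates, 10/10
  seeds).
* **Golden-sine + Lévy hybrid.** With switching probability
  0.5·(1 − t/T) the exploitation move becomes
  x′ = x + r·sin θ·(φ·x_food − x) + α·Lévy(λ), φ = (√5−1)/2,
  r ~ U[0,1], θ ~ U[0,2π], Mantegna steps with λ = 1.5 and
  α = 0.01·(ub − lb). Larger α (0.05–0.1 of the box) was benchmarked
  and did not improve basin escape, so the small default stands.
* **Adaptive simulated annealing.** Temperature T = T₀·e^(−βt),
  T₀ = 100, β = ln(100)/T_max (so the final temperature is 1 % of
  T₀); a linear schedule T₀(1 − t/T_max) is also available. Each
  iteration the incumbent best is perturbed by a Gaussian with scale
  (T/T₀)·0.1·(ub − lb). The candidate replaces the global best only if
  strictly better; otherwise it may replace the worst population
  member under Metropolis acceptance min(1, e^(−Δf/T)). This
  resolution lets strict elitism of the best archive and
  worse-solution acceptance coexist. At T ≤ 0 the frozen limit
  applies.

Early stopping triggers after 30 consecutive iterations without an
improvement larger than 1e−12. Non-finite objective values are treated
as +∞ with a warning. Defaults: n = 30 individuals, T_max = 100.

An honest benchmark note: on the sphere (dim 3) the full stack reaches
a median best fitness around 1e−23 with the default budget, and the
improved initialization is measurably more uniform; on Rastrigin
(dim 3, matched budget, paired seeds) the full stack and the plain
base dynamics are statistically indistinguishable — the subgroup-mean
exploration of the base is already a strong diversifier, and the
acceptance property is the non-inferiority "full ≤ plain", which holds
with equality in the typical case.

## Random-forest tuning and evaluation

The search box is n_estimators ∈ [10, 300], max_depth ∈ [3, 30],
max_features ∈ [2, 20]; positions decode by round-half-away-from-zero
and clipping. The third dimension is interpreted as maximum tree depth
— the method names only the tree count and the feature-sampling
dimension explicitly but declares a three-dimensional search, and
[3, 30] fits depth semantics; this is an assumption and is documented
as such. Fitness is 1 − mean stratified 5-fold CV accuracy, fully
seeded; since decoded triples are integers, fitness values are
memoized per triple, which removes most repeated forest fits late in a
run. The tuned forest is a `ranger` model (it exposes `max.depth`);
prediction ties are broken with a pinned seed so reports are bitwise
reproducible.

Evaluation builds the C×C confusion matrix (rows actual, columns
predicted) and per-class precision, recall and F1 from one-vs-rest
counts; aggregates are support-weighted, under which weighted recall
equals accuracy exactly — the identity the tests assert on random
confusion matrices. A class never predicted gets precision 0 with a
warning.

## Synthetic fixtures: what they emulate and what they do not

The generator mirrors the structure of a four-class seed study with 65
samples per class (260 total, split 182/78): board images of
non-overlapping ellipse-like seeds with class-dependent axes and
smooth intra-seed texture on a dark noisy background, and reflectance
on a 350–2500 nm grid built as baseline − Σ Gaussian absorption bands,
then per-sample multiplicative gain (sd 0.08) and additive offset
(sd 0.03), then white noise (sd 0.004). The scatter layer is exactly
the generative model MSC assumes, so scatter correction is testable by
construction: MSC must recover near-identical rows from corrupted
copies of one spectrum.

Two generator design points are identifiability requirements, not
tuning: the three class-informative bands (670, 1100, 1670 nm; shared
water bands at 1450/1940 nm carry no class signal) are *narrow*
(8–12 nm), because recovery is asserted within ±3 grid positions and a
wide band spreads its signal far beyond that window; and the classes
carry linearly independent on/off depth signatures across the bands,
because with identical monotone depth patterns a single band separates
all classes and any correct selector rightly collapses onto it. The
difficulty presets scale the separations (easy = full, medium = 0.4×,
null = 0, i.e. all classes identical).

What passing tests on these fixtures does **not** show: real seed
images have shadows, touching seeds, specular highlights and
non-elliptical outlines; real spectra have wavelength-correlated
instrument noise, baseline drift beyond gain/offset, and broad
overlapping absorption features. Results on fixtures bound
implementation correctness, not field performance.

## Problem sizes and reproducibility

The test suite and acceptance script size their simulations for a
single CPU: band-recovery runs use 30 samples/class on a 5 nm grid
over 10 seeds; optimizer benchmarks use n = 30, T_max = 100 over 20
seeds; the end-to-end runs use the full 65 samples/class on the native
1–2 nm grids with a reduced tuning budget (population 8, 15
iterations), which the memoized fitness makes inexpensive. Every
random stage takes a sub-seed derived from one global seed by a
counter-based scheme (`derive_seed()`), so any stage can be rerun in
isolation and identical configurations give bitwise-identical reports.

## Known limitations

* The texture block is computed on the masked grayscale crop; whether
  background-masked or unmasked texture better matches any particular
  acquisition setup is data-dependent.
* SPA evaluates at most 50 chain starts on large grids for tractability;
  exhaustive starts can change the selected subset on near-ties.
* The Metropolis slot insertion can, at high temperature, overwrite a
  useful worst-slot individual; diversity loss was not observed at the
  default schedule but the slot choice is a heuristic.
* The optimizer's advantage over its own plain base is
  problem-dependent (see the benchmark note above).
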