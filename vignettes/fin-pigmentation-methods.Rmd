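---
title: "Pigmentation-based photo-identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pigmentation-based photo-identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finpigment)
```

## The problem

Mark–recapture photo-identification of delphinids normally relies on nicks
and notches along the dorsal-fin edge. In poorly-marked species most
individuals carry no usable edge damage, but adults often show a stable
spatial pattern of light and dark pigmentation on the fin. `finpigment`
quantifies that pattern as a fixed-length feature vector, identifies
individuals with a regularised linear discriminant classifier, and tests
the stability assumption itself with a permutation test against temporal
trend. Everything is exercisable on a ground-truthed synthetic catalogue,
because real catalogues of this kind are typically not redistributable.

## The descriptor

**Normalisation.** Pixel intensities inside the fin mask are converted to
grey (ITU-R BT.601 weights 0.299/0.587/0.114 — the common default of
imaging tools; the choice is immaterial after normalisation) and reduced to
z-units by subtracting the mean and dividing by the standard deviation of
the fin pixels. The standard deviation uses the *population* convention
(divide by n), which makes the two-pixel case `{0, 2} -> {-1, +1}` exact;
the convention is pinned so oracles agree bit-for-bit. Any positive affine
change of the raw intensities — camera exposure, global illumination —
yields the identical normalised fin, and the test suite asserts this end to
end through rendered photos. Background pixels are represented as missing,
never zero, so no patch statistic can mix background in.

**Grid subdivision (33 patches).** The fin base is the line through the
point where the leading edge flows into the body, running parallel to the
body axis. The base-normal extent `H` of the fin (pixel units, extent =
max − min + 1) is divided into 10 bands of height `h = H / 10.5` plus an
ignored half-band at the tip — the tip is where specular highlights
concentrate. The literal reading "10 equal subdivisions with the upper
limit defined as half a segment's height from the top" is circular; the
`H / 10.5` tiling is the unique self-consistent resolution (an alternative
`H / 10` with a truncated top half-band is available via
`tip_half_band = FALSE`). From the base up, bands are split into
4, 4, 4, 4, 4, 3, 3, 3, 2, 2 equal-width patches along the base-parallel
axis, between each band's *own* extreme fin pixels (per-band extent keeps
patches on-fin for strongly raked fins). Band membership uses half-open
lower-inclusive intervals; pixel coordinates enter the binning with a
half-pixel offset so that axis-aligned rectangles give exact closed-form
patch counts.

**Contour subdivision (9 patches).** An exact Euclidean distance transform
is computed on the fin pixels against the outline, where the outline is the
set of boundary *pixels* of the mask (so boundary pixels have distance 0
and an O(n²) brute-force oracle can reproduce the transform exactly). With
`D` the maximum distance, five bands of width `D/5` run along the outline;
the outermost four are split into leading and trailing halves by nearest
outline arc — the contour is cut at the fin tip and at the base into a
leading and a trailing arc, and each pixel joins the side of its nearest
arc point. This is the "set of points equidistant from the leading and
trailing edges" formulation of the medial axis; a ridge-tracking
skeletonisation could differ by a pixel at exact ties. The centre-most band
stays unsplit (it is thin and noisy), giving 9 patches.

**Features (142).** Mean, median and interquartile range of the normalised
intensities are computed per patch: 42 × 3 = 126 values. Median and IQR are
deliberately robust: a specular highlight or a water droplet corrupts only
the patches it touches (the suite asserts *exactly zero* change elsewhere,
holding the normalisation fixed — through the global mean/sd every pixel
influences every feature slightly). Sixteen inter-patch features summarise
the spread and location of the per-patch statistics: population standard
deviation and IQR of the grid/contour patch means, medians and IQRs, plus
mean and median of the patch IQRs. Quantiles interpolate linearly at rank
`(n − 1)p` (R type 7). The feature order and names are frozen in
`feature_names()` and form the CSV header.

## Registration

Pose correction registers each fin outline to a reference outline under a
full projective transform. Contours are traced at the 0.5 iso-level of the
mask (marching squares), Taubin-smoothed (λ = 0.5, μ = −0.53, 10
iterations — a low-pass that does not shrink the outline, removing the
half-pixel staircase while keeping the base corner), and resampled to 400
points by arc length. ICP alternates correspondence with normalised-DLT
re-estimation of the homography, initialised by a similarity alignment of
centroids, RMS radii and principal axes (both axis orientations tried).
Three deliberate choices:

* **Correspondences are nearest points on the reference polyline**
  (projection onto the segments at the nearest vertex), not nearest
  vertices. Point-to-point matching on resampled contours locks into
  off-by-one tangential minima ~0.2 px above the optimum; projection lets
  the match slide and reaches machine precision on exact data.
* **Trimming** discards the worst 10% of correspondences each iteration,
  tolerating local segmentation errors from highlights or water.
* **Monotone reporting.** Correspondence + algebraic DLT is not guaranteed
  monotone in the geometric residual, so iteration continues through
  non-improving steps while `residual_history` records the best residual
  so far (non-increasing by construction) and the best transform is
  returned. Convergence is declared on a relative change `< 1e-4`, a
  residual below 5e-3 px (beyond physical meaning), or a 5-iteration
  plateau.

A practical limit worth knowing: when both fins are re-rasterised binary
masks at the default 150 px canvas, contour extraction has a ~0.2 px noise
floor, and the near-degeneracy between scale and perspective of a smooth
fin outline amplifies it into ~1 px of error in the *recovered pose*, even
though the contours themselves align to ~0.17 px. The error shrinks with
resolution (~0.3 px at 2.5×). Identification is unaffected — the
subdivisions were designed to be pose-robust in the first place, and on the
synthetic world registered and unregistered accuracy are statistically
tied, which mirrors the original finding that registration gave limited
improvement.

The reference fin defaults to each individual's highest-PQ photo
(`reference = "individual"`), with a single global reference available;
which fin the original analysis registered to is not recoverable.

## The classifier

With p = 142 features and a handful of images per animal the pooled
within-class covariance is singular. The correlation matrix is shrunk
toward the identity, `Sigma* = D[(1 − λ)R + λI]D`, with λ estimated
analytically from the data (ratio of the summed sampling variances of the
off-diagonal correlations to their summed squares, clipped to [0, 1] — the
James–Stein-type estimator of the Schäfer–Strimmer school). Variances stay
empirical; exact zeros are floored at 1e-8 with a warning. Pooling centres
each class at its mean and uses denominator n − K; the λ formula treats the
pooled residuals as one sample, an approximation that is immaterial at the
n ≫ K regimes where λ matters. Discriminant scores are the usual
`δ_k(x) = xᵀΣ⁻¹μ_k − ½μ_kᵀΣ⁻¹μ_k + log π_k`, posteriors by softmax, ties
broken by class-ID order for reproducible top-k sets.

Priors default to uniform; because a published "lift" value of this kind of
analysis is ambiguous between a uniform baseline (`1/K`) and an empirical
one (`Σ p_i²`), `loocv()` reports both. Leave-one-out cross-validation
refits *everything* per fold — class means, λ, and the imputation means
used for missing features — so the held-out image contributes nothing to
its own fold (asserted in the suite). Singleton classes are never held out
but remain candidate labels, since every catalogue member is a legitimate
answer. Missing features are imputed with training means inside the
classifier only; the extractor never imputes.

## The seriation test

The stability question is whether an individual's feature vectors drift
with time. The test is Mantel-type: the observed statistic is the Spearman
correlation between pairwise feature-space Euclidean distances and pairwise
time-rank distances |i − j|; the null permutes the time order (the date
order of stable pigmentation is arbitrary); the p-value uses the add-one
estimator `(1 + #{null ≥ obs}) / (1 + N)` so p is never 0; the alternative
is one-sided (drift predicts positive association). Time enters as *rank*
of encounter date, robust to irregular sampling (a calendar-gap mode is a
one-line change in the distance definition if needed). The statistic is
invariant to rigid rotations of feature space and matches `vegan::mantel`'s
Spearman statistic on the same matrices (asserted). Across the screened
individuals — ranked by time span, then image count — the per-test level is
`sidak_alpha(m, 0.05)`, which is 0.003414 at m = 15 and is recomputed with
a warning when fewer individuals are eligible. Defaults: 999 permutations
in the API (the original analysis's exact statistic and permutation scheme
are not recoverable, so numeric agreement with published p-values is not
claimed; the suite instead verifies type-I calibration, power against
planted drift, and family-wise control). LDA trajectories project each
image onto the leading discriminant axes of the shrunk-covariance model
(axis signs fixed by the largest loading; with two classes the second axis
is reported as 0).

## The synthetic world

`generate_catalogue()` states the world the tests live in:

* **Fin shape**: a closed spline through four landmarks (base-front, tip,
  trailing notch, base-rear); base width ~N(100, 3) px, height
  ~N(112, 4) px, rake ~N(34, 4) px, trailing depth ~U(11, 17) px on a
  150 × 140 canvas. Identity-to-identity shape spread is deliberately kept
  *below* the shape variation a single fin shows under pose jitter: the
  species is poorly marked, so the outline itself must carry essentially no
  identity signal — with `distinctiveness = 0` (unpigmented animals) LOOCV
  accuracy collapses to the guessing baseline, which is the generator's
  defining null.
* **Pigment**: 6 Gaussian blobs in fin-anchored unit coordinates (centres,
  scales U(0.09, 0.22), signed amplitudes U(0.5, 1.5) × distinctiveness)
  plus a dorsal–ventral gradient; deterministic given the identity seed, so
  pigment moves with the fin under pose change, as in real photographs.
* **Nuisance defaults** (`photo_nuisance()`): projective tilt up to 8°,
  gain U(0.7, 1.4), offset U(−20, 20), pixel noise sd 4 (8-bit units),
  specular highlight with probability 0.25 covering 1% of the fin near the
  tip, 3% waterline occlusion, zero drift. These are one-shot choices for a
  moderately difficult field-photography regime; the scene is quantised to
  8 bits *before* gain/offset so that integer illumination settings leave
  the descriptor exactly invariant.
* **Seeding** is hierarchical (master → identity → photo), so enlarging a
  catalogue never changes existing photos.
* **Dates** spread each individual's encounters uniformly over 10 years;
  the `"study"` photos-per-individual option draws 2 + Poisson(2.6)
  images per animal (mean 4.6), the shape of the motivating catalogue.

What a green suite does and does not establish: the generator reproduces
the *statistical* structure the pipeline assumes — stable identity-specific
patterns, photo-level nuisance, near-uninformative shape — not the visual
appearance of dolphin fins, wave artefacts or real segmentation error. A
green identity-recovery criterion means the method works in that stated
world; it does not reproduce any published accuracy on real animals.

## Numerical conventions and edge cases

* Coordinates: origin top-left, x right (column), y down (row), pixel
  centres at integers; homographies act on (x, y, 1), normalised to
  `H[3,3] = 1`.
* Quantiles: type 7 everywhere; population sd in the inter-patch block.
* Band intervals: half-open, lower-inclusive; maximal points fall into the
  last band.
* Degenerate inputs fail loudly: constant-intensity fins, masks with < 2
  pixels, multi-component masks (override with `keep_largest_component`),
  1-px-thin masks in the distance transform, collinear contours in ICP,
  single-class training sets.
* Grade thresholds: the exact published score-to-grade table is not in the
  main text of the motivating study; the implemented rule — *poor* if any
  category is at its minimum, else *good* ≥ 20 and *excellent* ≥ 30 —
  reproduces the stated weighting intent and is configurable
  (`pq_thresholds()`).
* PQ filtering happens before feature extraction; empty results are
  permitted with a warning.

## Known limitations

* No automatic fin segmentation: the binary mask is an input.
* No nick/notch features, no open-set detection of new individuals, no
  nonrigid registration — all out of scope by design.
* Ground-truth pose recovery through re-rasterised masks is
  resolution-limited (see Registration); treat exported homographies as
  alignment maps, not as calibrated pose measurements.
* The seriation test's power depends on the number of images per
  individual; below ~8 images only strong drift is detectable at the
  Šidák-corrected level.
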