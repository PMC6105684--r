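# finpigment

Photo-identification of individual dolphins from dorsal-fin **pigmentation
patterns**. Many delphinids — short-beaked common dolphins in particular —
carry too few nicks and notches for classical edge-based photo-id, but most
adults show a stable, individually distinctive pattern of light and dark
pigment on the fin. `finpigment` implements a full pipeline that turns a
segmented fin photograph into a 142-dimensional pigmentation descriptor and
uses it to identify individuals and to test whether their pigmentation is
stable over time. It is aimed at cetacean researchers running photo-id
catalogues, and at anyone benchmarking pattern-based re-identification
methods against a ground-truthed synthetic catalogue.

## What it computes

Given a cropped fin image, a binary fin mask and catalogue metadata:

1. **Photographic-quality grading** — clarity/focus (1/4/9), contrast
   (1/3/9), orientation (1/2/9) and edge visibility (1/8) are scored and
   summed (total in [4, 35]); any category at its minimum forces a *poor*
   rating, and only *good*/*excellent* photos are analysed.
2. **Normalisation** — intensities inside the mask are reduced to
   z-units, `(x - mean) / sd`, absorbing exposure and global illumination.
3. **Registration (optional)** — the fin outline is registered to a
   reference outline by the iterative closest point algorithm under a full
   projective transform (3x3 homography), and the image is warped into the
   reference frame.
4. **Subdivision** — two pose-robust partitions of the fin interior:
   a **grid** of 33 patches anchored to the fin base (10 bands split
   4/4/4/4/4/3/3/3/2/2 from the base up, tip half-band ignored) and a
   **contour** partition of 9 patches from iso-level bands of the Euclidean
   distance transform, the outer four bands split at the medial axis into
   leading/trailing halves.
5. **Features** — mean, median and interquartile range of the normalised
   intensities in each of the 42 patches (126 values) plus 16 inter-patch
   summaries: a fixed, named 142-vector.
6. **Identification** — regularised linear discriminant analysis with a
   James–Stein-type shrinkage covariance
   `Sigma* = D[(1 - lambda) R + lambda I]D`, evaluated by leave-one-out
   cross-validation with top-k accuracy and lift.
7. **Stability over time** — per-individual Mantel-type permutation test of
   Spearman association between feature distances and time-rank distances
   ("seriation"), with Šidák-corrected decisions
   (`alpha = 1 - (1 - 0.05)^(1/15) = 0.003414` for 15 individuals), and
   LDA-space trajectories for visual inspection.

A first-class synthetic-catalogue generator (`generate_catalogue`) renders
ground-truthed fin photos — identity-specific pigment blobs on parametric
fin silhouettes with projective pose jitter, illumination change, specular
highlights, waterline occlusion and optional pigment drift — so the whole
pipeline is testable without field data.

## Worked example

```r
library(finpigment)

cat_  <- generate_catalogue(10, 4, master_seed = 42)  # 40 synthetic photos
cat_  <- filter_by_grade(cat_)                        # keep good/excellent
feats <- catalogue_features(cat_)                     # 142 features/photo
fc    <- setdiff(names(feats), c("image_id", "individual_id", "date"))

loocv(as.matrix(feats[fc]), feats$individual_id)
#> <cv_report> 27 photos, 10 classes
#>   top1 accuracy: 100.0%
#>   top5 accuracy: 100.0%
#>   lift: 10.0 (uniform baseline), 8.9 (empirical)

stability_screen(feats, top_n = 5, n_permutations = 999, seed = 1)
#> <stability_report> 5 individuals, alpha_sidak = 0.010206, 0 rejections
```

Top-1 accuracy is the share of photos whose true individual ranks first by
posterior; lift compares it with guessing (uniform: `1/K`; empirical:
`sum p_i^2`). Zero seriation rejections means no individual shows a
systematic temporal trend in feature space — pigmentation is stable, as it
must be for a usable identifier (the generator's default drift is 0).

The same pipeline is scriptable:

```sh
Rscript -e 'finpigment::fin_cli()' simulate --out cat --n_individuals 10 --seed 42
Rscript -e 'finpigment::fin_cli()' features --catalogue cat --out run
Rscript -e 'finpigment::fin_cli()' identify --features run/features.csv --out run
Rscript -e 'finpigment::fin_cli()' stability --features run/features.csv --out run
```

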