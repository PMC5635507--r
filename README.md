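# netdamage

Quantifying physical damage to long-lasting insecticidal bed nets
(LLINs) by three complementary assessment methods, with a synthetic
net-image generator for validation against known ground truth.

Malaria control programmes replace nets based on field assessments of
physical condition. The standard WHOPES protocol counts holes in four
size classes — thumb (0.5 < d ≤ 2 cm), fist (2 < d ≤ 10 cm), head
(10 < d ≤ 25 cm), larger than a head (d > 25 cm) — and imputes each hole
the area of a **circle** at the class midpoint diameter (1.2, 28.3,
240.5, 706.9 cm²). Real holes are elongated (typical aspect ratio a/b of
2–5), so the circular imputation overestimates damaged area, which can
misclassify a net's serviceability (good < 80 cm², damaged 80–789,
too torn ≥ 790) and distort replacement decisions. This package is for
researchers who want to quantify that bias and validate image-based
alternatives.

It implements, as a tested reusable pipeline:

* **Synthetic nets** — elliptical holes planted on the five panels of a
  190 × 180 × 150 cm net with a calibrated size-class mixture (84%
  thumb-class), log-normal aspect ratios (median ≈ 2.6, rising with hole
  size), and bottom-of-net clustering; panels rendered as raster images
  with an in-frame scale marker, plus the exact ground-truth inventory.
* **Image analysis** — the ImageJ-style measurement chain: scale
  calibration (cm/px from the marker), Otsu or fixed binarization,
  8-connected particle labelling (Rcpp), and per-hole area, perimeter
  (chain-code with √2 diagonals), circularity 4πA/P², moment-fitted
  ellipse axes and aspect ratio, and centroid coordinates.
* **Damage metrics** — WHOPES classification and midpoint areas, ruler
  ellipse areas A = πab, comparison cutoffs (≥ 0.5 cm, sensitivity
  0.4 cm), per-net totals, and serviceability classes.
* **Method comparison** — paired Wilcoxon signed rank (exact under ties
  by sign-assignment enumeration up to 15 pairs; tie- and
  continuity-corrected normal beyond), Spearman rank correlation, simple
  linear regression, Kruskal–Wallis, and Bland–Altman limits of
  agreement.
* **Spatial damage** — ellipse reconstruction from (centroid, area, AR),
  cell-center rasterization and cross-net composites, and Getis-Ord Gi*
  hot/cold-spot grids with Benjamini–Hochberg FDR labelling.

## A worked example

```r
library(netdamage)

res <- run_pipeline(generator_config(), n_nets = 30, seed = 1)

summarize_distribution(res$assessments$whopes$total_area_cm2)
summarize_distribution(res$assessments$image$total_area_cm2)
```

At seed 1, 30 synthetic nets give per-net total hole areas of median
73.4 cm² (mean 182.2, IQR 2.4–253.7) under the WHOPES circular model
against median 18.9 cm² (mean 59.6, IQR 1.0–64.8) from image analysis of
the rendered panels — the circular imputation inflates the damaged area
roughly four-fold at the median. Serviceability shifts accordingly: 16
good / 12 damaged / 2 too-torn nets under WHOPES versus 25 / 5 / 0 from
the measured areas.

```r
res$comparisons$whopes_vs_image$area
#> Paired comparison: whopes vs image on total_area_cm2 (n = 30 nets)
#>   Wilcoxon signed rank: V = 351.0, p = 8.804e-06 (normal, zeros: drop)
#>   Spearman: rho = 0.962, p = 2.273e-17
#>   Regression (a on b): slope = 1.917, intercept = 67.982
#>   Bland-Altman: bias = 122.596 [-179.307, 424.499]
```

The two methods rank nets almost identically (ρ = 0.96) while disagreeing
systematically in scale — the signature of a biased but monotone area
model.

```r
res$spatial$long$gi
#> gi_star_grid: 15 x 19 cells of 10 cm, band 20 cm; 4 hot, 0 cold
```

The hot cells sit in the lowest quarter of the long sides, where the
generator concentrates damage (as field nets do, from tucking and
snagging); uniformly-holed roofs show no structure beyond chance.

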