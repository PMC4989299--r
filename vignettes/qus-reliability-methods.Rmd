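---
title: "Methods: QUS measurements of tendon integrity and their generalizability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QUS measurements of tendon integrity and their generalizability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonqus)
```

# The measurement model

A B-mode frame is an M×N grid of 8-bit intensities `I(x,y)` with a square
pixel calibration (default pixel area 0.0057 mm², i.e. ≈ 0.0755 mm per
edge). Measurements are taken inside a manually traced region of interest:
a closed contour around the tendon cross-section (transverse view) or the
band between the traced superficial and deep tendon edges (longitudinal
view, nominally 1 cm long).

## Geometric measurements

Longitudinal thickness places `n_points` (default 100) points equidistant
in x across the common x-span of the two edges, linearly interpolated along
each polyline, pairs them by index and averages the Euclidean pair
distances. Index pairing at shared x reduces to the mean vertical edge
separation; it is the deterministic reading of "equidistant points on each
edge" and coincides with the obvious construction for horizontal edges.
Transverse thickness and width are the height and width of the axis-aligned
bounding rectangle of the contour; the cross-sectional area is the shoelace
polygon area (absolute value, so tracing direction is irrelevant).

## Histogram statistics

Echogenicity, variance, skewness and kurtosis are population moments over
the ROI pixels: denominators are the pixel count (no Bessel correction) and
kurtosis is non-excess (Gaussian → 3). For a constant ROI (σ = 0) skewness
and kurtosis are undefined; they are flagged and excluded from any
downstream reliability analysis of that cell rather than coerced to 0.

Entropy deserves a note. The measurement family classifies entropy as a
first-order (histogram) statistic, but the conventional printed formula
sums over a co-occurrence structure `p(i,j)`. Both readings are computed:
the default `entropy_mode = "histogram"` uses `−Σ q_k log₂ q_k` over the
256-bin normalized histogram (bounded by 8 bits), and
`entropy_mode = "cooccurrence"` uses the direction-averaged
`−Σ p log₂ p` of the co-occurrence matrix. Which one a given legacy
analysis used is generally not recoverable; making the switch explicit
keeps both reproducible. Logarithms are base 2 throughout and
`0·log 0 ≡ 0`.

## Co-occurrence texture

The GLCM counts ordered pixel pairs `(p₁, p₁ + offset)` with both pixels in
the ROI, over the full 256-level grayscale (no quantization). Offsets for
distance `d` (default 10 px) are `(0,d)`, `(−d,d)`, `(−d,0)`, `(−d,−d)` for
0°, 45°, 90°, 135°: diagonal directions step d pixels per axis (Chebyshev
distance), a deterministic convention that avoids rounding Euclidean
offsets. Counting is symmetric by default (each pair plus its reverse, the
standard Haralick convention, making 0° ≡ 180°), each direction's matrix is
normalized separately, and contrast, energy, homogeneity and co-occurrence
entropy are averaged over the four directions; per-direction values are
retained in the detail record. A mask too small to contain any pair at the
requested offset is an explicit error, never a silent zero matrix.

## Rasterization

A pixel belongs to the ROI when its center lies inside the region:
even-odd ray crossing for contours, vertical containment between the
interpolated edges for bands; centers exactly on the boundary are included.
The pixel grid has its origin at the top-left corner, x = column,
y = row (depth), and pixel (r,c) has center (c+0.5, r+0.5). Mask area times
pixel area converges to the shoelace area within 2% for convex ROIs
enclosing ≥ 500 pixels; the tests enforce this.

# Generalizability analysis

## G-study

The measurement design is fully crossed S×E×V×I (subject/tendon,
evaluator, visit, image replicate), all facets random, one observation per
cell. The 15 variance components are estimated by the method of moments:
balanced ANOVA sums of squares via inclusion–exclusion over marginal means,
expected mean squares by the Cornfield–Tukey rule (the coefficient of
`σ²_g` in `EMS(f)`, for `g ⊇ f`, is the product of the sizes of facets
absent from `g`), and the triangular system solved from the four-way term
downward. `σ²_SEVI` is the residual: with one observation per cell it is
confounded with pure error and absorbs the highest-order mean square.
Raw estimates may be negative (sampling noise); the conventional treatment
is applied — raw values are reported, and zero-clamped values feed the
proportion table and the D-study. Facets observed at a single level have
zero degrees of freedom; their components are structurally zero and
reported as such.

On noise-free single-effect data the estimator returns the *sample*
variance of the realized effects (the n−1 denominator falls out of the EMS
algebra); this is the unbiased method-of-moments answer and what dedicated
G-theory software computes.

## D-study

For a protocol averaging `n_e` evaluators, `n_v` visits, `n_i` images, the
absolute error variance is

σ²_Δ = Σ over the 14 non-subject effects of σ²_effect / (product of the
protocol sizes of the E/V/I facets in that effect),

e.g. `σ²_SEI/(n_e·n_i)` and `σ²_SEVI/(n_e·n_v·n_i)`. Then
`Φ = σ²_S/(σ²_S+σ²_Δ)`, `SEM = √σ²_Δ`, `MDC_abs = z·√2·SEM` with z = 1.65
(90% confidence, configurable), and `MDC_norm = 100·MDC_abs/mean`. The
dependability (absolute-error) coefficient Φ is the primary index because
the intended use is criterion-referenced clinical measurement; the
relative-error generalizability coefficient (only subject-interaction
terms in the error) is computed alongside, since published reliability
tables frequently do not state which was used and the two differ whenever
evaluator or visit main effects are non-negligible. Interpretation bands:
poor < 0.50 ≤ moderate < 0.75 ≤ good < 0.90 ≤ excellent.

MDC normalization uses the per-group mean (symptomatic and asymptomatic
tendons are analysed separately throughout, matching how such studies
report them); the grand mean can be passed explicitly instead. The default
confidence interval in the group summary is the normal approximation
`mean ± 1.96·SD/√n` over tendons (each tendon's images averaged first);
a t-based option exists because the convention varies between reports and
printed CIs rarely pin it down.

# The synthetic world

`simulate_tendon_image()` renders a smooth echo map — a horizontal tendon
band with sinusoidal fibrillar striation (longitudinal) or an ellipse
(transverse) on a darker background — multiplied by i.i.d. unit-mean gamma
speckle, clipped to 0..255. Defaults state the two conditions:

| parameter | healthy | pathologic | unit | why |
|---|---|---|---|---|
| thickness | 0.52 | 0.68 | cm | published group means used as plausible anatomy |
| width (transverse) | 1.30 | 1.37 | cm | same |
| mean echo | 83 | 79 | gray | same |
| band amplitude | 30 | 10 | gray | fibrillar striation is disrupted in tendinopathy |
| lesion | none | 35-gray drop, radius 0.6·t/2 | | focal hypoechoic core |
| speckle shape | 4 | 4 | | typical fully developed speckle roughness |

The band period (8 px ≈ 0.6 mm) and background echo (45) are single fixed
choices of plausible scale. The generator emulates: group-dependent
echogenicity/texture direction, exact ground-truth geometry, and
reproducibility from seed. It does **not** emulate: physical wave
propagation, probe-angle anisotropy, attenuation with depth, scan
conversion, or blurred tendon borders — so a green geometric round-trip
establishes correctness of the measurement code on idealized tracings, not
robustness to real tracing ambiguity.

`simulate_feature_study()` has two modes. *Linear* mode draws one
independent zero-mean Gaussian per realized level combination of each of
the 15 effects with the requested variances and sums them — the textbook
random-model generator, used for estimator-recovery tests. *Imaging* mode
renders a phantom per design cell and maps facets onto image-formation
causes: a per-evaluator intensity gain (SD 0.03) and a per-(subject,
evaluator) vertical ROI placement error (SD 3 px ≈ 0.23 mm) for the
evaluator; a per-visit gain (SD 0.015); a fresh speckle draw per image.
The placement jitter is the deliberate source of subject×evaluator
interaction — each evaluator re-places the tracing differently on each
tendon — and the tests verify that the SE-family components (SE, SEV, SEI)
exceed their jitter-free counterparts, as a directional property of the
simulator only. Effect-size defaults are free choices of realistic
magnitude (published tables give only variance *proportions*, never
original-unit components), fixed once here.

# Numerical and degenerate-input choices

* 8-bit intensities enforced; deeper data only with explicit min–max
  rescale; unequal RGB channels only with explicit collapse (mean).
* Anisotropic pixel spacing is rejected — one area constant implies square
  pixels.
* Self-intersecting contours, < 3 vertices, zero area, coincident or
  crossing band edges: errors at construction.
* Probabilities sum to 1 within 1e−9 in every GLCM; proportion rows sum to
  100 within 1e−9.
* `MDC_abs/SEM ≡ 1.65·√2` exactly, all inputs.
* All randomness flows from a single seed per generator call; identical
  seeds give bit-identical images, masks and tables.

# Known limitations

* Only balanced, fully crossed designs: no nesting, no missing cells, no
  confidence intervals on variance components.
* The GLCM on 256 levels makes energy/homogeneity magnitudes sensitive to
  ROI size; legacy analyses that quantized gray levels will not be
  numerically comparable even on identical images.
* Published D-study tables from undeposited images cannot be reproduced and
  are deliberately not asserted; the package validates its reliability
  machinery against closed forms and Monte-Carlo recovery instead.
* DICOM input requires the optional Python pydicom package.
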