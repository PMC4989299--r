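# tendonqus

Quantitative ultrasound (QUS) measurements of tendon integrity, and the
generalizability analysis needed to decide whether those measurements are
reliable enough to use in the clinic.

## The problem

B-mode ultrasound of a tendon (the Achilles is the motivating case) shows
healthy tissue as a bright, regularly striated band and tendinopathic
tissue as a thickened, darker, more homogeneous region. Reading such images
by eye is subjective, so quantitative measures are extracted from a traced
region of interest (ROI) instead. This package computes the standard set of
11 QUS measurements from an 8-bit grayscale frame:

* **geometric** — mean thickness (longitudinal view: 100 x-equidistant
  point pairs across the traced edges, averaged), maximum thickness, width
  and cross-sectional area (transverse view: bounding rectangle + shoelace
  polygon area);
* **grayscale-histogram statistics** over the ROI pixels `I(x,y)` —
  echogenicity `x̄ = Σ I/n`, population variance `σ²`, skewness
  `S_k = m₃/σ³`, kurtosis `K_t = m₄/σ⁴` (non-excess), entropy
  `E = −Σ q_k log₂ q_k` over the 256-bin histogram;
* **co-occurrence texture features** from gray-level co-occurrence matrices
  `p(i,j)` at offset distance d = 10 pixels in the four directions
  0°/45°/90°/135° (direction-averaged, symmetric counting) — contrast
  `Σ|i−j|² p(i,j)`, energy `Σ p(i,j)²`, homogeneity `Σ p(i,j)/(1+(i−j)²)`.

Any single measurement is contaminated by who held the probe, the visit and
the particular frame. The package quantifies each error source with
**generalizability theory** on the fully crossed subject × evaluator ×
visit × image (S×E×V×I) random design:

* **G-study** — the 15 variance components `σ²_S … σ²_SEVI` by balanced
  ANOVA expected mean squares (the four-way term is the residual);
* **D-study** — for a protocol averaging `n_e` evaluators, `n_v` visits and
  `n_i` images: dependability `Φ = σ²_S / (σ²_S + σ²_Δ)` where `σ²_Δ` sums
  every non-subject component divided by the number of averaged levels of
  its facets; `SEM = √σ²_Δ`; minimal detectable change
  `MDC_abs = 1.65·√2·SEM` (90% confidence) and
  `MDC_norm = 100·MDC_abs / group mean`.

A synthetic phantom generator (gamma-speckled tendon images with known
geometry and group-dependent echotexture) and a crossed-design feature
simulator with known variance components make the whole pipeline testable
without any image data.

## Worked example

```r
library(tendonqus)

# a transverse phantom with known geometry, and its traced ROI
sim <- simulate_tendon_image(tendon_image_params(view = "transverse"), seed = 7)
extract_features(sim$image, sim$roi)
#> <qus_features 'sim_transverse_healthy'> transverse view, 9296 ROI pixels
#>   thickness_cm  0.519683      # truth: 0.52 cm
#>   width_cm          1.3       # truth: 1.30 cm
#>   area_cm2      0.530498      # truth: pi*a*b = 0.5307 cm^2
#>   echogenicity  82.5962
#>   variance      1661.45
#>   ...

# a crossed 20 x 2 x 2 x 2 thickness study with known variance components
p <- study_sim_params(n_s = 20,
                      components = c(S = 0.010, E = 0.0004,
                                     SE = 0.0015, SEVI = 0.0010),
                      grand_mean = 0.52)
tab <- simulate_feature_study(p, "linear", seed = 42, feature = "thickness_cm")
vc <- estimate_variance_components(tab)
round(variance_proportions(vc), 1)
#>    S    E    V    I   SE   SV   SI   EV   EI   VI  SEV  SEI  SVI  EVI SEVI
#> 87.3  0.6  0.0  0.0  6.3  0.3  0.0  0.0  0.0  0.0  0.3  1.8  1.1  0.0  2.2

protocol_grid(vc, group_mean = mean(tab$value))
#>   n_e n_v n_i   phi     label    sem mdc_abs mdc_norm rel_coefficient
#> 1   1   1   1 0.873      good 0.0525  0.1226     23.9           0.879
#> 2   1   1   2 0.896      good 0.0469  0.1096     21.3           0.902
#> 3   1   1   3 0.904 excellent 0.0449  0.1049     20.4           0.910
#> 4   1   2   1 0.891      good 0.0482  0.1125     21.9           0.897
#> 5   1   2   2 0.907 excellent 0.0442  0.1030     20.1           0.913
#> 6   1   2   3 0.912 excellent 0.0427  0.0997     19.4           0.918
```

Read: 87% of the observed thickness variance is true between-tendon
variance; averaging three images from a single visit by one evaluator
lifts dependability from 0.87 to 0.90 ("excellent") and shrinks the
90%-confidence minimal detectable change from 23.9% to 20.4% of the group
mean — the protocol-design question the D-study answers.

## Command line

```sh
qus simulate   --out-dir study --seed 1 --n-s 4        # phantom study
qus extract    --design study/design.csv --images study --rois study \
               --out study/features.csv
qus summary    --features study/features.csv --out study/summary.csv
qus reliability --features study/features.csv --out-dir study/report
```

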