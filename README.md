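# fibroquant

Digital quantification of myocardial fibrosis on Masson's-trichrome
stained tissue images, for pathology-image and method-validation work.
The package implements three independent estimators of the collagen
**area fraction** (fibrosis %) and the full agreement-statistics battery
to compare them:

* **Colocalization** — Ruifrok–Johnston colour deconvolution
  (OD = −log10((pixel + 1)/I0), per-pixel unmixing `a = OD · V⁻¹`),
  strict per-stain thresholds, eight stain-combination categories, and
  fibrosis % = %[3] + %[2+3] + %[1+3] of tissue (non-NONE) pixels;
* **Trainable per-pixel classifier** — glass / myocardium / fibrosis from
  colour + local texture features (3 OD + local mean + local SD, 7 px
  window), multinomial logistic learner, 1000-iteration budget,
  fibrosis % = 100·nF/(nF + nM) ignoring glass;
* **Point-grid stereology** (reference method) — systematic lattice
  (interval 200 px at whole-slide scale, random offset for unbiasedness),
  p̂ = nF/n over points ignoring glass/other, with the Weibel
  point-counting uncertainty RSE = sqrt((1 − p)/(p·n));
* **Agreement statistics** — summary tables, Pearson matrix, Friedman
  test (tie-corrected) with Wilcoxon signed-rank post hoc under
  Bonferroni (0.05/4 = 0.0125), raw and ln(x+1) regression, and
  Bland-Altman limits of agreement (mean ± 2 SD) with the reference on
  the X axis.

A synthetic-histology module generates trichrome-like tiles with exact
per-pixel ground truth (Beer–Lambert rendering through documented stain
OD vectors), so the whole pipeline is testable end to end without real
slides. See the vignette `vignettes/fibrosis-quantification.Rmd` for the
models, parameter choices and design rationale.

## Worked example

```r
library(fibroquant)

# a 256x256 phantom with 22% true fibrosis of tissue, rendered with camera noise
ph   <- generate_phantom(256, 256, 0.22, seed = 42)
tile <- render_trichrome(ph, noise_sd = 0.02, seed = 43)
ph
#> Tissue phantom 256 x 256 px (0.50 um/px)
#>      GLASS MYOCARDIUM   FIBROSIS      OTHER
#>      30.00      53.51      15.09       1.40
#> fibrosis % of tissue: 22.00

quantify_colocalization(tile)
#> Colocalization result: 44957 tissue px, fibrosis 22.00%
#>    S1    S2    S3   S12   S13   S23  S123
#>  0.00  0.73 12.38 77.26  9.62  0.00  0.00

grid <- build_grid(c(0, 0, 256, 256), sampling_interval = 9,
                   offset = "random", seed = 44)
estimate_area_fraction(auto_label_points(grid, ph))
#> Point count: 553 effective points, fibrosis 20.98% (RSE 0.083)

mont <- build_training_montage(seed = 45)
tr   <- train_classifier(mont, seed = 46)       # accuracy 1.0000
genie_fibrosis_fraction(classify_tile(tile, tr$model))
#> [1] 22.00

bland_altman(c(10, 20, 30), c(12, 19, 33))
#> Bland-Altman: bias 1.333, LoA [-2.830, 5.497] (mean +/- 2 SD, n = 3)
```

The three routes agree on the phantom to within their expected errors:
colocalization and the classifier recover the 22.00% truth exactly on
this tile, and the 553-point stereology grid estimates 20.98% with a
relative standard error of 8.3% — i.e. 21.0 ± 1.7 percentage points,
bracketing the truth.

A full synthetic study (cohort, all three routes per slide, simulated
pathologist, comparison report) is one call:

```r
st <- run_study(study_config(n_slides = 116, seed = 1), "study_out/")
st$report$friedman          # Friedman chi2(3) over the four matched methods
st$report$bland_altman$genie
```

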