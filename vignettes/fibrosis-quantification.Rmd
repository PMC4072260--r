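---
title: "Quantifying myocardial fibrosis on trichrome images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial fibrosis on trichrome images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## The problem

Myocardial fibrosis — excess collagen in heart muscle — is routinely graded
on Masson's-trichrome stained endomyocardial biopsies. The clinically
interesting quantity is the collagen **area fraction**: the percentage of
tissue area occupied by collagen. Visual scoring by a pathologist is fast
but semi-quantitative; digital methods promise objectivity but need
validation against an independent reference. This package implements three
estimators of the same quantity and the statistics needed to compare them:

1. **Colocalization** — colour-deconvolution stain unmixing followed by
   per-pixel stain-combination classification;
2. a **trainable per-pixel classifier** (glass / myocardium / fibrosis)
   using colour and local texture features;
3. **point-grid stereology**, the reference method, with the Weibel
   point-counting uncertainty.

Because real annotated slides are rarely available for testing, a
synthetic-histology module renders trichrome-like tiles from phantoms with
exact per-pixel ground truth, so every claim the package makes about its
estimators is checked by code against known truth.

## Image model

Stains obey the Beer–Lambert law: with background (glass) intensity $I_0$
and per-stain unit optical-density (OD) vectors $v_s$, a pixel carrying
amounts $a = (a_1, a_2, a_3)$ transmits

$$I_c = I_0\,10^{-\sum_s a_s v_{s,c}}, \qquad c \in \{R, G, B\}.$$

The OD transform used throughout is
$\mathrm{OD}_c = -\log_{10}\!\big((\mathrm{pixel}_c + 1)/I_{0,c}\big)$,
clamped at zero; the one-count guard keeps fully dark pixels finite.
Unmixing solves the linear system $a = \mathrm{OD}\,V^{-1}$ per pixel.

### Default stain directions

The trichrome deconvolution matrix is rarely published, so the package
ships documented defaults (`trichrome_od_vectors()`), all overridable:

* stain 1, Weigert's iron hematoxylin — brown-black nuclei, broad
  absorption strongest in blue: $(0.52, 0.46, 0.72)$ normalised;
* stain 2, Biebrich scarlet / acid fuchsin — red muscle, absorbing green
  and blue: $(0.10, 0.74, 0.67)$;
* stain 3, aniline blue — collagen, absorbing red and green:
  $(0.80, 0.59, 0.11)$.

The triple was chosen for physical plausibility **and** conditioning: with
a conventional alum-hematoxylin direction the matrix is nearly singular
(hematoxylin ≈ red + blue), amplifying quantization noise roughly
fifty-fold. The shipped triple has condition number ≈ 5, which keeps the
8-bit render–unmix round trip quantization-limited: in the
light-to-moderate staining regime (per-stain amounts up to 0.2 OD) the
worst-case amount error stays below 0.01 OD, and the class-mean defaults
round-trip to about 0.005 OD.

## The three estimators

**Colocalization.** A stain is *present* where its deconvolved amount
strictly exceeds a per-stain threshold (default 0.15 OD — the toolkits
this emulates expose thresholds but not values; amount-space was chosen
and is not silently changed). Each pixel lands in one of eight categories
(none, 1, 2, 3, 1+2, 1+3, 2+3, 1+2+3). *Tissue* is the set of non-NONE
pixels — the algorithm's own 8-way output defines its denominator — and

$$\text{fibrosis \%} = \%\,[3] + \%\,[2{+}3] + \%\,[1{+}3],$$

the collagen-bearing combinations. Negative deconvolved amounts are kept
(they simply fail the threshold). An eight-colour markup image with a
fixed documented palette (NONE white) supports visual review.

**Trainable classifier.** A surrogate for proprietary trainable
segmentation engines, defined by the same I/O contract: marked example
regions of glass / myocardium / fibrosis in, per-pixel class map out,
with the fibrosis percentage *of tissue* computed ignoring glass,
$100\,n_F/(n_F + n_M)$. Features are deliberately restricted to
"spatial recognition without morphology": the 3 ODs plus the local mean
and local population SD of each OD channel over a square window (default
7 px ≈ 3.5 µm at 0.5 µm/px). The learner is multinomial logistic
regression (`nnet::multinom`) with the iteration budget (default 1000)
as `maxit`, a small ridge penalty (decay $10^{-4}$) for stability on
separable data, and inverse-frequency class weights (switchable).
Because the weights preserve class proportions, duplicating all training
regions leaves the decision rule unchanged, though coefficients can shift
slightly through the fixed ridge penalty — decisions, not parameters, are
the invariant. Training accuracy is estimated by reclassifying the
training pixels.

**Stereology.** A systematic lattice with sampling interval $T$ (default
200 px, the whole-slide setting) is anchored at the ROI origin plus an
offset; drawing the offset uniformly from $[0, T)^2$ (seeded) makes the
estimator unbiased. A point is the single pixel at the lattice node —
`pattern_size` only scales the rendered marker. With $n$ effective points
(glass and "other" ignored, consistently in both numerator context and
denominator) and $n_F$ fibrosis points,

$$\hat p = n_F / n, \qquad
  \mathrm{RSE}(\hat p) = \sqrt{\frac{1 - p}{p\,n}},$$

the standard expected relative error of point counting (the Weibel
coefficient of error; the toolkit this emulates cites it without printing
the expression, so the binomial form is used and tested against a
Monte-Carlo oracle). At $p = 0$ the uncertainty is reported as undefined
rather than zero. `recommended_sampling_interval()` plans the spacing so
small tiles still meet the 500-point floor used for the smallest
biopsies, or the general 150–200-point precision recommendation.

## The synthetic generator

`generate_phantom()` builds the label map: a contiguous tissue blob
(smooth Gaussian field plus a radial bias, default 70 % of the tile),
small OTHER inclusions (default 2 % of tissue), and collagen assigned by
taking the top-$k$ pixels of an anisotropically smoothed field (default
row/col smoothing 2/8 px, giving strand-like collagen). Choosing $k$ by
count makes the achieved fibrosis fraction of tissue exact to one pixel —
only area fraction and spatial contiguity matter downstream, so no
attempt is made at photorealistic histology.

The fraction's denominator is myocardium + fibrosis: glass and OTHER are
excluded, matching the stereology counting rule. The OTHER class is
rendered nearly unstained — glass-like areas inside the myocardium, one
of the category's real constituents. This is a deliberate design choice:
a strongly stained OTHER class would enter the colocalization route's
tissue denominator (which is defined by staining, not by truth labels)
and bias that estimator by construction rather than by anything the
method does. Glass-like OTHER keeps all three routes consistent with one
truth definition while still exercising the denominator rule — stereology
points on OTHER come from the label map, not from appearance.

`generate_cohort()` draws per-slide true percentages
stratified-uniformly over the study range (default 0–90 %, matching the
span reported for real biopsy series), renders one tile per slide
(default 256×256 px at 0.5 µm/px), and applies per-slide log-normal
staining jitter (SD 0.05 — slide-to-slide variability is real but
unreported, so the value is a modest choice, exposed as a parameter).
Camera noise is Gaussian in OD (default SD 0.02, clamped at zero
amounts). `simulate_pathologist()` models visual scoring as truth plus
Gaussian reading noise (SD 4 points), rounded to a 5-point step — the
granularity visible in real score tables — and clipped to [0, 100].

What the generator does **not** emulate: nuclei and cell-level texture,
focus/tiling scanner artifacts, stain diffusion at class boundaries
(pixels are class-pure, so boundary mixing — a real error source — is
absent), and uneven section thickness. Passing tests therefore validate
the algorithms and their contracts, not performance on real slides.

## Statistics battery

All conventions follow common statistics-package defaults of the era the
comparison design comes from, and each one is tested against an
independent oracle:

* summary tables use the sample SD ($n-1$) and `range = max - min`;
* Pearson correlations with two-sided $t$-distribution p values
  ($n - 2$ df); zero-variance columns are flagged undefined, never NaN;
* Friedman test on within-slide average ranks with the tie-corrected
  (Conover) statistic, reducing to the classical formula without ties;
  all-tied data give $\chi^2 = 0$ by convention; df $= k - 1$;
* Wilcoxon signed-rank post hoc: zero differences dropped, average ranks
  for ties, tie-corrected variance, **no** continuity correction, signed
  $Z = (W^+ - \mu)/\sigma$; the Bonferroni-adjusted level is
  `family_alpha / n_pairs` (0.05/4 = 0.0125 for the four standard pairs).
  At $n = 8$ the normal approximation agrees with exhaustive
  $2^8$ enumeration within 0.06 in two-sided p (mid-range p is the worst
  case; tails agree within 0.01) — that is the documented tolerance;
* regression is OLS, raw and after $\ln(x + 1)$ (the +1 offset handles
  the exact zeros that occur at both ends of the scale; configurable);
* Bland-Altman uses `test - reference` differences plotted against the
  **reference** (not the pairwise mean — appropriate when one method is a
  reference standard), with limits of agreement mean ± 2·SD (sample SD);
* p values are formatted as `p < 0.001`, never literal zero.

The Friedman comparison defaults to the four matched columns
stereology, colocalization, genie, pathologist_mean (df = 3); the column
set is configurable.

## The full study and problem sizes

`run_study()` composes everything: cohort generation (or tile ingestion
via a manifest), one classifier trained on a rendered three-class
montage, the three estimators per slide, simulated week-0/week-2
pathologist readings, and the complete report (summary, correlations,
Friedman + post hoc pairs, Bland-Altman and raw/ln regressions against
the reference), with deterministic CSVs: identical config and seed give
byte-identical files.

Problem sizes used by the package's own validation: 116 slides of
256×256 px (the synthetic analogue of the real series size), 20-tile
recovery cohorts at 128×128 px, a 1024×1024 px phantom with 1000 random
grid offsets for the unbiasedness/calibration check, and a stereology
interval of 9 px on 256 px tiles — the spacing
`recommended_sampling_interval()` returns for the 500-point floor at
70 % tissue. These sizes keep the whole validation suite desk-scale
while leaving every estimator's statistical behaviour measurable.

A constructed mis-calibration case documents the known failure mode of
threshold-based colocalization: with broad OD noise and the collagen
threshold placed inside the myocardium/collagen overlap, false-positive
collagen dominates at low true fibrosis and false-negative at high —
positive bias at the low end, negative at the high end of the scale.

## Known limitations

* The classifier surrogate is a linear model on 9 features; it matches
  a trainable segmentation engine's *contract*, not its internals, and will not
  reproduce behaviours that depend on evolved morphological features.
* Synthetic tiles have class-pure pixels; boundary-pixel mixing, the
  main source of real colocalization error at interfaces, is absent.
* The Weibel uncertainty assumes near-binomial sampling; for strongly
  clustered collagen and coarse grids the systematic-grid variance can
  deviate from the prediction (the calibration test bounds this at 20 %
  for the generator's morphology).
* Percentages are planar area fractions on a projection of a 3 µm
  section, not true volume fractions.
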