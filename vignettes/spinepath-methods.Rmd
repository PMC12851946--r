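---
title: "spinepath: models, synthetic worlds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinepath: models, synthetic worlds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package is

`spinepath` is an end-to-end digital-pathology toolkit for vertebral
compression fractures (VCF). A VCF can be osteoporotic (fragility), traumatic
(high-energy injury) or neoplastic (marrow replaced by tumor), and the three
etiologies leave different marks on an H&E-stained bone biopsy: thin, sparse,
fragmented trabeculae with fat-rich marrow; a fracture cleft surrounded by
inflammatory infiltrate; or dense clusters of atypical, elongated nuclei.
The package implements the full analysis chain — slide preprocessing, bone
histomorphometry, attention-based multiple-instance-learning (MIL)
classification with Grad-CAM explanations, a gradient-boosted survival risk
score with exact SHAP attributions, transcriptomic signature scores, and a
survival-statistics toolkit — together with a seeded synthetic-data module
that renders H&E-like slides and cohorts with *planted ground truth*, so
that every stage can be verified against a known answer.

Real WSI cohorts of this kind are private; nothing here claims to reproduce
any particular clinical cohort's numbers. What a green test establishes is
that each algorithm recovers what was planted, at stated tolerances, under
the stated synthetic world.

# The synthetic world

## Slides

Slides are composed in *stain-concentration space*. Three fixed unit-norm
optical-density vectors (hematoxylin, eosin, and a collagen-toned third
vector; `he_reference_stains()`) convert per-pixel concentration maps to RGB
through the Beer-Lambert relation `I = I0 * 10^-(V c)` with the same OD
convention the preprocessing stage uses (`OD = -log10((I8+1)/255)`). This
gives Macenko stain estimation a known answer and makes stain unmixing an
exact inverse problem up to 8-bit quantization.

Geometry and defaults:

* **Scale.** 4 µm/px, so a 512-px slide is a 2 × 2 mm field. The source
  imagery this emulates is scanned at 0.25 µm/px on ~100,000-px slides;
  desk-scale tests need realistic trabecular geometry (widths 80–160 µm,
  spacings 200–800 µm) to fit in a small canvas, which 4 µm/px provides.
  This constant is stated once and never tuned.
* **Trabeculae.** Two orthogonal families of sinusoidally displaced strands
  of width *w* and spacing *s*, with *s* solved from the bone-fraction
  target via `1-(1-w/s)^2 = f` and *w* then bisected against the rendered
  mask because, with only a handful of strands, pixelation and edge clipping
  move the area fraction by more than the ±0.02 recovery tolerance. The
  fitted width is recorded as the planted thickness.
* **Class hallmarks.** Osteoporotic: *w* ≈ 18 px, bone fraction 0.14,
  adiposity 0.45, strand gaps punched; traumatic: *w* ≈ 36 px, fraction
  0.30, a jagged cleft with 60% of inflammatory cells within 30 px of it;
  neoplastic: four disjoint tumor clusters of high-eccentricity nuclei,
  adiposity 0.05, collagen 0.20. Eccentricity is plantable exactly because
  nuclei are filled ellipses: for semi-axes `a = 2b`,
  `e = sqrt(1-(b/a)^2) = sqrt(3)/2`.
* **Recoverability.** Every scalar in the ground truth is recomputed from
  the emitted masks (bone fraction, adiposity, collagen fraction, lacunae
  count), so the truth cannot drift from the image.

What the generator does **not** emulate: realistic chromatin texture,
scanner optics, out-of-plane tissue, pyramidal formats, or annotation noise.
A green morphometry test therefore says the estimator is correct on ideal
geometry, not that it is robust to every real-world artifact.

## Cohorts

`generate_cohort()` draws, per patient: a class (largest-remainder
apportionment, so n = 150 with proportions (0.4, 1/3, 4/15) gives exactly
60/50/40), clinical covariates, morphometry (fast mode draws the true
feature values from class-conditional Gaussians whose means were calibrated
once on rendered default slides; render mode actually renders), an
expression matrix, and survival.

The latent structure is deliberately simple and fully recorded in
`$truth`:

```
z_sev  = (1.5 z_ecc + 0.5 z_coll - 0.5 z_thick + 0.3 z_infl) / 1.68
z_imm  = 0.6 z_sev + 0.8 eta,            eta ~ N(0,1)
risk   = plogis((0.7 z_sev + 1.2 z_imm + 0.15 eps) / 1.9)
```

Nucleus eccentricity carries three times the weight of any other morphometric
feature, which is the planted "dominant feature" the SHAP ranking must
recover. The immune latent `z_imm` is coupled to severity (coefficient 0.6)
but keeps an independent component; that component is what the
transcriptomics-ablation test measures (dropping the marker genes removes
~30% of the predictable risk variance). Expression: five immune-effector
genes load 1.0 on `z_imm`, five inflammatory genes load 0.6, against unit
gene noise — individually weak, jointly informative, so that boosting cannot
recover the immune signal from a single gene and per-gene SHAP stays below
the eccentricity feature.

**Survival.** Weibull baseline (shape 1.3, median 30 months at the average
risk) with proportional-hazards multiplier `exp(beta * z)`, where `z` is the
*standardized* risk linear predictor and `beta = 1.5` by default.
The effect size is per standard deviation rather than per unit of the
bounded [0,1] score: under proportional hazards the probability that the
riskier of a pair fails first is `1/(1+exp(-d))` for a linear-predictor gap
`d`, and an effect applied to a [0,1] score caps the attainable concordance
near 0.65 — below what the planted-signal recovery examples themselves
expect. Per-SD effects give C ≈ 0.8 at `beta = 1.5` and > 0.9 for large
`beta`, matching those examples. Censoring is an independent exponential
whose rate is bisected against the cohort's own risk distribution (plus a
60-month administrative cap), so the requested censoring fraction is met
without touching the event process. Complications are a second
proportional-hazards process under the same latent risk, observed only
within 12 months.

**A planted impossibility worth knowing about.** The generator couples
immune activity *positively* to risk (emulating a reported tight positive
risk-immune correlation interpreted as pathologic, tumor-promoting
inflammation). Under any hazard monotone in the latent risk this makes
low-risk/low-immune — not low-risk/high-immune — the longest-surviving
quadrant of a median-split risk/immune stratification: conditioning on the
low-risk half leaves a positive residual immune-hazard association. A world
where high immune activity is additionally protective *given* risk would
contradict the planted coupling. The strata machinery is therefore tested
against the ordering this world actually implies (low-risk strata outlive
high-risk strata).

# Preprocessing

* **Tissue segmentation** applies Otsu's criterion to
  `1 - intensity*(1 - saturation)`, not to plain luminance: background is
  bright *and* unsaturated, while faint eosinophilic marrow is bright but
  saturated and must survive. Enclosed white holes below 1% of the frame are
  refilled — fat vacuoles are tissue, not background. Otsu's threshold is
  reported at the bin edge `(k-0.5)/255` so that `x > threshold` on the raw
  [0,1] image reproduces the 8-bit bin split exactly; the test suite holds
  the implementation to an exhaustive between-class-variance search.
* **Macenko estimation** keeps pixels with OD norm above 0.15, takes the
  top-two singular directions, and reads the stain vectors off the 1st/99th
  angle percentiles (both configurable; the source method leaves them
  unstated). Hematoxylin is ordered first by blue-channel OD. Concentrations
  use a closed-form two-variable non-negative least squares, vectorized per
  pixel.
* **Tiling** uses 0-based (row, col) coordinates over half-open intervals,
  stride `T*(1-overlap)`, grid over the tissue bounding box. The final
  row/column is shifted inward so tiles never leave the image; when the
  span is not a stride multiple this adds one tile beyond the naive
  `floor((W-T)/S)+1` count. Tiles more than 50% blank are dropped, as are
  tiles flagged by the artifact checks (variance-of-Laplacian blur test;
  folds as very dark saturated area — nuclei bottom out near gray 0.17, so
  the fold cutoff at 0.12 separates them; blankness). Every decision is
  logged.

# The MIL classifier

The desk-scale encoder is a 3-block CNN (3×3 convolutions, widths 8/16/32,
average pooling, global average pooling to a 32-d embedding) over 64×64
tiles, with a gated-attention head (`softmax(w' (tanh(Vh) * sigmoid(Uh)))`)
and a linear 3-class classifier, trained end-to-end by Adam on
class-weighted cross-entropy with optional rotation/flip augmentation.
Forward and backward passes are BLAS-batched im2col matrix products; the
gradient is verified against finite differences in the test suite, and a
fixed seed makes training bit-reproducible. Inputs are centered at 0.8 and
scaled by 0.25 — H&E tiles are mostly bright, and removing the DC component
is what lets a small Adam step budget converge.

Attention pooling is permutation-invariant by construction, which the tests
assert to 1e-6 along with the simplex constraints. Argmax ties break to the
lowest class index.

**Grad-CAM.** For a single-tile bag the class logit is linear in the
global-average-pooled last-conv activations, so the channel weights are
`Wc[class,]/HW` and the map is the rectified weighted activation sum,
bilinearly upsampled and min-max scaled. Constant tiles short-circuit to an
all-zero map flagged degenerate. The slide-level composite is the
attention-weighted mosaic of per-tile maps — the upstream description never
says how tile maps become a slide heatmap, so this is the package's choice.

The heavyweight pretrained encoders used on real cohorts (2048-d features)
are out of scope; the encoder interface takes any model object that
produces per-tile embeddings.

# The risk model

Gradient boosting with regression trees (depth ≤ 3 by default — complexity
is capped on purpose) fit to Cox partial-likelihood gradients with Breslow
risk sets, over the composite endpoint = first of death or major
complication. Missing transcriptomics is routed by learned default
directions at each split, never imputed. The raw margin maps to [0,1]
through a logistic centred at the training-margin median and scaled by its
IQR — monotone, so the C-index of the score equals that of the margin
exactly — and risk groups are the training tertiles.

**SHAP.** Because trees are shallow, exact per-tree Shapley values are
computed by enumerating subsets of each tree's used features (at most 7),
with coalition values evaluated by cover-weighted tree traversal. Local
accuracy (`sum(phi) + base = margin`) and the interaction row-sum identity
hold to machine precision, which the tests assert at 1e-6. This is exact
attribution, not sampling.

Ablation retrains on identical folds without one feature block and reports
the paired CV C-index difference with a percentile bootstrap CI over pooled
out-of-fold predictions.

# Survival statistics

Kaplan-Meier with Greenwood variance on the log scale (band clipped to
[0,1] so it always contains the estimate), two-group log-rank, Cox via
`survival::coxph` with Efron ties (the one deliberate "buy" in this module;
everything else is implemented directly and held to enumeration oracles),
Harrell's concordance with 0.5 credit for score ties, Mann-Whitney /
Kruskal-Wallis / Pearson / Spearman with Benjamini-Hochberg adjustment
across declared families, and seeded percentile bootstrap CIs (resamples on
which the metric is undefined are redrawn, counted, and capped). All
p-values are two-sided.

# Numerical conventions worth restating

* OD: base-10 log, I0 = 255, +1 offset; images are [0,1] arrays quantized
  to 8 bits by the renderer.
* Tile coordinates: 0-based (row, col), half-open.
* Otsu ties: lowest threshold wins.
* Responder rule: score strictly above threshold; equality is
  non-responder.
* Mann-Whitney U: reported for the first group (`wilcox.test` W
  convention), so {1,2,3} vs {4,5,6} gives U = 0.
* All randomness flows from one seed through `derive_seed(seed, stage)`;
  derived seeds stay below 2^31.

# Known limitations

Synthetic slides are geometric idealizations; inflammatory-cell density is
systematically undercounted at high planted densities (touching nuclei
merge faster than the watershed splits them), and slide-level trabecular
thickness reads ~15% low on wobbly lattices relative to the strand width
(junction and end effects on the skeleton) — both are documented biases,
bounded in the tests, and irrelevant to the planted *orderings* the
downstream stages consume. The MIL encoder is deliberately small; nothing
here speaks to ImageNet-scale transfer. Survival generation is proportional
hazards by construction, so the toolkit's calibration tests cannot detect
non-PH misspecification.
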