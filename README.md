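# spinepath

An explainable digital-pathology pipeline for **vertebral compression
fractures (VCF)**, written for methodologists who need every stage of such a
pipeline — from H&E pixels to survival curves — to be verifiable against a
known answer. VCFs arise from osteoporosis, trauma, or malignancy, and the
biopsy histology differs accordingly: thin fragmented trabeculae with
fat-rich marrow, a fracture cleft ringed by inflammatory cells, or marrow
replaced by dense clusters of atypical nuclei. `spinepath` implements:

* **Synthetic slides and cohorts with planted ground truth** — H&E-like
  images composed in stain-concentration space through fixed optical-density
  vectors (`I = I0·10^(−Vc)`), with pixel masks, nucleus tables, latent risk,
  and censored Weibull survival all recorded, so every estimator downstream
  has an oracle.
* **Preprocessing** — Otsu tissue segmentation (held to an exhaustive
  between-class-variance search), Macenko stain estimation/normalization
  (SVD plane + angle percentiles; closed-form NNLS unmixing), overlapping
  tiling with blank/blur/fold QC.
* **Bone histomorphometry** — trabecular fraction, thickness/separation
  (`2 × mean EDT on the skeleton`), a disruption score
  (endpoints + components − 1 per bone mm²), marrow adiposity, collagen
  fraction by 3-stain deconvolution, watershed nuclear morphometry with
  moment-based eccentricity `e = sqrt(1 − (b/a)²)`.
* **Attention-MIL classification** — a slide is a bag of tiles; a small CNN
  encoder, gated attention `softmax(wᵀ(tanh(Vh) ⊙ σ(Uh)))` and a linear
  head are trained end-to-end on slide labels (class-balanced cross-entropy,
  Adam, bit-reproducible given a seed), with Grad-CAM tile maps and
  attention-weighted slide heatmaps.
* **Survival-augmented gradient boosting** — depth-capped trees fit to Cox
  partial-likelihood gradients over the composite endpoint (first of death
  or major complication), margins mapped monotonically to a [0,1] risk
  score, tertile risk groups, **exact** per-tree Shapley values and
  interaction values (subset enumeration; `Σφ + base = margin` to machine
  precision), and block ablations.
* **Omics signatures** — immune activity (mean of effector genes), RANKL /
  steroid / chemotherapy response scores, threshold responder calls,
  combined risk × immune strata.
* **Survival statistics** — Kaplan–Meier with Greenwood bands, log-rank,
  Cox (Efron ties), Harrell's C (ties = 0.5), Mann–Whitney/Kruskal–Wallis,
  Benjamini–Hochberg, seeded percentile bootstrap.

Everything is exercised on synthetic data; no claim is made about
reproducing any private clinical cohort.

## Worked example

```r
library(spinepath)

co <- generate_cohort(cohort_spec(n_patients = 150, seed = 1))
table(co$clinical$fracture_class)
#>   neoplastic osteoporotic    traumatic
#>           40           60           50

ep <- composite_endpoint(co$clinical)
fu <- fuse_features(co$clinical, co$features, co$class_probs, co$expression)
m  <- train_risk(fu, ep$time, ep$event, seed = 1)
m
#> <risk_model> 120 trees, 27 features; CV C-index 0.713

sc <- score_risk(m, fu$X)
round(tapply(sc$risk_score, co$clinical$fracture_class, median), 3)
#>   neoplastic osteoporotic    traumatic
#>        0.625        0.420        0.486

head(explain_shap(m, fu$X, interactions = FALSE)$importance, 3)
#>                     feature mean_abs_shap
#> 1 nucleus_eccentricity_mean     0.6099596
#> 2 marrow_adiposity_fraction     0.4482006
#> 3                 expr_PRF1     0.3942606
```

The class counts are the planted 60/50/40 split; risk medians reproduce the
planted ordering osteoporotic < traumatic < neoplastic; and nucleus
eccentricity — planted with three times the weight of any other morphometric
feature — tops the SHAP ranking. Stratifying survival by the risk tertiles
separates the high and low groups decisively on this cohort
(log-rank χ² = 103.4, p = 2.7e-24), and the risk score correlates with the
immune activity score (Pearson r = 0.72) because the generator couples the
immune program to the latent risk.

Slide-level work is just as direct:

```r
r   <- render_slide(slide_spec("neoplastic", seed = 7))
pre <- preprocess_slide(r$image, preprocess_config(tile_size_px = 64))
feats <- compute_histomorphometry(pre$normalized, 4, pre$mask)
```

A command-line interface mirrors the R API
(`exec/spinepath <synth|preprocess|features|train-mil|predict|explain-cam|
train-risk|score|shap|omics|survival|run|validate>`); `run` executes the
whole pipeline from one JSON config and writes a hashed run manifest.

## Acceptance

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance contract for this package is property-based (planted-signal
recovery at stated tolerances) and lives in
`tests/testthat/test-acceptance.R`: Otsu-oracle equivalence, Macenko
recovery within 5°, tiling exactness, morphometry recovery (bone fraction
±0.02, bar thickness ±1 px, adiposity ±0.03, eccentricity ±0.01, disruption
monotonicity), MIL held-out accuracy ≥0.90 with attention and Grad-CAM
localization, risk-model recovery (CV C-index ≥0.75, exact SHAP, ablation),
survival-statistics calibration, and bit-determinism of the full pipeline.
There are no numeric acceptance targets; the script verifies an end-to-end
seeded smoke run and writes an empty JSON object.
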