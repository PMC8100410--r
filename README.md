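# ADStage

Severity staging of Alzheimer's disease from imaging-derived morphometric
features: an end-to-end, fully testable R implementation of a
denoise → feature-learn → reduce → classify → evaluate pipeline.

## The problem and who this is for

Clinicians grade Alzheimer's severity with the Mini-Mental State Examination
(MMSE, an integer 0–30 score), banded into four ordinal stages: low (25–30),
mild (20–25), moderate (10–20) and severe (0–10). Given per-patient
imaging-derived feature vectors (285 morphometric features in the reference
setting) the pipeline predicts that stage. The package is aimed at
methods-oriented neuroimaging analysts who need each stage of such a
pipeline as an inspectable, tested component rather than a black box — and
who usually cannot redistribute the underlying clinical data, which is why
every input has a seeded synthetic generator.

## What is inside

* **Variational denoising** of 3-D volumes by gradient descent on
  `E(I) = Σ_Ω [1 + β²|∇I|² + (λ/2)(I − I₀)²]`, with a candidate-filter
  local search (Gaussian blur, mean filter, intensity scaling) that only
  ever accepts energy decreases, plus PSNR evaluation and NIfTI I/O.
* **Robust multitask feature learning (rMTFL)**: weights `W = P + Q` with a
  row-sparse shared component and column-sparse outlier tasks,
  `min Σᵢ (1/(m nᵢ))‖Xᵢᵀwᵢ − yᵢ‖² + λ₁‖P‖₁,₂ + λ₂‖Qᵀ‖₁,₂`,
  solved by accelerated proximal gradient with closed-form group
  soft-thresholding; feature scores, outlier-task detection, and grid-based
  penalty selection.
* **PCA reduction** with the normalized cumulative eigenvalue rule
  (keep the smallest i with NCSE(i) ≥ 0.98).
* **MMSE severity banding** with explicit, configurable boundary
  conventions.
* **Classifiers**: KNN, SVM, decision tree, LDA, random forest behind one
  contract, and a small 1-D CNN (16×5 convolution → 384-384-384 → 4,
  softmax/cross-entropy) with hand-written, finite-difference-verified
  backpropagation.
* **Evaluation**: confusion matrices, per-class sensitivity/precision
  (undefined reported as `n/a`, never 0), accuracy, one-vs-rest ROC/AUC.
* **Synthetic generators** for phantom volumes with known clean truth,
  multitask problems with planted supports, and labelled patient cohorts.

## Worked example

```r
library(ADStage)

co  <- makeCohort(nPatients = 1000, effectSize = 3, seed = 1)
res <- runSeverityPipeline(co, seed = 1)

res$nSelected
#> [1] 192
res$reductionPercent
#> [1] 32.6
round(sapply(res$reports, function(r) r$accuracy), 3)
#>   knn   svm    dt   lda    rf   cnn
#> 1.000 0.895 1.000 1.000 0.900 1.000
```

The cohort has 1000 patients with 285 features; a stratified 80/20 split
trains on 800. PCA fitted on the training split keeps 192 components to
reach 98% variance (a 32.6% feature reduction), and the six classifiers are
trained on the projected scores and evaluated on the 200 held-out patients.
At `effectSize = 3` the classes are separable by construction, so the
distance- and discriminant-based methods are perfect; the two methods that
subsample or rescale features (RF, SVM) lose the rare classes in the ~190
uninformative retained components — see the vignette for why that is a
property of the deliberately low-rank generator. Per-class detail:

```r
comparisonTable(res$reports)["cnn", c("sens_low", "sens_severe", "accuracy")]
#>   sens_low sens_severe accuracy
#> cnn 100.0%      100.0%   100.0%
```

Two self-contained worked numbers from the reference analysis reproduce
exactly: dropping 285 features to 167 is a 41.4% reduction
(`reductionPercent(285, 167)`), and a low-severity confusion row of
(656, 30, 4, 0) over 690 patients gives 95.1% sensitivity.

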