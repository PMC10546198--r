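# fundusplus

Screening for **plus disease** — the treatment trigger of retinopathy of
prematurity (ROP), marked by dilation and tortuosity of the posterior
retinal vessels — from **smartphone fundus photographs**. Smartphone images
taken through an inexpensive condensing lens vary wildly in size
(300–1200 px), lighting and reflections; `fundusplus` provides the full
workflow that makes them usable:

* **Harmonization** (`harmonize()`): green channel → Hough-circle fundus
  mask → crop/zero-pad to square → linear unsharp masking (5×5 box, gain 3)
  → CLAHE → Gaussian smoothing → bilinear resize to 800×800. Deterministic,
  with per-image provenance.
* **Enhancement quantification** (`cii()`): the contrast improvement index,
  the ratio of mean local contrast C = mean over 3×3 windows of
  (max−min)/(max+min), processed vs original; CII > 1 means enhancement.
* **Imbalance handling** (`stratified_kfold()`, `augment_eightfold()`,
  `balance_select()`): stratified folds, eightfold geometric augmentation
  (identity, five rotations, two reflections) and randomized balanced
  selection, with provenance tags that forbid train/test leakage through
  augmented descendants.
* **Cost-weighted learning** (`loss_spec("rwwce")`): real-world-weight
  cross-entropy

  `J = -(1/M) Σ [ w_fn · y · log h + w_fp · (1−y) · log(1−h) ]`

  with default dollar weights w_fn = $1,700,000 (a missed case ≈ lifelong
  blindness) and w_fp = $17,000 (an unnecessary treatment) — a 100:1 ratio.
* **Classifier** (`train_classifier()`, `predict()`, `cam()`): a small
  4-block CNN with global average pooling (C++ backprop, verified against
  finite differences) and exact class activation maps. A
  `transfer_inception` mode mirrors the published pretrained-backbone setup
  but requires weights unavailable offline, and says so.
* **Evaluation** (`confusion_counts()`, `classification_metrics()`,
  `roc_empirical()`, `roc_binormal()`, `real_world_cost()`,
  `cohort_projection()`, `cost_delta()`): threshold metrics, empirical and
  binormal-parametric ROC (AUC = Φ((μ₁−μ₀)/√(σ₀²+σ₁²))), dollars per
  screened infant, and cohort-level projections of missed cases.
* **Synthetic data** (`generate_cohort()`): labeled synthetic preterm
  retinas — disc-on-black geometry, tortuous radial vessels darkest in the
  green channel, illumination tilt, specular highlights, heavy class
  imbalance — so the whole pipeline is testable without patient data.

Everything tabular flows as tibbles (images ride in list-columns), so
stages chain with the pipe; results provide `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate a cohort whose two classes genuinely overlap
(`effect_size = 0.3`), harmonize, split 4-fold, train on a balanced
augmented selection, and evaluate on the held-out unaugmented fold (20
images, 5 plus) — once per loss:

```r
library(fundusplus)

for (ln in c("ce", "rwwce")) {
  rep <- run_pipeline(pipeline_config(
    n_no_plus = 60, n_plus = 20, effect_size = 0.3, k = 4,
    balance_total = 240,
    classifier = classifier_config(input_side = 64, epochs = 10),
    loss = loss_spec(ln), seed = 7))
  cat("loss:", ln, "\n"); print(unlist(rep$confusion))
  cat("sens:", rep$metrics$sensitivity,
      " cost/$:", round(rep$real_world_cost, 2), "\n\n")
}
#> loss: ce
#> tp fp tn fn
#>  4 14  1  1
#> sens: 0.8  cost/$: 96900
#>
#> loss: rwwce
#> tp fp tn fn
#>  5 15  0  0
#> sens: 1  cost/$: 12750
```

The 100:1 dollar weighting eliminates the remaining missed plus case
(fn 1 → 0, sensitivity 0.8 → 1) at the price of one more false positive,
cutting the average error cost per screened infant from $96,900
(dominated by one $1.7M miss in 20 infants) to $12,750 — exactly the
trade the cost-weighted loss is designed to make on ambiguous images.

Cohort-level arithmetic, independent of any model:

```r
cohort_projection(1000, 0.125, 11, avg_fn = 3.3)   # 38 missed (cross-entropy)
cohort_projection(1000, 0.125, 11, avg_fn = 2.65)  # 30 missed (cost-weighted)
cost_delta(38, 30)                                 # $13,600,000
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's acceptance targets from scratch — the projected
numbers of misdiagnosed infants in a 1000-infant cohort at 12.5%
prevalence under the cross-entropy and cost-weighted false-negative rates —
by running `cohort_projection()` and writes them as JSON.

## Command line

A thin wrapper over the same functions:

```sh
inst/cli/fundusplus simulate --out data/ --n-no-plus 88 --n-plus 12 --seed 1
inst/cli/fundusplus harmonize --in data/ --out harm/ --save-provenance
inst/cli/fundusplus cii --proposed harm/ --original data/
inst/cli/fundusplus run --loss rwwce --seed 1 --out run1/
```

See `vignettes/plus-disease-screening.Rmd` for the model assumptions,
parameter rationale, what the synthetic world does and does not establish,
and known limitations.
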