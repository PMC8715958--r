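# petriage

Diagnosing the *uncertain* cases of memory impairment — samples whose three
neuropsychological memory tests disagree — from FDG-PET, with a compact 3-D
convolutional classifier, and validating those diagnoses statistically.

## The problem

Cohort studies of Alzheimer's disease screen memory with three instruments
that all probe delayed word recall: the MMSE recall item (0–3), the
ADAS-Cog delayed recall (0–30 words recalled, higher = better) and the CDR
memory box (0, 0.5, 1, 2, 3). A case is *certain impaired* when

    MMSE-Recall ≤ 1  and  ADAS-Cog-Recall < 12  and  CDR-Memory ≥ 1,

*certain healthy* when

    MMSE-Recall > 1  and  ADAS-Cog-Recall > 23  and  CDR-Memory = 0,

and *uncertain* otherwise — the tests conflict, which happens in roughly
73% of samples. The ADAS cut points are mean ∓ SD of the baseline ADAS
distribution. `petriage` implements the full pipeline around this rule:

* **triage** of a cohort table into the three groups;
* a **3-D CNN** (3×3×3 conv → batch norm → ReLU → 2×2×2 max-pool blocks,
  filters 16→128, a 1×1×1 convolution head instead of stacked dense
  layers, one sigmoid output) trained with Adam (lr 0.001, batches of 4,
  binary cross-entropy, early stopping on the training loss: min-delta
  0.01, patience 10) on pons-normalised, 8-mm-smoothed SUVr volumes of the
  certain cases, then used to **diagnose the uncertain cases**
  (impaired iff probability ≥ 0.5);
* **evaluation**: subject-level fivefold cross-validation (60/20/20
  train/validation/test), accuracy/precision/sensitivity/specificity/F1,
  ROC-AUC, baseline comparators (MLP, C-/ν-SVM, linear and logistic
  regression), PCA/t-SNE embeddings of the last flatten-layer features;
* **validation of the diagnoses**: 6-month-binned Welch tests with
  Bonferroni correction over 6–96 months, OLS decline trends with 95%
  CIs, within-subject stability SDs, voxelwise GLM t-maps with
  age/sex/education/ApoE covariates and FWE/FDR + cluster-extent (> 5,
  18-connectivity) control, ROI comparisons, a 15-item geriatric
  depression scale chi-squared battery (corrected threshold
  0.05/16 = 0.0031), and a balanced repeated-subsampling two-way ANOVA;
* a **synthetic cohort + phantom volume generator** that reproduces the
  study's structure (group proportions 312/333/1741 of 2,386, published
  score moments, CDR-Memory slopes 0.0046–0.0076 vs 0.0011–0.0020 per
  month, AD-pattern and depression-pattern regional hypometabolism,
  per-group energy-item rates), so the whole pipeline runs and is tested
  without any clinical data.

## Worked example

```r
library(petriage)
library(dplyr)

# Generate a synthetic cohort under the default study conditions, triage it
cfg <- generator_config(n_samples = 600, seed = 42)
cohort <- generate_cohort(cfg) |> triage_cohort()
triage_summary(cohort)
#> # A tibble: 3 × 3
#>   label                n fraction
#>   <chr>            <int>    <dbl>
#> 1 certain_impaired    78     0.13
#> 2 certain_healthy     84     0.14
#> 3 uncertain          438     0.73

# Phantom volumes for the certain cases; SUVr + 8 mm smoothing pipeline
atlas <- build_atlas(cfg$volume_params$grid_edge)
certain <- filter(cohort, triage_label != "uncertain")
vols <- generate_volumes(certain, atlas, cfg) |>
  lapply(preprocess_volume, atlas = atlas)
labels <- as.integer(certain$true_state == "impaired")

# Train the compact 3-D CNN and diagnose 100 uncertain cases
model <- build_network(network_spec(input_edge = 32)) |>
  nn_train(vols, labels, train_config(seed = 1, max_epochs = 16))
uncertain <- filter(cohort, triage_label == "uncertain")[1:100, ]
vols_unc <- generate_volumes(uncertain, atlas, cfg) |>
  lapply(preprocess_volume, atlas = atlas)
dx <- diagnose_uncertain(model, vols_unc, ids = uncertain$id)
count(dx, diagnosis)
#> # A tibble: 2 × 2
#>   diagnosis     n
#>   <chr>     <int>
#> 1 healthy      76
#> 2 impaired     24

# Validate: positive diagnoses decline faster over 6–96 months
visits <- generate_longitudinal(uncertain, config = cfg)
slopes <- visits |>
  group_by(sample_id) |>
  group_modify(~ fit_trend(.x, "cdr_memory")) |>
  ungroup() |>
  inner_join(rename(dx, sample_id = id), by = "sample_id")
slopes |> group_by(diagnosis) |> summarise(mean_slope = mean(slope), n = n())
#> # A tibble: 2 × 3
#>   diagnosis mean_slope     n
#>   <chr>          <dbl> <int>
#> 1 healthy      0.00310    76
#> 2 impaired     0.00565    24
t.test(slope ~ diagnosis, data = slopes)$p.value
#> [1] 5.749082e-06
```

The diagnosed-impaired uncertain cases decline at the impaired-range rate
(the generator draws truly impaired slopes from 0.0046–0.0076 per month),
while the diagnosed-healthy group declines significantly more slowly —
the longitudinal surrogate for diagnostic validity. The mean of the
negative-diagnosis group sits above the pure healthy band because every
mild (uncertain-impaired) phantom carries exactly half the full metabolic
effect and therefore lies on the classifier's decision boundary; see the
methods vignette (`vignettes/methods.Rmd`) for the analysis.

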