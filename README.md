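# hepadose

Predicting the outcome of unfractionated heparin (UFH) treatment in
intensive care, and recommending the total dosage most likely to land the
patient in the therapeutic window.

## The problem

UFH has a narrow therapeutic window and a patient-variable dose-response.
Anticoagulation intensity is monitored via the activated partial
thromboplastin time (aPTT, seconds); the steady-state response to the
initial dosing period is summarized as the **therapeutic aPTT** — the mean
of the aPTT values measured 8-24 h after the first infusion. Against an
institution-specific target band this yields a ternary outcome:

- **subtherapeutic** (aPTT below the band — thrombosis risk),
- **normal therapeutic**,
- **supratherapeutic** (above the band — bleeding risk).

Two band schemes are built in: `mimic` (60-100 s normal band) and `pumch`
(35-45 s), with correspondingly different feature dialects.

`hepadose` models the outcome with a fully connected shallow neural network
(hidden layers 32/64/24, rectified-linear activations, softmax output over
the three classes) trained by full-batch gradient descent on demographic,
laboratory and SOFA-score features plus the **total heparin dosage** (the
dose sum within 8 h of the first infusion). On top of the classifier:

- **Metrics** from the 3x3 confusion matrix: accuracy, Cohen's kappa, and
  macro-averaged precision P, recall R and F1 = 2PR/(P+R).
- **Ablation feature importance** E_i = A − A_i: the drop in 5-fold
  cross-validated accuracy when feature i is removed and the model retrained
  under pinned folds and seeds.
- **Counterfactual dosage recommendation**: for patient record x and
  candidate dose α, M(x, α) is the softmax normal-therapeutic probability
  after substituting α for the actual dose; the recommended dose is
  σ(x) = argmax over a dose grid O of M(x, α), audited as *reasonable* when
  subtherapeutic patients are told to increase and supratherapeutic patients
  to decrease.

Because the clinical source cohorts behind this kind of analysis are
credentialed or private, the package ships a seeded synthetic event-level
cohort generator whose per-class feature summaries emulate the published
cohort characteristics and whose labels arise from a known monotone
dose→aPTT mechanism — giving every component a ground truth to be tested
against. See the vignette (`vignettes/heparin-outcome-modelling.Rmd`) for
the generator's mechanism, its calibration, and all numerical conventions.

## Worked example

```r
library(hepadose)

coh <- generate_cohort(generator_config(800, "mimic", seed = 7))
ds  <- preprocess_cohort(coh)        # inclusion, 3-sigma filter, 3-NN imputation, one-hot
nrow(ds$rows)
#> [1] 766                            # 34 outlier rows removed, 229 SOFA values imputed

cfg <- train_config(epochs = 600, momentum = 0.9, clip_norm = 0.5, seed = 8)
cv  <- cross_validate(ds, cfg)       # stratified 5-fold CV
round(cv$mean, 3)
#>        accuracy           kappa macro_precision    macro_recall        macro_f1
#>           0.903           0.845           0.888           0.862           0.875

sp    <- stratified_split(ds$rows$label, 0.8, seed = 8)
model <- train_network(ds, cfg, rows_idx = sp$train)
recs  <- recommend_doses(model, ds$rows[sp$test, ],
                         dose_grid(max(ds$rows$total_dose[sp$train])))
head(recs[, c("patient_id", "actual_dose", "recommended_dose", "direction")], 3)
#>   patient_id actual_dose recommended_dose direction
#> 1          1   11123.337         9389.674  decrease
#> 2          5    6014.398         8079.487  increase
#> 3         10    5264.592         7861.123  increase

audit_recommendations(recs)
#> $sub_increase_frac   1   (71/71 predicted-subtherapeutic patients told to increase)
#> $supra_decrease_frac 1   (25/25 predicted-supratherapeutic patients told to decrease)
```

The cross-validated accuracy (0.903) approaches the cohort's generative
Bayes accuracy (~0.94 under the default noise), the kappa shows strong
chance-corrected agreement, and every patient the model judges sub- or
supratherapeutic is pushed in the direction that the hidden mechanism
confirms is correct. `run_pipeline()` wires all stages together and writes
`patients.csv`/`events.csv`, a serialized model, a recommendations table and
a JSON manifest with per-stage counts.

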