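# trisk

Transformer and ODE-based survival modelling for longitudinal coded
electronic health records (EHR), aimed at mortality risk prediction in
heart-failure cohorts — for biostatisticians and clinical-ML researchers who
want a fully inspectable, CPU-scale implementation of the method together
with the classical benchmark and evaluation machinery around it.

## What it does

A patient's coded history (diagnoses, medications, procedures) up to an
index date is tokenised into three aligned channels — code, integer age at
the encounter, and visit number — closed by a `PREDICT` token. Token
embeddings are combined by concatenation and a learned projection
`[e_code ‖ e_age ‖ e_pos] W (3E→E)` with a tanh non-linearity, encoded by a
multi-head self-attention transformer, and the `PREDICT` state **h** feeds a
hazard network λ(t, **h**) ≥ 0 (softplus output). The survival curve solves

    dΛ/dt = λ(t, h),   S(t) = exp(−Λ(t)),   F(t) = 1 − S(t)

by fixed-step RK4 (equivalently composite Simpson), and training minimises
the exact right-censored negative log-likelihood

    −δ·log λ(t) + Λ(t)

plus α times a differentiable D-calibration (XCal) penalty that pushes the
predicted CDF values F(tᵢ | xᵢ) toward uniformity, with censored mass spread
above F(cᵢ). Risk at horizon τ is `1 − S(τ)`.

Around the model: a synthetic-cohort generator with known hazard structure
(per-code log hazard ratios, optional recency decay, realistic measurement
missingness); a MAGGIC-EHR-style Cox benchmark with chained-equation multiple
imputation (PMM + Nelson–Aalen auxiliary), Rubin's-rules coefficient pooling
and cloglog prediction pooling; censoring-aware evaluation (Harrell C, AUPRC,
RCS-3 calibration curves and ICI, D-calibration, KM-corrected decision
curves, impact and subgroup analyses, bootstrap CIs); transfer learning
across vocabularies; and integrated-gradients attribution of the horizon
risk to individual encounters.

## Worked example

```r
library(trisk)

co <- simulate_cohort(simulation_config(n_patients = 1000, seed = 42))
co
#> trisk_cohort: 1000 patients, 34257 encounters, 41819 measurements, 628 events

sp  <- split_by_practice(co, fraction = 0.75, seed = 7)
dtr <- build_dataset(sp$derivation, max_len = 64)
dva <- build_dataset(sp$validation, vocab = dtr$vocab, max_len = 64)
dtr
#> trisk_dataset: 750 examples, 476 events, vocab 30 codes

cfg   <- trisk_config(E = 32, n_layers = 2, n_heads = 2, max_len = 64,
                      max_epochs = 15, seed = 1)
model <- train_trisk(dtr, cfg)
model
#> trisk_model: E=32, 2 layers, 2 heads, mode=concat, 13 epochs (best 8)

risk <- predict_risk(model, dva$sequences, tau = 36)
head(data.frame(patient_id = dva$labels$patient_id, risk_36m = round(risk, 3)), 4)
#>   patient_id risk_36m
#> 1    P000001    0.673
#> 2    P000004    0.418
#> 3    P000005    0.526
#> 4    P000009    0.939

c_index(dva$labels$time, dva$labels$event, risk)
#> c_index: 0.5899 (n = 248)

# ceiling: the generator's true linear predictor on the same patients
gtv <- sp$validation$ground_truth
c_index(gtv$observed_time, gtv$event, gtv$eta)
#> c_index: 0.6630 (n = 250)
```

The model's held-out concordance (0.590) is read against the oracle
concordance of the true linear predictor (0.663), the ceiling any model can
reach on this cohort; at the reference scale used by the test suite
(2000 patients, 20 epochs) the gap closes to under 0.05. Per-patient risks
are 36-month mortality probabilities.

A command-line pipeline over the same functions lives at
`inst/cli/trisk.R`:

```sh
Rscript inst/cli/trisk.R simulate --out run1 --seed 11
Rscript inst/cli/trisk.R prepare  --out run1
Rscript inst/cli/trisk.R train    --out run1
Rscript inst/cli/trisk.R predict  --out run1
Rscript inst/cli/trisk.R benchmark --out run1
Rscript inst/cli/trisk.R evaluate --out run1
Rscript inst/cli/trisk.R report   --out run1
```

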