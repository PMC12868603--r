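---
title: "Transformer-ODE survival modelling for coded EHR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformer-ODE survival modelling for coded EHR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Heart-failure patients accumulate long, irregular streams of coded clinical
events — diagnoses, prescriptions, procedures — interleaved with sparse
measurements. `trisk` models all-cause mortality risk directly from these
streams: a transformer encoder reads the coded history up to an index
("baseline") date and an ODE-defined survival head converts the patient
representation into a full survival curve, trained by censored maximum
likelihood with an explicit distributional-calibration penalty. A
MAGGIC-style Cox benchmark with multiple imputation, a censoring-aware
evaluation suite, and integrated-gradients explainability complete the
pipeline. Because real primary-care datasets of this kind are
licence-restricted, the package ships a synthetic-cohort generator with a
known hazard structure, so that every stage can be validated against a
ground-truth oracle.

# Data model and tokenisation

Patients carry demographics (sex, birth year, practice/site), a date-sorted
encounter stream, measurement records, and outcome dates. Diagnosis codes are
ICD-10 truncated to level 4 (the three-character category plus at most one
character after the decimal, `N29.9` style), medication codes are BNF section
codes (first four digits) with a virtual-therapeutic-moiety fallback for
products outside the BNF map, and procedure codes pass through unchanged.
Codes carried by fewer than 0.1% of patients are dropped from the vocabulary.

Each training example is anchored at a baseline date sampled uniformly from
the patient's eligibility window (first HF diagnosis to the earliest of
death, loss to follow-up, and end of study). Patients who die on the
diagnosis day have no post-diagnosis follow-up and are excluded. Sampling a
random baseline trains the model across the whole disease trajectory rather
than at a single landmark.

The token sequence carries three aligned channels: code ids; integer age at
each encounter (birth date taken as July 1 of the birth year, one embedding
per year of age 40–110 plus an out-of-range slot); and a visit-number
position id, where all encounters sharing a calendar date form one visit. A
terminal PREDICT token closes the sequence, carrying the age at baseline and
the next visit number; its encoder state is the patient representation.
Sequences longer than `max_len` keep the most recent encounters, and visit
numbers are then renumbered from 1 inside the retained window so position ids
stay inside the embedding table; recency, not absolute visit index, is the
signal the positions encode. Follow-up is measured in months at 30.4375
days per month. Encounters dated on the baseline day itself are included by
default (`include_baseline_day = FALSE` turns this off).

# The model

**Embeddings.** Each token's code, age and position embeddings (width `E`
each) are concatenated and projected by a learned map `3E -> E` followed by
tanh — so token latents live strictly in (-1, 1). The ablation mode
`embedding_mode = "sum"` replaces this with the BEHRT-style elementwise sum.

**Encoder.** A standard post-norm transformer: per layer, multi-head
self-attention with residual and layer normalisation, then a two-layer ReLU
feed-forward block (width `ffn_mult * E`) with residual and layer
normalisation. Padding positions are stripped before encoding, so they can
neither attend nor be attended to. The representation is read at the PREDICT
position.

**Survival head.** A small MLP takes `[h, t / t_scale]` (the representation
and rescaled time) and outputs a hazard through a softplus, guaranteeing
positivity. The cumulative hazard solves `dLambda/dt = lambda(t, h)` from 0
by a fixed-step fourth-order Runge–Kutta scheme with step at most
`ode_step = 0.5` months. Because the hazard does not depend on `Lambda`
itself, this integrator is exactly composite Simpson quadrature, which gives
two things for free: bit-reproducible solutions, and exact agreement between
the solver used at prediction time and the quadrature weights used to
backpropagate the likelihood during training. `ode_survival()` accepts an
optional step-halving tolerance check. Internally time is rescaled by
`t_scale` (60 months) for conditioning of the head's input.

**Likelihood.** For label `(t, delta)` the censored negative log-likelihood
is `-delta * log lambda(t) + Lambda(t)`, averaged over the batch — the exact
right-censored log-likelihood of the hazard model, with `Lambda` obtained by
the quadrature above (no sampling approximation).

**Explicit calibration (XCal).** D-calibration asks that predicted CDF values
`F(t_i | x_i)` at observed event times be uniform on [0, 1]. The training
penalty bins [0, 1] into `B = 20` equal bins; uncensored examples get
differentiable soft memberships through sigmoids of temperature `gamma` at
the bin edges; a censored example with `F(c_i)` spreads its remaining mass
`1 - F(c_i)` uniformly over the region above `F(c_i)` (piecewise linear,
differentiable almost everywhere). The penalty is the squared deviation of
the bin masses from `1/B`, and the objective is `NLL + alpha * XCal` with
`alpha = 1` by default; `alpha = 0` reproduces pure-NLL training exactly.
The default temperature is `gamma = 100` rather than a near-hard setting:
with 0.05-wide bins, a sigmoid of temperature 100 still spreads useful
gradient across a bin, whereas a near-step sigmoid concentrates all gradient
in a vanishing neighbourhood of the edges and the penalty stops steering
training. The evaluation-side statistic (`d_calibration()`) uses hard bins
and the same censored-mass construction.

**Training.** Minibatch Adam (default learning rate 3e-3, batch 64), fully
seeded: initialisation, the held-out split, and batch order all derive from
`config$seed`, so identical configs give identical results. 5% of the
dataset is held out for end-of-epoch testing; the checkpoint with the best
end-of-epoch loss is returned, with early stopping after `patience = 5`
epochs without improvement. Divergence (non-finite loss) is an error, never
silently absorbed.

**Transfer.** `fine_tune()` copies embeddings of codes shared between the
source and target vocabularies, initialises new codes freshly, and continues
training on the target cohort with a 10% end-of-epoch split. With zero
epochs it returns the transferred parameters unchanged.

# The synthetic generator

The generator emulates the study conditions the package is validated under:
patients enter at an age uniform on 40–90, accrue visits as a homogeneous
Poisson process (default 4/patient-year) across a 10-year study window,
record codes per visit with per-code first-recording probabilities and
chronic re-recording, and receive an index date uniform over their
eligibility window. The true linear predictor `eta` sums `beta * w(dt)` over
distinct codes in the history at baseline, with `w = 1` or an exponential
recency decay `2^(-dt/half_life)` keyed on the code's *first* recording.
Event times are exponential with rate `lambda0 * exp(eta)` (constant
post-baseline hazard, chosen so closed-form oracles exist for the likelihood
and Kaplan–Meier checks); dropout censoring is exponential and independent
of `eta`, which keeps Cox and KM oracles valid; administrative censoring
applies at the end of study.

The default effect set has 30 codes across the three modalities, five causal
with |log HR| between 0.5 and 1.5 (lung cancer 1.5, hepatic failure 1.0,
CKD 0.7, MI 0.9, beta-blockers -0.5), with per-visit recording rates chosen
so baseline prevalences land in a realistic 5–35% band and roughly half of
patients die in follow-up. Measurement models reproduce the missingness
rates observed in large UK HF cohorts (BMI 26.7%, smoking 14.0%, SBP 4.0%,
creatinine 9.1%, NYHA 96.6%, sodium 9.7%); measurement *values* are noise
around patient-level means and deliberately carry no hazard signal — the
deep model's advantage over the measurement-driven benchmark on these
cohorts is therefore structural, and the imputation machinery is validated
separately on covariate-level cohorts with true linear effects. None of
this is a claim about real primary-care data: visit patterns, code
co-occurrence, disease progression and measurement-outcome correlations are
all richer in reality, so passing tests demonstrate correctness of the
machinery, not clinical performance.

# The Cox benchmark

MAGGIC-EHR covariates are extracted at baseline: continuous measurements as
the mean of records in the preceding 36 months, smoking and NYHA as the last
known status in that window, disease/prescription/procedure flags as
any-record-ever-before-baseline, HF duration >= 18 months, and HF subtype;
the extended variant adds sodium, AF, stroke, MI, PCI and CABG. Age-by-
subtype and SBP-by-subtype interactions are included. Missing values are
multiply imputed (m = 5) by chained equations — predictive mean matching
with 5 donors and a Bayesian parameter draw for continuous variables,
bootstrap multinomial regression for categoricals — with all model
variables, the event indicator and the Nelson–Aalen cumulative hazard as
predictors, 10 sweeps per imputation, derivation and validation imputed
separately. Cox fits use Breslow ties with a Breslow baseline hazard;
coefficients pool by Rubin's rules and predicted survival pools on the
cloglog scale, `exp(-exp(mean log(-log S)))`. NYHA imputes as nominal (the
ordinal alternative is defensible; nominal makes no ordering assumption at
96.6% missingness). A variable with no observed value at all is excluded
from the model with a warning — the same pragmatic handling that fully
absent LVEF receives in EHR adaptations of MAGGIC — and a variable observed
in derivation but not in a (small) validation cohort is drawn from the
derivation's observed distribution before local imputation, again with a
warning.

# Evaluation choices

All binary-status metrics at horizon `tau` share one evaluable-set rule:
events by `tau` are positives, patients followed to at least `tau` without a
prior event are negatives, and patients censored before `tau` are excluded
(exclusion rather than IPCW weighting: deterministic, simple, and flagged in
the output metadata). The concordance index is Harrell's: pairs comparable
iff the earlier time belongs to an event, ties in risk credited 0.5, risks
taken at the fixed horizon over all follow-up. Calibration curves smooth the
horizon status on predicted risk with a logistic restricted cubic spline
(three knots at the 10th/50th/90th risk percentiles — a logistic link keeps
fitted risks in [0, 1]); the ICI is the mean absolute gap between smoothed
observed and predicted risk. Decision curves weight false positives by the
threshold odds, with the event probability among predicted positives
estimated by Kaplan–Meier at `tau` inside that group, so with no censoring
the curve reduces exactly to the count-based net benefit. Confidence
intervals are percentile bootstrap over patients (200 resamples, seeded).
Subgroup analyses report each group's metric and its signed deviation from
the overall estimate, skipping groups under 50 evaluable patients.

# Explainability

Integrated gradients attribute the horizon risk `F(tau) = 1 - S(tau)` to
individual encounter tokens, taken at the embedding layer with the PAD code
embedding as the reference (ages, positions and mask preserved — PAD is the
model's native "absence of clinical content"). Scores sum over the embedding
dimensions to one scalar per encounter; summed over tokens they approximate
`F(x) - F(reference)` (completeness), and padded positions score exactly 0.
Repeated codes collapse to their maximum score per patient. Population
summaries keep codes in at least 1% of patients, with normal-approximation
95% CIs, and stratify by sex, by age at the code's first recording
(50–59/60–69/70–79/>=80), or by time from first recording to baseline
(<1y/1–5y/5–10y/>10y). Note that sequence truncation interacts with the
recency strata: a first recording that falls outside the retained window
cannot be attributed, so long-recency analyses need `max_len` generous
enough to cover the histories of interest.

# Numerical choices and degenerate inputs

Softplus hazard output (with a 1e-12 floor inside logs); fixed-step RK4 =
Simpson quadrature, step <= 0.5 months, optional step-halving check; tanh
embedding combiner; layer-norm epsilon 1e-5; Adam defaults (0.9/0.999);
same-date encounters keep input-file order (stable sort); empty histories
yield a bare-PREDICT sequence; an all-padding input, an empty cohort, a
variable 100% missing, thresholds outside (0, 1), or F values outside [0, 1]
are errors, not silent repairs. All randomness flows from explicit seeds
through per-stream derived seeds (`derive_seed`), so every artifact is
reproducible from its config.

# Validation scales

The test-suite study conditions are deliberately desk-sized: the reference
cohort has 2000 patients (30 codes, 5 causal) with a 3:1 practice split and
a model of width 32, 2 layers, 2 heads, sequences up to 64 tokens and at
most 20 epochs — enough for the held-out concordance to come within 0.05 of
the ground-truth linear predictor's oracle concordance. The recency
experiment uses a 25-year record span, 1200 patients, sequences to 96
tokens, a 36-month half-life decaying cancer code and a persistent
hepatic-failure code, each recorded once per patient so that the
time-to-baseline stratum of a code is unambiguous. The transfer experiment
fine-tunes the reference model onto a 400-patient cohort whose baseline
hazard is 2.5x higher, against from-scratch training at an equal epoch
budget over five seeds. Calibration comparisons train XCal and no-XCal
variants on a 700-patient cohort with heavy dropout censoring.

# Known limitations

The generator's constant post-baseline hazard cannot express time-varying
effects after baseline; measurements carry no signal by default; the
transformer is trained on CPU-scale cohorts, so absolute discrimination on
real data is out of scope; AUPRC/ICI handle censoring by exclusion rather
than weighting; attribution CIs are normal approximations; and the XCal
censored-mass construction follows the standard differentiable
D-calibration recipe rather than a paper-specific variant.
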