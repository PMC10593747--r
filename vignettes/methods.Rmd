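---
title: "Methods: real-time prediction of intradialytic blood-pressure events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time prediction of intradialytic blood-pressure events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During a hemodialysis session a patient's blood pressure is measured roughly
hourly (more often when unstable). Two complications matter clinically and
are defined from those readings:

* **Intradialytic hypotension.** `IDH-1`: any systolic BP (SBP) reading below
  90 mmHg. `IDH-2`: a fall of ≥ 20 mmHg in SBP **and/or** ≥ 10 mmHg in mean
  arterial pressure (MAP = (2·DBP + SBP)/3) from the session-initial reading.
* **Intradialytic hypertension.** `IDHTN`: a rise of ≥ 10 mmHg in SBP above
  the session-initial value. The session-level sensitivity variant `IDHTN-2`
  flags IDHTN in ≥ 4 of 6 consecutive sessions.

This package implements a *real-time* dual predictor: at every recorded
timestamp `t` it emits three probabilities, one per outcome, for the event
occurring among the recorded readings in the half-open window `(t, t + 60]`
minutes. The reading at `t` never labels itself (the task is prospective),
and a timestamp with no BP recording inside the horizon has an undefined
label, which is excluded from training and evaluation through a label mask.
Timestamps after an event has already occurred remain labelable: prediction
continues across the whole session. Only recorded readings are used — BP is
never interpolated.

## Cohort construction

Sessions are excluded, in a fixed documented order (age < 18 years, no BP
record at session start, duration outside [2, 6] h, any gap between
consecutive BP recordings above 1.5 h), each session counted at the first
rule it fails, so the exclusion tally is well defined. Every kept session is
matched with up to 5 previous sessions of the same patient within 31 days
("1 month" is interpreted as 31 calendar days and is configurable). Patients
— never sessions — are split 70/10/20 into training/validation/test by
uniform randomization (largest-remainder apportionment), which makes
session-level leakage impossible by construction. No stratification is
applied: the split models simple patient-level randomization.

## Feature pipeline

The full variable layout has 56 time-invariant and 10 time-varying variables;
the model consumes `|time-invariant| + 2·|time-varying| + 2` columns: the
originals, one auxiliary indicator per time-varying variable (1 = observed,
0 = imputed — the inverted-looking convention is deliberate and preserved),
and two elapsed-time channels (minutes on dialysis; days since the previous
session). For the full schema that is 56 + 10 + 10 + 2 = 78.

Numerical conventions, all fitted on the **training split only**:

* continuous time-invariant variables are imputed with the mean when
  approximately normal and the median otherwise; the normality rule is
  |sample skewness| < 1, stored in the schema (a deliberate, documented
  choice: the mean-vs-median convention needs *some* normality test, and
  skewness is the property that matters for the mean);
* categorical variables are imputed with the median of their ordinal codes
  after frequency-ordered encoding (most frequent level = code 1);
* time-varying variables are forward-filled; a leading gap falls back to the
  most recent value of the matched previous session, then to the training
  median — our reading of "filled with information from the previous
  session" for the session-boundary case;
* continuous variables (including both elapsed-time channels — an open point
  we resolved as "yes, normalize them") are z-scored with training
  mean/standard deviation; a constant training column is an error, not a
  silent division by zero;
* the timestep grid is the native recording grid, truncated at a maximum
  sequence length (default 24) for batching; padded positions are masked
  everywhere downstream.

## The model

The classifier is a temporal-fusion-transformer variant reduced to the
real-time classification task: the quantile forecasting heads and the
known-future-input channel of the original architecture are removed.

Every input channel is embedded to an `H`-vector by a per-variable dense
layer. The workhorse block is the **gated residual network** (GRN): four
dense layers with an exponential-linear-unit nonlinearity and a sigmoid
gate, `out = skip(x) + σ(W₄η + b₄) ⊙ (W₅η + b₅)` with
`η = W₁·ELU(W₂x + Wc·c + b₂) + b₁`, where the skip is a projection when the
widths differ; the gate can close and pass the input through unchanged. We
omit the layer normalization of the original design — at the widths used
here (H = 64 default) training is stable without it, and the simplification
keeps the hand-rolled backward pass small.

**Variable selection** transforms each channel with its own GRN and fuses
them with a softmax weight vector produced by a GRN over the concatenated
embeddings (conditioned on the static context for the temporal block). The
weights form a simplex and double as feature importance. **Previous-session
re-entry**: each matched previous session passes through the same embedding
→ selection → GRU → attention stack (shared weights, zero initial context,
depth one — previous sessions of previous sessions are not recursed) and its
terminal representation joins the time-invariant variable set of the current
session. An unavailable slot contributes a zero vector and its selection
logit is masked to −∞, so its softmax weight is exactly zero and garbage in
masked slots cannot influence any prediction — an exact invariant, tested as
such. The fused static vector initializes the GRU state and conditions the
temporal selection GRN (we do not feed it to the attention block as well;
a design point the original temporal-fusion-transformer family leaves
open; we chose the recurrent-state interpretation).

A unidirectional **GRU** provides local (short-term) context; padded
positions propagate the state unchanged. A **single-headed causally masked
scaled-dot-product attention** (GRN input layer, gated residual output)
provides long-term context; strictly-future positions carry exactly zero
weight. A GRN plus one dense layer maps each timestep to three logits, and
sigmoids give the per-outcome probabilities. The loss is the unweighted mean
of the three per-head binary cross-entropies over valid (timestep, head)
pairs; the optimizer is Adam (default learning rate 1e-3, batch 32, global
gradient-norm clip 5, early stopping on validation loss). Loss weighting and optimizer are our
choices (the clinical definitions fix only the outcomes, not the training
objective). Training is deterministic for a fixed seed in
single-threaded mode.

There is no deep-learning runtime in the target environment, so the network
runs on a small reverse-mode automatic-differentiation tape written for this
package (`R/autodiff.R`); every primitive has a finite-difference gradient
check, and the composed GRN and GRU blocks are tested against hand-written
forward passes.

The recurrent baseline (`variant = "rnn"`) removes variable selection,
attention and previous-session context: concatenated embeddings → dense →
GRU → dense head. Tabular baselines (logistic regression) see a flattened
table with each time-varying variable at exactly three timestamps — session
start, prediction time, previous recording — plus the time-invariant block
and the two elapsed-time channels.

## Explainability

Selection weights are collected per example; time-varying weights are
averaged over valid timesteps within an example first, then over examples
(this order is a documented choice), and each reported table is renormalized
to sum to one. Slim schemas keep the top-`k` original variables ranked by
mean weight with lexicographic tie-breaks; the time-varying/time-invariant
split of a slim schema is whatever the ranking induces, and indicator and
elapsed columns are recomputed by the pipeline (so a slim-30 schema with 6
time-varying variables yields 30 + 6 + 2 = 38 columns).

## The synthetic cohort: what it emulates, and what a green test shows

No source data are deposited, so the package ships a generator whose world
is stated once and then frozen:

* per patient: 4–8 sessions, 3–5 h long, hourly vitals with 30-minute
  sampling after any systolic reading below 100 mmHg;
* systolic trajectory, in closed form:
  `SBP(t) = 139 + b_p + carry_s + (r_p + r_s)·t/60 − Σ_v coef_v·sens_p·driver_v·t/60 + ε(t)`,
  with patient level `b_p ~ N(0, 8)` mmHg, carryover
  `carry_s = 0.25·(previous-session nadir − 115)` (zero when no previous
  session lies within the window), patient and session linear trends
  (hypertensive patients drift upward slightly more), a log-normal patient
  sensitivity `sens_p` multiplying the ultrafiltration driver
  (0.5 mmHg per mL·kg⁻¹·h⁻¹ per hour; the prescribed rate varies widely
  across sessions, N(10, 5) mL·kg⁻¹·h⁻¹, so fluid removal is the dominant
  observable driver of the decline slope), and reading noise whose standard
  deviation (6.5 mmHg) scales with `sens_p^0.8` — unstable patients both
  respond more to fluid removal and swing more. Diastolic pressure and heart
  rate derive from the *latent* level with independent noise (diastolic
  noisier than systolic), so the systolic channel is the single best level
  readout and the declared drivers are the dominant information carriers;
* trend components are parameterized in units of `patient_effect_sd` and
  `noise_sd`, so the degenerate configuration (all three zero) produces
  exactly flat series with no IDH-2/IDHTN labels;
* noise is pre-drawn on the dense 30-minute grid, so realized values at a
  timestamp do not depend on the sampling path — this makes prevalence
  monotone in the driver coefficient under a fixed seed, a tested property;
* missingness is MCAR at 10% per cell for both variable classes, with BP
  and age exempt (any missing interior SBP would trip the 1.5 h-gap filter
  and discard the session); ground truth (drivers, patient traits, event
  occurrences) ships in a sidecar, never in model-facing files;
* generator defaults were calibrated once, before any acceptance
  measurement, to per-session event rates typical of a large in-centre
  hemodialysis population (10.7% / 51.9% / 40.5%); the frozen defaults give
  ≈ 7% / 53% / 37% on a 300-patient draw.

The generator emulates repeated sessions, irregular sampling, carryover,
missingness in both variable classes, and patient heterogeneity. It does
**not** emulate real EMR phenomena such as informative missingness,
medication interventions during sessions, measurement artifacts, or
arrhythmia-related instability. A green driver-recovery or model-ordering
test therefore establishes that the implementation can learn and explain the
structure this world contains — not that it would reach any particular
performance on hospital data, whose headline metrics are out of scope here.

## Numerical and design choices

* AUROC confidence intervals use the DeLong placement-value variance, and
  model comparisons the paired DeLong test (two-sided normal approximation;
  identical score vectors report difference 0 with p = 1 by convention).
  AUPRC uses the step-curve (average-precision) integral with a seeded
  bootstrap CI; a constant classifier scores exactly the prevalence.
* Precision/recall/F1 use threshold 0.5; a zero denominator reports 0 with a
  warning.
* Elapsed-time stratification uses 30-minute bins by default (the source
  figure's granularity is unstated); bins lacking a class are reported as
  undefined rather than dropped.
* Ties in importance rankings break lexicographically by variable name.
* Degenerate single-timestep sessions are valid model inputs; their
  attention matrix is [[1]].

## Known limitations

* The autodiff tape favours clarity over speed; at EMR scale (300k sessions)
  this implementation would need the compiled route it deliberately avoids.
* The hand-rolled network omits layer normalization and multi-context
  conditioning of the original architecture; with the small hidden widths
  used in testing this is immaterial, but it is a simplification.
* Calibration of predicted probabilities is reported, not enforced; no
  recalibration layer is fitted.
* The logistic baseline uses an unpenalized GLM; with many collinear
  features R drops aliased columns rather than regularizing.
* At desk scale the flattened-table GLM is close to the information ceiling:
  the generator's closed-form trajectories make event risk monotone in each
  observable, and AUROC is rank-based, so a correctly-specified linear model
  ranks nearly optimally. The ordering experiment therefore demonstrates the
  previous-session contribution (full model above the recurrent baseline)
  but does not reproduce a deep-network advantage over logistic regression;
  on real EMR data that advantage comes from large-scale, strongly nonlinear
  structure that this synthetic world deliberately does not contain.
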