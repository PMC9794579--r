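---
title: "Assessing torsadogenic risk from beat-to-beat biomarker variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing torsadogenic risk from beat-to-beat biomarker variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drugs that block the rapid delayed-rectifier potassium current (hERG / IKr)
can prolong ventricular repolarization and trigger torsades de pointes
(TdP), a potentially fatal arrhythmia. Because pure hERG screening is overly
conservative — many multichannel blockers prolong QT without ever causing
TdP — the CiPA paradigm combines in-vitro pharmacology of seven cardiac ion
channels (INa, INaL, ICaL, IKr, IKs, IK1, Ito) with in-silico simulation of
a human ventricular myocyte to place compounds into high, intermediate or
low TdP-risk classes.

`tdprisk` implements such a pipeline end to end, with one distinguishing
idea: the classifier does not consume a single summary value of a TdP
metric, but the ordered beat-by-beat series of that metric over the last
500 of 1,000 slow-paced beats. Beat-to-beat variability of repolarization
carries arrhythmogenic information that a scalar averages away.

## Pipeline stages

### 1. Dose-inhibition uncertainty quantification

Fractional block of channel current at drug concentration $D$ follows the
Hill model
$$b(D) = \frac{1}{1 + (IC_{50}/D)^h},$$
with $b(0) = 0$ by convention. Rather than propagating a point estimate of
$(IC_{50}, h)$, `fit_hill_samples()` draws posterior samples by MCMC —
2,000 per drug x channel in the reference configuration — so that
downstream biomarkers inherit the measurement uncertainty.

The uncertainty-quantification step requires a likelihood, priors and
convergence rules; the package pins explicit, standard choices and
documents them as its own:

* likelihood: independent Gaussian residuals on the block fraction with an
  inferred noise scale;
* priors: log-uniform $IC_{50}$ on $[10^{-3}, 10^6]$ nM, uniform $h$ on
  $(0, 10]$, log-uniform noise scale on $[10^{-4}, 1]$;
* sampler: four adaptive random-walk Metropolis chains, 1,000 burn-in steps
  each (proposal scale adapted toward ~30% acceptance during burn-in only),
  pooled and thinned to the requested sample count;
* convergence: split-$\hat R$ reported via an attribute and a warning above
  1.05, never enforced — a hard failure here would silently change sample
  counts that the rest of the pipeline pins.

Parameter recovery is verified in the test suite: on noise-free tables
generated from known $(IC_{50}, h)$ at eight log-spaced doses, posterior
medians land within 10% of the generating truth, and the posterior
interquartile range shrinks monotonically with the noise level.

Per drug, sampled blocks are evaluated at 1-4x the clinical free plasma
Cmax (`sample_block_sets()`), giving 2,000 x 4 = 8,000 block sets per drug.
Channels without measurements are treated as unblocked — the only
convention under which every reference drug can be simulated.

### 2. Paced myocyte simulation

`cell_sim` defines a pluggable model contract: named conductance scale
factors over the seven channels, a stimulus, and readable traces of Vm,
intracellular calcium and the named currents. Drug application is
multiplicative, `conductance x (1 - block)`, so blocks compose as
$1-(1-b_1)(1-b_2)$.

Two models ship with the package:

* **`cell_model_biophysical()`** — a mid-complexity human ventricular
  myocyte model written for this package: Hodgkin-Huxley gating for INa
  (fast, Luo-Rudy-style rate constants), INaL, a d/f-gated L-type calcium
  current with a phenomenological calcium transient, delayed rectifiers IKr
  (activation plus instantaneous inward rectification) and IKs, inward
  rectifier IK1, transient outward Ito, sodium-calcium exchange and a small
  background sodium leak; 13 state variables. Conductances were tuned once
  so that, paced at cycle length 2,000 ms (30 bpm, the bradycardic
  reference protocol), the control cell rests near -86.5 mV, has APD90
  around 220 ms, and responds to channel block in the physiologically
  expected directions: 50% IKr block prolongs APD90 by roughly a quarter,
  and ICaL block monotonically lowers qInward. A full transcription of a
  published state-of-the-art ionic model was deliberately not attempted: a
  transcription that cannot be verified equation by equation is worse than
  a compact model whose required properties are all property-tested. The
  model contract accepts alternative right-hand sides.
* **`cell_model_surrogate()`** — a closed-form waveform surrogate honouring
  the same contract, with monotone block-response rules built in, a damped
  beat-number transient toward steady state and a small block-dependent
  alternans term. It runs about three orders of magnitude faster and is the
  workhorse of the test suite and of pipeline-scale rehearsals. It makes no
  claim of biophysical fidelity beyond the monotonicities just listed.

Integration uses deSolve's `lsoda` with relative tolerance 1e-6, absolute
1e-8, output resampled at 1 ms (configurable). The stimulus (-52 A/F, 1 ms)
is delivered at t = 0 of every beat; state carries over between beats with
no reset. The initial condition is the control limit cycle obtained by
pacing the control model 100 beats, so control runs start at steady state
and drug runs converge within tens of beats. Endocardial-style defaults are
used throughout; cell-subtype variants, tissue coupling, rate adaptation
and dynamic (state-dependent) drug binding are out of scope.

### 3. Per-beat biomarkers

Seven biomarkers per beat (`beat_features()`):

* **qNet** — trapezoidal integral over the beat of
  $I_{NaL}+I_{CaL}+I_{Kr}+I_{Ks}+I_{K1}+I_{to}$ (A/F·ms);
* **qInward** — $\tfrac12\left(\frac{AUC_{ICaL,drug}}{AUC_{ICaL,control}} +
  \frac{AUC_{INaL,drug}}{AUC_{INaL,control}}\right)$, the drugged and
  control beats paired by beat index under identical protocols. AUCs
  integrate the *signed* (inward-negative) current, so the ratio of two
  negative areas is positive and equals exactly 1 for control vs control;
* **APD50/APD90, CaD50/CaD90** — time from the upstroke (instant of maximal
  first difference) to the first interpolated crossing of
  peak − fraction x (peak − baseline) on Vm and Cai respectively, the
  baseline being the mean over the 10 ms preceding the upstroke. Beats that
  never recover past the threshold return the remaining beat duration with
  a `repolarized = FALSE` flag;
* **dVm/dt_max_repol** — the maximum difference quotient of Vm inside the
  [APD30, APD90] window (bounds configurable). The signed convention is
  kept: normal beats give negative values and EAD-like re-depolarizations
  show up as positive slopes. Both the window bounds and the signed
  convention are exposed, documented parameters.

`variability_series()` then keeps the raw, untransformed series of the
final 500 beats. Two readings of "variability" were possible — a scalar
variance or the beat-indexed series; the series reading is forced by the
classifier's input length of 500, whose stage arithmetic yields the
documented 5 x 5 -> 25 flatten. No normalization happens at this stage; the
one scaling step in the pipeline belongs to the classifier and is stored
inside the fitted model.

### 4. The 1-D CNN classifier

The network is pinned exactly: six stages of 4/3/2/2/1/1 convolution layers
(13 total), each with five width-2 filters, stride 1, no padding, ReLU;
max-pooling of width 2 (stages 1-4) or 4 (stages 5-6), always stride 2;
batch normalization closing stage 1; flatten (500 -> stagewise
248/122/60/29/13/5 -> 5 x 5 = 25); 20% dropout; a 10-unit ReLU hidden
layer; a 3-unit softmax. Valid (unpadded) convolution is the only padding
scheme consistent with that arithmetic, so the builder errors out if an
input length collapses a stage.

Training (`train_cnn()`) minimizes categorical cross-entropy with Adam at
learning rate 1e-5, batch size 20, 300 epochs, under 10-fold sample-level
stratified cross-validation; the retained model maximizes the mean of
training and validation accuracy with ties broken by lower validation
loss. Label encoding is fixed (high, intermediate, low) and persisted.
Inputs are z-scored by the training-pool global mean and standard
deviation (stored in the fitted model and reapplied at prediction time):
centering places the class levels on both sides of zero so that each class
drives a different ReLU activation pattern, which is what keeps the middle
class separable at the reference learning rate. All
randomness — initialization, fold assignment, shuffling, dropout — flows
from the single config seed; the compute core is compiled (Rcpp) but draws
from R's RNG, so runs are bit-reproducible. Weight initialization follows
two deliberate choices. First, the output layer starts at zero so initial class scores
are neutral: with a learning rate of 1e-5 the optimizer moves parameters
by at most a few hundredths over a full schedule, and a randomly
initialized output layer would dominate the argmax far longer than
training can correct. Second, convolution biases start at a small positive
value (0.1) rather than zero: a z-scored series whose entire level sits
below zero otherwise dies in the first ReLU layers, and every such series
collapses to exactly tied class probabilities — fatal for rank-based AUC
within that class. Hidden and convolution weights use He initialization
(variance 2/fan-in), the standard scaling for ReLU stacks. Argmax ties in
hard predictions are broken deterministically (first class in label order)
so that repeated evaluations are reproducible.

The update granularity is realized as batch size 20, with the epoch and
fold counts exposed as configuration. Cross-validation
stratifies by sample; drug-level stratification is a documented option for
`assemble_training_set()` users who want leave-drug-out behaviour.

### 5. The repeated-test evaluator

`run_repeated_test()` implements the 10,000-test procedure: each iteration
draws one series per test drug uniformly from that drug's 8,000-series
(sample x multiplier) pool, predicts all 16 drugs, and scores the
iteration. Per-class one-vs-rest AUC uses the soft class probabilities
(with 16 drugs an argmax-based AUC would be degenerate); likelihood
ratios, accuracy and F1 use the argmax labels. LR division by zero yields
`Inf` — reported as such, and summarized by medians over the extended real
line — and 0/0 yields a missing value skipped in the summaries. F1 is
macro-averaged over the three classes (micro exposed). Summaries report
median (min-max) per metric; per-iteration records are retained so
summaries can be recomputed without re-prediction.

### 6. Synthetic study data

`synthetic_data` makes the whole pipeline exercisable without external
datasets. `gen_dose_response()` emits dose-inhibition tables from known
Hill truths with Gaussian noise. `gen_variability_pool()` emits
class-conditioned 500-beat series directly: an AR(1) process around a
class mean, plus an even/odd-beat alternans term and a per-drug random
offset. AR(1)-plus-alternans is the minimal structure exhibiting the serial
dependence and alternation that make beat-indexed series informative; no
physiological fidelity is claimed. The defaults emulate a qInward-like
biomarker and are fixed as the package's study conditions:

| class        | mean | beat-to-beat sd | lag-1 autocorr. | alternans |
|--------------|------|-----------------|-----------------|-----------|
| high         | 0.55 | 0.03            | 0.5             | 0.006     |
| intermediate | 0.75 | 0.03            | 0.5             | 0.003     |
| low          | 0.95 | 0.03            | 0.5             | 0         |

with a per-drug offset sd of 0.05, i.e. adjacent class means sit 4 drug-
level standard deviations apart. High-risk drugs depress qInward the most
(strong inward-current block) and carry the most alternans; low-risk drugs
sit near 1 with none. The drug fixture (`fixture_drugs()`) carries the 28
CiPA reference compounds with risk class, train/test split (12/16) and
clinical Cmax in nM.

What passing on these pools does and does not show: it validates the
machinery — cardinalities, seeded reproducibility, the architecture, the
estimator and evaluator — under class structure that is genuinely
separable. It does not certify classification performance on real
in-vitro data, whose class structure is harder (the intermediate class
overlaps both neighbours) and whose inter-laboratory variability is the
dominant error source.

## Numerical choices and degenerate inputs

* Hill block at `d = 0` is defined as 0; negative doses are errors.
* Percent-vs-fraction dose tables are auto-detected per file (any block
  value above 1.5 means percent) and rescaled with a warning.
* Threshold crossings are located by linear interpolation between samples;
  upstroke detection uses the maximal first difference, with the baseline
  averaged over the 10 ms preceding the upstroke.
* Beats that never repolarize return sentinel durations (beat end minus
  upstroke) and a flag rather than an error, so long-blocked runs still
  produce finite series.
* qInward is undefined (error) when a control AUC is zero — only possible
  for non-physiological traces.
* Max-pooling ties keep the earliest element; `Inf` likelihood ratios and
  missing AUCs (single-class iterations) are carried, not clamped.
* Integrator failures (non-finite state, step underflow) abort with the
  offending beat index.

## Problem sizes used by tests and the acceptance script

Unit and property tests run the surrogate model, reduced beat counts
(tens), reduced MCMC sample counts (hundreds) and a shortened CNN input
(length 40) so the suite completes in minutes; the acceptance script runs
the reference cardinalities (2,000 Hill samples, 8,000 block sets per
drug, 600 training rows, a 128,000-series test pool, 10,000 test
iterations) and the full 300-epoch training schedule, with the biophysical
model paced for tens of beats from its pre-paced limit cycle rather than
the full 1,000 (the control drift over the final beats is itself measured
and reported). These sizes are the package's own choices of scale; all
counts that the reference configuration pins are reproduced exactly.

## Known limitations

* The biophysical model is deliberately compact; it reproduces the
  property-level physiology the pipeline needs, not the full ionic detail
  of state-of-the-art human ventricular models, and uses fixed intracellular
  sodium/potassium.
* Heart rate is fixed at 30 bpm; no rate adaptation or mechano-electric
  feedback.
* Deterministic simulation at steady state yields low intrinsic
  beat-to-beat variability; the richer variability structure that motivates
  the series classifier is supplied by the synthetic generator, not the
  ODE model.
* The repeated-test evaluator quantifies sampling spread via min-max
  ranges, not confidence intervals; no calibration analysis is attempted.
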