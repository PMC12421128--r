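---
title: "Modeling approach-avoidance conflict behavior with aacpomdp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling approach-avoidance conflict behavior with aacpomdp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacpomdp)
```

## The task and the choice model

The approach-avoidance conflict (AAC) runway task presents, on each trial,
an avatar that the participant moves to one of nine terminal positions.
Each end of the runway carries a cue — a positive or negative affective
stimulus, worth 0 to 6 reward points — and the probability of receiving an
end's outcome rises in 10% steps from 10% to 90% as the avatar approaches
it. Five trial types (12 trials each, 60 total) define the conflict at
stake: avoid-threat (AV, aversive stimulus vs. nothing), approach-reward
(APP, 2 points vs. 0) and three conflict levels (CONF2/4/6, an aversive
stimulus worth 2, 4 or 6 points against a safe 0-point positive stimulus).
We use the canonical frame in which position 9 is adjacent to the
high-value (rewarded or aversive) cue, so a larger mean position means more
approach.

The agent is a one-shot partially observable Markov decision process with
identity observation mappings: the only stochasticity is the
position-dependent outcome lottery. Two parameters govern choice:

* **Emotion conflict (EC ≥ 0)** — the disvalue of observing the aversive
  stimulus, in reward-point units, anchored at 0 for the safe positive
  stimulus. An outcome's utility is `points − EC·[aversive]`; at EC = 4,
  four points exactly offset the aversive stimulus.
* **Decision uncertainty (DU > 0)** — a softmax temperature. The action
  distribution is `softmax(V/DU)`; larger DU flattens choice toward the
  middle of the runway and makes choices inconsistent across trials.

Utilities pass through a softmax and a log to give the log preference
distribution `ln p(o|C)` over the seven observations (a starting sentinel,
the positive stimulus with 0/2 points, the negative stimulus with
0/2/4/6). Because the observation model is an identity mapping, the
expected-free-energy ambiguity term is identically zero and the position
value reduces to the risk term

$$V(k) = \sum_o p(o \mid k)\,\ln p(o \mid C) \;-\; \sum_o p(o \mid k)\,\ln p(o \mid k),$$

with `p(high|k) = k/10`. An expected-log-preference form that drops the
outcome-entropy term is available behind the `form` switch
(`"risk"`/`"logpref"`); the exact value computation inside the reference
MATLAB routine is not published, so both forms are supported and all
distributional properties asserted in the test suite hold under either.
The softmax normalizer of the preference distribution cancels in action
selection, so taking it over the full 7-outcome set is observationally
neutral (asserted by the brute-force equivalence tests).

### The preference scale

Utilities are defined in reward points, but the published DU scale fixes
their conversion into log-preference units. With 1 nat per point, DU
values near the published group means (≈ 4–5) would produce essentially
uniform policies — expected accuracy ≈ 0.16 against a chance level of 1/9 —
which contradicts the published model-validity figures (average action
probability 0.56–0.70 and accuracy 0.72–0.83 at exactly those fitted DU
values). We therefore treat the utility-to-log-preference conversion as an
explicit model constant, `aac_preference_scale()` = 100, calibrated once
so that cohorts simulated at the published group parameter moments fall
inside the published validity band (they land at mean action probability
≈ 0.66 and accuracy ≈ 0.73). Only the ratio scale/DU is identified, so
this constant is a units convention for DU — chosen so that DU values on
the published scale mean what they meant in the study.

## Estimation

Per subject-visit, parameters are estimated in log space
(`θ = (log DU, log EC)`, enforcing positivity) by maximizing the log joint
(choice log-likelihood plus Gaussian log-prior) with BFGS using
central-difference gradients, restarted deterministically from the prior
mean and its four ±1 SD corners. Convergence uses a relative log-joint
tolerance of 1e-6 within 64 iterations per start. The posterior is
approximated as Gaussian at the optimum with covariance the inverse
negative Hessian (Laplace); a singular or indefinite Hessian falls back to
a pseudo-inverse and is flagged.

Likelihood evaluation uses two numerical choices worth stating:

* Policies depend on a trial only through its type, so the likelihood is
  computed from a 5×9 choice-count matrix and five policies per
  evaluation.
* Log-probabilities come directly from a log-softmax rather than
  `log(probability)`. At sharp settings tail probabilities underflow to
  zero; flooring them (e.g., at 1e-12) caps the penalty for choices in a
  sharp policy's tail and systematically biases the temperature downward.
  The log-softmax is finite everywhere and needs no floor.

The default prior is weakly informative — mean (0, 0), variance (4, 4) on
the log scale, spanning raw values from roughly 0.02 to 55 at ±2 SD — and
fully configurable, since the study's priors are not published. For
parameter-recovery experiments the generating population is known by
construction, so `recovery_experiment()` defaults to `cohort_prior()`:
the same weak variance centered at the cohort specification's
moment-matched log-scale means. Without that centering, subjects whose
behavior is nearly uniform (large DU) carry little likelihood information
and are pulled toward the prior mean of 0, producing a spurious aggregate
bias of about −0.25 on log-DU.

`fit_grid()` evaluates the log joint exhaustively on a log-space lattice
and serves as a brute-force oracle: the MAP optimum must dominate every
lattice node, a property exercised in the tests over a 50×50 lattice
spanning the prior's ±3 SD box.

Model validity is summarized by the average action probability (mean
policy probability of the chosen position) and accuracy (fraction of
trials whose choice attains the policy maximum; any member of a tied
argmax set counts as correct — ties are resolved generously because the
convention is not published). A uniform policy yields 1/9 ≈ 11% for both,
the task's chance level.

Group-level analyses conventionally log-transform the skewed parameter
estimates; `optlog_transform()` chooses the offset `c` in `log(x + c)`
from {0} ∪ a 25-point geometric grid on [1e-3, 1e2] to minimize the
absolute adjusted Fisher–Pearson sample skewness.

## Choice uncertainty, response times, reliability

Choice uncertainty is the Shannon entropy of the trial's action
distribution, `−Σ p ln p` (nats, at most ln 9). Its per-subject Pearson
correlation with response times is the model-based RT statistic; RTs that
are non-positive or non-finite are dropped with a count, and zero variance
in either series returns a missing value with a reason code rather than a
number. Model-free summaries are the mean and SD (n−1) of chosen position
and mean RT, overall and per condition.

Longitudinal reliability uses ICC(3,1) — two-way mixed, consistency,
single measures — computed directly from the ANOVA decomposition with
k = 2 occasions: `(MS_subjects − MS_error) / (MS_subjects + MS_error)`.
The consistency form ignores additive visit shifts. Labels follow the
conventional cutoffs: poor below 0.4, fair 0.4–0.6, good above 0.6.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without any
data download. It emulates the study's structure: three groups (HC,
DEP/ANX, SUD) × two visits × the 60-trial design. Its defaults are the
study conditions:

* Group (DU, EC) distributions are log-normal, moment-matched to the
  published raw-scale baseline means and SDs (EC 3.53 (3.57) / 2.97 (3.06)
  / 1.69 (1.94); DU 3.96 (4.65) / 4.14 (4.57) / 5.26 (5.72)).
* Follow-up attrition is 0.25 for HC and, for the clinical groups, the
  rates implied by the published baseline/follow-up group sizes (0.35 and
  0.53), inside the 0.32–0.64 band used by the study's own power
  simulations. Attrition is independent of parameters (MCAR) by default.
* RTs are `intercept + slope·entropy + Gaussian noise`, truncated at
  0.1 s. Rather than fixing the slope, each group specifies a target
  entropy–RT correlation (0.11 for HC and DEP/ANX, 0.16 for SUD — the
  published group-level estimates); the per-subject slope is derived from
  the target, the noise SD and that subject's entropy spread, so the
  expected per-subject correlation equals the target.
* Latent log-parameters are correlated across visits
  (`visit_param_correlation`, default 0.8). The study provides no
  within-subject stability mechanism, so this is an artifact knob: it sets
  the ceiling for fitted-parameter ICCs but is not itself a published
  quantity.
* Ages are uniform on 18–55 and sex is Bernoulli (65% female, near the
  study's composition); an optional multiplicative female EC shift exists
  for sex-effect studies and is off by default so null tests stay null.

What the generator does **not** emulate: the real demographic joint
distribution, symptom scales, comorbidity structure beyond the group
label, condition-specific RT effects beyond entropy coupling, learning or
fatigue across trials, and any deviation of real choice behavior from the
fitted model family. Passing tests therefore demonstrate internal
consistency of the pipeline (the estimator recovers what the model
generates; the classifier finds differences that exist by construction),
not claims about real data.

## The stacked classifier

Binary diagnostic classification uses three base learners — elastic-net
logistic regression, k-nearest neighbors, and bagged AdaBoost — combined
by AUC-weighted linear stacking, evaluated by repeated stratified 5-fold
cross-validation. Design choices where the published description leaves
room:

* **Nested tuning.** Inside each training fold, a stratified 80/20
  training/validation split drives hyperparameter search: 7 random
  starting values per hyperparameter (uniform over alpha ∈ [0,1],
  log10-lambda ∈ [−4,1], k ∈ 1..25, mfinal ∈ 10..150, maxdepth ∈ 1..5),
  searched as a grid for two-parameter algorithms.
* **Up-sampling placement.** The minority class is up-sampled with
  replacement *after* splitting, inside training portions only — never in
  validation or test folds. The fold detail returned by
  `stacked_classify()` records the up-sampled indices so leakage is
  auditable, and the tests assert that duplicated rows never reach test
  folds.
* **Stack weights** are proportional to `max(validation AUC − 0.5, 1e-6)`,
  normalized: learners at or below chance get essentially zero weight.
* **Bagged AdaBoost** is implemented in-package as AdaBoost.M1 over
  depth-limited `rpart` trees on bootstrap resamples (default 5 bags),
  with early stopping on weighted error 0 or ≥ 0.5; the predicted
  probability is the bag-averaged weighted vote share.
* **Variable importance** combines |standardized elastic-net coefficients|
  with permutation importance (AUC drop on the validation split) for the
  other learners, weighted by the stack weights and min-max rescaled to
  0–100.
* **Threshold** 0.5 on the stacked probability; predictions at the
  threshold count as positive. AUC is rank-based (Mann–Whitney with
  average ranks).

Feature sets mirror the study's five predictor sets, from demographics
only (age centered; sex coded −1 female / +1 male) up to the full seven
predictors (log-scale EC and DU at both visits, the entropy–RT
correlation, age, sex). Subjects missing follow-up fits are excluded from
sets that need them, with a reported count.

## Power analysis by simulation

The power module reproduces the study's post-hoc design: outcomes
`y = β₀ + β_g·g + β_t·t + b_subject + ε` with group and visit coded −1/+1,
between- and within-subject variances 0.1 and 0.9 (total 1), and follow-up
observations deleted with group-specific probability (0.25 HC; clinical
values in 0.32–0.64). Each replication fits
`y ~ group*time + (1|subject)` by REML; power is the fraction of
group-term p-values below 0.05, with a binomial CI. The default test is a
Wald t with a between-subject degrees-of-freedom approximation
(n_subjects − 2), appropriate for a between-subject term in a
random-intercept model; a Satterthwaite option is available at roughly
15× the cost. Type-I calibration at the null is part of the acceptance
suite. The replication count is configurable; 4000 matches the study,
while the test suite uses 2000.

## Problem sizes and runtimes in the test suite

The suite exercises: oracle equivalence on 20 simulated subjects with a
50×50 grid each; parameter recovery on a 200-subject cohort at the
60-trial design; classifier calibration over 20 permuted-label seeds at
n = 400 with reduced tuning grids (the null and separability properties
do not depend on grid richness); and the power null at 2000 replications
with 60 subjects per group. These sizes keep the full suite near five
minutes on one core while leaving every assertion at its stated
tolerance.

## Known limitations

* The model is one-shot: no learning, habit formation, or multi-step
  planning; trial order carries no information and the likelihood is
  permutation-invariant by construction.
* DU and EC are estimated per subject-visit independently; no hierarchical
  pooling across subjects is provided.
* The preference-scale constant is a units calibration against published
  validity summaries, not an estimate; analyses that only interpret
  log-scale differences are unaffected by it.
* ICC(3,1) assumes two complete occasions and excludes incomplete pairs
  listwise, mirroring standard practice but discarding information that a
  mixed-model reliability estimate would retain.
* The power simulation's Wald test is slightly liberal in very small
  samples; at the module's intended sample sizes (dozens per group) the
  approximation error is well inside the Monte-Carlo tolerance.
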