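---
title: "Theta-series feature engineering and learner classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-series feature engineering and learner classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetanav)
options(thetanav.quiet = TRUE)
```

## The problem

During virtual spatial navigation, frontal-midline theta power (4–8 Hz,
averaged over F3/Fz/F4) carries signatures of spatial learning. This
package engineers subject-level features from per-trial theta-power time
series and from the navigation trajectories themselves, and evaluates how
well standard classifiers separate subjects who learned a hidden goal
location from time-matched controls without one. The package starts from
already-extracted theta power and x–y coordinates; EEG acquisition,
artefact handling and time–frequency decomposition are upstream and out of
scope.

## Models and procedures

### Per-series standardisation

Two rescalings are supported besides the raw values: min–max,
$x^{\mathrm{minmax}}_t = (x_t - \min \mathbf{x})/(\max \mathbf{x} - \min
\mathbf{x})$, and the Z-score $x^{Z}_t = (x_t - \bar x)/s$ with the
$n-1$ sample SD. Both are computed **within** each subject×trial series,
never pooled: the formulas reference a single series, and per-series
scaling guarantees no cross-subject leakage under leave-one-out
evaluation. Constant series make both transforms undefined and raise a
degenerate-input error.

### Gaussian hidden Markov features

Each series is modelled by an $M$-state Gaussian HMM: a first-order Markov
chain $C_t$ with transition matrix $P$ and free initial distribution, and
emissions $X_t \mid C_t \sim N(\mu(C_t), \sigma^2(C_t))$, conditionally
independent given the state. The serial dependence of the observed series
is induced entirely through the state chain — emissions are not
autoregressive. Estimation is Baum–Welch EM with scaled forward–backward
recursions (the scaled forward pass also provides the log-likelihood used
everywhere); decoding is by Viterbi. The EM stopping rule is a relative
log-likelihood change below $10^{-8}$ or 500 iterations, from 5 seeded
restarts (means initialised at series quantiles with jitter, variances at
the sample variance, near-uniform transitions with a mild diagonal boost).
Emission variances are floored at $10^{-6}\,\mathrm{var}(x)$; if every
emission density underflows at a time point, that step falls back to
uniform state weights rather than propagating NaNs.

State labels are arbitrary, so fitted states are canonically reordered by
ascending mean (ties by ascending variance) before any feature is
extracted; this makes "state 1" comparable across subjects and makes
feature extraction invariant to label permutations.

With $M = 4$ (the default, supported by an AIC comparison across
$M = 2\ldots5$ via `aic_profile()`), each subject×trial contributes 8
parameter features (4 means, 4 variances) and the first 3 Viterbi-path
occupancy frequencies (the fourth is one minus their sum): 11 features.
Occupancy can alternatively be computed from posterior marginals
(`freq_method = "posterior"`), and the $M(M-1)$ free transition entries can
be appended behind `include_transitions = TRUE`; both default off. The AIC
uses $M^2 + 2M - 1$ free parameters ($M$ means, $M$ variances, $M(M-1)$
transition entries, $M-1$ initial probabilities).

### Peak mixed-model features

Peaks are strict interior local maxima ($x_{k-1} < x_k > x_{k+1}$; a flat
plateau whose neighbours are lower counts once, at its first index). This
minimal definition is what the 3-point curvature formula
$x_{k-1} - 2x_k + x_{k+1}$ requires; curvature is kept signed (negative at
peaks). Peak heights $y_{ij}$ are regressed on curvatures $x_{ij}$ with
independent per-subject random intercepts and slopes (diagonal
random-effects covariance). One model is fitted per trial with both groups
pooled, since classification is evaluated per trial; the fit uses `lme4`
by maximum likelihood (REML available via `reml = TRUE`). The features are
the per-subject conditional means of the random effects (BLUPs),

$$\hat b_i = \beta + D Z_i^\top (Z_i D Z_i^\top + \sigma^2 I)^{-1}
  (y_i - Z_i \beta), \qquad D = \mathrm{diag}(\sigma_0^2, \sigma_1^2),$$

implemented in closed form so that a subject *never seen by the fit* gets
a prediction from the trained parameters and its own peaks alone. That is
what the leakage-free cross-validation mode uses: inside every
leave-one-out training fold the mixed model is refitted on the remaining
subjects and the held-out subject receives the held-out BLUP
(`lmm_mode = "per_fold"`, the default when peaks are supplied); a
fit-once mode is available for comparison.

### Trajectory features

Per subject×trial: total idle time (sum of 0.25 s steps with Euclidean
displacement at most `eps`, default 0), total path length, total angle
shift, and average speed (path length divided by the trial's total time,
which time-matching makes comparable across groups). Headings use the
four-quadrant arctangent rather than a ratio arctangent — the ratio form
is undefined for vertical steps and conflates opposite directions — and
absolute heading differences are wrapped to $[0^\circ, 180^\circ]$ so a
turn and its mirror count equally. Zero-displacement steps have no heading
and are skipped; they contribute to idle time instead.

### Classification protocol

Six fixed configurations: polynomial SVM (degree 3), RBF SVM
($\gamma = 1/(p\,\mathrm{var}(X))$), random forest (1000 trees, depth 5),
1-nearest-neighbour, elastic-net logistic regression, and an 8-layer MLP
(hidden widths 100, 150, 200, 150, 46, 20, 10; ReLU; sigmoid output;
binary cross-entropy; full-batch Adam at $10^{-3}$ for 200 epochs, seeded
initialisation). The elastic-net mixing weight 0.98 multiplies the **L2**
term (the model is near-ridge), which maps to `glmnet`'s `alpha = 0.02`;
the penalty strength defaults to $\lambda = 1$. Unprinted hyperparameters
keep package defaults and are recorded on the specification object.

Evaluation is leave-one-out cross-validation with the AUROC
(Mann–Whitney, ties counting one half) computed once over the $n$ pooled
held-out scores. Two protocol details matter at $n = 50$:

* *Within-fold feature standardisation* (centre/scale by training-fold
  statistics) for all scale-sensitive learners — everything except the
  random forest.
* *Fold-shift correction.* A leave-one-out training fold lacks exactly one
  subject of the held-out class, so each fold's trained model is shifted
  slightly against that class; pooling raw scores then leaks the held-out
  label and biases the AUROC downward even for exchangeable (no-signal)
  features. Two measures counteract this: inverse-frequency class weights
  during training, and centring each held-out score by the trained model's
  mean score over its own training fold (`center_scores = TRUE`). Neither
  affects the ROC of any single fixed model; both only calibrate scores
  across folds. The 1-NN vote is exempt from centring: it has no
  model-level score scale, so the correction would add a label-dependent
  offset instead of removing one.

### Local surrogate explanations

For each subject, the trained scorer is probed on Gaussian perturbations
of the subject's feature vector (SD = 0.25 × each feature's cohort SD, 500
samples), weighted by an exponential kernel on standardised Euclidean
distance (width $0.75\sqrt{p}$). A K-Lasso surrogate — lasso path to
select at most $K = 3$ features, then kernel-weighted least squares on the
selection — yields local weights on the raw feature scale, so a linear
scorer is recovered with its actual coefficients. Per-(group, trial)
rankings count how often each feature is retained across subjects. None of
these constants are prescribed by the task; they are package defaults,
exposed as arguments.

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` fixes the study conditions: 25 subjects per group, trials
1 and 12, a circular arena of radius 37.5 Vm with a central goal of 15 %
of the arena area, constant speed 4.76 Vm/s, 0.25 s trajectory sampling, a
60 s cap, and theta series at 4 Hz (a deliberately low rate — the method
is sampling-rate-agnostic and tests stay fast; up to 512 Hz is supported).
Trial-1 generating parameters are identical across groups — nobody has
learned yet — while trial-12 learners differ twice over: their theta-state
means are shifted by 3 state SDs (`effect_size = 3`) and their walks are
goal-biased (bias 0.5 blended into the heading, noise SD 0.6 rad, idle
probability 0.1), terminating at the goal. Non-learner durations are
time-matched by drawing the stopping time of an independent "phantom"
goal-seeking walk with the learner kinematics of that trial, so durations
follow exactly the learner law without duplicating any individual
learner's time; matching to the mean instead would make non-learner
durations a constant and turn duration variance into a spurious group
signal. Theta-series length is duration × sampling rate, so trial length
itself carries behavioural information, as in the recorded task.

The generator reproduces the structure the method assumes — HMM-distributed
theta with known states, mixed-model-compatible peak structure,
goal-directed versus undirected kinematics — and records every hidden truth
for recovery tests. It does **not** emulate 1/f EEG background, artefacts,
volume conduction, inter-trial learning curves, or human path kinematics
(wall-following, head-direction dynamics). Passing tests therefore show
that the pipeline recovers what its models assume and discriminates when
the assumed structure separates groups; they do not certify performance on
recorded EEG.

## Numerical choices and edge cases

* EM log-likelihood monotonicity is checked every iteration; a decrease
  raises a warning.
* Series shorter than `min_length` (default $10M$ for a direct fit, $3M$
  in the cohort feature extractor, where short learner trials are
  legitimate) are rejected.
* AUROC requires both classes; constant-score inputs return 0.5 by the
  tie rule.
* Degenerate inputs (constant series for scaling, all-idle paths for the
  angle shift, zero perturbation variance for the explainer) raise typed
  errors rather than returning silent NaNs.
* All randomness flows from one integer seed per entry point, fanned out
  to named substreams (simulation, per-series restarts, per-fold training,
  perturbations), so every result is bit-reproducible.

## Problem sizes used by the test-suite and acceptance script

Oracle comparisons run on exhaustive-enumeration scales (state paths with
$M \le 3$, $T \le 8$); EM recovery uses $T = 2000$ with 20 replicates;
mixed-model recovery uses 50 subjects × 30 peaks; the end-to-end
evaluation uses the full 25-per-group cohort with the random forest and
the MLP on trials 1 and 12. These sizes were chosen so the whole suite
exercises every claim at meaningful precision while remaining quick to run
on a laptop.

## Known limitations

* One HMM per series: no population-level or shared-state model, so state
  identities align across subjects only through the mean-ordering
  convention.
* The mixed model has a single covariate and diagonal random-effects
  covariance by construction; correlated random effects are out of scope.
* LOOCV AUROC at $n = 50$ has substantial sampling variance (SD ≈ 0.08
  under the null even after fold-shift correction); single-cohort values
  near the chance band should be read accordingly.
* The trajectory generator's arena physics is minimal (positions clamped
  to the wall, heading turned inward); it makes no claim of fidelity to
  human kinematics beyond the goal-directed/undirected contrast.
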