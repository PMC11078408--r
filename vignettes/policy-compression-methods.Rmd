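---
title: "Models and methods: capacity-limited reinforcement learning in polcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: capacity-limited reinforcement learning in polcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcomp)
```

## The scientific problem

An agent learning a stimulus-response task holds a *policy* $\pi(a \mid s)$
mapping states to actions. Viewed as a communication channel, the policy
carries $I(S;A)$ bits of state information per decision — its *policy
complexity*. A capacity-limited agent cannot exceed some rate $C$, so it must
trade expected reward against complexity. The optimal policy under the
constraint takes the form

$$\pi^*(a \mid s) \propto \exp\big[\beta\, Q(s,a) + \log P^*(a)\big],$$

a softmax over state-action values biased toward actions with high marginal
probability $P^*(a) = \sum_s P(s)\,\pi^*(a\mid s)$. The Lagrange multiplier
$\beta$ interpolates between a state-independent policy that just reproduces
the marginal ($\beta \to 0$) and greedy reward maximization
($\beta \to \infty$); $1/\beta$ is the slope of the optimal
reward-complexity curve. `polcomp` implements this framework end to end:
task environments, the optimal frontier, learning agents that implement the
trade-off online with trial-wise response-time (RT) predictions,
non-compressing comparison models, joint choice+RT maximum-likelihood
fitting, and the behavioral metric suite used to detect compression
signatures in data.

## Task environments

Three instrumental-learning tasks share a 3-state/3-action structure with
binary feedback and two conditions each (Q1 control, Q2 manipulation):

* **Task 1** manipulates the *state distribution*: Q1 presents each stimulus
  30 times (90 trials); Q2 presents one stimulus 90 times and the others 30
  (150 trials, $P(s) = (0.6, 0.2, 0.2)$). Both conditions share one reward
  function.
* **Task 2** manipulates *action redundancy*: Q1 is a deterministic
  one-to-one mapping; in Q2 action $A_1$ is deterministically rewarded in
  every state, and $S_2$/$S_3$ each have a second deterministic optimal.
* **Task 3** manipulates *time pressure*: one reward function (optimal
  shared action for $S_1$/$S_2$, own optimal for $S_3$), with a 2 s response
  deadline in Q1 and 1 s in Q2.

Within each task the two conditions are constrained to share the maximum
reward probability and the state-weighted mean of the per-state best reward;
`build_condition()` enforces this. The reward probabilities of Tasks 1 and 3
are not fully pinned down by the design, only their ordering; the defaults
(Task 1: 0.8 optimal vs. two 0.2 suboptimals; Task 3: 1.0 / 0.25 / 0) satisfy
the constraint and are exposed in the task configuration rather than
hard-coded. Stimuli and responses are represented in the canonical
already-remapped space; physical key randomization is not modeled.

## The optimal frontier

`blahut_arimoto()` alternates the optimal-policy form with the marginal
update $P(a) \leftarrow \sum_s P(s)\pi(a\mid s)$ until the policy is
stationary (tolerance $10^{-8}$ on the max-abs policy change, at most
$10^4$ iterations, uniform initialization). Tracing $\beta$ over a grid
(`compute_frontier()`) yields the reward-complexity curve; both coordinates
are non-decreasing in $\beta$ and the curve is concave. Internally all
logarithms are natural; reported complexities are converted to bits, which
is what the estimators and figures in this literature use. The suite checks
the fixed point against an exhaustive policy-grid search on 2-state
instances and against closed-form complexities of deterministic policies.

## The compression agent

The process model is an actor-critic that follows the policy gradient of
the cost-sensitive objective $\mathbb{E}[\beta r - \log \pi(a\mid s)/P(a)]$
under the parameterization
$\pi_\theta(a \mid s) \propto \exp[\beta\,\theta_{sa} + \log P(a)]$:

* prediction error $\delta = \beta r - \log\frac{\pi(a|s)}{P(a)} - \hat V(s)$,
* propensities: $+\alpha_\theta\,\delta\,(1-\pi)\,\beta$ for the chosen
  action, $-\alpha_\theta\,\delta\,\pi\,\beta$ for the others,
* critic: $\Delta\hat V(s) = \alpha_V\,\delta$,
* marginal estimate: $\Delta P(a) = \alpha_P[\pi(a|s) - P(a)]$ applied to
  every action of the visited state's policy row, then floored at $10^{-6}$
  and renormalized,
* running complexity and reward estimates $\xi$ and $\rho$ as exponential
  moving averages with fixed rates $\alpha_\xi = \alpha_\rho = 0.01$.

A property test verifies that the expected propensity update equals the
numerical gradient of the objective to $10^{-5}$.

Five variants differ in how $\beta$ evolves: fixed (one $\beta$, or one per
task-condition cell in canonical order), capacity-targeting
($\Delta\beta = \alpha_\beta(C - \xi)$), aspiration-targeting
($\Delta\beta = \alpha_\beta(R - \rho)$), and the hybrid
$\Delta\beta = \alpha_\beta\!\left(\frac{C-\xi}{R-\rho} - \beta\right)$,
which steers $\beta$ toward an estimate of the local slope of the optimal
frontier. In the time-pressure block the capacity/aspiration variants swap
in $C_{\text{reduced}}$/$R_{\text{reduced}}$.

Numerical guards (the equations do not supply them): the $R-\rho$
denominator is clamped away from zero at $10^{-3}$ preserving sign;
adaptive $\beta$ is clamped to $[0, 100]$; propensities and critic values
are clamped at $\pm 10^3$, far outside any sane trajectory, purely so the
likelihood stays finite in pathological parameter corners. Initialization is
$\theta = 0$, $\hat V = 0$, uniform $P(a)$, $\xi = \rho = 0$, and
$\beta = \beta_0$ (or the fitted fixed $\beta$); the learning state resets
at every block boundary because each block uses new stimuli.

Capacity units: $\xi$ averages the natural-log policy cost, so $C$ and
$C_{\text{reduced}}$ are in nats. The boundary `lb` splitting their fitting
ranges ($C \in [lb, 3]$, $C_{\text{reduced}} \in [0, lb]$) defaults to one
bit, i.e. $\log 2$ nats; because $C \ge lb \ge C_{\text{reduced}}$, the
ordering constraint holds by construction and no reparameterization is
needed.

### Response times

Each trial's RT is lognormal around a regression on the trial's policy cost
and policy entropy:
$\log \mathrm{RT} = \log(t_0 + b_1 \log\frac{\pi(a|s)}{P(a)} + b_2 H) +
\epsilon$, $\epsilon \sim N(0, 0.9^2)$, $t_0 = 150$ ms, with the inner term
floored at 1 ms (the cost can be negative). The likelihood is the lognormal
density in milliseconds (Gaussian on $\log$ RT including the $1/\mathrm{rt}$
Jacobian) and is *not* truncated at the deadline; simulation, by contrast,
resamples draws until they beat the deadline, so simulated sessions contain
no missed trials. Simulated RTs are deliberately not truncated from below:
the lognormal noise can produce responses faster than the accumulator
models' non-decision time, and the inability of those models to explain such
trials is a genuine — in fact dominant — discriminating signal between the
model classes (see model recovery below). Missed trials in real data are
excluded from both likelihood terms and trigger no learning update.

## Comparison models

**Standard RL** learns $Q(s,a)$ by a delta rule and responds via
$\pi \propto \exp[\beta Q]$ (one $\beta$ or six). **RLWM** adds a
working-memory module with one-shot learning ($\alpha_{WM}=1$), trial-wise
decay of all associations toward $1/n_A$ at rate $\phi$, scaling of both
modules' learning rates by $\gamma$ on negative feedback, and a mixture
policy with weight $w = \rho\,\min(1, C/n_S)$; both softmax temperatures are
fixed at 50. Decay is applied to every cell, including the visited one,
before the learning step.

Choice and RT for both models come from a Linear Ballistic Accumulator:
start points uniform on $[0, A]$, drifts $N(v_i, 0.1)$ with
$v_i = \eta\,\pi(a_i|s)/H_{\text{prior}}$, where $H_{\text{prior}}$ is the
base-2 entropy of the state-averaged policy (recomputed each trial over the
block's three states, floored at $10^{-3}$ bits). The uncertainty-scaled
drift form is used for both comparison models. The bound is $B_1$ in 2 s
blocks and a separately fitted $B_2$ under time pressure. Simulation redraws
drifts until a positive one exists; the likelihood is the standard defective
first-passage density (winner's density times the losers' survivors),
normalized by the probability that at least one drift is positive, which the
suite validates against Monte-Carlo samples (KS < 0.02 at $n = 10^5$) and by
quadrature.

When *fitting*, the per-trial LBA density is floored at $10^{-10}$. The
exported `lba_loglik()` honors the hard contract that an RT at or below
$t_0$ is impossible ($-\infty$), but a hard $-\infty$ makes the subject-level
objective flat and unusable wherever a dataset contains such trials — which
compression-simulated cohorts essentially always do. The floor converts each
impossible trial into a ~23-nat penalty, the standard robust-likelihood
device in this literature.

## Fitting

`fit_subject()` maximizes the joint choice+RT likelihood per subject across
all six blocks with one parameter vector, under the box bounds of the model
registry (`model_spec()`). The compiled likelihood replays the learning
recursion deterministically from the observed $(s, a, r)$ stream; an R
reference implementation built from the single-step agent functions is
tested for exact agreement.

The adaptive-variant likelihood surfaces are only piecewise smooth and, in
parts of the bound box, chaotic: near $R \approx \rho$ trajectories the
$\beta$ dynamics diverge, and a 0.01 shift in $R$ can move the
log-likelihood by $10^5$. A plain bounded quasi-Newton search is unreliable
there, so each start runs Nelder-Mead on a logistic-transformed (unbounded)
space followed by an L-BFGS-B polish, cycled while it improves. Starts come
from a seeded shifted-Halton design: equally space-filling as a Latin
hypercube but *nested*, so increasing `n_starts` can only improve the
result. BIC is $2\,\mathrm{nll} + k \log n$ with $n$ the number of responded
trials (each contributes one joint term).

`parameter_recovery()` simulates a cohort, refits it, and reports
per-parameter Pearson correlations; `model_recovery()` fits all eight
variants to one generating model's cohort and tabulates BIC (mean, SD, and
best-model counts; group-level Bayesian model selection such as PXP is out
of scope, BIC comparison substitutes). Model recovery defaults to a rougher
search (3 starts, 1 cycle) because the compression/non-compression BIC gap
it must resolve is three to four orders of magnitude larger than residual
optimization error.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` produces fully synthetic cohorts: per-subject
parameters from a declared sampler, a randomized
task/condition order per subject, seeded stimulus sequences, and
model-generated choices and RTs, written to the canonical CSV with a truth
sidecar. The default sampler is uniform over the fitting bounds except that
learning rates are log-uniform on $[10^{-2}, 1]$ — a cohort dominated by
near-zero learning rates produces flat trajectories that carry no
information for recovery. Recovery studies on human datasets in this
paradigm are typically run by simulating from parameters *fitted to the
subjects*, which concentrates the generating values in the smooth,
well-identified region of the model; a declared uniform sampler explores the
whole bound box instead, so recovery statistics from it are systematically
harsher and should not be compared against fitted-parameter studies at face
value.

A green cohort-level test therefore establishes that the implemented
mechanisms produce the predicted *directions* (marginal-action bias, the
complexity/reward orderings across conditions, the RT-complexity
correlation), not that the synthetic cohort is distributionally human-like.
Known gaps: uniform parameter draws visit dynamical regimes human fits
likely avoid (full compressors with $R$ below attainable reward; $\beta$
pinned at its clamp); real data contain missed and anticipatory responses,
practice effects, and motor idiosyncrasies none of which are generated.

## Empirical metrics

Policy complexity is estimated from (state, action) counts by the Bayesian
posterior-mean mutual information under a symmetric Dirichlet prior
(`hutter_complexity()`), with per-cell pseudocount $1/(n_S n_A)$ by default
(the total prior mass of one observation; the estimate is insensitive to
this choice at task-sized $n$, and the concentration is config-exposed).
Stochasticity is the state-weighted conditional entropy of row-normalized
counts. Action bias contrasts the high-marginal action with its
reward-matched alternative per state (tasks 1-2) or tracks per-state
suboptimal-choice proportions across deadline conditions (task 3).
`learning_dynamics()` computes 30-trial sliding-window complexity, reward
and RT series truncated to $n - 30$ points; `setsize_bias()` implements the
generic memory-load analysis for external multi-set-size datasets; and
`mean_split()` supports the low/high-complexity individual-difference
contrasts. Reward in the trade-off analyses is the raw mean reward per
trial, unnormalized.

## Known limitations

* The capacity $C$ is the weakest-identified parameter of the
  capacity-value model under the uniform sampler: its profile likelihood is
  flat or displaced for many draws, and no optimizer can rescue a parameter
  the data barely constrain. Its recovery correlation (~0.2-0.3 at 30
  subjects) is the floor of the model's recovery profile.
* The chaotic regions of the adaptive likelihoods mean multistart MLE is
  approximate there; fitted dynamics parameters for individual subjects in
  those regimes should be read with caution.
* The LBA density floor, the $\beta$ clamp, and the RT inner-term floor are
  pragmatic guards without empirical content; conclusions that depend on
  data sitting exactly on these guards would not be meaningful.
* Only the 3-state/3-action block structure is implemented; set-size
  analyses beyond it accept external tabular data only.
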