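---
title: "Models and simulation studies for the two-stage decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation studies for the two-stage decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
```

## The task and its generative environment

The two-stage task is the standard laboratory assay for dissociating
model-based from model-free control of choice. On every trial the subject
picks one of two first-stage options; with fixed probability 0.7 ("common"
transition) this leads to one designated second-stage state, otherwise
("rare", 0.3) to the alternative state. Each second-stage state offers two
bandits paying a binary reward whose probability follows a slow Gaussian
random walk, so values must be tracked continuously. `task_config()`
captures this environment. Two conventions are fixed by the package and
documented rather than configurable facts of nature:

* the frequent destination of first-stage action 1 is state 2 (action 2
  leads commonly to state 3);
* the walks take Gaussian steps of sd 0.025 reflected at \[0.25, 0.75\],
  initialized uniformly, the classic design for this task. Both step size
  and bounds are `task_config()` arguments.

Sessions default to 201 trials in two blocks (the canonical follow-up
length; 121 is the canonical short baseline). A 2 s response deadline is
*not* imposed during simulation by default: the fitted likelihood has no
censoring term, and keeping the generative model identical to the
likelihood makes simulation-based studies interpretable. A `deadline`
option resamples timed-out stages for users who want realistic surfaces.

## The hybrid learner

Both models share one latent value recursion. Model-free values of the four
second-stage bandits and the two first-stage actions start at zero and are
updated once per trial by SARSA prediction errors:

$$Q^{MF}(a_2) \leftarrow Q^{MF}(a_2) + \alpha_2\,(r - Q^{MF}(a_2)),$$
$$Q^{MF}(a_1) \leftarrow Q^{MF}(a_1) + \alpha_1\,(Q^{MF}(a_2) - Q^{MF}(a_1))
  + \alpha_1 \lambda\,(r - Q^{MF}(a_2)),$$

where the eligibility trace $\lambda$ controls how strongly the
second-stage prediction error reaches the first stage. Both prediction
errors use the *pre-update* second-stage value; the two updates are
committed together at the end of the trial (the standard SARSA($\lambda$)
reading — this ordering is asserted against an independent R trace in the
tests). Unchosen values neither decay nor update.

Model-based first-stage values combine the known transition probabilities
with the best reachable bandit,
$Q^{MB}(a_1) = P(s_2\mid a_1)\max Q^{MF}(s_2) + P(s_3\mid a_1)\max Q^{MF}(s_3)$,
with $P$ fixed at (0.7, 0.3): the transition structure is treated as known
to the agent, not learned online. The net first-stage value blends the two
systems and adds a perseveration bonus for the previous trial's choice:

$$Q^{net}(a_1) = (1 - w)\,Q^{MF}(a_1) + w\,Q^{MB}(a_1) + p\,\mathrm{Stay}(a_1).$$

The weight $w \in [0,1]$ is the quantity of scientific interest: 0 is a
pure model-free, 1 a pure model-based agent. The stay indicator resets on
each block's first trial (no previous action), so those trials carry no
perseveration and are excluded from stay-based scores.

## Choice-only likelihood (RL model)

Choices enter a softmax at each stage: $Q^{net}$ under inverse temperature
$\beta_1$ at stage one, the visited state's $Q^{MF}$ pair under $\beta_2$
at stage two. The full variant has seven parameters
($\alpha_{1,2}, \beta_{1,2}, \lambda, w, p$); the tied variant shares
$\alpha$ and $\beta$ across stages (five parameters).

## Joint choice and RT likelihood (DDM-RL)

The DDM-RL model replaces the softmax with a Wiener diffusion: evidence
starts midway between two absorbing boundaries separated by $a$ (no prior
bias), accumulates with unit noise and drift
$\delta = b\,(Q(\text{chosen}) - Q(\text{unchosen}))$, and the reaction
time is the first-passage time plus a non-decision time $\tau$. The chosen
option is always assigned the upper boundary, which is equivalent to a
drift-sign convention. Stage one uses $Q^{net}$ (including $w$ and
perseveration), stage two the visited state's $Q^{MF}$ values. The full
variant has eleven parameters (stage-specific $b, a, \tau$), the tied
variant eight. There are no inter-trial variability parameters and no
starting-point bias, deliberately.

### Numerics of the first-passage density

`dwfpt()` evaluates the density by the two classical series expansions,
switching between the small-time and large-time forms by the standard
fewest-terms criterion, truncated at an absolute tolerance of $10^{-8}$
(configurable). Three numerical decisions matter in practice:

* **RTs at or below $\tau$.** The density is floored at $10^{-10}$
  (log $\approx -23$) instead of returning $-\infty$, which keeps
  optimizers on a finite surface; the floor is configurable through
  `twostep_loglik()`.
* **Exact sampling.** With a symmetric start the absorption probability is
  logistic, $P(\text{upper}) = 1/(1 + e^{-a\delta})$, and the decision time
  is independent of which boundary absorbs and of the drift sign.
  `rwfpt()` exploits this: it draws the boundary from the closed form and
  the time by safeguarded-Newton inversion of the conditional survival
  series. There is no discretization error; tests verify the sampler
  against both the analytic CDF and a brute-force Euler–Maruyama
  simulation (`rwfpt_euler()`, step 1e-4 s), the latter kept as a fully
  independent oracle.
* **First trial / tied values.** All values are zero at session start, so
  stage drifts are zero and choice odds are exactly even — a property the
  tests assert.

## Fitting

`twostep_fit()` estimates per-session parameters by multistart
maximum likelihood in unconstrained space: logit transforms for
$\alpha, \lambda, w$; log for $\beta, b, a, \tau$; identity for $p$.
Box constraints (by default the simulation-study sampling ranges) are
applied on the transformed scale, starts are drawn uniformly inside them,
and each start is polished with `nlminb`. The fit is deterministic given
`fit_options(seed =)`. A global genetic-algorithm search would serve
equally; the optimizer is a means, not part of the model, and the
parameter-recovery study is the arbiter of adequacy.

With `hierarchical = TRUE` the package runs expectation-maximization with
a Laplace approximation: each parameter is an independent Gaussian random
effect in transformed space; the E-step computes per-session MAP estimates
and inverse-Hessian variances, the M-step the moment updates
$\mu = \overline{\theta_i}$,
$\sigma^2 = \overline{\theta_i^2 + V_i} - \mu^2$ with a variance floor of
$10^{-6}$ (a singular Hessian falls back to the prior variance and is
counted in the fit object). Convergence is a relative change of the summed
Laplace evidence below $10^{-4}$, capped at 200 iterations.
`bic_int()` reports the group-level criterion
$-2\sum_i \widehat{\log p(D_i)} + 2d\,\log N_{obs}$, where the
hyperparameter count is two (mean, variance) per free parameter and an
observation is one stage of one trial. The hyperparameter-count convention
inside the penalty is not uniquely pinned down in the literature; this
choice is documented here and used consistently, so model comparisons
(which difference the penalty) are unaffected by the shared constant.

## Model-agnostic scores

* **MB-I (choice)** is the transition-by-reward interaction on the
  probability of repeating the first-stage choice,
  $(P_{stay}^{c,r} - P_{stay}^{r,r}) - (P_{stay}^{c,u} - P_{stay}^{r,u})$.
  Positive = model-based. Stay pairs spanning a block break or a removed
  trial are dropped — the conservative reading of first-trial omission.
* **MB-II (RT)** is the mean second-stage RT after rare minus after common
  transitions. Model-based agents discriminate second-stage values better
  after common transitions (larger $\Delta Q$, hence higher drift and
  faster passage), so positive = model-based. The `w_sweep()` study
  reproduces this mechanism: the state holding the globally best bandit
  also shows the larger within-state value spread, and higher $w$ routes
  the agent there via common transitions.
* **Hierarchical variants** come from mixed models fitted across subjects
  (lme4 with BOBYQA, Laplace approximation): a logistic regression of stay
  on previous transition × reward with full factorial fixed and random
  effects (−1/+1 coding, +1 = common/rewarded; the subject-level
  interaction slope is the score) and a linear regression of RT2 on
  transition with random intercept and slope. For the RT model the package
  codes rare = +1 so that, like the individual score, positive means more
  model-based; flipping the coding flips the sign and nothing else. The
  returned score is the subject-level conditional slope (fixed + random
  effect); correlation-based analyses are invariant to the shared fixed
  offset.
* **Effect sizes** are classical (non-partial) $\eta^2$ over condition-cell
  means per subject × timepoint, computed with `aov()`: the interaction
  sum-of-squares share for MB-I cells, the transition share for MB-II cell
  means. Trial-level and partial variants would give different numbers;
  the cell-mean classical form is the documented choice.

## Simulation studies and their problem sizes

All studies are seeded and reproducible. Default sizes follow the original
study design (100 agents for recovery, 1000 iterations for power, 200
experiments × 5000 trials per sweep level); the bundled acceptance script
and tests use reduced but statistically adequate sizes — 80 recovery agents
with 12 optimizer restarts, 200–300 power iterations, 40 sweep experiments,
250-agent reliability cohorts — chosen so each study still pins its
estimate inside the comparison tolerances. Reliability cohorts draw the
model-based weight from a Gaussian truncated to \[0, 1\] (mean 0.5,
sd 0.2) with the remaining parameters uniform: a uniform $w$ makes both
scores' split-half reliabilities saturate (the cohort is unrealistically
heterogeneous), while very narrow $w$ spreads leave the choice score
unreliable at any feasible length; the chosen spread brackets empirically
reported reliability levels for the choice score.

* **Parameter recovery** (`parameter_recovery()`): agents drawn uniformly
  from the documented ranges ($\alpha,\lambda,w \in [0,1]$,
  $\beta \in [1,8]$, $p \in [0,.5]$, $b \in [1,10]$, $a \in [1,3]$,
  $\tau \in [.01,.5]$), simulated, refitted with the same ranges as box
  constraints, summarized by per-parameter Spearman correlations. The
  sampling ranges double as optimizer bounds because nothing outside them
  was generated.
* **Split-half reliability** (`split_half()`, `reliability_curve()`):
  odd/even split by the *outcome* trial's parity; the conditioning trial's
  transition/reward coding is kept regardless of its own parity, so no
  pairs are lost to the split itself. Spearman-Brown ($2r/(1+r)$) restores
  full-length reliability.
* **Power** (`power_analysis()`): two groups of agents whose $w$ is drawn
  from Gaussians truncated to \[0, 1\] (sd 0.1; means .49/.51, .475/.525,
  .46/.54 for small/medium/large effects), 200-trial DDM-RL sessions,
  individual MB-I and MB-II per agent, and a two-group MANOVA via Wilks'
  $\Lambda$ with Bartlett's $\chi^2$ approximation at $\alpha = .05$.
  The non-$w$ parameters are not part of the effect definition; the
  package draws them uniformly **once per simulated experiment** (all
  agents of an iteration share them), the same unit used by the mechanism
  sweep. Drawing them per agent instead (`nuisance = "agent"`) inflates
  between-subject score variance and lowers power, especially for large
  samples; with per-experiment draws a minority of experiments receive
  weakly informative settings (e.g. small drift scaling $b$), which caps
  attainable power below 100% even for large effects. Both units are
  exposed because the choice is a genuine degree of freedom of the design.
* **Temporal stability** (`temporal_stability()`): Pearson, Spearman, or
  Spearman partial correlation (rank-residualized on a covariate), with
  Fisher-z intervals (variance inflation 1.06 for the rank-based forms).

## What the simulator does and does not emulate

Simulated cohorts reproduce the task's trial structure, transition
statistics, reward walks, block breaks, and (for DDM-RL) full RT
distributions with non-decision floors. They do not emulate attention
lapses, posture/motor artifacts, deadline censoring (unless enabled),
fatigue or learning-to-learn across blocks, or stimulus-identity effects
(the fractal-identity control regression is an explicit extension point,
not implemented). Passing recovery or reliability studies on simulated
data therefore bounds what the *models and scores* can do when their
assumptions hold; they cannot certify robustness to violations real
participants produce.

## Known limitations

* The DDM-RL likelihood treats the 2 s deadline as absent; fitting data
  with heavy censoring near the deadline will bias $a$ and $\tau$.
* The hierarchical EM uses diagonal (per-parameter) priors; correlated
  random effects are not modelled.
* `eta_squared()` is undefined for degenerate cohorts (zero variance) and
  returns `NA` there.
* Empirical-data results from the original cohort study (correlation
  tables, empirical reliability, BIC values) require that external
  dataset; the package ingests any schema-mapped CSV and emits the
  corresponding tables, but ships no empirical data.
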