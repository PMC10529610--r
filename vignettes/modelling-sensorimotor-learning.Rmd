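---
title: "Modelling trial-by-trial sensorimotor learning with hierarchical Gaussian filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial sensorimotor learning with hierarchical Gaussian filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgfbms)
```

## The modelling problem

Many sensorimotor behaviours are driven by *predictions*: the grip force
applied before an object is lifted reflects the expected weight, and the
location fixated ahead of a bouncing ball reflects the expected bounce
height. When the environment's regularities change over trials, these
predictive behaviours trace out a learning process. `hgfbms` implements
the computational machinery for turning such trial series into
interpretable learning parameters: candidate perceptual models mapping a
binary input series $u^{(k)}$ to beliefs, a response model mapping
beliefs to binary actions $y^{(k)}$, subject-level Bayesian inversion,
random-effects model comparison, and group statistics on the extracted
parameters. Two task families motivate the defaults: a size–weight-illusion
(SWI) lifting task (5 baseline + 32 test lifts; two diameters
× two masses, eight lifts each, heavy objects encountered before light
ones) and a bounce-interception task (45-trial stable and volatile
conditions with 30 expected / 15 unexpected balls, volatile blocks of
6/9/12 trials at 83/67/50 % predictiveness).

## Perceptual models

### Binary hierarchical Gaussian filter

The HGF represents the environment as a hierarchy of Gaussian random
walks. The binary outcome $x_1 \in \{0,1\}$ is governed by a tendency
$x_2$ (logit units) which drifts with step variance
$\exp(\kappa_2 x_3 + \omega_2)$; the log-volatility $x_3$ drifts with
step variance $\exp(\kappa_3 x_4 + \omega_3)$ in the 4-level variant or
with a constant variance $\vartheta$ when it is itself the top level,

$$x_L^{(k)} \sim \mathcal{N}\!\left(x_L^{(k-1)}, \vartheta\right).$$

Filtering proceeds with the standard variational (precision-weighted)
update equations for the binary HGF: the level-2 belief moves in
proportion to the first-level prediction error
$\delta_1 = u - \hat\mu_1$ weighted by the ratio of prediction
precisions, and each higher level is driven by the volatility prediction
error from the level below. `hgf_filter()` runs this recursion (in
compiled code) and rejects any parameterisation whose trajectory
produces a non-positive posterior precision, raising an
`hgf_divergence` condition carrying the offending trial; the inverter
treats such proposals as infinitely improbable rather than crashing.
Because the exact update equations are easy to mis-transcribe, the test
suite contains an independent hand-written one-step transcription and
requires agreement to $10^{-10}$ — this oracle caught a real
level-coupling indexing error during development.

Interpretation of the reported parameters:

* `om2` ($\omega_2$): tonic log-volatility of the tendency — how fast
  beliefs about the outcome contingency can move. Unbounded,
  log-variance units; default prior mean −3 (variance 4).
* `om3` ($\omega_3$, 4-level only): tonic log-volatility of the
  volatility. Default prior mean −6 (variance 4).
* `th` ($\vartheta$): top-level random-walk variance; positive, fitted
  on the log scale. In the 4-level model its log is exposed as
  $\omega_4$ with a deliberately tight prior (variance 0.05), which
  reproduces the empirical degeneracy of a fourth-level volatility
  parameter on series of a few dozen trials while keeping it formally
  estimable.
* `kappa` ($\kappa_i$): inter-level couplings, fixed at 1 by default
  (standard practice for the binary HGF; they trade off against the
  $\omega$'s on short series).
* Initial states default to $\mu^{(0)} = (0, 1, 1)$,
  $\sigma^{(0)} = (0.1, 1, 1)$ for levels 2–4 and are not estimated.

Per-trial learning rates are defined operationally as the realised
update/prediction-error ratio: $\alpha_2^{(k)}$ is the first-level-space
belief shift divided by $\delta_1^{(k)}$ (always in $[0,1]$), and
$\alpha_3^{(k)}$ the level-3 shift divided by the volatility prediction
error $\delta_2^{(k)}$ (not bounded by 1). Subject summaries are means
over trials, skipping near-zero prediction errors. The `alpha_3`
summary is strongly right-skewed in practice, which is why the group
battery offers rank tests.

### Associative learners

The Rescorla–Wagner rule $v^{(k)} = v^{(k-1)} + \alpha\,\delta^{(k)}$
with fixed $\alpha$, and Sutton's K1 gain-adaptation scheme in which the
log learning rate is nudged by the correlation between the current
prediction error and a decaying trace of recent updates
($\beta^{(k)} = \beta^{(k-1)} + \mu\,\delta^{(k)} h^{(k-1)}$,
$\alpha^{(k)} = \min(e^{\beta^{(k)}}, 1)$,
$h^{(k)} = h^{(k-1)}\max(0, 1-\alpha^{(k)}) + \alpha^{(k)}\delta^{(k)}$).
K1's gain is tracked as an offset from $\log\alpha_0$ so that
$\mu = 0$ reproduces Rescorla–Wagner *exactly*, which the tests assert
bit-for-bit.

## Response model

Beliefs map to response probabilities through the unit-square sigmoid

$$p\!\left(y^{(k)}{=}1\right)
  = \frac{m^{\zeta}}{m^{\zeta} + (1-m)^{\zeta}},$$

where $m$ is the belief held *before* trial $k$'s input (for the HGF,
$s(\mu_2^{(k-1)})$; for the associative models, $v^{(k-1)}$) and
$\zeta > 0$ is the inverse decision temperature: $\zeta = 1$ is
probability matching, large $\zeta$ approaches a deterministic step.
Composing the logistic with the unit-square sigmoid keeps all four
perceptual models on the same response model with the same $\zeta = 1$
baseline. Probabilities are clamped at $10^{-12}$ in the likelihood so
deterministic limits stay finite (clamped trial counts are reported in
the fit diagnostics).

## Subject-level inversion

`fit_learner()` maximises log-likelihood + log-prior in a transformed
space (log for variances and $\zeta$, logit for rates and initial
values, identity for the $\omega$'s) with BFGS from the prior mean plus
jittered restarts (default 10; jitter SD is the prior SD capped at 2).
The returned optimum is never worse than the prior mean. The Laplace
approximation supplies the log model evidence,

$$\mathrm{LME} = \log p(y \mid \hat\theta)\,p(\hat\theta)
  + \tfrac{d}{2}\log 2\pi - \tfrac12 \log \det H,$$

with $H$ the finite-difference Hessian of the negative log joint,
symmetrised and eigenvalue-floored at $10^{-8}$ when not positive
definite (repairs are flagged). The tests require exactness to
$10^{-8}$ on an analytic 1-parameter Gaussian case and invariance under
an affine reparameterisation with consistently transformed prior.

Priors are Gaussian in the transformed space with variance 4
("relatively uninformative" on these scales; configurable).
`elicit_priors()` optionally sets the perceptual prior means to the
least-surprise values for the actual design sequences — the values
under which an ideal observer is least surprised by its inputs — via a
coarse grid search; the acceptance computations use the documented
defaults so that all four candidates are treated symmetrically.

`parameter_recovery()` and `model_recovery()` close the loop: they
simulate agents with known parameters, re-fit, and report
true-vs-recovered correlations, bias, RMSE, the identifiability matrix,
and the confusion matrix of protected-exceedance winners.

## Population-level model comparison

`rfx_bms()` treats the generative model as a random effect with unknown
population frequencies $r$ under a Dirichlet prior ($\alpha_0 = 1$),
iterating subject responsibilities and Dirichlet concentrations to
convergence ($10^{-6}$). Exceedance probabilities use the exact Beta
comparison when $K = 2$ and seeded Monte-Carlo sampling (default
$10^5$ draws) otherwise; the two paths are cross-checked to 0.005 in
the tests. The Bayes omnibus risk compares the variational free energy
of the random-effects model against the equal-frequency null,
$\mathrm{BOR} = 1/(1+e^{F_1-F_0})$, and the protected exceedance
probability is $\mathrm{PXP}_k = \mathrm{EP}_k(1-\mathrm{BOR}) +
\mathrm{BOR}/K$. `family_bms()` collapses models onto families by the
log mean of member evidences (uniform within-family prior) before
running the same machinery — this is how the hierarchical-vs-associative
question is posed.

A consequence worth knowing: with a 20-subject synthetic cohort of
32-trial series, the family EP is routinely 1.0000 while the PXP sits
at 0.97–0.999, because the omnibus risk cannot fall to zero with that
much data — protection is doing exactly its job. Driving PXP to 1.00 at
two decimals takes either more subjects or longer series.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* the analysis
assumes, not the physics of the tasks:

* `gen_swi_design()` — 5 baseline lifts of the medium object, 32 test
  lifts (8 per object) in constrained pseudorandom orders (both heavy
  objects before any light one). Three fixed orders are regenerated
  deterministically from internal seeds; the content of the original
  laboratory orders is not public, so these are synthetic counterparts
  satisfying the same constraints.
* `gen_interception_design()` — exact 30/15 expected/unexpected counts;
  the stable condition's marginal probability is 30/45 and the volatile
  schedule draws block lengths from {6, 9, 12} summing to 45 with
  per-block predictiveness switching among {0.83, 0.67, 0.50}
  (consecutive blocks always differ) and per-block outcome counts
  adjusted to the exact totals. The original trial-by-trial schedule is
  not reconstructed.
* `synth_force_trace()` — a logistic force rise whose asymptote grows
  with the heaviness belief (closed-form peak rate $f_{\max}/4\tau$),
  500 samples/s. `synth_gaze_trace()` — a pursuit ramp into a
  pre-bounce fixation at the belief-driven pitch, 120 samples/s, with
  seeded tracking loss. Both are parametric kinematics sufficient to
  exercise the preprocessing operators; they contain no biomechanics,
  no saccade dynamics and no ball flight, so passing tests demonstrate
  correctness of the *pipeline*, not realism of the signals.

Agents sample $y^{(k)}$ from the response model applied to their own
belief trajectory, so simulated cohorts are exactly the generative
process the inversion assumes — recovery results on them are upper
bounds on what real data allow.

## Preprocessing conventions

* Grip force: zero-phase (forward–backward) 2nd-order 14 Hz Butterworth
  smoothing, then the five-point central-difference derivative (exact
  through degree-4 polynomials), then the pre-contact maximum = pGFR.
  The filter order is unstated in the source analyses; 2nd order
  matches the gaze filter and motor-control practice. Each trial's pGFR
  is baselined against the final baseline lift.
* Grip coding: inputs $u = 1$ iff size predicted weight (large∧heavy or
  small∧light), either veridically or from felt heaviness (z-scored
  ratings split at the subject median — the felt binarisation is this
  package's choice). Responses: per-subject pooled median split of
  baseline-corrected pGFR, `y = 1` iff above-median for large or
  at/below-median for small objects; exact-median ties fall in the low
  class for determinism.
* Gaze: three-frame median filter, zero-phase 2nd-order 15 Hz
  Butterworth, dispersion-based fixation detection (windows within 3°
  for ≥ 100 ms), pitch read out at the bounce moment. Trials with
  > 20 % missing samples or > 100 ms tracking loss are flagged invalid;
  values beyond 3.29 SD are outliers; subjects with > 15 % bad trials
  are excluded. Screening statistics are computed once from the full
  table, so the screen is idempotent.
* Gaze coding: the trial-to-trial pitch *change* is compared against
  ±1 SD of the within-condition changes (the SD-of-changes reading of
  an ambiguous rule; the SD-of-angles alternative is less sensitive to
  drift); smaller changes carry the previous response forward, and the
  first trial starts at the modal expectation `y = 1`.

## Group statistics

Student/Welch t-tests with pooled-SD Cohen's *d* (a variance-ratio
screen > 2 selects Welch in `"auto"` mode, with explicit overrides
because test variants are often chosen by inspection); a 2×2
between × within ANOVA via `aov()` error strata with
$\eta_p^2 = SS_e/(SS_e+SS_{err})$ (SS types coincide in this
balanced-within design); Friedman, Kruskal–Wallis and Mann–Whitney
(tie-corrected, with normal-approximation $z$ and rank-biserial
$r = 1 - 2U/n_1n_2$); Holm step-down correction.

`sensitivity_power()` uses the noncentral t for the two-sample design
(for groups of 29 and 26 at $\alpha = .05$ it returns a detectable
$d \approx 0.82$ at 85 % power and $d \approx 0.54$ at 50 %) and the
noncentral F for the 2×2 interaction. The interaction noncentrality
depends on a repeated-measures correlation never stated in the source
analyses; the default is $\rho = 0.5$ with
$\lambda = N f^2 m/(1-\rho)$, and a `"spss"` convention
($\lambda = N f^2$, correlation absorbed into $f$) is provided because
published sensitivity figures for this design are typically computed
that way.

## Numerical choices and problem sizes

Optimisation: BFGS, `reltol` $10^{-10}$, 500 iterations, 10 restarts
(fits are bit-reproducible given a seed). Likelihood clamping
$10^{-12}$; Hessian eigenvalue floor $10^{-8}$; BMS convergence
$10^{-6}$; Monte-Carlo EP $10^5$ draws. The shipped test-and-acceptance
workloads use cohorts of 12–20 subjects with 32–90 trials and 50
replicate pipeline runs of 6 + 6 subjects — sizes chosen so the full
battery completes in a few minutes on one core while leaving the
qualitative conclusions (family recovery, planted-direction group
effects, recovery correlations) stable across seeds.

## Known limitations

No continuous-response models (gaze could alternatively be modelled
with a continuous link); no hierarchical (empirical-Bayes) pooling
across subjects — fits are independent per subject × condition; inputs
must be binary-codable; the Laplace evidence inherits the usual
quadratic-approximation caveats for skewed posteriors; fixed-effects
model comparison is deliberately not offered as a headline method.
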