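---
title: "Models and methods in cbtmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cbtmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbtmech)
```

cbtmech implements the computational machinery for two-session randomized
experiments that probe cognitive mechanisms of brief psychotherapy
components: a reward-effort decision task paired with a behavioural
activation style intervention, and a causal attribution task paired with a
cognitive restructuring style intervention. This vignette documents the
models, the sampler, the synthetic-data generator and the design choices a
maintainer would want to know about.

## The reward-effort choice model

Each trial offers two options; option values are linear in the offered
reward (coins) and the required effort (fraction of the participant's
calibrated maximum press rate):

$$V = \mathrm{rewSens}\cdot \mathrm{reward} - \mathrm{effSens}\cdot \mathrm{effort},$$

and the probability of choosing the higher-reward option is
$\mathrm{logit}^{-1}(V_{hi}-V_{lo})$. Both sensitivities are sign-free. Per
participant, the session-1 and session-2 values of each sensitivity are
bivariate normal with free means, SDs and a cross-session correlation with a
uniform prior on $[-1,1]$; allocation to the active arm adds a group-level
effect $\phi_{INT}$ (standard-normal prior) to each parameter's session-2
mean. Subject parameters use the non-centred parameterization. Catch trials
(dominant offers used as attention checks) are excluded from the likelihood
by default because they carry no trade-off information and would otherwise
bias the sensitivities upward; `include_catch = TRUE` restores them.

Priors: group means are centred on zero with SD 2 (rewSens, reward gaps are
1-4 coins) and SD 5 (effSens, effort gaps are fractions below one), chosen so
prior-predictive choice rates span (0,1) without piling on the boundaries;
subject SDs are half-normal(1); $\phi_{INT} \sim N(0,1)$.

## The causal attribution model

Every scenario response is coded on two binary dimensions: internal vs
external and global vs specific. Each code is Bernoulli with probability
$\mathrm{logit}^{-1}(\theta)$ of its own latent tendency. Per valence
(negative/positive events), the four tendencies per subject (2 dimensions x
2 sessions) are multivariate normal with free means (prior $N(0,2)$), scales
(half-normal(1)) and a $4\times4$ LKJ(1) correlation, which reduces to the
uniform-correlation prior in the bivariate case. Intervention effects enter
session-2 means per dimension and valence, as in the choice model. The
latent-to-probability link is logistic: the generative description uses a
Bernoulli on an unbounded trait, and the logit link is the reconciliation
that keeps the trait scale of the MVN meaningful.

Because the linear predictor is constant within a subject x valence x
dimension x session cell, per-cell success counts are sufficient; the
sampler works on counts, which is exact and fast.

## Joint symptom-trait moderation

Ordinal symptom items load on one of two latent traits: behavioural
amotivation (six AMI behavioural items plus the two PHQ9 items indexing
anhedonia and fatigue) and negative cognition (eight DAS short-form items
plus the two PHQ9 items indexing depressed mood and failure). Items follow a
graded response model: $P(y \ge k) = \mathrm{logit}^{-1}(a_j\theta -
\kappa_{jk})$ with $\theta \sim N(0,1)$ and $a_j > 0$ for identification
($a_j$ is sampled on the log scale with a standard-normal prior; thresholds
have $N(0,2)$ priors under an increasing transform).

In the joint model the traits shift the moderated target parameter at
baseline ($\beta_{BASE}$, both arms) and scale the intervention effect in
the active arm at session 2 ($\beta_{INT}$); the group effect $\phi_{INT}$
is then the intercept of that regression. $\beta_{INT}$ is applied only in
the active branch, exactly as the moderation model is written; whether it
should also touch control-arm session-2 parameters is a sensitivity analysis
we deliberately leave out. Default targets are `effSens` for choice data and
`internal_pos` for attribution data, both configurable. A two-step
diagnostic mode fits the GRM alone and plugs posterior-mean traits into the
behavioural model; it understates trait uncertainty and is not the default.

## Sampling

Fits use an adaptive Metropolis-within-Gibbs sampler written in C++:
scalar random-walk updates with Robbins-Monro step adaptation toward 0.44
acceptance during warm-up (frozen afterwards, so kept draws form a valid
chain), plus three structural moves that the posterior geometry demands:

* a centred interweaving step (group means, scales, correlations and
  moderation weights are re-sampled against the Gaussian density of the
  *fixed* subject values, then offsets are back-transformed), which
  decouples hierarchical scales from offsets;
* an arm-decoupling move that shifts the session-2 group mean and
  $\phi_{INT}$ in opposite directions, touching only the control arm's
  likelihood;
* per-subject "soft-mode" moves for the choice model that translate a
  subject's reward and effort offsets jointly along the
  $(\overline{\Delta r}, \overline{\Delta e})$ ridge the offer structure
  induces.

The published sampler configuration (four chains of 2000 iterations, 1000
warm-up) is the `"paper"` profile of `mcmc_control()`; the `"test"` profile
(two chains of 500/250) is for quick checks. Convergence is gated at
rank-normalized split R-hat <= 1.05 on group-level parameters; fits beyond
the gate warn and carry `converged = FALSE` rather than failing silently.

Correctness of the whole simulate-fit loop is established by
simulation-based calibration (the `sbc_*` functions): ground truth drawn
from the priors, data simulated, the model refitted, and the rank of each
true value within thinned posterior draws tested for uniformity
(chi-square over equal bins plus a DKW ECDF envelope). Draws are thinned
(default every 4th; the model adapters use 6) because MCMC autocorrelation
otherwise clumps ranks; refits whose group-level R-hat exceeds 1.2 are
excluded with a recorded count. A deliberately biased adapter (posterior
shifted by one SD) is the built-in negative control and is firmly rejected.

## The synthetic cohort generator

The generator is the package's replacement for raw participant data. It
emulates: two sessions per subject, deterministic interleaved 1:1
allocation, MVN-correlated subject parameters across sessions, an additive
group-level intervention shift at session 2 in the active arm, catch trials,
lognormal response times and uniform option positions (so the exclusion
rules are exercisable in both directions), optional standard-normal traits
that moderate a target parameter, and GRM-distributed item responses.

Two generator choices deserve emphasis because the study conditions they set
are what every calibration result in this package is conditional on.

**Offer structure.** Offers are nondominated (the higher reward always
costs strictly more effort; catch trials invert this). A Fisher-information
analysis of the Bernoulli-logit model shows that if reward and effort gaps
are drawn independently from uniform grids they are nearly collinear as
regressors (both strictly positive, little spread), and the joint
per-session variance of an effort-sensitivity estimate is bounded near 1.5 -
far too noisy for the group-effect precision this design demonstrably
reaches. The default generator therefore mixes two probe types: 75% effort
probes (reward gap one coin, efforts contrasting the extremes of the
calibrated range) and 25% reward probes (reward gap 3-4 coins, adjacent
effort levels). That is the "optimised for reliable parameter detection"
regime a short trade-off task must occupy, made explicit.

**Population regime.** Defaults: rewSens mean 0.35 (SD 0.10, cross-session
R 0.85) and effSens mean 0.7 (SD 0.5, R 0.9); attribution tendencies have
unit SDs, a self-serving mean asymmetry (internal-positive +0.8,
internal-negative -0.5), within-session dimension correlation 0.4 and
cross-session correlation 0.7. Under these conditions a cohort of 100 gives
the intervention effect on effort sensitivity a posterior SE near 0.15 and
subject-level recovery correlations near 0.75, the same uncertainty regime
reported for the deployed tasks. These are choices, fixed once; they are
not re-tuned per analysis.

What the generator does **not** emulate: choice autocorrelation, fatigue and
learning drifts within a session, block-level subjective ratings,
response-time dependence on decision difficulty, item-level residual
correlations, and missingness. Passing tests therefore demonstrate that the
estimators are calibrated and powerful *under the stated generative model*,
not that real cohorts behave this way. One visible consequence: the
synthetic regime keeps choices stochastic in order to identify parameters,
so posterior predictive accuracy (~0.55) and pseudo-R2 (~0.1) run below the
values observed in real cohorts, where behaviour is more deterministic.

## Downstream analyses

* **Test-retest reliability** refits the two-session hierarchical model
  without an intervention term and reports the posterior of the
  cross-session correlation - a uniform prior on $[-1,1]$, so the posterior
  is data-driven and properly widened by subject-level measurement error.
* **Fit metrics**: posterior predictive accuracy (stochastic replication
  from posterior-mean subject parameters by default, draws-resampling
  optional; attribution data scored as separate internal and global
  streams) and pseudo-$R^2 = 1 - L/C$ with $C = t\log(1/2)$. $L$ uses
  posterior-mean subject parameters by default; a draws-averaged variant is
  available.
* **Heterogeneity of treatment effects**: per-subject change scores in
  posterior means, standardised by the pooled baseline SD (per-arm
  standardisation optional), then
  $SD_{IR} = \sqrt{SD_{Act}^2 - SD_{Con}^2}$ with
  $SE = \sqrt{2(SD_{Act}^4/DF_{Act} + SD_{Con}^4/DF_{Con})}$, a symmetric
  95% CI, and the 0.1/0.3/0.6 thresholds for small/moderate/large
  individual response heterogeneity. A negative variance difference clamps
  to zero with a flag (variances cannot be negative); the signed root is
  available for diagnostics.
* **Power**: the between-within interaction of a two-group
  repeated-measures ANOVA via the noncentral F distribution with
  $f = d/2$, $\lambda = f^2 N m/(1-\rho)$, $df_1 = (g-1)(m-1)$,
  $df_2 = (N-g)(m-1)$ - the convention of the standard power software for
  this test, verified in the suite against simulated rejection rates.

## Numerical notes and problem sizes

Logistic likelihoods use `log1p`-stable forms; GRM category probabilities
are floored at `1e-300` before logging; correlation Cholesky factors floor
pivots at `1e-12`. Ties in SBC ranks are broken by uniform randomisation.
The test suite runs reduced but honest problem sizes chosen to finish a full
run in well under half an hour: recovery protocols use 10 cohorts of 100
(choice) or 200 (attribution) subjects with two chains of 1100-1600
iterations, SBC uses 200 prior-predictive datasets of 20 subjects with short
chains, and the paper-scale sampler profile remains available through
`mcmc_control(profile = "paper")`.

## Known limitations

* The samplers are single-machine and sequential; paper-scale SBC (1000
  datasets, 2000 draws) is hours of compute.
* The GRM infers the number of categories per item from the observed
  maximum; items whose top category is never used are treated as having the
  observed range.
* Reliability and HTE analyses operate on posterior summaries of one fit;
  fully draws-propagated change scores are out of scope.
* The crossover-study configuration is expressed by relabelling arms
  (active = one component, control = the comparison component); no
  factorial structure is modelled.
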