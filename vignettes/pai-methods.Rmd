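---
title: "Model-based treatment allocation in two-arm trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based treatment allocation in two-arm trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairct)
```

## The problem

In a two-arm randomized trial each patient is observed under one
treatment only, yet the clinically interesting question is
counterfactual: which of the two treatments would have left *this*
patient better off? `pairct` implements a complete answer pipeline for
trials of depression treatments scored on the PHQ-9 (0–27 points,
lower is better): arm-specific outcome models selected by Bayesian
model averaging (BMA), leave-one-out factual and counterfactual
predictions, and the Personalized Advantage Index (PAI) — the absolute
difference between a patient's two predicted outcomes, with the arm
achieving the lower prediction labelled that patient's *optimal*
treatment.

Because patient-level trial data of this kind are rarely shareable,
the package ships a synthetic-trial generator with known ground truth,
so every stage of the pipeline is testable end to end: the generating
coefficients fix each patient's expected outcome under *both* arms,
hence a true optimal arm and a true PAI against which the estimates
can be scored.

## Outcome model and prior

Within one arm, the 12-week severity score $y$ is modelled as Gaussian
linear in an unknown subset $\gamma$ of the encoded baseline
covariates:

$$ y = \alpha_0 + X_\gamma \beta_\gamma + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma^2 I). $$

Rather than committing to one subset, BMA scores *all* subsets. Under
Zellner's $g$-prior on $\beta_\gamma$ (with flat priors on intercept
and $\log\sigma$, and $y$ and the columns of $X$ centered), the Bayes
factor of model $\gamma$ against the intercept-only null is available
in closed form:

$$ \operatorname{BF}(\gamma \mid g) =
   (1+g)^{(n-1-p_\gamma)/2}
   \left\{1+g\,(1-R_\gamma^2)\right\}^{-(n-1)/2}, $$

where $p_\gamma$ is the model size and $R^2_\gamma$ its coefficient of
determination (`log_bf_given_g()`). The Zellner–Siow prior replaces
the fixed $g$ by the mixing density
$g \sim \text{Inverse-Gamma}(1/2,\; n\alpha/2)$ — equivalent to a
Cauchy prior on the standardized coefficients — and the marginal Bayes
factor is the one-dimensional integral of the closed form over that
density. The scale multiplier $\alpha$ defaults to 1, the conventional
calibration. Posterior model probabilities are proportional to
marginal likelihood times model prior (uniform by default;
Beta-Binomial(1,1) available), and a covariate's posterior inclusion
probability (PIP) is the total posterior mass of models containing it.

### Evaluating the integral

`log_marginal_zs()` evaluates the mixture integral on the $t=\log g$
scale. The default evaluator is a Laplace approximation whose mode is
found by safeguarded Newton iteration on the analytic score and whose
leading Gaussian term is multiplied by the standard second-order
(skew/kurtosis) correction built from the analytic third and fourth
derivatives. The correction matters: the integrand is markedly skewed
when few predictors are included, and the plain second-derivative
Laplace term alone is off by roughly 0.08 log units at $p_\gamma = 1$
— larger than differences between competing models can be. With the
correction the error against adaptive quadrature is about $10^{-3}$
log units across $n \in [30, 300]$, $p_\gamma \in [1, 15]$,
$R^2 \in [0, 0.8]$. The quadrature evaluator
(`method = "quadrature"`) is retained as an independent oracle and is
what the test suite compares against. The null model short-circuits to
exactly 0 on the log scale.

## Exploring the model space

With $p$ encoded columns the space holds $2^p$ models.
`enumerate_models()` scores all of them (default limit $p \le 20$)
from precomputed centered cross-products — one Cholesky solve per
model. Beyond that, `mcmc_bas()` runs the two-phase hybrid:

1. **Exploration.** A Metropolis–Hastings chain over inclusion
   vectors (flip one uniformly chosen bit with probability 0.9,
   otherwise swap an included/excluded pair), targeting posterior mass.
   Every distinct model encountered is scored once and cached; chain
   visit frequencies give provisional inclusion estimates. The phase
   ends after the configured iterations or once half the model budget
   is spent.
2. **Sampling without replacement.** Further distinct models are drawn
   column-wise Bernoulli with probabilities equal to the current
   inclusion estimates, clamped to $[0.025, 0.975]$ so that no
   column's fate is frozen; already-scored models are skipped, and the
   estimates are refreshed from the renormalized posterior every 500
   new models. When duplicates dominate — the unscored remainder of
   the space carries little proposal mass — the sampling probabilities
   are progressively flattened toward $1/2$, and persistent starvation
   ends the run early with a note.

Final PIPs and model probabilities renormalize
$\exp(\text{log marginal}) \times \text{prior}$ over all unique scored
models. If the budget (default 30,000 models) covers the whole space,
the entire space is scored and the result is *identical* to
enumeration — the test suite asserts this bitwise. Models with
$p_\gamma \ge n-1$ are unidentifiable and get zero posterior mass.
Reported Bayes factors in the five-best-model table are renormalized
so the top model's factor is 1.

## From models to allocations

`select_predictors()` turns a per-arm BMA fit into a fixed predictor
set, by default the highest-posterior model (HPM). The
median-probability model (all PIPs > 0.5) is available, but HPM is the
default because the two rules genuinely disagree under correlated
predictors and the HPM matches the "single best model" reporting
convention of PAI studies — a borderline PIP near 0.5 can sit inside
the best model or outside it. Both selections are logged with their
PIPs.

`loo_predictions()` then produces, for every patient:

* a **factual** prediction — ordinary least squares (intercept + the
  received arm's selected predictors) fit on the received arm *minus
  that patient*, evaluated at the patient's covariates (jackknife,
  so a patient's own outcome never leaks into their prediction);
* a **counterfactual** prediction — OLS with the other arm's selected
  predictors fit on the *entire* other arm, which never contains the
  patient.

PAI = |factual − counterfactual|; the arm with the smaller prediction
is optimal. `summarize_pai()` reports the mean PAI, the fraction at or
above the clinically meaningful threshold (5 PHQ-9 points by default),
observed-outcome means split by whether the received arm was the
predicted-optimal one, and the mean absolute factual-prediction error.

Deliberate choices here, where reasonable analyses could differ:

* predictor sets are selected **once** on the full per-arm samples and
  held fixed across folds — refitting but not reselecting per fold.
  This mirrors the two-regression-models convention and is a known
  optimism source, since selection has seen every outcome;
* prediction is plain OLS on the original scale; BMA is used for
  *selection* only, not model-averaged prediction;
* predictions are raw linear predictors, not clipped to 0–27
  (`clip_predictions = TRUE` clips, which slightly changes the error
  summary at the scale edges);
* an exact tie (PAI = 0) counts the patient as having received the
  optimal treatment;
* an empty median-probability selection falls back to intercept-only
  with a warning and an explicit flag;
* within a fold, a constant predictor column is dropped for that fit
  and a singular design falls back to the minimum-norm solution, each
  with a warning.

A best-model criterion based on the Bayesian information criterion is
deliberately not offered: model ranking is by posterior probability
throughout, which under this prior already encodes the
dimensionality penalty.

## Filtering and imputation

`filter_completers()` keeps patients with an observed 12-week outcome
(the outcome is never imputed). `screen_missingness()` then drops
covariates missing for at least half of the completer cohort — the
strict "<50% acceptable" rule, computed after completer filtering;
the order is configurable but completer-first is the default since
the downstream model set is defined on completers. Both operations are
idempotent and preserve row order.

`missforest_impute()` fills the remaining gaps with the iterative
random-forest scheme: initialize missing cells with column mean/mode;
sweep variables in ascending order of missingness, each regressed by a
random forest (100 trees, default feature subsampling, `ranger`
engine) on all other covariates using its originally observed rows;
stop when the difference between successive imputed matrices increases
for both the continuous part (normalized squared difference) and the
categorical part (disagreement proportion), returning the previous
iterate. The treatment-arm label participates as a predictor feature
by default (imputation is pooled across arms; switchable). Observed
cells are never altered, imputed categories are always observed
levels, and a fixed seed makes the whole sweep reproducible. Imputed
count variables are continuous forest predictions, not rounded.

## The synthetic-trial generator

`generate_trial()` draws baseline covariates per a declared schema
(Gaussian, Poisson, binary, multi-level nominal), assigns arms by 1:1
block randomization, and computes each patient's expected outcome
under both arms from arm-specific linear models before adding
Gaussian noise and clipping/rounding the observed outcome to the 0–27
integer scale. Missingness is injected per covariate after the truth
record is computed (completely at random by default; a
missing-at-random hook makes the missingness probability logistic in a
designated covariate), and a small fraction of outcomes is set missing
to emulate dropout.

Generator-level design decisions:

* block sizes are restricted to the even values {8, 10, 12, 14} so the
  1:1 ratio is exact inside every full block; a single (possibly
  smaller) final block absorbs the remainder, so arm totals differ by
  at most one incomplete block;
* the truth record stays on the unclipped continuous scale while the
  observed outcome is an integer in [0, 27] — a documented, testable
  divergence at the scale edges;
* one integer seed drives covariates, allocation, noise, masks and
  dropout through a single generator stream.

Four presets define the study conditions. `ecompared_like` mimics a
secondary-care blended-treatment trial table: n = 251 with roughly
2.4% outcome dropout (six patients), 28 candidate predictors spanning
sociodemographics (including 4-level country and 5-level
marital-status nominals), symptomatology and quality of life,
healthcare-utilization counts and patient expectancy, with per-item
missingness between 1.2% and 40.8%; effects are prognostic (baseline
severity, expectancy) in both arms with differing utilization and
quality-of-life effects between arms, residual noise 5 points.
`prescriptive` is the recovery benchmark fixed at n = 500 and noise 4:
one binary covariate carries +4/−4 point arm-specific effects against
an arm intercept gap of −4, so the arm contrast is $-4 + 8x$ — the
optimal arm flips with $x$ and every patient's true PAI is exactly
4 points, a convenient sharp target. `null` (and the richer
`prognostic_only`) have identical outcome models in both arms — any
estimated advantage is pure noise, which is what a calibrated pipeline
should report as such.

What the generator does *not* emulate: between-covariate correlation
(covariates are drawn independently), item-level questionnaire
structure, longitudinal trajectories, and informative dropout. Passing
tests therefore demonstrate the pipeline's correctness and calibration
under known conditions — not that real trial data satisfy the
generator's independence assumptions. In particular, forest imputation
only outperforms mean imputation where covariates are mutually
informative, which the tests exercise on explicitly correlated tables.

## Problem sizes and reproducibility

The test suite checks the Laplace evaluator against quadrature on a
27-point grid; sampler-versus-enumeration agreement at n = 245 with
p = 15 under the full 30,000-model budget (and bitwise equality at
p = 10 where the budget covers the space); the jackknife against an
independent normal-equations refit on a 30-patient fixture; recovery
of the prescriptive benchmark over 10 generator seeds (mean PAI within
20% of truth, allocation agreement at least 80%); calibration on 20
null-scenario replicates (sign test on optimal-versus-suboptimal
observed means, large-PAI fraction below 10%); forest-versus-mean
imputation on 20 masked replicates of 150-patient correlated tables;
and byte-identical reports from repeated runs at the trial-sized
scenario. These sizes were chosen to exercise each property at the
scale the design targets while keeping a full run comfortably
interactive.

Every stochastic stage (generation, imputation forests, the model-space
sampler) is governed by one master seed from which stage seeds are
derived, and the pipeline's `report.json` is a pure function of the
input table and that seed.

## Known limitations

* Selection and evaluation share the same sample; the leave-one-out
  scheme removes per-patient outcome leakage from *fitting* but not
  from *selection*, so PAI magnitudes retain optimism. Prospective
  validation is outside the package's scope.
* The Gaussian linear outcome model ignores the bounded integer nature
  of the score except through optional clipping.
* Inclusion probabilities from a partial sampler run are renormalized
  over the scored subspace; with very small budgets they can be biased
  toward the explored region (the exploration phase mitigates, and the
  budget default makes this negligible at trial-like p).
* The imputation stopping rule follows the canonical
  difference-increase criterion; it bounds iterations in practice but
  carries no optimality guarantee.
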