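---
title: "Methods: the HSROC model and its summary points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HSROC model and its summary points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsrocpoint)
```

## The problem

Meta-analyses of diagnostic test accuracy (DTA) pool per-study 2x2
tables — true positives (TP), false negatives (FN), false positives
(FP), true negatives (TN) — across primary studies. When the studies use
different positivity thresholds, pooled sensitivity and specificity from
a bivariate model are uninterpretable; the hierarchical summary ROC
(HSROC) model of Rutter and Gatsonis is the standard alternative. Its
natural output is a summary ROC *curve*, but guideline workflows (GRADE
summary-of-findings tables) need a summary *point*: the estimate and 95%
credible interval of sensitivity at a clinically chosen fixed
specificity, or vice versa. This package computes exactly that quantity,
plus the diagnostics needed to trust it.

## Model

For study $i$, with $n_{1i} = TP_i + FN_i$ diseased and
$n_{0i} = FP_i + TN_i$ non-diseased subjects,

$$TP_i \sim \mathrm{Bin}(n_{1i}, \pi_{1i}), \qquad
  FP_i \sim \mathrm{Bin}(n_{0i}, \pi_{0i}),$$

$$\mathrm{logit}(\pi_{1i}) = (\theta_i + \alpha_i/2)\,e^{-\beta/2},
  \qquad
  \mathrm{logit}(\pi_{0i}) = (\theta_i - \alpha_i/2)\,e^{+\beta/2},$$

where $\theta_i$ is the study's cut-point (positivity threshold) on the
latent logistic scale, $\alpha_i$ its accuracy (the log diagnostic odds
ratio when $\beta = 0$), and $\beta$ a scale parameter governing the
asymmetry of the summary curve. The disease-group coding $X = \pm 1/2$
is the fixed model convention. Across studies,

$$\theta_i \sim N(\Theta, \sigma_\theta^2), \qquad
  \alpha_i \sim N(\Lambda, \sigma_\alpha^2).$$

Study $i$'s sensitivity is $\pi_{1i}$ and its specificity $1-\pi_{0i}$;
the summary curve implied by the hyper-means is

$$\mathrm{logit}(\mathrm{sens}) = \Lambda\,e^{-\beta/2}
  + e^{-\beta}\,\mathrm{logit}(1-\mathrm{spec}),$$

which `sens_at_spec()` evaluates and `spec_at_sens()` inverts exactly.

### The summary point

Fixing specificity at $s_0$, each retained posterior state contributes
one draw of the summary sensitivity by plugging that state's $\Lambda$
and $\beta$ into the curve; the posterior mean and the 2.5%/97.5%
pooled quantiles of those draws are the headline output (monitored as
`other_snsp[max]`). Per-study analogues `other_snsp[i]` substitute
$\alpha_i$ for $\Lambda$. Two points are deliberate:

* **Mean of transform, not transform of means.** The estimate is the
  posterior mean of the transformed draws, which differs from plugging
  posterior means into the curve (the transform is nonlinear). Both
  conventions exist; the draw-wise one propagates uncertainty correctly
  and is what the package reports.
* **Hyper-mean, not predictive.** `other_snsp[max]` uses $\Lambda$
  itself rather than a predictive draw
  $\alpha_{new} \sim N(\Lambda, \sigma_\alpha^2)$: it describes the
  average study, and its posterior SD is, to first order by the delta
  method, $|\partial\,\mathrm{invlogit}/\partial x| \cdot
  e^{-\beta/2}\,\mathrm{sd}(\Lambda)$ — a predictive definition would
  add the full between-study variance and give a far wider interval.

## Priors

Non-informative by default: improper flat priors on $\Theta$, $\Lambda$
and $\beta$, and Uniform$(0, \infty)$ on $\sigma_\theta$ and
$\sigma_\alpha$. With at least two studies the posterior is proper (the
flat-SD prior induces a proper inverse-gamma conditional on each
variance once $n \ge 2$). `prior_config()` can truncate both families
(`sd_upper`, `hypermean_halfwidth`) for users who want hard bounds; with
the nine-study example the posterior is data-dominated and truncation at
any sane width is immaterial. The occasionally seen phrase "uniform
priors on probabilities" is interpreted here as a statement of bounded
support for the derived probability quantities — they are deterministic
transforms of $(\theta_i, \alpha_i, \beta)$, so no extra prior factor is
applied.

## Sampling

`run_mcmc()` uses a blocked sampler chosen so every conditional update
is either exact or a well-mixing Metropolis step:

* **Per-study pairs** $(\theta_i, \alpha_i)$: joint Gaussian random-walk
  Metropolis. Given the hyper-parameters the studies are conditionally
  independent, so all pairs update in one vectorised sweep with
  per-study proposal scales.
* **$\beta$, move 1**: scalar random walk against the full likelihood.
* **$\beta$, move 2 (ridge move)**: $\beta$ is strongly correlated with
  the study parameters because the likelihood constrains the two
  within-study logits, not $\beta$ alone. The second move proposes
  $\beta'$ together with the deterministic rescaling that keeps every
  study's logits — hence the entire likelihood — exactly fixed: in
  coordinates $u_i = \theta_i + \alpha_i/2$, $v_i = \theta_i -
  \alpha_i/2$ the map is $u_i \to c\,u_i$, $v_i \to v_i/c$ with
  $c = e^{(\beta'-\beta)/2}$, whose Jacobian is 1. The acceptance ratio
  then involves only the hierarchical normal terms. This move travels
  along the likelihood ridge and is what makes $\beta$ (and with it
  $\Theta$) mix at the default chain lengths.
* **Hyper-means**: exact Gibbs draws from truncated normals.
* **Hyper-variances**: exact Gibbs draws from the inverse-gamma
  conditionals implied by the flat-on-$\sigma$ prior, truncated through
  the inverse CDF when `sd_upper` is finite.

Proposal scales adapt during warmup by a Robbins-Monro recursion
targeting 35% acceptance and freeze afterwards, so the retained chain is
a valid time-homogeneous Markov chain.

**Configuration.** The defaults are 4 chains x 1000 iterations, 500
warmup, thin 1 — 2000 retained draws. `refine` (default 5) internally
multiplies iterations and thinning by the same factor, leaving the
retained-draw arithmetic untouched while cutting autocorrelation; with
it, the effective sample sizes of all monitored quantities at the
default configuration are comparable to what a NUTS sampler achieves on
this model, at about two seconds for the nine-study example.

**Initialization.** Each chain starts from the continuity-corrected
empirical logits (0.5 added to every cell, used *only* here — the
likelihood itself never applies a correction), with hyper-parameters at
their empirical moments and $\beta = 0$; chains after the first are
jittered (SD 0.5 on location components, 0.25 on log-SDs) so they start
overdispersed, and initialization retries with fresh jitter until the
log-posterior is finite. All randomness flows from the single `seed`, so
runs are exactly reproducible.

**Degenerate and collapsed cases.** A state with $\sigma = 0$ has a
degenerate hierarchy and log-posterior $-\infty$; the sampler never
proposes it (variance draws are almost surely positive). For testing,
`fix = list(beta = 0, s_theta = 0, s_alpha = 0)` collapses the model to
two pooled binomials in $(\Theta, \Lambda)$, which the test suite checks
against a two-dimensional grid-quadrature oracle.

## Diagnostics

`summarize_draws()` reports, per monitored quantity: pooled mean, SD,
type-7 interpolated quantiles (2.5/25/50/75/97.5%), split R-hat,
effective sample size, and `se_mean = sd / sqrt(n_eff)`. Split R-hat
halves each chain before the classic between/within comparison, so
within-chain drift is detected. ESS uses chain-averaged autocovariances
combined with the between-chain variance and Geyer's initial monotone
truncation; rank-normalised variants are out of scope. The quantile type
and estimator vintage were chosen to match the long-standing defaults of
the major MCMC software of the era; differences among quantile types
are far below Monte-Carlo noise at 2000 draws. Constant draws give
`NaN` R-hat/ESS: such rows are excluded from the convergence maximum
with a warning. `check_convergence()` applies the usage rule — interpret
nothing unless every finite split R-hat, in particular
`other_snsp[max]`'s, is at or below 1.1 — and the pipeline refuses to
print a summary point without that verdict, exits nonzero, and warns
when the rule fails.

## Data handling choices

Headers are matched case-insensitively in any order; exactly the five
columns `study_name, TP, FN, FP, TN` must be present — extra columns are
rejected rather than ignored so a silently shifted file cannot parse.
Counts like `90.0` are accepted (coerced), `90.5` is an error naming row
and field. Blank lines and standard CSV quoting are tolerated. In
space-delimited files any run of spaces is one separator, so study names
must not contain spaces there. Zero cells are legal (exact binomial
likelihood) but flagged, as is a dataset with fewer than five studies;
fewer than two is an error because the between-study SDs are then
unidentifiable.

## What the simulator does and does not emulate

`simulate_dataset()` draws study parameters from the hyper-normals and
counts from the binomials — exactly the generative model, with equal
group sizes across studies. It does not emulate unequal or correlated
group sizes, publication bias, threshold-to-accuracy correlation beyond
the model's, or covariate effects. Passing recovery tests therefore
demonstrates correctness of the fitting machinery under the model's own
assumptions, not robustness to their violation.

## Problem sizes used by the test suite

Chosen as the smallest sizes at which each property is sharply testable:
the worked nine-study example at the full default configuration for the
reproduction checks; 25 studies with 500 subjects per group over four
replicate simulations for hyper-parameter coverage (20 nominal-95%
intervals, at least 16 required to cover); 4 chains of 500-2000 draws
for the diagnostic calibration checks, with the AR(1) effective-sample-
size comparison averaged over five replicate chain sets because the
estimator itself is noisy at autocorrelation 0.9.

## Limitations

No covariate extensions, no bivariate (sensitivity/specificity
random-effects) model, and no SROC curve drawing — the package computes
summary points, not the curve. The fixed value is a single scalar per
run. GRADE certainty judgments are human work: `sof_row()` renders only
the quantitative row. And as with any MCMC tool, estimates from
unconverged chains are meaningless; the convergence verdict is attached
to every output for that reason.
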