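---
title: "Signal detection analysis of urgent referral decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection analysis of urgent referral decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refersdt)
```

## The decision problem

UK general practitioners can refer a patient urgently (the two-week-wait
pathway) when they suspect cancer; national guidance sets the referral
threshold at an estimated cancer risk of 3%. In a vignette study of this
decision, each responder sees a series of brief patient descriptions, half
with risk above 3% ("positive" cases, where urgent referral is the
guideline-concordant response) and half below ("negative" cases), and chooses
to refer urgently, refer routinely, or not refer. Signal detection theory
separates two aspects of this behavior that raw referral rates conflate: how
well a responder *discriminates* patients above the threshold from those
below it, and how much evidence they demand before referring (*response
bias*).

`refersdt` implements the full analysis pipeline for such a study —
including a synthetic-data generator that reproduces its statistical
structure, so every stage can be exercised and tested without clinical data.

## The equal-variance Gaussian model

For the analysis, decisions are dichotomized: urgent referral versus no
urgent referral (routine referrals and non-referrals collapsed). For
responder $i$, with hit rate $H_i$ (urgent referrals among positive cases)
and false-alarm rate $FA_i$ (urgent referrals among negative cases):

$$ d'_i = z(H_i) - z(FA_i), \qquad
   c_i = -\tfrac{1}{2}\left[z(H_i) + z(FA_i)\right], $$

where $z$ is the standard normal quantile function. $d'$ is the distance, in
SD units, between the evidence distributions of negative and positive cases;
$c$ is the placement of the decision threshold, with negative values lenient
(refer-prone) and positive values conservative.

Because $z$ diverges at 0 and 1, 0.5 is added to **all** response cells for
**all** responders before computing rates, giving
$H = (\text{hits} + 0.5)/(N_+ + 1)$ and similarly for $FA$. Applying the
correction uniformly, rather than only to boundary responders, avoids
introducing a selective bias; its cost is a mild shrinkage of all estimates
toward chance (about 0.05 on $d'$ with 24 + 24 trials), visible in the
package's recovery tests. Pooled sample-level rates are reported as raw
ratios, uncorrected, since they are arithmetic on the aggregate decision
table rather than per-responder estimates.

## Probit GLM formulation

The same quantities can be estimated without any correction by probit
regression on the trial-level binary decisions. With the vignette class
coded $s = +1/2$ (positive) and $-1/2$ (negative),

$$ \Pr(\text{urgent}) = \Phi\left(\beta_0 + \beta_1 s + \cdots\right), $$

the intercept estimates $-c$ and the signal slope estimates $d'$ at the
covariate reference; covariate main effects shift $-c$ and covariate
$\times$ signal interactions shift $d'$. The centered $\pm 1/2$ coding is
what makes this mapping exact — with 0/1 coding the intercept would mix the
two. `fit_probit_sdt()` implements this with three nesting options for the
repeated decisions per responder: plain fixed effects, a per-responder
random intercept (each responder their own criterion), or the default random
intercept plus random signal slope (their own criterion and $d'$), fitted
with `lme4::glmer`. The fixed-effects route is retained for small fixtures
and single responders, where it is the saturated model: its coefficients
reproduce the empirical probits $z(H) - z(FA)$ and $-\frac{1}{2}[z(H) +
z(FA)]$ on the *uncorrected* rates, a closed-form identity the test suite
checks to optimizer tolerance (the fixed-effects deviance tolerance is 1e-6
with at most 200 iterations).

The closed-form and GLM routes agree at the population level but not
exactly: unmodeled responder heterogeneity attenuates marginal probit
coefficients by $1/\sqrt{1 + \sigma^2}$, while the count correction shrinks
the closed-form indices. The comparability test therefore uses a design with
modest heterogeneity, where both distortions are small.

Complete separation (a covariate level with all-urgent or all-non-urgent
responses) is detected before fitting and raised as an error naming the
covariate rather than returning a divergent coefficient.

## Covariate analyses

`regress_index()` regresses a per-responder index on practice positive
predictive value (PPV, the percentage of a practice's urgent referrals that
convert to a cancer diagnosis), practice sensitivity (detection rate),
gender and experience, by OLS with analytic 95% CIs. Conventions: gender is
coded female = 1, so a negative coefficient on $c$ means women refer more
readily; PPV and sensitivity stay in percentage points and experience in
years, so coefficients are per-unit on natural scales; experience enters
continuously by default (a quartile option exists, off by default, since
categorization is only warranted when skew genuinely breaks linearity); no
multiple-testing adjustment is applied. `stability_correlation()` computes
Pearson correlations of an index across two tasks on the responders present
in both; `compare_groups()` is the pooled-variance Student t-test, whose
df = $n - 2$ convention matches reported group comparisons of this kind.

## Mediation and Monte Carlo power

`fit_mediation()` fits the three-regression single-mediator model (default:
gender → stress-from-uncertainty → criterion) on complete cases (listwise
deletion). The indirect effect is the product $ab$; its confidence interval
is a nonparametric percentile bootstrap (default 5000 resamples, seed 1234).
The percentile bootstrap is the field default for indirect effects because
the product of two normals is skewed; point estimates and the OLS identity
$\text{total} = \text{direct} + \text{indirect}$ are exact regardless of the
interval method. The proportion mediated is indirect/total, reported even
when sign-inconsistent (flagged) and undefined at a zero total effect.

`mc_power_indirect()` estimates power for the indirect effect: each
replication simulates $n$ trivariate-normal observations from a supplied
correlation matrix and SDs, fits the two path regressions by OLS, draws
(a, b) pairs from normal approximations to the coefficient sampling
distributions (20,000 draws by default), and rejects when the percentile
interval of the products excludes zero. Raw data are simulated per
replication, rather than drawing coefficients directly from a population
covariance, so sampling variability in the design enters the power estimate.
When the correlation matrix is not available directly,
`derive_power_inputs()` reconstructs it from printed summaries: a two-group
t statistic gives the point-biserial predictor–mediator correlation
$r = t/\sqrt{t^2 + df}$, regression slopes give outcome correlations via
$r = b\,\sigma_x/\sigma_y$, and the binary predictor's SD is
$\sqrt{p(1-p)}$ from the group sizes. `required_n_for_power()` bisects a
sample-size grid, re-using the same seed at every $n$ so the power curve it
walks is monotone up to Monte Carlo noise; with 5000 replications the Monte
Carlo SE of each power estimate is below 0.01, and the returned $n$ is
accurate to roughly the grid step plus that noise mapped through the power
curve's slope.

## The synthetic-data generator

`generate_study()` simulates the study structure end to end. Design choices,
in the package's own terms:

- **Generative decision model.** Urgent-referral probabilities are
  $\Phi(d'/2 - c)$ on positive and $\Phi(-d'/2 - c)$ on negative cases —
  the symmetric placement is the unique choice making `dprime()` and
  `criterion()` exact inverses of the generator at the population level
  (verified as a round-trip property test).
- **Defaults are the study conditions.** 252 responders × (24 + 24)
  vignettes; true $d' \sim N(0.79, 0.32)$; true criterion
  $c = \beta_0 + 0.05\,\mathrm{ppv} - 0.17\,\mathrm{female} + \varepsilon$
  with $\beta_0$ solved so the mean is −0.29 and residual SD 0.449 so the
  marginal SD of $c$ is ≈ 0.50 given the covariate spread; PPV uniform on
  [2, 16] points. These imply pooled rates near (0.74, 0.46) and an urgent
  share near 60%.
- **Routine vs. none.** The SDT model is binary, so routine referrals are
  generated conditionally on "not urgent" at the fixed share 1024/4820 of
  non-urgent decisions.
- **Vignette risks** are log-uniform on (3, 18.04]% for positive and
  [0.18, 3)% for negative cases — bounds from the observed risk range,
  log-uniform because risk estimates of this kind are right-skewed.
- **Stress scores**: male mean 26.65, female +3.76, SD 8.45, truncated to
  [8, 48] (an 8-item scale under assumed 6-point scoring — the truncation
  only affects tails), with 3 missing values assigned to women.
- **Experience** is truncated log-normal (meanlog = log 13, sdlog 0.8144,
  range [1, 42] years), targeting median 13 with quartiles near 8 and 24 and
  a positive skew.
- **Cross-task indices** (`generate_cross_task()`) are drawn conditionally
  on the empirically standardized first-task truth, criterion correlated at
  0.39 and $d'$ at 0, with a more conservative second-task mean (0.50,
  SD 0.75), emulating a prior task on a different cancer.

What the generator does *not* emulate: vignette-specific difficulty (all
positive cases are exchangeable given a responder's $d'$), order and
learning effects, non-normal responder heterogeneity, and any dependence of
stress on experience or PPV. Passing recovery tests therefore demonstrate
that the estimators are consistent with this generative model, not that real
referral data satisfy it.

One consequence worth noting: because estimated indices add binomial noise
(~0.39 SD on $d'$ from 48 trials) on top of the true spread, the *observed*
SD of $d'$ in synthetic cohorts exceeds the generating SD of 0.32. The
generating values are treated as the latent truth the estimators are asked
to recover, not as targets for the observed spread.

## Numerical and procedural choices

- Inverse-normal evaluation uses `qnorm`; tests compare it against an
  independent root-finding oracle at 1e-4 absolute over a 99 × 99 rate grid.
- Percentages in the decision table are reported to 2 decimal places of the
  grand total; medians use the midpoint convention for even $n$; SDs are
  sample SDs.
- Bootstrap and Monte Carlo procedures are bit-reproducible for a fixed
  seed; `run_analysis()` records the seed, an options hash and the package
  version in its report, and its CSV outputs are byte-identical across
  reruns with the same inputs.
- Degenerate inputs raise typed errors (`refersdt_*` condition classes):
  rates at 0/1 without correction, responders lacking a vignette class,
  separation in the GLM, constant mediator/outcome, non-positive-semidefinite
  correlation inputs, an unreachable power target.
- Problem sizes in the test suite are chosen to keep the full run at a few
  minutes while leaving Monte Carlo margins well clear of the assertion
  thresholds: 200 cohorts for regression recovery, 200 draws for stability
  recovery, 150 replicates × 400 resamples for bootstrap coverage, and the
  full 5000 × 20,000 setting for the headline power computation.

## Known limitations

- The equal-variance model is assumed throughout; unequal-variance SDT and
  nonparametric indices (A′, B″) are out of scope, as the underlying
  decisions are binary-ized single judgments.
- Mediation is a single-mediator OLS decomposition; no causal sensitivity
  analysis is provided.
- The mixed-effects probit nests responders only; vignettes are not crossed
  random effects.
- Reconstructing power-analysis inputs from printed summaries (rather than a
  raw covariance) propagates rounding of those summaries into the power
  estimate; the package treats the reconstruction as the documented default
  input and reports Monte Carlo uncertainty alongside the estimate.
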