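---
title: "Constructing short Likert scales with ant colony optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing short Likert scales with ant colony optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acoscale)
```

## The problem

Shortening a validated multi-factor questionnaire is a combinatorial
problem: choosing 5 of 13 items per factor of a two-factor pool leaves
$\binom{13}{5}^2 \approx 1.66$ million candidate short forms. Classical
strategies pick items one at a time by a single statistic (factor loading,
item-total correlation), which can distort the factor structure and overlook
good item *combinations*. `acoscale` instead searches the subset space with
an ant colony optimization (ACO) metaheuristic whose objective scores whole
subsets on several psychometric criteria simultaneously.

The package's running example is a decisional-balance instrument for
at-risk alcohol use: 13 "pros of drinking" and 13 "cons of drinking" items
answered on a 5-point importance scale, from which a 5 + 5 item short form
is to be selected, with selection restricted to each item's original factor.

## Measurement model

Responses are ordered categories, so all structural estimation runs on the
**polychoric correlation matrix**. Estimation is two-step maximum
likelihood: item thresholds are the standard-normal quantiles of the
observed cumulative category proportions, and each pairwise correlation
$\rho$ then maximizes the bivariate-normal contingency likelihood with
thresholds held fixed (bounded search on $[-0.999, 0.999]$, tolerance
$10^{-6}$). Rectangle probabilities use a Gauss–Legendre implementation of
the bivariate normal CDF accurate to ~$10^{-8}$ even at $|\rho| = 0.999$.
If the assembled matrix is not positive definite, eigenvalues are clipped
at $10^{-8}$ and the matrix rescaled to a unit diagonal; the
`smoothing_applied` attribute exposes this so callers can reject smoothed
input.

A candidate subset is evaluated by a simple-structure confirmatory factor
model: every item loads on exactly one factor, factor correlations are
free, and residual variances are fixed at $1-\lambda_i^2$ (standardized
correlation-structure parameterization). The discrepancy

$$F(S, \Sigma(\theta)) = \log|\Sigma| - \log|S| +
  \operatorname{tr}(S\Sigma^{-1}) - p, \qquad
  \Sigma(\theta) = \Lambda\Phi\Lambda' + \operatorname{diag}(1-\lambda^2)$$

is minimized by L-BFGS-B with an analytic gradient, loadings bounded in
$[-0.999, 0.999]$, starts $\lambda = 0.7$, $\phi = 0.5$, and up to three
jittered restarts. The test statistic is $T = (N-1)\hat F$; the baseline
(independence) model gives $T_b = -(N-1)\log|S|$. Fit indices follow

$$\mathrm{CFI} = 1 - \frac{\max(T - df, 0)}{\max(T_b - df_b,\; T - df,\; 0)},
\qquad
\mathrm{RMSEA} = \sqrt{\frac{\max(T - df, 0)}{df\,(N-1)}},$$

with CFI set to 1 when the denominator vanishes and to 0 in the degenerate
case of a baseline fitting better than the model. Model degrees of freedom
are $p(p-1)/2 - p - q$ with $q$ free factor correlations, which gives
298, 34 and 43 for 26-, 10- and 11-item two-factor models. Reliability is
McDonald's omega per factor,
$\omega = (\sum\lambda_i)^2 / ((\sum\lambda_i)^2 + \sum(1-\lambda_i^2))$.

This is deliberately *ML-on-polychoric* rather than full WLSMV: the
mean-and-variance-adjusted test statistic would require the asymptotic
covariance matrix of the polychoric estimates, and published RMSEA values
from WLSMV software are not reproducible from the printed $\chi^2$, df and
N under any unscaled formula anyway. Consequences: loadings, factor
correlations, omega and df are comparable with WLSMV results, while the
absolute magnitudes of $T$, CFI and RMSEA are not bit-compatible with a
scaled statistic. Candidate subsets are still ranked on a like-for-like
basis because every subset passes through the same estimator.

A loading reaching the $\pm 0.999$ bound is treated as a Heywood case; the
fit is flagged inadmissible and the subset receives zero pheromone —
conservative and deterministic, so an inadmissible solution can never win.

## The pheromone objective

Four criteria enter the objective through logistic ("sigmoid") transforms
centred next to conventional cut-offs, so each contributes a value in
$(0,1)$ that is ~0.5 at its cut-off and saturates as the criterion is
comfortably met or missed:

| component | formula | centre |
|---|---|---|
| $\varphi_{CFI}$  | $1/(1+e^{95-100\,\mathrm{CFI}})$ | CFI $= 0.95$ |
| $\varphi_{RMSEA}$ | $1 - 1/(1+e^{5-100\,\mathrm{RMSEA}})$ | RMSEA $= 0.05$ |
| $\varphi_{Fit}$ | $(\varphi_{CFI} + \varphi_{RMSEA})/2$ | — |
| $\varphi_{Rel}$ | $1/(1+e^{9-10\,\omega})$ | $\omega = 0.90$ |
| $\varphi_{Corr}$ | $1/(1+e^{85-100\,\mathrm{cor}})$ | cor $= 0.85$ |
| $\varphi_{Fc}$ | $1 - 1/(1+e^{3-100\,d})$ | $d = 0.03$ |

$\varphi_{Corr}$ uses the Pearson correlation between the short form's and
the full form's unit-weighted per-factor sum scores; $d$ in $\varphi_{Fc}$
is the largest absolute difference between the subset's and the full pool's
factor correlations, which anchors the short form's internal structure to
the original instrument. The total pheromone is the sum
$\varphi = \varphi_{Fit} + \varphi_{Rel} + \varphi_{Corr} + \varphi_{Fc}
\in (0, 4)$.

Two aggregation rules are not dictated by the formulas and were fixed as
package design choices: per-factor $\omega$ values are combined by the
arithmetic mean of their sigmoid values (symmetric with the equal weighting
inside $\varphi_{Fit}$), while sum-score correlations are combined by
applying the sigmoid to the *minimum* across factors, which makes the
"at least 0.85" requirement enforceable per subscale rather than on
average. `pheromone_components()` also accepts an optional extra
$(0,1)$-valued term, the hook for user-defined criteria such as
correlations with external variables.

## The search loop

Each of `n_ants` ants draws a subset: per factor, the quota is drawn
sequentially without replacement with probabilities proportional to the
per-item pheromone levels $\tau_i$ (initially equal, so the first
iteration is uniform). Distinct subsets within an iteration are evaluated
once (evaluations are memoized by sorted item set — ants resample heavily
once $\tau$ concentrates). After each iteration,

$$\tau_i \leftarrow e\,\tau_i\;\text{for all items}, \qquad
  \tau_i \leftarrow \tau_i + \varphi_{best}\ \text{for items in the
  iteration-best subset}, \qquad \tau_i \leftarrow \max(\tau_i, 10^{-6}),$$

where $e$ is the evaporation (retention) factor. The iteration-best-deposit
rule follows the classic ACO lineage and keeps the update $O(p)$; who
deposits is a genuinely open design point, and depositing from all ants
would merely smooth the same signal. Convergence is stagnation-based: the
run stops once the best-so-far value has not improved for `patience`
iterations (`patience = 0` therefore executes exactly one iteration). Ties
anywhere are broken toward the lexicographically smallest sorted item
tuple, and the best-so-far solution is replaced only on strict improvement,
making every run a deterministic function of its seed.

Defaults (60 ants, ≤ 50 iterations, evaporation 0.5, patience 15) sit in
the region where, for pools of this size, independent runs agree well:
more ants mainly reduce run-to-run variance beyond ~60, additional
iterations add little beyond the 30–90 range, and evaporation near 0.5
already yields homogeneous selections — slower evaporation only prolongs
runs.

Because separate runs can end in different optima, `run_aco_many()`
executes `n_runs` independent runs (run $r$ seeded `seed + r`) and two
final scales are derived:

* **ACO-P** — the best run's subset (highest pheromone overall);
* **ACO-C** — the consensus set of items selected in at least 60% of the
  runs' best solutions. This is a union rule: it may return unequal factor
  sizes (e.g. 5 + 6 items), and no re-balancing is applied.

`baseline_top_loadings()` provides the traditional comparator (per factor,
the quota items with the highest full-pool loadings), and
`comparison_report()` tabulates any set of candidate scales through the
identical evaluation pipeline.

## The synthetic generator

No public dataset accompanies the instrument, so `generate_responses()`
simulates from the measurement model itself: factor scores from
$N(0, \Phi)$, latent item responses
$y^*_i = \lambda_i f + \sqrt{1-\lambda_i^2}\,\varepsilon_i$, discretized by
per-item thresholds. Factor scores are drawn before item noise, items in
item-ID order, from one seeded generator, so output is reproducible per
seed and the global RNG stream is left untouched. `adbs_like_spec()`
reproduces the published full-pool structure of the German Alcohol
Decisional Balance Scale — 13 + 13 items, loadings 0.25–0.94 (mean 0.72),
factor correlation 0.56, N = 1834 — and `planted_optimum_spec()` builds
pools with a known high-loading optimum for oracle tests.

Default thresholds are equal-probability quintile cuts, which keeps
recovery tests clean; a `"skewed"` preset (cumulative probabilities 0.45,
0.70, 0.85, 0.95) mimics the right-skew typical of importance ratings,
whose exact form for the real items is unpublished. The generator emulates
the reported factor structure, not the real data: it assumes exact simple
structure, bivariate normal latents and homogeneous thresholds, and it
ignores the original pooling of three study samples. Passing recovery
tests therefore demonstrates internal consistency of estimator and
generator, not agreement with the restricted study data — which is also
why published $\chi^2$/CFI/RMSEA values are not reproduction targets while
df, omega-from-loadings and loading summaries are.

## Numerical choices and edge cases

* Polychoric $\rho$ clipped to $\pm 0.999$; identical columns therefore
  return 0.999, protecting the CFA from singular input.
* Degenerate items (fewer than two observed categories) are fatal, with
  the item named; boundary-empty categories yield infinite threshold
  sentinels and a warning at the threshold stage.
* Listwise deletion is the only missing-data treatment, mirroring
  complete-case analysis; it is idempotent and the dropped-row count is
  reported.
* Item IDs are opaque strings; every tie-break is lexicographic over item
  IDs; categories must be consecutive integers from 1.
* Factors reduced to two items are allowed with a warning when another
  factor anchors identification; one-item factors are rejected.

## Problem sizes used in the test suite

Closed-form checks run on the published loading solutions directly. The
search-optimality check uses a 6 + 6 pool with a 3 + 3 quota (400
candidate subsets, N = 500), where exhaustive enumeration through the same
evaluation pipeline is feasible and ACO recovers the global optimum in
≥ 18 of 20 seeded runs. Parameter recovery uses the 26-item ADBS-like pool
at N = 2000 over 10 seeds (loading RMSE ≤ 0.05, factor correlation within
± 0.05). Monte-Carlo consistency checks for single polychoric pairs use
N up to $10^5$. These sizes were chosen so each property is tested at the
scale where its expected behavior is unambiguous.

## Limitations

* The test statistic is unscaled ML-on-polychoric; CFI/RMSEA magnitudes
  differ from WLSMV software on the same data.
* The asymptotic covariance of polychoric estimates is not computed, so
  standard errors of loadings are unavailable.
* Consensus (ACO-C) scales may violate per-factor quotas by construction.
* The algorithm optimizes only the configured psychometric criteria;
  content validity of the selected items remains a judgment call outside
  the package's scope.
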