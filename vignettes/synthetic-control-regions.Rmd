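---
title: "Synthetic control regions: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic control regions: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthregion)
```

## The estimation problem

Hospital-level policies — a pay-for-performance scheme, a staffing mandate, a
reporting requirement — are typically switched on for every provider in one
administrative region at once. The evaluation panel then contains `K1`
treated units and `J` untreated donors observed over `T` periods, with the
policy active after period `T0`, and the question is the average treatment
effect on the treated (ATT) for an outcome such as risk-adjusted 30-day
mortality, in percentage points.

Difference-in-differences (DiD) identifies the ATT under parallel trends:
unobserved differences between the groups must have *time-constant* effects
on the outcome. The synthetic control method relaxes this. Writing the
treatment-free outcome as an interactive fixed-effects model

$$Y^N_{it} = \delta_t + \lambda_t' \mu_i + \theta_t' Z_i + \varepsilon_{it},$$

the loadings $\mu_i$ of unobserved unit factors enter with time-varying
coefficients $\lambda_t$. A convex donor combination that reproduces the
treated region's pre-treatment outcome path over enough periods must — if the
outcome is linear in observed and unobserved predictors — also match the
treated region in $\mu$ and $Z$, and therefore tracks the treatment-free
counterfactual even when $\lambda_t$ drifts.

## The aggregate estimator

Because a single treated unit is required, the treated units are aggregated
into a treated region with per-period patient counts $f_{it}$ as weights,
$\bar Y_t = \sum_i Y_{it} f_{it} / \sum_i f_{it}$; covariates are aggregated
with each unit's pre-period mean patient count (covariates are
time-invariant, so a time-invariant unit weight is the consistent choice).
The donor pool is *not* aggregated: weighting the individual donor units
directly leaves far more resolution than first collapsing them into a
handful of regions. Indeed, with only $n$ aggregate reference regions a
two-sided placebo test can never report less than `min_pvalue(n)` $= 2/n$
(0.22 for $n = 9$), which is why the package resamples placebo *regions of
units* from the donor pool instead.

The donor weights solve

$$\min_{W \in \Delta^{J-1}} (X_1 - X_0 W)' V (X_1 - X_0 W),$$

where $X_1$ stacks the treated region's covariates and its $T_0$
pre-treatment outcomes (all pre-periods by default, mirroring the practice
of matching every pre-intervention quarter) and $V$ is a nonnegative
diagonal importance matrix. $V$ itself is chosen to minimise the
pre-treatment RMSPE of the induced weights $W(V)$. The ATT averages the
post-period gaps $\bar Y_t - \sum_j w_j Y_{jt}$ with per-period total
treated patient counts as weights; a `"cumulative"` switch uses running
totals instead, since "cumulative patient numbers" admits either reading and
the choice is deliberately surfaced rather than hidden.

## Numerical choices

**Predictor scaling.** Each predictor row of $(X_1, X_0)$ is standardised to
unit standard deviation across the pooled treated region and donors, so $V$
is scale-free; the constants are stored for invertibility, and zero-variance
rows are dropped with a recorded warning.

**Inner QP.** The weight problem is a convex least-squares program over the
simplex. It is solved exactly by an active-set method in the style of
Lawson–Hanson non-negative least squares, adapted to the sum-to-one
constraint: solve the equality-constrained KKT system on the current
support, step to the boundary when a weight would cross zero, and admit the
most violating coordinate until dual feasibility holds. Rank-deficient KKT
systems (ubiquitous, since the number of predictors is usually far below the
number of donors) are resolved by the minimum-norm pseudoinverse solution,
which makes the returned weights deterministic when the optimum is a face of
the simplex rather than a point. The test suite verifies the solver against
exhaustive simplex grid search and an independent interior-point QP solver.

**Outer search over V.** The nested objective `pre_rmspe(W(V))` is
non-convex, and where the inner optimum is non-unique it is only piecewise
continuous in $V$, with genuine jumps at the boundary of the $V$ simplex
(the tie-break changes there). The search therefore combines (i) a
deterministic coarse sweep — a dense one-dimensional grid when $k = 2$, a
seeded Dirichlet sample of 200 points otherwise, (ii) multi-start
Nelder–Mead in a softmax parameterisation (uniform start, one one-hot start
per predictor, seeded random starts, and the best coarse points), and (iii)
re-evaluation of exact simplex vertices and hard-thresholded versions of
every local optimum, because softmax can only approach exact zeros. All
candidate values are retained in the fit object so that near-ties — several
weightings predicting the pre-period equally well — are visible as a
diagnostic rather than silently resolved.

**Fast mode.** `scm_control(fast_v = TRUE)` skips the outer search and uses
a fixed (default uniform) $V$. It exists for replication and placebo studies
where thousands of fits are needed; single analyses default to the full
nested optimisation. When a perfect pre-period fit is attainable (treated
region inside the donor hull), every $V$ yields it, so fast mode is exact in
that regime.

**Fit diagnostics.** The pre-treatment RMSPE is always reported, never
thresholded away: a poor pre-period fit is the method's own warning that the
counterfactual may be unreliable, and downstream interpretation should
depend on it.

## Inference

Placebo regions of `size` (default $K_1$) units are drawn from the donor
pool without replacement; the remaining donors form that placebo's pool; the
complete procedure — including the nested $V$/$W$ optimisation unless fast
mode is requested — is re-fitted; draws are independent, so donors recur
across placebo regions. The default p-value is the plain proportion of
placebo ATTs at least as extreme in absolute value as the observed one,
which can be exactly zero; an add-one rule is available but off by default
because the plain proportion is the convention being reproduced. The
observed region never enters its own reference distribution. A structural
per-unit variant (placebo draws analysed with per-unit synthetic controls
and frequency-weighted aggregation) mirrors the hospital-level analysis; it
is a reconstruction, not a documented original procedure.

`min_pvalue()` implements the separate analytic floor $2/n$ under the
rank-doubling convention, capped at 1 (with a single reference unit no
rejection is possible). The doubling logic and the counting rule are two
different conventions and are deliberately kept in separate functions.

## Comparator estimators

* `did_estimate()`: two-way fixed-effects regression; cluster-robust (by
  unit) sandwich variance with the HC1-type small-sample correction;
  p-values on $t_{G-1}$ with $G$ the number of clusters. Optional analytic
  weights (`"freq"`) weight each unit-period by its patient count.
* `match_units()`: greedy 1:1 nearest-neighbour Mahalanobis matching without
  replacement on standardised covariates and pre-period outcomes, treated
  units processed in a seeded random order (an explicit `order` argument
  makes the greedy path reproducible in tests). Genetic matching would also
  serve; greedy Mahalanobis is transparent, dependency-free and — as the
  balance table of standardised mean differences before/after documents —
  sufficient for the balance it is asked to deliver. A singular feature
  covariance falls back to diagonal scaling, logged.
* `scm_per_unit()` + `scm_plus_did()`: one synthetic control per treated
  unit, gaps aggregated with patient counts; the hybrid stacks treated units
  and their synthetic counterparts into a new panel and applies DiD. Its
  inference is conditional on the estimated weights and the result carries a
  `conditional_on_weights` flag, because the weight-estimation uncertainty
  is not propagated.
* `leave_one_out()`: drops one donor region at a time and refits, reporting
  the ATT spread — the standard check that no single region drives the
  result.

## The synthetic-data generator

`generate_panel()` draws from exactly the factor model above, so every
estimator can be exercised against known ground truth without any external
data. Four frozen scenarios define the study conditions used throughout the
tests; sizes are desk-scale choices (a realistic regional evaluation shrunk
to run thousands of times in a test suite), with 12 quarters split 6/6
around the cut, nine donor regions, and truncated-Poisson patient counts
with mean 150 per unit-quarter (no claim is made to reproduce real
admission volumes):

| scenario    | donors | treated | key features                                        |
|-------------|-------:|--------:|-----------------------------------------------------|
| `parallel`  | 30     | 6       | constant $\lambda_t$, level confounding, $\alpha=1$, $\sigma_\varepsilon=0.2$ |
| `hull`      | 24     | 3       | noiseless; treated $(\mu, Z)$ an exact convex donor combination; $\alpha=2$ |
| `divergent` | 30     | 6       | trending $\lambda_t$ plus a treated $\mu$ shift; $\alpha=1$, $\sigma_\varepsilon=0.1$ |
| `null`      | 20     | 4       | no effect, no confounding shift; treated and donors exchangeable |

The `hull` construction makes the identifying logic literal: a perfect
synthetic control exists, and because the pre-period paths of $\lambda_t$
and the columns of $\theta_t$ are chosen linearly independent, a zero
pre-RMSPE forces the moment match $\sum_j w_j \mu_j = \bar\mu$,
$\sum_j w_j Z_j = \bar Z$, hence an exact counterfactual. With three
affinely independent donors the generating weights are the unique solution
and are recovered by the solver to numerical precision. The `null` panel is
smaller so that placebo-calibration studies (hundreds of replications, each
with dozens of placebo re-fits) remain cheap.

What the generator does **not** emulate: serial correlation and
heteroscedasticity of the shocks, drifting covariates, regional correlation
beyond the factor structure, entry/exit of units, or realistic mortality
levels and geography. Passing tests therefore demonstrate correctness of
the estimators under the stated factor model, not performance on any real
administrative dataset.

`generate_patients()` adds a patient level (Bernoulli deaths from a logistic
model with unit-period baseline shifts) for the risk-adjustment stage:
`fit_risk_model()` fits the logistic risk score on pre-intervention patients
only — separation is detected and reported as an error rather than silently
returning divergent coefficients — and `risk_adjust()` returns
$100(\text{observed} - \text{mean predicted risk})$ per unit-period cell.
Cells with no patients come back missing and flow into the explicit balance
policy of `read_panel()` (`"drop-unit"` by default, discarding units that do
not contribute to every period with a report; `"strict"` turns imbalance
into an error naming the offending cells). Zero patient counts in an
otherwise complete panel are valid data, not imbalance.

## Validation performed by the package itself

The test suite and `scripts/acceptance.R` recompute, among others: the QP
objective against exhaustive simplex grids (100 random problems) and an
independent interior-point solver; the nested optimum against a dense grid
over $V$ (toy two-predictor problems); exact recovery of the hull-scenario
effect by all three synthetic-control variants; the DiD closed form and a
double-demeaning oracle; replication-averaged agreement of DiD and SCM under
parallel trends; the smaller bias of SCM when loadings diverge (200
replications); and the placebo test's rejection rate at the 10% level under
the null (200 replications of 50 placebos, fast mode), checked against the
exact binomial band. Replication counts were sized to keep the full suite
around a minute of compute; they are stated here as the package's own
validation conditions.

## Known limitations

* Linearity in observed and unobserved predictors is assumed throughout;
  with few pre-treatment periods a good pre-period fit can arise by chance,
  and the pre-RMSPE diagnostic cannot rule that out.
* With many donors and few predictors the optimal weights are routinely
  non-unique; the deterministic minimum-norm tie-break makes results
  reproducible but is still a choice among equally good solutions.
* Placebo inference treats units as exchangeable with the treated region
  under the null; patient-count heterogeneity between treated and donor
  units weakens that premise.
* The hybrid estimator's standard errors condition on the estimated weights.
* Confidence sets by inverting the permutation test, two-way clustered
  variances for the DiD sensitivity analysis, and bias-corrected or
  factor-model ("generalised") synthetic control variants are out of scope.
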