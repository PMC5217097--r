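---
title: "Weighted composite endpoints with cone-constrained simultaneous inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted composite endpoints with cone-constrained simultaneous inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcomp)
```

## The problem

Randomized trials often combine several clinical events — say non-fatal
myocardial infarction, stroke and vascular death — into a single composite
endpoint. The conventional analysis counts any first event with equal
weight, which is routinely criticized because the components differ
sharply in severity. `wcomp` implements a weighted alternative: the test
statistic is the weighted sum of absolute risk differences across *event
types*,

$$\hat T(w,\tau) \;=\; \sum_{k=1}^{K} w_k\,
\big(\hat p_{A,k}(\tau)-\hat p_{B,k}(\tau)\big) \;=\; w^\top \hat D(\tau),$$

where $\hat p_{\cdot,k}(\tau)$ is the estimated probability that a subject
in the given arm realizes event type $k$ in $(0,\tau]$. If the weights are
standardized to sum to one, $\hat T$ is a weighted average of absolute
risk differences; if the weights are costs (for instance DALYs lost per
event type), $\hat T$ estimates the expected cost difference between the
arms.

Because stakeholders rarely agree on one exact weight vector, the package
also provides *simultaneous* confidence intervals and tests that remain
valid for **every** weight vector in a user-specified convex cone — for
example "all non-negative weights" or "weights ordered by clinical
severity". The multiplicity adjustment is based on the chi-bar-squared
distribution of the cone-restricted maximal standardized contrast, a
generalization of Scheffé's method to cone constraints.

## Event types and schemes

A subject's history over $(0,\tau]$ is summarized by which components
occurred. Four schemes map histories to event types:

* **exhaustive** — one type per realized component combination (the
  no-event category is always dropped so the covariance matrix of
  $\hat D$ has full rank);
* **competing risks** — one type per possible *first* event;
* **worst event** — one type per most severe realized component;
* **marginal** — one (overlapping) type per component.

All four are linear images of the exhaustive probabilities,
$p = L\,p_{\mathrm{ex}}$ with a 0/1 matrix $L$, so estimates and
covariances transform by congruence. For one non-fatal and one fatal
component:

```{r schemes}
nf <- component_set(c("N", "F"), fatal = c(FALSE, TRUE))
build_scheme(nf, "marginal")$L     # rows: N+, F+; columns: N+F-, N-F+, N+F+
```

## Estimation

With complete follow-up through $\tau$, event-type probabilities are
multinomial proportions and the covariance is $(\operatorname{diag}(\hat
p)-\hat p\hat p^\top)/n$ (`estimate_binary_arm()`). Under right-censoring
the package fits the Aalen–Johansen estimator on a multistate model whose
states form a *directed tree* — each state is a unique event history, so
state-occupation probabilities at $\tau$ are exactly the exhaustive
event-type probabilities (`aalen_johansen_arm()`). Without censoring the
two estimators coincide exactly.

The covariance of the Aalen–Johansen probability vector is a
Greenwood-type estimator obtained by linearizing the product-integral: at
each event time the multinomial covariance of the hazard increments of
each at-risk state is propagated through $\hat P(0,u^-)$ and $\hat
P(u,\tau)$, and the per-time contributions are summed. We validated it two
ways: against subject-level leave-one-out jackknife covariances (relative
Frobenius error below 15% at $n = 500$, part of the test suite) and
against the multistate machinery in `mstate`, which reproduces both the
probabilities and their standard errors.

For time-to-event data with staggered follow-up the package also offers
the integrated statistic
$\hat T'(w,\tau)=\sum_k w_k \int_0^\tau h(t)(\hat p_{A,k}(t)-\hat
p_{B,k}(t))\,dt$ (`integrated_difference()`), evaluated by a
left-endpoint Riemann sum on a regular grid (default step $\tau/200$; the
suite checks the sum has converged at that resolution). With $h \equiv 1$
and a single absorbing event it equals the difference in restricted-mean
integrals. Its covariance is the sum of per-arm leave-one-subject-out
jackknife covariances — the one place we use resampling, because no
closed-form estimator is available in general.

## Simultaneous inference over a cone

A weight cone is written as $s$ equalities and $K-s$ inequalities,
$C=\{w: A_{\mathrm{eq}}w=0,\ A_{\mathrm{in}}w\ge 0\}$, with the stacked
matrix of full rank (`cone()`, shorthands `cone_nonneg()`,
`cone_ordered()`, `cone_spanned()`). For
$Z(C,V)=\max_{w\in C} w^\top z/(w^\top V w)^{1/2}$ with $z\sim N(0,V)$,
the squared statistic follows a chi-bar-squared distribution: a mixture of
$\chi^2_0,\dots,\chi^2_K$ whose weight on $i$ degrees of freedom is the
probability that the Euclidean projection of a standard normal vector onto
the transformed cone $V^{1/2}C$ lands on a face of dimension $i$.

Two implementation notes matter here:

* **Parametrization.** Projecting $N(0,V)$ onto $C$ in the $V^{-1}$
  metric gives a *different* chi-bar-squared law than the one governing
  $Z(C,V)$; the correct weights come from the cone $V^{1/2}C$,
  equivalently from applying the classical subset-enumeration formula to
  $V^{-1}$. We confirmed this by direct Monte Carlo of the maximal
  statistic and, independently, by reproducing published relative
  efficiencies to three decimals; the test suite pins the bivariate closed
  form ($\tilde w_K = \arccos(\rho)/2\pi$ for $K=2$).
* **Computation.** After reducing by the equality block (a change of
  basis turns the cone into an orthant), the exact weights are sums over
  subsets $J$ of products of two multivariate-normal orthant
  probabilities. Orthant probabilities use closed forms up to dimension 3
  and quasi-Monte Carlo integration (`mvtnorm`) above, with tolerance
  $10^{-6}$ in analyses and $2.5\times10^{-4}$ inside simulation loops. A
  Monte Carlo face-counting estimator (`chibar_weights(..., method =
  "mc")`) serves as in-package ground truth; exact and MC weights agree
  within three Monte Carlo standard errors in the tests. Projections are
  exact active-set quadratic programs (`quadprog`), checked against
  brute-force face enumeration.

Given the mixing weights, all two-sided intervals have the form
$w^\top\hat D \mp \eta^{1/2}(w^\top\hat V w)^{1/2}$ where $\eta$ is

* the $1-\alpha/2$ chi-bar-squared quantile (simultaneous over the cone),
* Scheffé's $\chi^2_{K,1-\alpha}$ quantile (simultaneous over all
  contrasts), or
* $\chi^2_{1,1-\alpha}$ ($1.96^2$ at $\alpha=.05$; pointwise only).

The cone is one-sided but the two-sided interval covers both directions,
hence the $1-\alpha/2$ order of the chi-bar quantile. A consequence worth
knowing: because that two-sided construction is a union bound over the two
signs, $\eta_{\text{chibar}}$ can exceed Scheffé's $\eta$ for cones close
to a half-space. Across the covariance structures that event-probability
estimates actually produce (multinomial-type, with orthant or
severity-order cones) the familiar ordering $\eta_{\text{unadj}} \le
\eta_{\text{chibar}} \le \eta_{\text{Scheffé}}$ holds, and the test suite
asserts it on that class; only $\eta_{\text{unadj}} \le
\eta_{\text{chibar}}$ is a theorem for arbitrary cones.

Tests reject when zero falls outside the interval; adjusted p-values
invert the monotone quantile functions in closed form (for the chi-bar
method, twice the mixture tail of the squared standardized statistic)
rather than by iterative bisection — same quantity, exact.

`cone_ordered(K)` encodes severity chains. Event types are ordered from
least to most severe throughout the package (components in increasing
severity; exhaustive types by size, then severity), so the chain reads
$w_K \ge \dots \ge w_1 \ge 0$.

## The simulator and its oracle

`simulate_arm()` draws subject paths through a constant-hazard directed
tree by competing exponential clocks — exact by memorylessness — with
independent exponential censoring and administrative censoring at $\tau$.
`analytic_event_probs()` solves the Kolmogorov forward equations by matrix
exponentiation and is the exact oracle for every scenario: simulated
proportions must match it within three Monte Carlo standard errors at
$n = 2\times10^4$ in the tests.

Bundled scenarios (also as YAML configs under `inst/extdata/`):

* `tree_illness_death()` — non-fatal then fatal event, rates
  0.05 / 0.02 / 0.2 per year, three exhaustive event types;
* `tree_two_transient()` — two transient states and direct or subsequent
  death, rates 0.08 / 0.1 / 0.04 / 0.2 / 0.3, five exhaustive types;
* `tree_cardiovascular()` — MI / stroke / vascular death with doubled
  post-event rates and no stroke-to-MI transitions. At 3 years the control
  rates give a 29.2% any-event risk (worst events 8.1 / 16.1 / 5.0%) and
  the intervention rates 21.3% (6.9 / 11.2 / 3.2%). The middle
  intervention entry is a genuine rounding-boundary case: the stated rates
  give 11.23%, while the published table prints 11.3.

What the generator emulates: constant cause-specific hazards, independent
censoring, 1:1 randomization, at most one occurrence per component. What
it does not: time-varying hazards, dependent censoring, covariates,
recurrent events — so passing tests demonstrate correctness of the
machinery under the stated model, not robustness to those violations on
real data.

## Coverage, power and sample size

`coverage_study()` replicates a two-arm trial, re-estimates $\hat D$ and
$\hat V$ each time (chi-bar weights are recomputed from each
replication's $\hat V$), and records whether **all** intervals over a
weight grid cover their true values simultaneously. The grid is a regular
lattice on the simplex $\{w\ge0,\sum w=1\}$ filtered by cone membership,
with the resolution chosen so the kept count is closest to the target
(`simplex_cone_grid()`); with ~1000 grid points the discretization error
of simultaneous coverage is negligible. True values come from the
analytic oracle.

`power_samplesize()` estimates rejection probabilities across candidate
per-arm sizes and reports the smallest candidate reaching target power
plus the linearly interpolated crossing. For a cone spanned by a few
generator weight vectors (e.g. age-dependent DALY weights),
`cone_spanned()` converts the generators to the inequality form, and
simultaneous detection across the whole cone is equivalent to rejection at
every generator.

Default problem sizes in the shipped tests and acceptance script are
scaled down from the original studies: 2000 replications for coverage
(Monte Carlo s.e. about 0.5 percentage points), 1000–2000 for power
curves, 400–600 for relative-efficiency averages. These sizes make all
Monte Carlo tolerances explicit multiples of the corresponding standard
errors.

## Numerical choices and edge cases

* Events at exactly $\tau$ are inside the closed interval $(0,\tau]$.
* Tied transition times within one subject are rejected as invalid input
  (the directed tree admits no simultaneous transitions); ties across
  subjects are handled by grouped product-limit updates.
* A subject censored before $\tau$ without an absorbing event makes the
  multinomial path error with a pointer to the Aalen–Johansen path.
* If every subject leaves observation before $\tau$, the last estimable
  value is carried forward and flagged (`truncated_at`).
* Estimated covariances are refused as singular when the smallest
  eigenvalue is below $10^{-10}$ times the largest — the reason the
  no-event category is excluded from every scheme.
* Chi-bar quantiles are found by bracketed root-finding to $10^{-10}$;
  when the requested probability does not exceed the zero-degree mass the
  quantile is 0 and flagged.
* Replications with degenerate $\hat V$ (possible at small $n$ with rare
  types) are dropped from coverage studies and counted.
* Worst-event severity is taken from the component list order supplied by
  the user (least to most severe), as the ranking is a clinical input.

## Limitations

Single-step inference only (no closed testing), two arms, no covariate
adjustment or stratification, each component at most once per subject,
jackknife rather than bootstrap for the integrated statistic, and Wald
intervals throughout — with rare events and small samples the usual
caveats about Wald-type intervals apply, which is visible as mild
under-coverage at $n=100$ in the five-type scenario.

## A worked example

The enteric-fever data bundled with the package (printed trial counts:
acute treatment failure or death 1/92 vs 20/77, relapse 2/92 vs 6/77)
illustrate the workflow end to end:

```{r enteric}
d <- enteric_fever_data()
sch <- build_scheme(enteric_fever_components(), "competing_risks")
diff <- wce_estimate(d, sch, tau = 1, arms = c("Cefixime", "Gatifloxacin"))
tidy(diff)

cv <- critical_value("chibar", cone = cone_nonneg(2), V = diff$V)
simultaneous_test(diff, c(0.5, 0.5), cv)[, c("estimate", "lower", "upper", "reject")]

# smallest relative weight of acute failure at which the simultaneous
# interval excludes zero
weight_threshold(diff, cv, component = "failure")
```

The sweep over all relative weights (`ci_weight_curve()` plus
`autoplot()`) reproduces the familiar band plot: the simultaneous
intervals are only marginally wider than the unadjusted ones, and the
difference is significant for any weight of the acute-failure component
above roughly 9%.
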