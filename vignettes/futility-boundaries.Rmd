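---
title: "Optimal futility boundaries for two-stage group sequential designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal futility boundaries for two-stage group sequential designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsfutility)
```

## The design and its joint law

We consider a randomized two-arm superiority trial with a continuous
endpoint, normal in both arms with common standard deviation $\sigma$, and
the one-sided hypotheses $H_0\colon \mu^I - \mu^C \le 0$ versus
$H_1\colon \mu^I - \mu^C > 0$ for the standardized effect
$\Delta = (\mu^I - \mu^C)/\sigma$. The trial enrols $n$ patients per arm and
looks once at the data after $n_1$ per arm. The interim statistic is the
normal-approximation z-test
$T_1 = \frac{\bar X_1^I - \bar X_1^C}{S_{pooled,1}}\sqrt{n_1/2}$, and the
final analysis uses the inverse normal combination
$T_{1+2} = (w_1 T_1 + w_2 T_2)/\sqrt{w_1^2 + w_2^2}$ of the interim
statistic with the independent increment $T_2$ built from second-stage data
only. With the customary weights $w_i = \sqrt{n_i}$, $(T_1, T_{1+2})$ is
bivariate normal with unit variances, mean
$(\Delta\sqrt{n_1/2},\, \Delta\sqrt{n/2})$ and correlation $\sqrt{n_1/n}$.
Note that the correlation sits *off* the diagonal of the covariance matrix:
both components are standardized, and $\mathrm{Cov}(T_1, T_{1+2}) =
\sqrt{n_1/n}$ is what makes all operating characteristics below rectangle
probabilities of one bivariate normal.

Stopping rules, in p-value form ($p_i = 1 - \Phi(T_i)$):

* stop for **efficacy** at interim when $p_1 \le \alpha_1$;
* stop for **futility** (non-binding) when $p_1 > \alpha_0$;
* otherwise continue and reject at the end when $p_{1+2} \le \alpha_{1+2}$.

We take the boundary convention "continue while
$\alpha_1 < p_1 \le \alpha_0$"; under continuous distributions the choice of
strictness is immaterial, but fixing it keeps the simulator's tie handling
deterministic. The local levels are Pocock levels, i.e. the common value
$\alpha_1 = \alpha_{1+2}$ solving
$P_{H_0}(p_1 \le \alpha_1) + P_{H_0}(\alpha_1 < p_1,\ p_{1+2} \le
\alpha_{1+2}) = \alpha$. `gs_design()` accepts explicit `alpha1`/`alpha12`
values as an extension hook for other boundary families (O'Brien–Fleming,
spending functions), but only Pocock levels are solved natively.

```{r}
pocock_local_levels(0.5, 0.025)
```

## Admissible and optimal futility boundaries

Futility stopping trades power for the ability to abandon hopeless trials
early. Two prespecified parameters quantify what is acceptable:

* `pi_wrong` — the admissible probability of *wrongly* stopping for
  futility, i.e. stopping although the true effect equals the relevant
  effect $\Delta$. Condition (i), $P_\Delta(p_1 > \alpha_0) \le
  \pi_{wrong}$, has the closed-form solution $\alpha_0 \ge 1 -
  \Phi(z_{\pi_{wrong}} + \Delta\sqrt{n_1/2})$ (`pi_wrong_bound()`).
* `pow_loss` — the admissible *global* power loss caused by observing the
  futility rule. Condition (ii) bounds the rejection probability from below
  by the no-futility power minus `pow_loss`; since power is monotone
  non-decreasing in $\alpha_0$, the smallest compliant boundary is found by
  bisection (`pow_loss_bound()`).

Any boundary satisfying both is admissible. The probability of *correctly*
stopping — under the null or a non-relevant effect — increases as the
boundary decreases, so the optimal boundary is the minimum admissible one:

$$\alpha_{0,opt} = \max\{\text{bound}_{\pi},\ \text{bound}_{pow},\ \alpha_1\}.$$

`optimal_futility()` reports which constraint binds. Degenerate inputs are
permitted with a warning rather than an error: `pi_wrong = 0` forces
$\alpha_{0,opt} = 1$ (never stop), which is a legitimate, if extreme,
planning choice.

Two modelling decisions deserve emphasis. First, the *reference power* for
the power-loss condition is the group sequential design's power **without**
a futility rule at the same sample size — not the nominal planning power
$1-\beta$ of the fixed design. The two differ (e.g. 0.90 nominal versus
0.88 realized at $N = 172$ below), and only this reading keeps the power
loss a property of the futility rule alone; the nominal value is shown
alongside in summaries for transparency. Second, the continuation-region
probability is computed directly as the rectangle
$P(z_{1-\alpha_0} < T_1 \le z_{1-\alpha_1},\ T_{1+2} > z_{1-\alpha_{1+2}})$
rather than as a difference of orthant CDF values; the rectangle is
non-negative by construction and robust to sign conventions.

## Worked planning example

A trial powered at 90\% to detect $\Delta = 0.5$ at one-sided 2.5\% needs
`fixed_design_sample_size(0.5, 0.025, 0.90)` = 86 patients per group (the
noncentral-$t$ sample size of the two-sample $t$-test; only this planning
step uses the $t$ distribution — all interim arithmetic uses the normal
approximation, adequate at these sample sizes). Carried into the two-stage
design:

```{r}
d172 <- gs_design(0.5, 0.025, power = 0.90)
overall_power(d172, alpha0 = "none", delta_true = 0.5)

d188 <- gs_design(0.5, 0.025, n_per_group = 94)
d140 <- gs_design(0.5, 0.025, n_per_group = 70)
optimal_futility(d188, pow_loss = 0.05, pi_wrong = 0.05)
```

`sensitivity_grid()` crosses several admissible-parameter choices (here for
two competing sample sizes, with correct-stopping probabilities evaluated at
$\Delta/2$ and $0$, the default grid):

```{r}
sg <- sensitivity_grid(list(d188, d140), c(0.01, 0.05), c(0.01, 0.05, 0.10))
num <- setdiff(names(sg)[vapply(sg, is.numeric, logical(1))],
               c("n_total", "pow_loss", "pi_wrong"))
sg[num] <- lapply(sg[num], round2, 2)
sg
```

Reading such a table, a useful rule of thumb is to require the probability
of correctly stopping to stay above roughly 20\%; very small `pi_wrong`
values (0.01) push the boundary to 0.46–0.59 where correct stopping becomes
likely *too* rare, and comparing against the conventional arbitrary choice
$\alpha_0 = 0.5$ via `implied_admissible_params()` makes explicit how little
power that choice saves and how rarely it stops a null trial.

## Numerical choices

* **Bivariate normal kernel.** All probabilities reduce to rectangle
  probabilities of one bivariate normal, evaluated via inclusion–exclusion
  over upper orthants with the deterministic TVPACK algorithm
  (`mvtnorm::pmvnorm`); absolute error is far below the 1e-8 the boundary
  arithmetic assumes, and there is no Monte-Carlo noise in any analytic
  result.
* **Root finding.** The Pocock level and the power-loss bound are solved by
  plain bisection with bracket validation (both target functions are
  monotone), to an interval width of 1e-10 — deterministic and free of
  derivative approximations. The type I error equation then holds to
  better than 1e-6, which the tests assert.
* **Rounding.** Full double precision is kept everywhere internally;
  pretty-printed tables round half away from zero at 2 decimals
  (`round2()`), so 0.218 prints as 0.22 and 0.3275 as 0.33.
* **Sample-size conventions.** Equal allocation throughout; an interim
  "after 50% of patients" means $n_1 = n/2$ per group, and configurations
  whose interim size is not a whole number are rejected rather than rounded
  silently.

## The simulator: what it emulates and what it does not

`simulate_trials()` is an independent stochastic oracle, not the primary
computation. Its `z_scale` mode draws $(T_1, T_2)$ directly from their
normal laws; its `patient_level` mode draws individual observations, forms
the pooled-SD interim statistic and the second-stage-only increment, and
converts to p-values with the same normal approximation — so the comparison
of the two modes quantifies the (negligible at $n_1 \ge 35$, about $10^{-4}$
in stopping probability) effect of the $t$-type denominator the analytic
formulas ignore. Replication counts default to $10^5$ in the tests, giving
binomial standard errors around $10^{-3}$; every analytic probability is
checked to agree within three such standard errors. Seeds are explicit, and
per-effect streams are derived as `seed + index - 1`, so extending an effect
grid never perturbs earlier estimates.

The simulator emulates exactly the idealized model: normal data, equal and
known allocation, no dropout, no drift between stages, and a futility rule
that is always followed. Real trials violate all four; in particular the
futility rule here is *non-binding*, and the local levels are chosen so that
type I error control never relies on stopping. Passing tests therefore
demonstrate internal consistency of the analytic machinery under the model,
not robustness to non-normal endpoints or information-time misestimation.

## Scope and limitations

The implementation covers two stages, equal allocation, Pocock local levels
and the inverse normal combination. More than two stages, binding rules with
re-optimized (enlarged) local levels, Fisher's combination, spending-function
boundaries, and binary or time-to-event endpoints are out of scope. The
admissible parameters themselves remain a subjective planning choice; the
package's contribution is to make their consequences — power loss, wrong
stops, correct stops — explicit before the trial starts, over a grid of
candidate values (`sensitivity_grid()`, `plot()`), rather than to prescribe
a single "best" pair. The power-loss guarantee holds only at the assumed
effect $\Delta$; for smaller true effects the loss can be larger, which is
why $\Delta$ should be the *minimal clinically relevant* effect, not an
optimistic expectation.
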