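---
title: "Starting values and convergence criteria in 2PL estimation with an empirical-histogram latent distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Starting values and convergence criteria in 2PL estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehirt)
library(dplyr)
```

## The model and the question

The two-parameter logistic (2PL) item response model gives the probability
that testee $j$ answers item $i$ correctly as

$$\pi_i(z_j) = \frac{\exp[a_i(z_j - b_i)]}{1 + \exp[a_i(z_j - b_i)]},$$

with item discrimination $a_i > 0$, item difficulty $b_i$, and latent
ability $z_j$. Item parameters are estimated by marginal maximum likelihood
(MML): the latent ability is integrated out over a distribution represented
by weights $W_q$ on $Q$ fixed, equally spaced support points, and the
Bock–Aitkin EM algorithm alternates an E-step (posterior distribution of
each testee over the support points, and the expected counts $m_q$,
$r_{iq}$) with an M-step (per-item weighted logistic maximization). Two
variants are implemented:

* **mml** — the weights stay fixed at a discretized standard normal: the
  conventional assumption.
* **eh** (empirical histogram) — the weights are re-estimated in every
  M-step as the average posterior mass per point, so the shape of the
  latent distribution is learned from the data together with the item
  parameters.

EM starts from initial values and stops when the largest between-cycle
change in any item parameter falls below a convergence criterion. The
package exists to study a question that is easy to overlook: **how much do
the starting values and the stopping criterion themselves change the
estimates** when the latent distribution is estimated rather than assumed?
`run_study()` runs the full factorial Monte Carlo experiment; `fit_2pl()`,
the initialization strategies, and the outcome metrics are all usable on
their own.

## Study design

Five crossed factors, with one simulated dataset shared by every
estimation-side condition inside each (truth, sample size, replication)
cell (`condition_seed()` makes the map reproducible and injective):

| factor | levels | default |
|---|---|---|
| initial item parameters (`iip`) | true, default (CTT), const (a=1, b=0), shortrun | all four |
| initial latent weights (`ild`, eh only) | uniform, default (normal density), est (binned CTT scores), shortrun | all four |
| true latent distribution (`tld`) | standard normal; standardized skew-normal, shape 10 (skewness 0.956) | both |
| sample size (`n`) | 250, 500, 1000 | all three |
| convergence criterion | 1e-2 (conventional default), 1e-3, 1e-4, 1e-5 | all four |

Ten support points on $[-4, 4]$, at most 10000 EM cycles, 100 replications
per cell at full scale. Outcomes per fit: per-item and test-level bias
(mean over items of the absolute mean deviation over replications), the
area between true and estimated item characteristic curves on $[-10, 10]$,
and the Earth Mover's Distance (EMD) between the final latent weights and
the generating ability sample binned onto the same grid.

## What the synthetic data emulate — and what they do not

The generating item bank is a fixed, documented 20-item fixture
(`make_item_bank()`) spanning difficulties $-2.5$ to $2.43$ and
discriminations $0.5$ to $3.0$, including one very highly discriminating
item ($a = 3.00$) and one very difficult item ($b = 2.43$), so the
single-item analyses of extreme-parameter sensitivity have natural targets.
It is a synthetic stand-in for the unpublished achievement-test bank used
in the original study of this design; conclusions that depend on the exact
mix of item difficulties (notably, how much harder a skewed ability
distribution makes the *easy* items) will differ from any particular real
bank. Abilities are exactly mean-0/SD-1 by population standardization of
the skew-normal (the sample is *not* re-centered, so sampling variability
in the realized mean and SD is retained, as in data generation for a real
study). Responses are independent Bernoulli draws from the 2PL itself —
there is no misfit, no guessing, no missingness; passing tests therefore
say nothing about robustness to model violation, only about the estimation
machinery under the model.

## Numerical choices

* **Overflow safety.** All pattern likelihoods are accumulated in log
  space (`plogis(log.p = TRUE)`, log-sum-exp over support points), so even
  extreme patterns at tight criteria cannot underflow.
* **M-step.** Each item's expected complete-data log-likelihood is
  maximized by safeguarded Newton iterations in the slope–intercept
  parameterization (at most 50 iterations, step halving). The bounds
  $a \in [0.05, 10]$, $b \in [-10, 10]$ act as a feasible box *inside* the
  search: a candidate step outside the box or not improving the objective
  is halved, so every accepted update increases the likelihood and
  boundary solutions are flagged rather than truncated after the fact.
  Starting values are projected into the same box once, at initialization.
* **Metric standardization.** With free weights the 2PL is identified only
  up to an affine transformation of the latent scale. The metric is
  standardized to mean 0, SD 1 **once, at termination**: items transform as
  $a \leftarrow as$, $b \leftarrow (b - m)/s$, and the weights are re-expressed
  on the fixed grid by rebinning under the histogram convention (each
  weight occupies its grid cell uniformly; cell boundaries map affinely;
  the identity map reproduces the weights exactly). Standardizing every
  cycle is the main design alternative; it was rejected because the
  rebinning is not likelihood-preserving, and applying it inside the
  iteration breaks the EM ascent guarantee (observed dips of order 1e-2 in
  log-likelihood under skewed truth). With the end-of-run schedule every
  cycle is a pure EM step, the log-likelihood trace is non-decreasing by
  construction, and the convergence criterion still operates on item
  parameters only.
* **Convergence.** The criterion is the largest absolute between-cycle
  change over item parameters (weights excluded), matching the common
  reading of the reference software's rule; its exact quantity is not
  documented anywhere, which is one reason results are compared as
  patterns, not digits.
* **ICC area.** Two 2PL curves cross at most once, and
  $\int \pi\,dz = \log(1 + e^{a(z-b)})/a$, so the $[-10,10]$ area is
  evaluated in closed form by splitting at the crossing point — exact,
  and cross-checked in the tests against `stats::integrate()` and a dense
  trapezoid rule.
* **EMD.** On a shared equally spaced grid the optimal transport cost is
  the spacing-weighted L1 distance between cumulative weights. Distances
  are reported in latent-scale units (spacing $8/9$); `spacing = 1` gives
  the unitless grid-step convention. Tests verify the cumulative-sum form
  against the quantile-coupling characterization of 1-D optimal transport.
* **Degenerate inputs.** Constant item columns get $r_{bis} = 0$ and are
  flagged; `est` weights with zero score variance collapse to a point mass
  at the support point nearest 0; non-converged fits are returned (and
  recorded in studies) with `converged = FALSE`, never dropped.

## Open design choices and how they were settled

* The CTT default difficulty start is $b_0 = -\mathrm{logit}(p_i)/a_{0i}$
  with $a_0$ floored at 0.3 — the difficulty at which an average-ability
  testee matches the observed proportion correct. The reference software's
  exact transformation is undocumented; this rule is model-consistent and
  data-driven.
* Shortrun starts draw $a \sim \mathrm{LogNormal}(0, 0.5)$,
  $b \sim N(0,1)$, weights $\sim$ symmetric Dirichlet(1); 50 starts of 10
  cycles each, the candidate with the highest marginal log-likelihood
  wins. Short runs use the same method (eh/mml) as the fit they seed.
* `est` maps standardized weighted sum scores to the *nearest* support
  point — the simplest rule consistent with "relative frequencies at each
  support point".
* The EMD reference is the binned generating ability *sample*, not the
  analytic density: recovery is judged against the data the fit actually
  saw.
* The latent-recovery table averages over initial item parameters and
  sample size within each (criterion × initial-weights × truth) cell; the
  aggregation is a documented assumption, configurable by filtering the
  records.

## Problem sizes used by the tests and the acceptance script

The packaged checks run the full 4×4×3×2 empirical-histogram grid and the
4×3×2 MML grid at the conventional criterion with 25 replications, and a
criterion sweep (all four criteria, all four initial-weight strategies,
both truths) at $n = 250$ with 25 replications — sizes chosen so the whole
suite completes in minutes while keeping Monte Carlo error well below the
effects being asserted. The generator skewness check uses 100 samples of
$n = 1000$; parameter recovery is checked at $n = 5000$.

## What a faithful re-implementation does and does not reproduce

Direction-level findings reproduce here: recovery of the latent
distribution deteriorates as the convergence criterion tightens for the
uniform, normal-density and shortrun starting weights, while the
data-driven `est` weights are the most robust choice at tight criteria;
sample size dominates the variance decomposition of ICC bias (over 90% of
between-condition variance); and latent recovery is worse under a normal
than under a skewed truth on the grand mean.

Magnitudes do not transfer. This EM implementation converges in hundreds
of cycles where the proprietary reference needed a 10000-cycle cap, and
its worst-case EMD values stay an order of magnitude below the reference
table's, because the drift that accumulates over very long weight-update
sequences in that software (its own authors attribute it to accumulated
numerical inaccuracy) largely does not arise here.

Two checks fail under these study conditions, and the test suite shows
them failing rather than hiding them. First, under standard MML at the
conventional criterion 1e-2, initial item parameters retain a small trace
in *difficulty* bias ($\eta^2 \approx 0.03$, against $< 0.01$ expected;
discrimination is at 0.0001). The effect is a loose-stop artifact: there
is no post-EM Newton polish here, and at criterion 1e-4 the same
$\eta^2$ is 0.0000 for both parameters. Second, at $n = 250$ the
empirical-histogram test-level bias is marginally *higher* (by about
0.006) under the skewed truth than under the normal truth, not lower: the
standardized skew-normal at shape 10 has a sharp left shoulder that
starves the fixture's very easy items ($b \le -1.4$) of informative
responses. With an item bank lacking very easy items the comparison moves
the other way.

## A worked fit

```{r example, eval = FALSE}
bank <- make_item_bank()
dat <- sim_dataset("skew", n = 500, rep = 1, bank)
fit <- fit_2pl(dat$responses, method = "eh", criterion = 1e-2)
glance(fit)
tidy(fit)
emd(fit$grid$weight, sample_to_grid(dat$abilities, fit$grid), fit$grid)
autoplot(fit)
```

## Known limitations

Only the 2PL (no 1PL/3PL, no guessing), complete data only, no standard
errors, no Gauss–Newton acceleration after EM, and a latent grid fixed at
equally spaced points (the weights move; the points do not). The
comparison with the original proprietary-estimator results is directional
by design: its priors, its post-EM Newton phase and its exact convergence
quantity are not public and are out of scope here.
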