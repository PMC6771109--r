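---
title: "Methods behind atlasmooth: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind atlasmooth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atlasmooth)
```

`atlasmooth` estimates small-area cancer burden — incidence as
standardised incidence ratios (SIR) and five-year relative survival as
excess hazard ratios (EHR) — with Bayesian conditional-autoregressive
smoothing, and produces the uncertainty statistics and visual encodings
that an interactive atlas layers on top.  This vignette records the
models, their assumptions, the tunable parameters, and the design
decisions taken where reasonable implementations could differ.  It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## Spatial structure

Both models share a binary first-order spatial weights matrix: areas are
adjacent (`w_ij = 1`) when they share a boundary of *positive length*.
Corner-only contact does not count (rook, not queen, on a lattice); an
area wholly enclosed inside another shares its whole ring with the host
and so has exactly one neighbour.  Binary adjacency keeps the precision
matrix sparse (Markov property), matches the discrete data, and in the
model-comparison literature performs at least as well as distance-decay
weights, which are deliberately out of scope.

Structurally isolated areas (degree 0) would receive no smoothing, so
`repair_islands()` links each to a mainland area: a user-supplied manual
link where local knowledge exists (bridge or ferry connections, as on
real geographies), otherwise the nearest non-island area by centroid
distance, ties broken by lowest area id so builds are deterministic.  The
repair is idempotent and never touches existing adjacency.

## Standardisation

Expected incidence counts use *internal* indirect standardisation:
age-specific rates are computed from the analysis data itself
(`r_a = sum_i y_ia / sum_i n_ia`) and applied to each area's population.
The data could not tell us whether the original analyses used external
reference rates; internal standardisation is chosen because it makes
`sum_i E_i = sum_i y_i` an algebraic identity, so SIR = 1 is exactly the
national average — which is how the atlas colour scale and DPP interpret
the value 1.

Survival tables follow the period method: each patient contributes to
follow-up year `t` (1..5) only the overlap of `(diagnosis + t - 1,
diagnosis + t]` with the at-risk calendar window, truncated at
death/censoring.  Dates are continuous years and the window `c(2006,
2015)` means `[2006-01-01, 2015-01-01)`; sources that quote "2006–2014"
give calendar years only, and the half-open convention makes person-time
additive without double counting.  The four broad age groups are 15–54,
55–64, 65–74, 75–89 with closed-left boundaries; published tables print
the overlapping pair "65–74" and "74–89", which cannot both be
closed — we resolve the typo-level ambiguity as 65–74 / 75–89 and log the
convention here rather than guessing further.  Sex enters the strata only
for all-persons models, cancer site only for aggregate cancer groups.
Expected other-cause deaths are `d* = rate x person-time`, summed over
calendar-year slices when the background life table is year-specific; the
life-table convention behind real `d*` inputs is not reconstructable from
the sources, so the fitter consumes `d*` as given.

## The two models

Incidence:
`y_i ~ Poisson(E_i e^(beta0 + S_i))`, with `beta0 ~ N(0, 1e5)`,
`sigma_S^2 ~ InverseGamma(shape 1, scale 0.01)`, `rho ~ U(0, 1)`.

Survival:
`d_itk ~ Poisson(mu_itk)`,
`mu_itk = d*_itk + y_itk exp(alpha_t + x' beta + S_i)`, with
`alpha_t, beta_k ~ N(0, 1000)` and a half-normal prior on the variance
itself, `sigma_S^2 ~ N(0, 5) I(0, inf)`.  Two points deserve flagging:

* **The half-normal is applied to the variance, not the standard
  deviation**, exactly as the prior is printed in the motivating work.
  Software conventions differ (WinBUGS parameterises by precision), so
  the prior family and parameters are a configuration switch
  (`mcmc_config(variance_prior = ...)`), which doubles as the
  sensitivity-analysis hook (inverse-gamma vs half-normal with variance
  3, 5, 7.5, 10).
* **Strata use reference coding** (first stratum absorbed into the year
  intercepts) rather than a full indicator per stratum.  A full block
  plus five free intercepts is an exact ridge that only the weak priors
  would resolve; reference coding removes it, and it is the unique
  convention under which the model's single-stratum reduction collapses
  to the intercept-only model that the 1-D quadrature oracle checks.

In both models the spatial effects follow the Leroux prior, whose full
conditional mean blends the neighbour average (weight `rho`) with zero
(weight `1 - rho`) and whose joint precision is
`Q = [rho (D - W) + (1 - rho) I] / sigma^2`.  At `rho = 1` (intrinsic
CAR) `Q` is rank-deficient; the field simulator refuses it, while
`leroux_precision()` itself permits it since callers may want the ICAR
limit for analysis.

## MCMC

Metropolis-within-Gibbs, implemented in Rcpp:

* single-site adaptive random-walk updates for each `S_i` against the
  Leroux full conditional (step sizes tuned to ~44% acceptance during
  burn-in only, then frozen, so the post-burn-in kernel is valid);
* an O(1) collapsed random-walk update for `beta0` (the Poisson
  likelihood enters only through `sum_i E_i e^(S_i)`), and per-block
  updates for `alpha_t` and `beta_k` touching only their cells;
* conjugate Gibbs for the inverse-gamma variance,
  `IG(shape + n/2, scale + S'Q0 S / 2)` with
  `Q0 = rho (D - W) + (1 - rho) I`; Metropolis on `log sigma^2` with the
  Jacobian for the non-conjugate half-normal;
* reflected Gaussian random walk for `rho` on [0, 1], using the exact
  joint Leroux log-density; `log |Q0(rho)| = sum_j log(rho lambda_j + 1 -
  rho)` comes from one cached eigendecomposition of `D - W`.

**Identifiability.**  `beta0` (or the five `alpha_t`) and the mean of `S`
form an additive ridge softly resolved only by the priors.  A common
device is to re-centre `S` to mean zero each iteration, absorbing the
mean into the intercept.  We found that hard re-centring is *not
measure-preserving under the proper Leroux prior*: unlike the intrinsic
CAR, the Leroux prior is shift-sensitive (`1'Q1 = (1 - rho) n > 0`), and
on a 3-area oracle instance the re-centred sampler showed a reproducible
posterior-mean bias of several Monte-Carlo standard errors.  The package
therefore uses an exact Gibbs "gauge" move (a hierarchical-centering /
ancillarity sweep): the likelihood is invariant along
`(beta0 + c, S - c 1)`, the conditional of `c` is Gaussian with precision
`1/var(beta0) + (1 - rho) n / sigma^2`, and sampling it both fixes mixing
along the ridge and keeps the posterior exact.  As the intercept prior
variance grows this move converges to re-centring, so `beta0` retains its
interpretation as the overall log-SIR and `mean(S)` stays near zero
(softly — its posterior spread is `sqrt` of the inverse gauge precision,
which is why tests assert approximate, not exact, centring).

**Numerical guards.**  Linear predictors are clamped at |30| with a
counted warning (never silently); the `sum E e^S` cache is recomputed
rather than maintained incrementally (incremental updates proved
vulnerable to catastrophic cancellation); degenerate proposals evaluate
to `-Inf` and are rejected rather than propagating NaN.

The default schedule — 50,000 burn-in, 100,000 further iterations, thin
10, posterior sample 10,000 — matches the production schedule of the
motivating atlas and takes tens of seconds at the default synthetic scale
(402 areas).  Convergence is flagged per area by the Geweke diagnostic
(first 10% vs last 50% of the retained chain, AR spectral variance
estimates, two-sided p < 0.01); constant chains get a distinct
"degenerate" status instead of a fake p-value.

## Posterior summaries

Per area, on the ratio scale: posterior median (robust to stray draws),
equal-tailed 60% and 80% credible intervals, the exceedance probability
`PP_high = mean(draws > 1)` (strict inequality: draws exactly 1 count as
not greater), and `DPP = 2 |PP_high - 0.5|`.  Quantiles interpolate
linearly between order statistics (type 7); at a posterior sample of
10,000 the choice is immaterial, but tests need the convention pinned
down.  Exact equivariance of the summaries under `exp` holds when
`(n - 1) x prob` is integral (e.g. n = 1001 draws), otherwise only to
interpolation error — the suite tests the exact case.

## Evidence of spatial variation (Tango's MEET)

For decay scales `lambda` on a 10-point log-spaced grid from the minimum
inter-centroid distance to 2000 km (about half the continental extent in
the motivating application), the clustering statistic is
`C(lambda) = (r - p)' A(lambda) (r - p)` with
`a_ij = exp(-4 (d_ij / lambda)^2)`, `r` the modelled-count proportions
and `p` the expected-count proportions.  "Modelled counts" are
posterior-median fitted counts (`E_i x median SIR_i`; posterior-median
excess deaths for survival), matching the mapping convention.  The scale
is profiled out by the minimum Monte-Carlo p-value over the grid, and
that minimum is calibrated against the *same* multinomial null
replicates, with the `(b + 1)/(B + 1)` convention so p is never zero.
The statistic depends on counts only through proportions and is exactly
scale-invariant; the Monte-Carlo null, however, conditions on a total
count (`null_total`, by default the rounded modelled grand total), so the
p-value is scale-invariant only given that total — a deliberate,
documented conditioning.  Categories: strong (p < 0.01), moderate
(0.01 <= p < 0.05), weak (0.05 <= p < 0.10), none (p >= 0.10); the test
is run three times with distinct seeds and the category of the *largest*
p-value is reported.  Detection power is a function of counts: a single
tripled area among 400 is essentially undetectable at ~10 expected cases
per area (the signal `(delta p)^2 ~ 4/n^2` sits far below the multinomial
noise floor `~1/N`) and detected with near-certainty at ~500 per area,
which is why the power tests simulate a common cancer, not a rare one.

## Visual encodings

The colour gradient is linear in `log(estimate)`, anchored at 1.5
(darkest red), `1/1.5 ~ 0.67` (darkest blue) and 1 (yellow, the national
average); positions clamp outside the anchors and satisfy
`pos(v) + pos(1/v) = 1`.  The default stops are a blue–yellow–red
diverging palette usable under most forms of colour blindness; exact hex
values are configurable — the *positions* are the contract.  The
uncertainty mask interpolates linearly between its two defining
endpoints, 0% opacity at DPP = 1 and 100% at DPP = 0; only the endpoints
are specified upstream, so the linear curve is a package decision exposed
as a hook.  V-plots pair each area's posterior median with its DPP; wave
plots are kernel densities of the log-ratio draws (Silverman bandwidth —
the upstream sources are silent) with ratio-scale tick labels and CrI
shading shared with the summary computation; regional summaries reduce
any labelled partition of areas (socioeconomic quintiles, remoteness,
states) to five-number summaries and colour-band percentages.

## The synthetic world

`generate_synthetic_inputs()` emulates the restricted registry inputs
with known truth: a 20 x 20 rook lattice plus 2 islands (402 areas — a
scale at which the full MCMC schedule runs in well under a minute),
uniform area populations of 50–400 per 5-year age band to 85+,
age-specific baseline rates rising log-linearly from 1e-5 to 8e-3 cases
per person-year (the span of most adult cancers), a Leroux field with
`rho = 0.8`, `sigma^2 = 0.2` (clearly spatial but not intrinsic), and a
survival cohort of 5,000 patients diagnosed uniformly over 2001–2014 with
background mortality 0.01/year and baseline excess hazard 0.08/year.
Survival deaths are drawn at *cell level* from the model's own Poisson
law (`d* + y e^lp`), which is exactly the stated generating process for
recovery tests but is not a coherent patient-level death process — cell
totals are not bounded by cohort size, and person-time is accrued as if
all patients were censored at the window end.  The generator also does
not emulate realistic population pyramids, registry coding errors, or
cancer-site-specific age profiles.  A green recovery test therefore
establishes that the samplers recover the stated data-generating process,
not that the pipeline is robust to real registry pathologies.

Exclusion fixtures reproduce the small-area filters (no population, no
physical location, under five average residents, very remote islands)
with mutually exclusive flags, since the published counts sum exactly to
the published remainder.

## Scope and limitations

Out of scope by design: the interactive web atlas itself, real national
geographies and registry extracts (restricted), BYM and other CAR
variants, INLA estimation, distance-decay or row-standardised weights,
local cluster detection (scan statistics), cure or spline baseline
survival models, cartograms and spatio-temporal extensions.  The
full 50-prior sensitivity study is represented by its hook
(`variance_prior`), not re-run.  Known limitations: polygon adjacency
assumes topologically clean inputs (shared boundaries represented by
collinear overlapping segments — typical of snapped national geographies
and exact for the lattice generator); the survival sampler's single-site
updates would mix slowly on very large graphs with near-intrinsic fields;
and Monte-Carlo p-values inherit the usual granularity of `(b+1)/(B+1)`.
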