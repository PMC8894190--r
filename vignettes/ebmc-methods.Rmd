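---
title: "Methods: sufficient-component causes, extreme values, and intrinsic mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sufficient-component causes, extreme values, and intrinsic mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmc)
```

## The model

`ebmc` implements an evolution-based development of the sufficient and
component causes (SCC) model for aging-related diseases and intrinsic
mortality. The ingredients:

* **Component causes** are genetic or environmental factors that express
  their necessary causal role at a random age, described by a time-to-event
  law. They fall into four evolutionary categories: early-onset genetic
  effects (EOGE) and late-onset genetic effects (LOGE), split at the earliest
  age of reproduction in the population (≈10 years, the age at which the
  force of natural selection starts to decline); and evolutionarily conserved
  (ECEF) versus evolutionarily recent (EREF) environmental factors, split by
  whether adaptation to the exposure has had time to occur.
* **A sufficient cause** is a minimal set of component causes; it completes
  at the **maximum** of its components' expression ages, so its cdf is the
  product of the component cdfs.
* **The population outcome** (first disease onset, or intrinsic death) occurs
  at the **minimum** completion age over sufficient causes; under
  independence its survival function is the product of the cause survival
  functions. Both constructions are the exact theory of extremes and are
  implemented by `max_cdf()`, `min_survival()` and
  `system_incidence_survival()`.

The four categories form 15 non-empty subsets, the 15 types of sufficient
causes (`enumerate_cause_types()`). Types containing only EOGE/ECEF express
before the aging phase and are excluded, leaving 12 retained types. The
remaining split is the model's central dichotomy (`classify_molding()`):
causes containing LOGE without EREF have timing laws **molded** by the
declining force of natural selection; causes containing EREF are **not
molded**. Molding is decided purely by category content — never by a fitted
distribution shape — because the dichotomy is a statement about evolutionary
exposure, not about data.

## Domains of attraction and the two mortality laws

For a large number of sufficient causes, the minimum construction has only
two possible non-degenerate limits for well-behaved initial laws:

* initial cdfs **flat** at the lower terminus (all derivatives zero) lead to
  the **Gompertz** law, hazard $h(x) = \lambda e^{\theta (x-a)}$ — the
  molded case;
* initial cdfs **regularly varying** at the terminus,
  $F(x) \sim c\,(x-a)^\rho$, lead to the **Weibull** law, hazard
  $h(x) = \alpha\gamma (x-a)^{\gamma-1}$ with $\gamma = \rho$ — the
  not-molded case.

`classify_domain()` diagnoses an initial law numerically and never guesses:
it requires *both* vanishing one-sided derivative estimates at the terminus
(`derivatives_at_terminus()`, forward differences with Richardson
step-halving, flatness threshold $10^{-6}$) *and* a diverging Karamata
slope (`karamata_index()`, the slope of $\log F(a+t)$ against $\log t$ on a
decreasing offset grid; divergence = slope above 50 and still increasing)
before returning the Gompertz domain; a finite stable slope returns the
Weibull domain with $\hat\rho$; anything else is `undetermined`. A useful
consequence checked in the tests: the Gompertz law *itself* is not flat at
its terminus ($F \approx \lambda(x-a)$), so used as an initial law it
classifies into the Weibull domain with $\hat\rho \approx 1$ — being a
limit and being in a domain of attraction are different properties.

The canonical flat family is $F(x) = \exp(-b/(x-a))$, the standard smooth
function with all derivatives vanishing at $a^+$; the model names the
property, not a family, so this is the package's choice and is documented as
such. Unimodal genetic timing laws default to a shifted lognormal (unimodal,
positive support, adequately heavy right tail). Threshold-exposure laws for
EREF use linear accrual at a random rate — the minimal model consistent
with "cumulative exposure reaches a possibly random threshold" — and are
documented as replaceable.

## Simulation, dependence, and truncation

Sufficient causes sharing a component are *not* independent; the analytic
product is exact only without sharing. `simulate_first_event()` is the only
honest path under sharing: each component is drawn once per individual and
its draw is reused by every cause containing it. The engine therefore
reports the sharing status in the analytic object's metadata rather than
pretending the product formula covers dependence. Simulated minima under
sharing stochastically dominate the independent-product prediction on the
shipped test systems; the test suite measures the gap instead of asserting a
universal sign.

All laws are left-truncated at the earliest reproduction age $a$ (default
10 y): analytic curves are renormalised so $S(a) = 1$, and simulated
individuals whose first event falls at or below $a$ are redrawn (the count
is reported). EREF components may express before $a$; their causes count
only when the *cause* completes after $a$, which the truncation convention
implements.

`convergence_to_limit()` draws minima by the exact inverse transform
$Q\!\left(1-(1-U)^{1/n}\right)$ — one uniform per replicate, distributed
identically to the minimum of $n$ draws — classifies the initial law, fits
the predicted limit family by maximum likelihood and reports the
Kolmogorov–Smirnov distance to the fitted limit.

### A numerical finding worth stating plainly

For the canonical flat family the fitted-Gompertz KS distance decreases in
the number of causes (the tests check monotonicity over
$n \in \{10, 30, 100, 300\}$) but the decrease is slow, of order
$1/\log n$: the acceptance suite measures KS ≈ 0.09 at $n = 100$ and a
direct sup-norm minimisation over all Gompertz parameters (no Monte-Carlo
noise) bounds the attainable distance below by ≈ 0.05 at $n = 100$,
independently of $b$ (a change of variables $s = b/(x-a)$ makes the minimum
law $b$-free). Slow logarithmic rates are classical for limits of this
(Gumbel) type. The acceptance suite asserts a 0.02 tolerance at $n = 100$
for this family and that assertion fails; we report the measured distances
rather than adjusting the experiment to pass.

## Censored likelihood and the survival mixture

Intrinsic mortality in a population containing both molded and not-molded
sufficient causes is modelled as a mixture of **survival functions**,
$S(x) = p\,S_G(x) + (1-p)\,S_W(x)$: a Gompertz fraction $p$ (deaths through
molded causes) and a Weibull fraction $1-p$ (deaths through EREF-containing
causes). This is a mixture of divergent subpopulations, taken literally, not
a mixture of hazards.

`fit_mortality()` maximises the censored log-likelihood
$\sum_{\text{events}} \log f(t_i) + \sum_{\text{censored}} \log S(t_i)
- \sum_i \log S(e_i)$ (the last term the left-truncation correction) with
exact analytic densities. Numerical choices:

* unconstrained optimisation scale: log for positive parameters, logit for
  $p$; BFGS with multi-start;
* starting values are moment-matched profiles — for a Gompertz the event-age
  spread is $\approx (\pi/\sqrt 6)/\theta$ and for a Weibull the log-age
  spread is $\approx (\pi/\sqrt 6)/\gamma$, so the shape grids scale with
  the data (fixed grids fail badly when fitting the narrow minima
  distributions of the convergence experiments); the other parameter is
  profiled in closed form;
* the mixture adds split-sample starts (each component fitted to one half
  of the event-time range, both assignments), which removes the label-swap
  local optimum observed in pilot runs; jittered restarts are log-normal
  around the bases and fully seeded;
* the terminus is fixed at the earliest reproduction age by default (an
  evolutionary constant, not an estimand); `free_terminus = TRUE` profiles
  it for sensitivity analysis;
* standard errors come from the observed information on the transformed
  scale, delta-method mapped back; a mixture weight outside $(0.02, 0.98)$
  is flagged as effectively degenerate;
* the mixture is label-free structurally: the Gompertz component is the one
  with the exponential hazard, so no relabelling ambiguity exists.

## Healthy-aging scenarios

`apply_scenario()` evaluates morbidity (first disease onset) and mortality
survival curves before and after an intervention on a common age grid
(default 10–110 y, step 0.1 y, trapezoidal quadrature with a step-halving
error bound):

* **health promotion** reduces the Weibull weight $1-p$ of each curve by a
  factor $1-r$ (primary prevention removes EREF-containing causes);
  $r = 1$ yields the pure-Gompertz "rectangularized" curve;
* **postponed aging** rescales $\theta$ and/or delays the whole intrinsic
  schedule by a fixed number of years on both curves equally. The delay is
  implemented as a shift of the terminus of *both* mixture components — a
  pure translation of each curve. Shifting only the Gompertz component
  cannot leave the unhealthy-years area invariant when the two curves have
  different weights, and the equal-shift scenario is defined by that
  invariance; translation realises it exactly (up to horizon truncation,
  < 0.01 y on the default grid);
* **combined** composes the two.

Summaries: life expectancy $LE = a + \int S_{\text{mortality}}$, healthy
life expectancy $HLE = a + \int S_{\text{morbidity}}$, unhealthy years
$LE - HLE$ (the area between the curves; conservation is exact because the
same quadrature is used), and rectangularity (event-age IQR and survival
slope at the median). The morbidity ≤ mortality pointwise ordering is
validated, not enforced; violations flag the output.

The curve parameters behind published scenario figures of this kind are not
available, so the package ships a documented default
(`default_scenario()`): terminus 10 y, horizon 110 y, mortality mixture
$p = 0.8$, Gompertz $(\lambda = 4\times10^{-5}, \theta = 0.1)$, Weibull
$(\alpha = 7.2\times10^{-10}, \gamma = 5)$, chosen once so the baseline
life expectancy is ≈ 80 y; morbidity uses the same weights with the Gompertz
component ≈ 6 y earlier and the Weibull component ≈ 12 y earlier, reflecting
the longer morbid period of lifestyle-driven disease. All scenario claims
are treated as **ordering** properties on this config — LE up and unhealthy
years down under health promotion; LE up and unhealthy years unchanged under
an equal shift; combined gains at least each single gain — never as value
reproductions.

## What the synthetic data does and does not emulate

`generate_system()` draws causal systems with category-appropriate laws
(LOGE: shifted lognormal above the terminus; EREF: threshold exposure;
EOGE/ECEF: early-support gamma/uniform-type laws) and realises sharing by
component reuse with a configurable probability. `generate_cohort()`
emulates a long mortality follow-up: intrinsic ages from a causal system or
a parametric mixture (with latent component labels carried through),
optional extrinsic deaths from a constant hazard started at the terminus
(the Makeham partition as a *label*, not an estimand, so intrinsic-only
analyses can filter), administrative and/or random censoring, and optional
left-truncated adult entry with a fixed follow-up window (default 43 y).

Passing tests on these cohorts show that the estimators recover the
generating process under the model's own assumptions — independent
competing risks, exact parametric forms, homogeneous cohorts. Real mortality
data violate all three (secular trends, frailty heterogeneity, a late-life
hazard plateau above ~90 y that the Gompertz deliberately does not model),
so recovery here bounds what the machinery can do, not what any particular
data set will show.

## Problem sizes and experiment settings

The shipped experiments use: $10^5$ individuals for analytic-vs-simulation
equivalence (KS tolerance 0.01, sampling floor ≈ 0.004); $10^4$ replicates
for minima convergence; 20 replicates of $2\times10^4$-person cohorts with
≈10% administrative censoring (at age 75, which the mixture's own survival
puts at exactly the 10% quantile) for mixture recovery, where the mean
$\hat p$ lands within 0.005 of the generating 0.7. These sizes put
Monte-Carlo noise well below every tolerance asserted while keeping the
whole suite in the tens of minutes on one core.

## Known limitations

* The analytic incidence path ignores sharing-induced dependence by
  construction (metadata says so); only simulation honours it.
* No late-life mortality plateau, no covariates, no Bayesian fitting, no
  multi-state (healthy → ill → dead) transitions, and no period/cohort
  life-table corrections.
* The threshold-exposure cdf/pdf use a deterministic quantile-grid
  quadrature (64 nodes per random ingredient; max error against $10^5$-draw
  Monte-Carlo ≈ 0.003 in the tests); exact for degenerate ingredients.
* `undetermined` is a real output of `classify_domain()` for laws near the
  flat/regular-variation boundary; downstream convergence fitting then
  reports both candidate limits rather than choosing.
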