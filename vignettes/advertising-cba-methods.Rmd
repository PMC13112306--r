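---
title: "Methods: cost-benefit analysis of outdoor unhealthy food advertising restrictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-benefit analysis of outdoor unhealthy food advertising restrictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msltcba)
```

## What the package models

`msltcba` evaluates, from a societal perspective, a policy that removes
unhealthy food and drink advertising from state-owned public transport
assets.  The causal chain is: less advertising exposure → a relative
reduction in unhealthy-food energy purchased → lower daily energy intake
→ lower body weight and BMI → lower incidence of obesity-related chronic
disease → health-adjusted life years (HALYs) gained and healthcare costs
avoided.  Benefits are monetised and set against the costs of developing,
monitoring and operating the policy, including foregone advertising
revenue for government and profit for outdoor advertisers, yielding a net
present value (NPV) and a benefit–cost ratio (BCR) over a 30-year
horizon at a 7 % real discount rate.

All inputs are synthetic.  The generator (`generate_inputs()`) emulates
the stratified tables such an analysis would normally extract from
population health surveys and administrative data, at Greater-Perth scale
(≈ 2.1 million people aged 2+), with known ground truth so that every
downstream stage can be tested for parameter recovery.  Realism of
magnitudes is explicitly *not* a claim: counts, rates, consumption and
revenue levels are plausible but invented, so the package's outputs
characterise the *method*, not Western Australia.

## Intervention effect pathway

The anchor effect size is the evaluated effect of the Transport for
London advertising restriction: a relative change of −6.7 %
(95 % CI −10.1 to −3.2) in weekly household energy purchased from
unhealthy foods.  Context differences are handled as multiplicative
*effectiveness adjustments*: each adjustment $a_i \in [0,1]$ scales the
effect by $(1-a_i)$,

$$\Delta_{\text{adj}} = \Delta \prod_i (1 - a_i),$$

which is order-independent.  The primary configuration carries one
adjustment, $a = 0.20$, for the lower weekly out-of-home advertising
exposure of Australian capital-city populations; a coverage adjustment of
$0.90 \times 0.20 = 0.18$ (comparator bus-shelter coverage × the
one-fifth share of media assets that are shelters) is available for the
corresponding sensitivity scenario.

The adjusted effect applies 1:1 to per-stratum unhealthy-food
consumption (purchasing is equated with intake; no household-size or
waste correction, and no substitution towards other foods — the
comparator evaluation found no significant spillover).  Energy changes
convert to steady-state weight changes with a linear energy-balance
rule, $\Delta w = \Delta E / \varepsilon$:

* adults (18+): $\varepsilon = 94$ kJ/day per kg, the widely used
  steady-state approximation for adult energy imbalance;
* children: $\varepsilon = 420$ kJ/day per kg of growth-adjusted change,
  a deliberately conservative placeholder for age-specific paediatric
  equations; both constants are configurable
  (`default_config(epsilon_adult=, epsilon_child=)`), so a different
  validated equation can be swapped in without touching the pipeline.

The weight change is realised at the end of year 1 and maintained for
the full horizon (no regain).  BMI change is
$\Delta b = \Delta w / h^2$ with the stratum's mean height $h$.

## Potential impact fractions

Each stratum's BMI is modelled as $B \sim \mathcal N(\mu, \sigma^2)$ with
a log-linear relative risk above a theoretical minimum-risk exposure
level $\tau$ (TMREL, default 21 kg/m²):
$RR(x) = \rho^{\max(0,\,x-\tau)}$, where $\rho$ is the relative risk per
BMI unit.  The potential impact fraction for a mean shift $\delta$ is

$$\mathrm{PIF} = 1 -
  \frac{\mathbb E[RR(B + \delta)]}{\mathbb E[RR(B)]}.$$

The expectation has an exact closed form (split the integral at $\tau$
and complete the square in the normal density):

$$\mathbb E\!\left[\rho^{\max(0,B-\tau)}\right]
 = \Phi\!\left(\tfrac{\tau-\mu}{\sigma}\right)
 + e^{\beta(\mu-\tau)+\beta^2\sigma^2/2}\,
   \Phi\!\left(\tfrac{\mu-\tau}{\sigma}+\beta\sigma\right),
 \qquad \beta = \log\rho.$$

`compute_pif()` uses this analytic form by default; a
`method = "quadrature"` route via adaptive numerical integration is kept
for cross-checking (the two agree to well below 1e-6 in the tests, and
both agree with a large-sample simulation).  $\sigma = 0$ degenerates to
the point-mass form $1 - RR(x+\delta)/RR(x)$.  PIFs use each cohort's
baseline (year-0) BMI distribution and are held constant over the
horizon; intervention incidence is $i' = i \times (1-\mathrm{PIF})$.

## The proportional multi-state lifetable

Each of the 40 (age band × sex) strata is a closed cohort — no births or
migration — simulated with annual cycles over the horizon; cohorts age
one year per cycle and adopt the rates of the 5-year band they currently
occupy (capped at the oldest band, 95–99).  Ten disease states are run
in parallel (nine diseases, with osteoarthritis split into hip and knee;
a merged mode exists): type 2 diabetes, hypertensive heart disease,
ischaemic heart disease, stroke, the two osteoarthritis sites, and
kidney, colorectal, endometrial and breast cancers.  Endometrial and
breast cancer have zero incidence in males in this model.

Within a cycle, with prevalence $p_d$, incidence $i_d$, case fatality
$f_d$ and remission $r_d$:

* disease-$d$ mortality removes a fraction $p_d f_d$ of the cohort;
* other-cause mortality is the decomposition remainder
  $m_{oc} = m_{acm} - \sum_d p_d f_d$ (an error is raised, naming the
  stratum and year, if modelled disease mortality exceeds all-cause
  mortality);
* survivors update prevalence by
  $$p_d' = \frac{p_d(1-f_d-r_d) + (1-p_d)\,i_d}{1 - p_d f_d},$$
  i.e. onset occurs among the healthy, case fatality and remission among
  the prevalent (new cases are exempt in their onset year), and the
  proportion is renormalised to survivors of the disease's own
  mortality; deaths from other causes and other diseases strike the
  diseased and healthy proportionally (the proportional-model
  assumption), so they cancel from the proportion.

The intervention arm reuses the *baseline* arm's $m_{oc}$ each year, so
incidence reductions propagate into total mortality.  Disease-specific
relative risks act on incidence only (a documented simplification; no
direct mortality effect), and no latency lag is applied to the cancers.

Accounting conventions, chosen so that hand and brute-force oracles are
exact: person-years in year $t$ are the survivors at the end of the
cycle; HALYs weight person-years by
$1 - \min\!\big(1, \sum_d p_d\,w_d\big)$ with disability weights $w_d$
combined additively and capped at 1 (a multiplicative option exists);
healthcare costs are $\sum_d p_d \times \text{alive} \times c_d$ with
per-case annual costs $c_d$.  Streams discount with the end-of-year
convention, $\sum_t x_t/(1+r)^t$, $t = 1..T$; year-0 entries (up-front
costs) are undiscounted; no half-cycle correction is applied.  Outcomes
are truncated at the horizon — no tail HALYs for cases incident within
it.  A zero BMI change short-circuits nothing: both arms run, and the
trajectories are bit-identical, which the tests assert.

## Costing model

Wages are loaded as
$w \times (1 + \text{oncosts}) \times (1 + \text{leave loading} \times 4/52)$
with 14 % salary oncosts and 17.5 % annual leave loading applied to four
weeks of annual leave (the standard Australian annual-leave entitlement;
the loading base is configurable).  Government costs comprise policy
development (FTE-years at loaded wages, year 0), monitoring (the larger
of half the national-scheme monitoring cost and one loaded full-time
compliance officer, years 1–30) and advertising revenue loss: the PTA
(public transport authority) component is food-and-drink advertising
income times the 55 % unhealthy share; the Main Roads (billboard)
component has no direct revenue input and is imputed as
$\text{PTA loss} \times 0.58/(1-0.58)$ from the 58 % billboard share of
out-of-home advertising — reconstructing a billboard:non-billboard
ratio — and can be overridden with a direct dollar amount
(`main_roads_revenue_loss`).  Industry costs are the advertiser's
national transport revenue × 7 % state concentration × 21 % unhealthy
advertising share × 13 % profit margin, annually.  Profit losses of food
manufacturers and early contract-termination costs are out of scope.
All amounts are 2019 A$; no CPI engine is included.

Benefits are HALYs gained × VSLY (value of a statistical life year,
A$213,000; A$314,772 in the contemporary-estimate scenario) plus
healthcare cost savings.  NPV = benefits − costs; BCR = benefits /
costs; when healthcare savings alone exceed total costs the result is
flagged *dominant*.  These identities are asserted exactly, per draw.

## Uncertainty analysis

`run_monte_carlo()` reruns the deterministic pipeline under 2000
parameter draws.  Default distributions: the effect size is normal with
the mean at −6.7 % and the standard deviation recovered from its CI,
$(\text{hi}-\text{lo})/(2 \times 1.959964)$; revenue, monitoring-cost,
consumption-scale and unit-cost-scale parameters take a Pert
distribution at ±25 % around the mean (classic Pert, Beta
reparameterisation with shape $\lambda = 4$); the VSLY is fixed.  Draws
across parameters are independent (no correlation structure is
specified for these inputs), and each parameter owns an RNG stream
derived from the master seed, so adding a parameter leaves the others'
draws untouched.  Uncertainty intervals are empirical 2.5th–97.5th
percentiles with linear interpolation between order statistics
(`quantile(type = 7)`), making summaries bit-reproducible under a fixed
seed.  A run aborts if more than 0.1 % of draws raise model errors.

## Scenarios

`build_scenario()` records only the deltas from the primary analysis:

| id | delta |
|----|-------|
| s1 | 10-year horizon (the alternative-horizon scenario states no value; 10 years is this package's assumption) |
| s2 | 4-year horizon |
| s3 | extra 18 % effectiveness reduction (bus-shelter coverage) |
| s4 | no effectiveness adjustments |
| s5 | effect restricted to the categories with statistically significant changes (chocolate and confectionery; puddings and biscuits).  The comparator evaluation's per-category estimates are not published in the source text, so the overall effect size is applied to those categories as a stand-in; per-category values are configurable |
| s6 | VSLY A$314,772 |
| s7 | + legislation cost A$1,306,180 (year 0) |
| s8 | no government revenue loss, no industry profit loss |
| s9 | full advertising replacement from year 2 (replacement fraction configurable) |
| s10 | phase-in after 10 years: development cost at year 10, recurring costs years 11–30, health effects from cycle 12 |

Expected orderings on any positive-effect bundle — BCR(s4) ≥
BCR(primary) ≥ BCR(s3), BCR(s2) < BCR(primary), costs(s8) <
costs(primary), benefits(s10) < benefits(primary) — are asserted in the
test suite.

## What the synthetic generator does and does not emulate

It reproduces the *structure* of the real inputs: 5-year age bands from
2 to 100 (the first band three years wide) by sex; Gompertz-type
all-cause mortality, non-decreasing with age above 35; heights and BMI
means rising through childhood to adult levels; disease incidence with
exponential age gradients, case fatality tied to a share of all-cause
mortality (which also guarantees a positive other-cause remainder),
remission zero except a 5-year "cured" convention (0.2/year) for
cancers; five unhealthy food categories that partition consumption.  It
does not emulate survey microdata, nutrient mapping, socioeconomic
gradients, secular trends in any rate, or correlated uncertainty between
strata.  Green tests therefore demonstrate the correctness of the
machinery and the internal consistency of the accounting — not the
magnitude of benefits a real population would experience.

## Problem sizes and numerical choices

The shipped configuration runs 40 strata × 10 diseases × 30 annual
cycles, twice (baseline and intervention) per evaluation, and 2000
Monte Carlo iterations in the uncertainty analysis; a full
2000-draw primary analysis takes on the order of half a minute on one
core.  Tolerances: the lifetable must match an independently coded
brute-force recursion to 1e-9 on small cases; analytic and quadrature
PIFs agree to 1e-6; conservation of persons (alive + cumulative deaths =
initial cohort) holds to 1e-9 relative.  Ties and degenerate inputs:
`bmi_sd = 0` uses the point-mass PIF; zero total cost yields an
undefined BCR, reported as infinite with `bcr_defined = FALSE`; an empty
cost ledger is an error.

## Known limitations

Beyond-BMI pathways (sugar, salt, saturated fat as independent risk
factors), productivity impacts, social-norm dynamics and equity
stratification are out of scope.  The child energy-to-weight constant is
a placeholder by design.  PIFs held at baseline BMI distributions ignore
the drift of a cohort's BMI as it ages across bands; disease risk
reductions are incidence-only.  The BCR reported from unrounded
internals will differ slightly from a ratio of independently rounded
headline numbers — e.g. benefit and cost totals quoted in whole millions
— which is documented behaviour, not error.
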