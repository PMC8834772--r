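---
title: "Projecting cancer burden with Bayesian age-period-cohort models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting cancer burden with Bayesian age-period-cohort models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model and its
assumptions, the conventions that resolve the APC identifiability
problem, the parameters that matter and their defaults, what the
synthetic-registry generator does and does not emulate, and the design
choices that were genuinely open.

## The estimation problem

A population-based cancer registry publishes, for a region, annual counts
of incident cases (or deaths) in 5-year age bands, together with the
person-years at risk. The task is threefold: (i) smooth and explain the
observed rate surface in terms of age, calendar period and birth cohort;
(ii) project counts and rates one to two decades ahead with honest
uncertainty; (iii) attribute the resulting change in case numbers to
changes in risk versus changes in the size and age structure of the
population. Ovarian cancer in women aged 45 and over is the motivating
application — event counts of a few hundred per year across nine age
bands — but nothing in the package is specific to that site.

## Model

Counts are Poisson with a person-years offset:

$$y_{ap} \sim \mathrm{Poisson}(n_{ap}\,\lambda_{ap}), \qquad
\log \lambda_{ap} = \mu + \alpha_a + \beta_p + \gamma_{c(a,p)}$$

* `a` indexes 5-year age bands (the open-ended top band is treated as one
  5-year step wide where a midpoint is needed);
* `p` indexes annual calendar years, observed plus projected;
* `c` indexes birth cohorts on a 5-year grid. A cell's birth year is its
  calendar year minus the floored band midpoint (band [45,50) has
  midpoint 47), and cohorts are the enclosing `[5k, 5k+5)` birth-year
  buckets. With this rule a cell one band older and five years later
  belongs to the same cohort, and the bucket sequence over the full
  lattice is contiguous — both properties are unit-tested.

Priors encode smoothness and trend persistence:

* `alpha`: second-order random walk — the age curve is smooth but free in
  level and slope;
* `beta`: first-order random walk **with drift** — the drift is the
  calendar trend, and it is what carries the decline (or rise) forward
  into projection years;
* `gamma`: first-order random walk without drift — generational
  deviations persist but have no built-in direction, since any linear
  cohort trend is not separable from the period drift anyway (next
  section);
* innovation standard deviations: half-normal priors with scales
  `sd_age = 1` (per squared 5-year band step), `sd_period = 0.05` per
  year and `sd_cohort = 0.2` per 5-year cohort step. On the log-rate
  scale these allow, respectively, visible curvature in the age profile,
  annual period wobble of a few percent around the drift, and
  generational excursions of up to tens of percent — generous for
  registry series of this size while still regularising;
* `mu` and the drift get diffuse normal priors (SD 10 and 1).

Inference is MCMC through JAGS (`rjags`), with the `glm` module loaded
for its block samplers. Defaults: 2 chains, 2000 adaptation and 3000
burn-in iterations, 60,000 sampling iterations thinned by 30 (4000
retained draws). These lengths are deliberately generous: the innovation
SDs sit near the boundary when the true surface is close to log-linear,
and shorter runs occasionally leave their split-$\widehat{R}$ just above
threshold. A full 9-band x 24-year fit takes on the order of one to two
minutes on a single CPU.

## Identifiability

Because `c = p - a`, the transformation
$\alpha_a \mathrel{+}= t\,a$, $\beta_p \mathrel{-}= t\,p$,
$\gamma_c \mathrel{+}= t\,c$ leaves every fitted rate unchanged: the
shared linear trend has no unique home, and the three levels likewise
trade against the intercept. The sampler is run unconstrained (the random
walk priors keep it proper), and a fixed convention is applied to every
draw afterwards:

1. the OLS slope of `gamma` over the observed cohorts is set to zero,
   with the slope re-allocated to the period axis (and the matching
   `-t*a` term to the age axis) — "net drift to period";
2. `alpha`, `beta`, `gamma` are centred to mean zero over the full band
   list, the observed years and the observed cohorts respectively, with
   constants absorbed into `mu`.

Fitted and projected rates never pass through this convention — they are
computed from the raw draws and are invariant by construction. The
convention only determines how effect curves are displayed and how
parameter-recovery tests compare fit against truth. On the bucketed
cohort grid the slope transfer is exact only up to the bucket rounding
residual; the same canonicalisation code is shared by the truth generator
and the fit post-processing, so comparisons are like-for-like.
Convergence diagnostics (rank-normalised split-$\widehat{R}$, flagged
above 1.01, and effective sample sizes) are computed on identifiable
quantities — the canonical effects, the innovation SDs and a spread of
fitted cell log-rates — not on the raw levels or the raw drift, which mix
slowly along the flat direction without affecting anything reported.

## Projection and prediction intervals

Future `beta` and `gamma` are additional nodes of their random walks, so
the sampler draws them from the prior dynamics (drift plus innovation
noise) conditional on everything observed. Posterior-predictive counts
are Poisson draws around each draw's rate surface times the supplied
person-years; intervals are central quantiles of those draws. This
captures all three uncertainty sources — parameters, future trend, and
Poisson sampling — and is why the intervals widen with the horizon.
Predictive sampling is seeded separately from the chains, so a fit is
reproducible draw-for-draw given its seed.

## Rates, trends, burden, decomposition

Age-standardised rates use standard-population weights renormalised over
the included bands (default truncation at age 45), which makes the ASR of
a constant-rate surface exactly that constant under any standard. The
2013 European Standard Population is the default, with the 1976 revision
bundled as an alternative; which revision a given published table used is
often unstated, so it is a configuration choice, not a fixed fact.

AAPC is provided in two forms: endpoint-geometric
(`100((r_to/r_from)^(1/(to-from)) - 1)`) and log-linear regression over
the span. They agree exactly on exponential series; on wiggly series the
regression form is less sensitive to endpoint noise. The endpoint form is
the default because published two-point comparisons (one reference year,
one horizon year) imply it.

The Bashir–Esteve decomposition splits the net change in expected cases
between a baseline and a final year into size, ageing and risk
components via a counterfactual ladder — baseline rates with baseline
structure scaled to final total (size), baseline rates with the final
population (ageing, given size), final rates with the final population
(risk, given both). All three are expressed relative to baseline cases,
so additivity `NC = A + R|A + S|A` holds exactly, and the published
arithmetic of the motivating study (−21.8 = −34.6 + 12 + 0.8) is
recovered by the same additivity. Components are point partitions;
no uncertainty is propagated through the decomposition.

Burden tables report counts, row percentages, totals, net change and
ASRs at the conventional display precisions (integers; 1 d.p.; 2 d.p.
for net change), always alongside a full-precision companion. One
caveat found while validating against published tables: row percentages
printed in publications are typically computed from unrounded model
estimates, so recomputing them from the printed integer counts can
differ by 0.1 of a point in a few cells.

## The synthetic registry generator

`scenario_config()` defines a noiseless APC truth (age curve, log-linear
period drift per year, log-linear cohort drift per 5-year bucket, an
optional Gaussian log-RR cohort bump) and a demographic trajectory
(baseline person-years per band, multiplicative annual growth, a
log-linear tilt that moves person-years toward older bands).
`sample_counts()` adds independent Poisson noise. The bundled
`catalonia_like_scenario()` fixes: nine bands 45-49..85+, years
1994–2030 with 1994–2017 observed; an age curve rising from 12 to about
38 per 100,000 with a plateau in the oldest bands; period drift −0.012
per year and cohort drift −0.05 per bucket (a decline of roughly 2% per
year in net); a +0.3 log-RR bump centred on cohorts born around 1985
(width 6 years); baseline person-years 55,000–245,000 per band with 0.4%
annual growth and a mild ageing tilt. These values were chosen once to
reproduce the qualitative shape of the motivating registry series —
yearly event totals of a few hundred, a declining truncated ASR in the
low twenties per 100,000, a net 2015→2030 decrease driven by the risk
component with ageing pushing the other way — and are versioned as part
of the package.

What the generator does **not** emulate: registry reporting artefacts
(delay, completeness, duplicate resolution), within-band age structure,
overdispersion beyond Poisson, and any dependence between incidence and
mortality. Passing tests on synthetic data therefore demonstrate that
the machinery recovers a truth of the assumed form at realistic size and
noise — not that real registry series satisfy those assumptions.

A note on the cohort bump and the reporting convention: a bump placed
near the edge of the observed cohort window contributes to the estimated
cohort slope, and the zero-slope convention then tilts the displayed
curve, which can move its maximum by one bucket. Detection tests
therefore use a window in which the bump cohorts are well inside the
observed range. In the Catalonia-like window itself, cohorts born in the
1980s are barely observed above age 45 before 2017 — their generated
excess shows up in the truth and in projections, which mirrors how
recent-cohort claims in real APC analyses lean on extrapolation.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle where
one exists (elementwise rate arithmetic, dot-product ASR, hand-coded
two-band counterfactuals, closed-form AAPC) and by simulation where not:

* parameter recovery on the full Catalonia-like scenario (9 bands, 24
  observed years, about 350 events/year), requiring at least 90% of
  canonical effect coordinates inside their 95% credible intervals;
* prediction-interval calibration over 200 replicates of a reduced
  scenario (4 bands, 12 observed + 3 projected years, short chains),
  requiring pooled coverage of the 95% count intervals between 91% and
  99%;
* a flat-surface oracle (constant rates, large person-years) in which
  posterior median rates must match the analytic events/person-years
  estimate and all relative risks must stay within 7% of unity;
* monotone error decay: centred-effect RMSE must fall as person-years
  grow 10-fold, twice.

The reduced sizes keep the full suite within a few minutes on one CPU;
they are stated here so results are read at the scale they were computed.

## Open choices, resolved

* **Incidence and mortality are fitted independently.** Nothing in the
  aggregated tables identifies their joint structure; a shared model
  would import assumptions the data cannot check.
* **Top modelling band**: 85+ by default; the band list is entirely
  user-controlled.
* **Under-45 events** are excluded from APC modelling (rates are very low
  and the cohort grid would be dominated by sparse young cells) but can
  be carried into burden tables by a year-only log-linear Poisson trend
  (`report_under45()`), clearly separated from the APC machinery.
* **Reference years inside the observed range** (e.g. a 2015 baseline
  with data through 2017) are reported as the model's fitted values, not
  raw observations — consistent with how published "estimates" for such
  years are produced.
* **Zero person-years** are an error, never imputed. All-zero count
  tables are rejected rather than fitted.

## Limitations

Single-region, single-outcome Poisson modelling only: no spatial
structure, no overdispersion family, no joint incidence-mortality or
incidence-survival coupling, no model comparison across prior families.
The decomposition is a point partition. Projections inherit the
random-walk-with-drift assumption; a genuine structural break after the
observed window (as, for instance, a new screening programme would
cause) is exactly what such a model cannot anticipate.
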