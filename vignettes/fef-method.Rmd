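---
title: "The future excess fraction method: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The future excess fraction method: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fefburden)
```

## The problem and the model

Burden-of-disease work usually asks: *of the disease cases occurring this
year, what fraction is attributable to past exposure?* That is the
attributable fraction (AF), and it needs historical exposure data that often
do not exist. The future excess fraction (FEF) asks the forward-looking
question instead: *of all the disease cases that the people alive today will
ever develop, what fraction will occur in those exposed to the agent this
year, because of that exposure?* Only a current (index-year) exposure
prevalence and a relative risk are needed, plus the demographic and registry
rates required to project the cohort forward.

`fefburden` implements this as a virtual-cohort calculation:

1. **Cohort.** The population of interest is enumerated at the index year
   (t = 0) by sex and closed integer age bands, with counts $N_p$ and an
   exposure prevalence giving $N_e$ exposed and $N_u = N_p - N_e$ unexposed.
   Only exposure *in the index year* counts; people exposed in the past but
   not now are unexposed by definition.
2. **Person-years at risk (PYAR).** A life table built from age-specific
   all-cause mortality (single decrement), optionally combined with
   first-diagnosis incidence as a competing exit (double decrement,
   appropriate when the disease is an absorbing state), gives the
   probability of still being at risk at each future age. The baseline
   population is pushed along the Lexis diagonal to yield person-years per
   baseline band and future estimation interval.
3. **Expected cases.** Projected age-specific incidence rates at each
   interval midpoint are multiplied by the person-years in the matching
   cell and summed: $D_{ij}$ and their grand total $FN_p$.
4. **Lifetime risk.** $LR_p = FN_p / N_p$, the person-years formulation of
   lifetime risk (expected future cases per cohort member).
5. **Excess risk.** Under the assumption that the lifetime-risk ratio in
   exposed vs unexposed equals the relative risk $RR \ge 1$,
   $$LR_u = \frac{LR_p\,N_p}{N_u + N_e\,RR}, \qquad LR_x = LR_u\,(RR-1).$$
   $LR_u$ is back-solved rather than approximated by $LR_p$ because for
   high-prevalence or high-RR agents the two differ materially.
6. **Burden.** $FEN = LR_x \times N_e$ and $FEF = FEN / FN_p$.

Two useful identities follow directly from the algebra and serve as strong
correctness checks (both are tested to near machine precision):

* For a one-stratum cohort with uniform prevalence $p$, the FEF collapses to
  Levin's formula $p(RR-1)/(1+p(RR-1))$ — regardless of the rate schedules,
  which cancel.
* As $p \to 0$, $LR_u \to LR_p$ and $LR_x \to LR_p(RR-1)$.

## Conventions the sources leave open

Several numerical conventions are not dictated by the method itself; the
package fixes them as follows.

* **Rates to probabilities.** Input age-specific rates are constant hazards
  within each single year of age. The annual exit probability is
  $1 - e^{-(h_\text{death}+h_\text{disease})}$, which combines competing
  risks coherently.
* **Within-year person-years.** A person at risk at the start of a year
  with exit hazard $h > 0$ contributes $(1-e^{-h})/h$ person-years that
  year (the exponential person-year integral), or a full year when $h = 0$.
* **Cohort aging and attribution.** PYAR rows are indexed by the *baseline*
  band; rate lookups use the *attained* age, band counts being spread
  uniformly over the band's single-year ages. The alternative (attained-age
  rows) is internally consistent too; we expose one convention and document
  it.
* **Censoring.** Everyone is administratively censored at `max_age`
  (default 100) or at the end of the configured horizon, whichever comes
  first. Because `max_age` is also the survival table's upper bound, a
  horizon reaching past the table is handled by censoring, not by error; a
  coverage error is raised only when a *baseline* age is outside the table.
* **Cumulative risk.** The registry-style cumulative risk sums incidence
  rates over single years of age up to the upper limit. We report the raw
  sum, the transform $1-e^{-\text{sum}}$, and "1 in n" from the raw sum
  (the common registry convention). It ignores competing mortality and so
  over-states the lifetime risk — a relation the tests assert.
* **Projection.** Two projectors are provided and chosen explicitly in
  configuration: `constant` (index-year rates applied to all intervals) and
  `loglinear` (band intercepts plus a shared annual drift fitted to a
  historical series by least squares on log rates, evaluated at interval
  midpoints). Decision-tree model selection among richer age–period–cohort
  projectors is deliberately out of scope; the method is projector-agnostic.
  Zero historical rates are replaced, for fitting only, by half the smallest
  positive rate in the series; an all-zero band is an error. Fewer than
  three distinct years falls back to `constant` with a warning.
* **Rounding.** $N_e = N_p \times$ prevalence is kept as a real number
  internally; counts are rounded only in the human-readable report
  (fractions to 3 decimals, risks to 2 significant figures in percent,
  counts to integers). Full-precision CSVs are written alongside.
* **RR bounds.** $RR = 1$ is allowed and yields zero burden; $RR < 1$ is
  rejected with an explicit message, because the excess-risk equation only
  holds for RR above 1.

## Sensitivity semantics

`fef_sensitivity()` perturbs one of five inputs multiplicatively and reruns
the pipeline. Two interpretations deserve a note:

* *Future incident cases* means scaling the projected rates (hence $D_{ij}$
  linearly), not the decrement table — which is why $LR_p$, $LR_x$ and
  $FEN$ respond exactly proportionally while $FEF$ is unchanged.
* *Population* scales the cohort denominators $N_p$ (and $N_u$) used in the
  lifetime-risk and excess-risk steps while the exposed count and the
  expected case numbers stay at baseline. This treats projected cases as an
  independent data input, which is the only reading under which a larger
  population *dilutes* $LR_x$, $FEN$ and $FEF$ — the observed behaviour of
  the method; if PYAR were rescaled too, $FN_p$ would rise with $N_p$ and
  the excess outputs would move the other way.

Default multipliers are $\{0.5, 0.9, 1, 1.1, 2\}$; the perturbation sizes
are reporting choices, not model parameters.

## The synthetic generator and the microsimulation oracle

`generate_scenario()` produces a complete, seed-reproducible input bundle:
a working-age population (bands 18–19, 20–24, …, 60–64 by sex, with mild
lognormal count noise), Gompertz all-cause mortality
$a\,e^{b\,\text{age}}$, power-law never-exposed incidence
$c\,(\text{age}/70)^k$, a uniform index-year exposure prevalence per sex,
and a known RR. The *observed* incidence handed to the pipeline is the
mixed-population rate $h_u(1 + p(RR-1))$ — what a registry would record.
Defaults emulate an Australia-2012-like asbestos/mesothelioma setting:
prevalences 0.0347 (male) and 0.0004 (female), index year 2012, 5-year
intervals, follow-up to 2094, censoring at 100. The default $RR = 14$ and
incidence scales ($6\times10^{-5}$, $3.4\times10^{-5}$ at the age-70
reference) were calibrated once so the default scenario's outputs sit at
the published order of magnitude (lifetime risks near 33 and 15 per 10,000;
a male FEF near a third); they are conditions of the simulated world, not
tuning knobs.

`microsimulate()` is the independent oracle: individuals are sampled iid
(sex/age from the population weights, exposure Bernoulli), and exit times
are drawn *exactly* from the piecewise-exponential distribution on annual
hazard pieces, with death and first diagnosis competing and diagnosis
absorbing; the exposed carry $RR \times$ the incidence hazard for life.
Because simulation and life table share the annual constant-hazard
convention, discretisation error cancels and disagreement isolates real
defects. Validation compares per-person PYAR, lifetime case risk and the
FEN (exposed cases beyond the unexposed-rate expectation) within 3 Monte
Carlo standard errors, on batteries of seeded scenarios with prevalences
0.1–0.3 and RR 2–10 at $n = 10^5$ simulated individuals (sizes chosen to
give the FEN comparison real power at second-scale runtimes).

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: migration in or out of the cohort, calendar
trends in mortality, exposure misclassification, duration- or
intensity-graded exposure effects, latency (deliberately absent from the
method), and non-uniform within-band age distributions. The oracle battery
uses age-uniform prevalence so the mixed incidence schedule is exact at
baseline; with strongly age-varying prevalence the registry-rate
approximation would add a (second-order) bias that is a property of the
method's inputs, not of this implementation.

## Known limitations

* No uncertainty propagation: projections eight decades out carry large
  errors, and interval estimates for FEN/FEF are future work.
* The modified excess-risk step assumes the lifetime-risk ratio equals the
  hazard-ratio RR; for non-rare diseases the competing-risk feedback makes
  this approximate (second-order in the cumulative incidence).
* Band-level $LR_x$ values are emitted for transparency, but the group
  (per-sex) FEN is computed from pooled counts; the band FENs need not sum
  to it because the excess-risk formula is nonlinear in the prevalence mix.
* Multi-state tables with return transitions, ever-exposed prevalence
  adjustments, and future-exposure burdens are out of scope.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
single-band property fixtures (51 ages, 40-year horizon) for the algebraic
identities (1,000 random prevalence/RR draws), five seeded oracle scenarios
at $n = 10^5$, and one $n = 2\times10^5$ microsimulation cross-check in the
acceptance script. The full suite completes in well under a minute on one
CPU.
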