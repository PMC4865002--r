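# fefburden

Estimate the **future excess fraction (FEF)** of disease burden: of all the
disease cases that a population enumerated today will develop over its
remaining lifetime, what number (FEN) and fraction (FEF) will occur in the
people exposed to an agent *this year*, because of that exposure?

The classic attributable fraction answers a backward-looking question and
needs historical exposure data. The FEF is the forward-looking alternative
for settings — occupational carcinogens are the motivating case — where
only a current exposure prevalence and a relative risk are available. The
package is aimed at epidemiologists and burden-of-disease analysts who have
age- and sex-specific population counts, all-cause mortality rates, disease
incidence rates, an index-year exposure prevalence, and a relative risk.

## The method

For a cohort of size $N_p$ at the index year, with $N_e$ exposed and
$N_u = N_p - N_e$:

1. A life table (single decrement, or double decrement with first diagnosis
   as a competing absorbing exit) converts the cohort into future
   person-years at risk per baseline age band and estimation interval.
2. Projected age-specific incidence rates (constant, or log-linear drift
   fitted to a historical series) are multiplied by the person-years in
   each cell and summed: expected cases $D_{ij}$, total $FN_p$.
3. Lifetime risk: $LR_p = FN_p / N_p$.
4. Excess lifetime risk per exposed person, with $LR_u$ back-solved from
   the exposure mix (valid for $RR \ge 1$):

$$LR_x = \frac{LR_p\,N_p\,(RR-1)}{N_u + N_e\,RR}$$

5. Burden: $FEN = LR_x \times N_e$, and $FEF = FEN / FN_p$.

Levin's attributable fraction
$AF = p(RR-1)/(1+p(RR-1))$ is included as the comparator, applied to the
expected cases of a single future year. A one-at-a-time sensitivity module,
a synthetic-scenario generator, and an individual-level microsimulation
oracle (used to validate the life-table pipeline to Monte-Carlo precision)
round out the package. See the methods vignette
(`vignettes/fef-method.Rmd`) for conventions and design choices.

## Worked example

Everything runs on generated data; no external files are needed.

```r
library(fefburden)

sc  <- generate_scenario(seed = 1)   # Australia-2012-like synthetic scenario
fit <- fef_from_scenario(sc)         # equivalently: fef(sc$population, ...)
fit
#> Future excess fraction model
#>   index year 2012; horizon 83 years (to 2094); 5-year intervals
#>   double-decrement life table; constant rate projection; max age 100
#>
#>                                      male    female
#> Population (N_p)                7,346,917 7,109,258
#> Proportion exposed (index year)    0.0347    0.0004
#> Number exposed (N_e)              254,938     2,844
#> Lifetime risk (LR_p)                0.31%     0.15%
#> Expected lifetime cases (FN_p)     23,004    10,759
#> Lifetime excess risk (LR_x)          2.8%        2%
#> Future excess number (FEN)          7,151        56
#> Future excess fraction (FEF)        0.311     0.005
```

Reading the output: of the ~23,000 disease cases the 2012 male working-age
cohort is expected to develop by 2094, about 7,151 (FEF 0.311, i.e. 31 %)
are projected to occur in the 254,938 men exposed in 2012 *because of* that
exposure; each exposed man carries an excess lifetime risk of about 2.8 %.
The female burden is small because almost no women are exposed.

The attributable-fraction comparator for a single target year:

```r
af_comparison(fit, 2052)
#> Attributable-fraction comparison (single-year cases vs lifetime FEF)
#>
#>   group year prevalence rr    af cases_in_year attributable_number   FEF
#>    male 2052     0.0347 14 0.311           424                 132 0.311
#>  female 2052     0.0004 14 0.005           204                   1 0.005
```

Sensitivity of the outputs to each primary input
(`numbers_exposed`, `population`, `incidence`, `mortality`, `rr`):

```r
fef_sensitivity(fit, "incidence", multipliers = c(0.5, 2))
summary(fit)     # per-band transparency table
plot(fit)        # expected cases per 5-year interval, by sex
```

Real data enter through plain CSV files plus a YAML config
(`read_run_config()`, `load_inputs()`, `fef_run()`); a thin command-line
front end lives at `inst/cli/fef.R`
(`Rscript fef.R run -c config.yaml`, `sensitivity`, `af`, `make-fixtures`).

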