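# carcmort

Mortality during and after incarceration, estimated from linked
administrative registries.

Prison administrations rarely publish usable mortality data: deaths in
custody are under-reported, movement logs identify people inconsistently,
and the registries that do record deaths (a civil mortality registry with
ICD-10 causes) know nothing about incarceration. `carcmort` implements the
full analysis pipeline a researcher needs to quantify the mortality burden
of a carceral system from such data:

* **Identity resolution** — deduplication of a movement log whose internal
  IDs and name spellings disagree, and fuzzy linkage of the resolved persons
  to mortality-registry rows by length-weighted Levenshtein similarity on
  names and mothers' names, with phonetic blocking and validated
  sensitivity/specificity/PPV.
* **Exposure intervals** — conversion of arrest/transfer/release/death
  events into censored episodes by facility type (closed prison, semi-open
  prison, police station, youth detention) and post-release time, with
  truncation of implausibly long stays and exact person-time tabulation by
  calendar year and years since release.
* **Age structure** — disaggregation of wide-binned published age tables
  into single-year masses by truncated negative binomial maximum likelihood,
  rescaled to reproduce the reported bins exactly; cohort aging and
  death subtraction for the formerly incarcerated population; a
  non-incarcerated denominator built by subtraction.
* **Cause of death** — an editable ICD-10 range table mapping underlying
  causes to intermediate and broad categories (violence, suicide,
  communicable, noncommunicable, transport, other/unknown), including the
  special reclassification of in-custody "hanging, strangulation and
  suffocation, undetermined intent" deaths of men as interpersonal violence.
* **Rates** — age-specific rates with exact Poisson intervals, direct
  standardization to the incarcerated age structure (gamma-approximation
  intervals), exact conditional-binomial two-sample rate ratios, and
  F-distribution intervals for ratios of standardized rates.
* **Hazard and survival** — penalized P-spline smoothing of the
  instantaneous death rate over custody or post-release time (person-time
  offsets, quasipoisson dispersion), Kaplan–Meier curves and log-rank tests
  on a reduced cohort with uniform 5-year follow-up, stratified by
  cumulative incarceration.
* **Synthetic registries** — a generator that simulates carceral careers as
  a continuous-time Markov process with a competing, age- and sex-specific
  mortality clock, renders noisy movement logs and mortality registries, and
  keeps the full ground truth, so every stage of the pipeline is testable
  without access to restricted data.

The core comparison is the standardized incidence rate ratio

    IRR = ASR_pop / ASR_ref,   ASR = sum_a w_a * (d_a / PY_a)

where `w_a` are the incarcerated population's age weights, `d_a` age-bin
death counts, and `PY_a` person-years at risk; exact intervals condition on
`d_1 + d_0` (binomial inversion), and standardized intervals use equivalent
counts `d* = ASR^2 / Var(ASR)` with F quantiles.

## Worked example

```r
library(carcmort)

cfg <- synthetic_config(n_individuals = 20000, seed = 3,
                        name_noise = name_noise(0, 0, 0, 0))
run <- run_pipeline(cfg, fit_hazards = FALSE, causes = "all")

run$linkage_metrics
#> # A tibble: 1 × 6
#>   sensitivity specificity   ppv n_true_pairs n_labeled_pairs undefined
#>         <dbl>       <dbl> <dbl>        <int>           <int> <list>
#> 1           1           1     1          126           21419 <chr [0]>

dplyr::filter(run$rates, cause == "all", sex == "male")[,
  c("population", "deaths", "rate_per_100k", "irr", "irr_low", "irr_high")]
#> # A tibble: 6 × 6
#>   population       deaths rate_per_100k   irr irr_low irr_high
#>   <chr>             <int>         <dbl> <dbl>   <dbl>    <dbl>
#> 1 non_incarcerated    462          305. NA    NA         NA
#> 2 closed               13          554.  1.81  0.958      3.13
#> 3 semi_open             2          537.  1.76  0.212      6.39
#> 4 police                1          738.  2.42  0.0611    13.5
#> 5 post_release         72          962.  3.15  2.42       4.05
#> 6 youth                 0            0   0     0       2075.
```

With clean names the linkage is perfect, and the post-release standardized
IRR (3.15; 95% CI 2.42–4.05) recovers the generator's configured
post-release rate ratio of 3.0; the closed-prison estimate (1.81 on 13
deaths) is noisy but its interval covers the configured 1.3. Rates are per
100,000 person-years, standardized to the male incarcerated age structure.

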