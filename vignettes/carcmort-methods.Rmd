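---
title: "Estimating mortality during and after incarceration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mortality during and after incarceration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carcmort)
```

`carcmort` estimates all-cause and cause-specific mortality among people
detained in, and released from, a carceral system, by linking two
administrative sources that were never designed to be linked: a movement
log (one row per arrest, transfer, release or in-custody death, carrying an
internal ID, a name and a mother's name) and a civil mortality registry
(one row per death, with names, sex, date, age and an ICD-10 underlying
cause). This vignette explains the statistical machinery, the choices made
where the problem is genuinely open, and what the bundled synthetic data
can and cannot tell you about behavior on real registries.

## Identity resolution

Administrative logs fail in two characteristic ways: one internal ID
accumulates several name spellings, and one person accumulates several
internal IDs. `deduplicate_movements()` applies two decision trees. Within
an ID, name variants are clustered single-link at a name-similarity
threshold (default 0.85); an ID carrying genuinely different names is
split. Across IDs, two clusters merge only if both the names and the
mothers' names agree (default 0.85); if a mother's name is missing on
either side the pair is *uncertain* and is merged only on request.

Similarity is Levenshtein-based:
$$s(a,b) = \Big(1 - \frac{d_L(a,b)}{\max(|a|,|b|)}\Big)\cdot
\Big(\frac{\min(|a|,|b|)}{\max(|a|,|b|)}\Big)^{\gamma},$$
with $\gamma = 0.5$ by default. The length-ratio factor penalizes a short
string that embeds in a longer one ("ANA" vs "ANASTACIA …"), which plain
normalized edit distance scores deceptively high. The exponent is
configurable because the weighting scheme is a design choice, not a given.

`link_deaths()` scores each registry row against candidate clusters; the
combined score is the mean of name and mother similarity when both sides
have a mother's name, and the name score alone otherwise. The default
acceptance threshold is 0.90, set specificity-first: in this problem a
false link fabricates a death in custody, while a missed link only loses
sensitivity, an asymmetry the validation metrics make explicit. Candidate
retrieval is blocked on the Soundex of the first and of the last name
token (a pair is considered if either key matches); tests verify against
unblocked brute force that blocking loses nothing at the default noise
level. Ties at equal score prefer the candidate whose last recorded
movement precedes the death date; unresolvable ties, and rows whose
mother's name is unusable while several clusters match the name perfectly,
are *uncertain* — a sensitivity switch includes or excludes them.

`evaluate_linkage()` computes sensitivity (true pairs accepted / true
pairs), specificity (false candidate pairs rejected / false candidate
pairs) and PPV against the synthetic ground truth, and
`select_threshold()` picks an operating point by maximizing sensitivity
subject to a specificity floor (default 0.998).

## Exposure intervals and person-time

`build_episodes()` converts each person's event sequence into half-open
episodes `[start, end)`: a facility episode ends at transfer to a
different facility type, release, death, or the window end; a post-release
episode opens at release from prison (closed or semi-open; configurable to
any facility for denominator work) and ends at reincarceration, death, or
the window end. A movement after a person's death raises an integrity
error rather than being dropped silently. The half-open convention means a
transfer day counts toward the destination — the convention is arbitrary
but must be fixed for person-time to partition exactly.

Stays in police stations, semi-open prisons and youth detention suffer
under-reported releases; `truncate_overlong()` caps such episodes (defaults
30 days, 2 years, 3 years; or an empirical-quantile rule), marking them
`truncated`. Closed-prison episodes are never truncated. Caps are recorded
in the run manifest because they are unverifiable assumptions about
reporting, not measurements.

`tabulate_person_time()` splits episodes exactly at calendar-year
boundaries and, for post-release time, at anniversaries of the release
date, so a cell is (location, sex, calendar year) or (sex, release year,
years since release). Person-years divide day counts by 365.25. Splitting
is conservative by construction and the tests assert it to 1e-9.

## Age structure

Published age structure comes in wide bins (18–24, …, 61+) by sex and
year. `fit_truncated_negbin()` maximizes the multinomial likelihood of the
bin masses under a negative binomial on integer ages truncated (by
renormalization) to 18–95 (14–95 for the general population), using
Nelder–Mead on (log size, log mean) from three starts, tolerance 1e-8; a
fit from fewer than three occupied bins, or a non-convergent one, falls
back (in the pipeline) to the sex-pooled table rather than failing
silently. `adjust_to_bins()` then rescales the fitted single-year masses
within each wide bin so the bin totals reproduce the reported proportions
exactly — the parametric shape only interpolates *within* bins.

Facility types share one age structure per sex-year, because separate
structures are not published; youth detention gets crude rates only, as an
explicit no-structure marker. The formerly incarcerated population ages:
each release-year cohort carries the incarcerated structure of its release
year shifted one year per year since release (`age_forward()`), depleted by
the cohort's own observed age-specific deaths (`subtract_deaths()`,
decedents in the current year forgo half a cell-year by default). The
non-incarcerated denominator is built by subtraction
(`non_incarcerated_denominator()`): projected population person-time minus
custody person-time minus formerly-incarcerated person-time recomputed
over releases from *any* facility type. Pre-first-arrest time of people
who later enter the system remains in the reference population — the same
compromise the subtraction method always makes.

Deaths of minors are excluded from age-based analyses (no structure under
18) but kept in all-cause hazard analyses; standardization uses 4-year
bins from 18 with an open top bin at 62+.

## Rates and rate ratios

Age-specific rates get exact Poisson intervals via the chi-square
formulation. A directly standardized rate is
$\mathrm{ASR} = \sum_a w_a d_a / \mathrm{PY}_a$ with the incarcerated age
weights; its interval uses the gamma approximation for weighted Poisson
sums with the usual max-weight adjustment of the upper bound.

For two crude rates the exact interval conditions on the total:
given $d_1 + d_0$, $d_1$ is binomial with success probability
$\mathrm{PY}_1\rho / (\mathrm{PY}_1\rho + \mathrm{PY}_0)$; inverting
Clopper–Pearson limits for that probability yields exact limits for
$\rho$. With no reference deaths the upper bound is infinite and flagged.
For ratios of standardized rates each ASR is reduced to an equivalent
count $d^\* = \mathrm{ASR}^2/\widehat{\mathrm{Var}}$, and the exact
two-count formulas are expressed through F quantiles with those equivalent
counts (method tag `f_approx`). Monte-Carlo tests require at least 93%
empirical coverage at the 95% level; exactness of the conditional interval
is asserted against direct tail-probability bisection. No multiplicity
adjustment is applied anywhere — results are presented as intervals.

## Hazard over exposure time and survival

`smooth_hazard()` aggregates events and person-time on a monthly grid and
smooths the log-hazard by penalized B-spline Poisson regression with a
person-time offset. The default smoothing estimates the penalty by REML
with a first-order difference penalty (null space = constant hazard) and a
quasipoisson dispersion estimate. We initially selected a fixed df by AIC
over a small grid, but risk-set correlation leaves the grid counts mildly
overdispersed (≈1.15 in our simulations) and AIC then systematically
undersmooths: on constant-hazard data it chooses wiggly fits whose
pointwise bands miss the truth at more than 10% of grid points. The
penalized default shrinks to near-constancy when the data support it while
tracking genuinely declining hazards; `df = "aic"` and fixed `df` remain
available, and `df <= 2` is the exact constant fit (total events / total
person-time). Bands are delta-method on the log scale. Competing causes
are censored, so curves are cause-specific hazards; violence and suicide
are pooled for post-release curves and separable for in-custody ones.

Survival uses the survival package behind `km_estimate()` (product-limit;
our tests pin it to hand-computed tables) and `log_rank()`.
`build_reduced_cohort()` restricts to people whose last prison release
precedes the window end by at least 5 years and censors follow-up at 5
years, so release cohorts are compared on equal observation periods;
cumulative prior incarceration sums all recorded facility episodes before
that release. Age-adjusted survival is deliberately not attempted — the
movement log has no individual ages — so the stratified comparisons are
descriptive.

## The synthetic registry generator

Careers are a continuous-time Markov jump process over states
{never-incarcerated, closed, semi-open, police, youth, post-release,
released-from-other}; all rates are piecewise constant in age, state, and
year since release, so the event-driven simulation is exact. Mortality is
a competing exponential clock: baseline(age, sex) × state rate ratio
(defaults 1.3 closed, 2.4 semi-open, 3.1 police, 8.1 youth, 3.0
post-release, optionally decaying by year since release). Conditional on
death, a broad cause is drawn from a per-state mix; this encodes
cause-specific rate ratios as `rr_all × mix_state / mix_reference` with
one fewer free surface than separate per-cause clocks. Registry rendering
adds the imperfections the pipeline exists to survive: per-character name
substitutions, token swaps and drops, missing mothers' names, duplicate
internal IDs, custody deaths missing from the log, deaths missing from the
registry, missing ages, and occasional certification of in-custody violent
or suicide deaths of men as Y20 ("hanging, strangulation and suffocation,
undetermined intent") — the case the cause-mapping rule reclassifies.

Default conditions: 10-year window (2009–2018), 92% male, adult ages drawn
from the published-style wide bins (mean ≈ 32), 5% minors (14–17, the
youth-detention pool), baseline mortality a male schedule rising from
150/100k (18–24) to 2,600/100k (65+) with a female schedule at roughly
half, arrest intensity 0.02/person-year (0.05 for minors), police-dominated
admissions with rapid police → closed transfer, and name noise of 2%
per-character substitution, 1% token swap/drop, 10% missing mothers'
names. These are realistic orders of magnitude for a high-incarceration
middle-income state; none is calibrated to a real error distribution,
which is unpublished.

What the generator does *not* emulate: out-of-state migration after
release, court events, sentencing structure, seasonality, real name
frequency distributions (the bundled pools are small), or correlated
reporting failures. Passing tests therefore demonstrate that the
estimators recover known truth under a faithful but idealized error model
— not that any particular real registry meets that model.

## The recovery experiment

`recovery_experiment()` generates cohorts with known rate ratios, runs the
entire pipeline (deduplication, linkage, episodes, age structure, rates)
and asks whether the standardized IRR intervals cover the configured
truths. It is run with name noise switched off so that it isolates the
person-time, age-structure and rate machinery; linkage loss is measured
separately (zero-noise runs must achieve sensitivity = specificity = PPV
= 1 exactly, and threshold sweeps must be monotone against ground truth).
Under the default noise model linkage sensitivity is ≈0.9, which
mechanically depresses observed death counts and hence IRRs by the missed
fraction — the same direction of underestimation the linked-registry
design suffers in reality.

Problem sizes: the recovery experiment uses 20 cohorts of 50,000
individuals over the 10-year window; hazard recovery uses 20,000 subjects
at a constant 0.02/person-year; kernel oracles run on desk-sized grids.
These sizes keep Monte-Carlo error well below the tolerances being
asserted.

## Known limitations

* Cluster-level canonical names are modal spellings; a person observed
  once inherits that row's corruption, which is the dominant source of
  linkage misses at realistic noise.
* Truncation discards time between an episode cap and the next recorded
  event; it is not reallocated.
* The post-release death-depletion uses observed (linked) deaths only, so
  unlinked deaths leave a slightly too-old modeled age structure.
* Applying the custody *cross-sectional* age structure to release cohorts
  (all that is available without individual ages) misallocates post-release
  person-time across 4-year bins by ±10–20% in our simulations; combined
  with numerator thinning from registry missingness this leaves the
  standardized post-release IRR with a small net bias (≈ +0.5 standard
  errors at n = 50,000) and interval coverage near 0.90 rather than the
  nominal 0.95. This is a property of the estimation design itself, which
  the recovery experiment makes visible.
* The F-distribution interval for standardized ratios is one of several
  published variants (equivalent-count construction); it is documented in
  `irr_standardized()` and swappable.
* Uncertainty from the age-structure fit itself is not propagated into
  rate intervals; bins are treated as known.
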