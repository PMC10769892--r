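---
title: "Estimating life expectancy gaps from matched primary-care cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating life expectancy gaps from matched primary-care cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifegap)
```

## The problem

Electronic health records from primary care make it possible to ask
whether people who carry a particular diagnosis die earlier than
otherwise-similar people without it. `lifegap` implements the full
analysis chain for that question: it samples a matched comparison group
for every diagnosed person, expands follow-up into single-year-of-age
strata, smooths age-specific mortality with a Poisson model, converts the
smoothed rates into a period life table, and reports life expectancy at
age 18 together with the years-of-life-lost (YLL) difference between
groups, with Monte-Carlo confidence intervals.

Because patient-level records of this kind cannot be shared, the package
also contains a first-class synthetic cohort generator. Every statistical
guarantee the package claims is demonstrated on synthetic populations
whose generating parameters — and therefore whose true life expectancies
and mortality ratios — are known exactly.

## Cohort construction

**Entry and exit.** A diagnosed person enters follow-up at the *latest*
of: their diagnosis date, the date their practice met data-quality
criteria, registration plus six calendar months, and the study start
(1989-01-01 by default). Starting exposed follow-up at diagnosis excludes
immortal time: a person cannot die before the diagnosis that put them in
the cohort, so pre-diagnosis time must not be counted. Everyone exits at
the *earliest* of death, deregistration, the practice's last data
collection, and the administrative study end (2019-01-16 by default).
Follow-up intervals are half-open `[entry, exit)`.

**Exposure density sampling.** For each diagnosed person, `k = 10`
comparison participants are sampled uniformly without replacement from
people of the same sex, birth year, and practice who are under follow-up
at the diagnosed person's entry date and carry no exposure or
intellectual-disability (ID) diagnosis on or before it; they are assigned
that same entry date. Matching on birth year rather than exact birth date
keeps sampling pools workable at realistic practice sizes. A person may
serve as a comparison and be diagnosed later; their comparison follow-up
is censored at their own first diagnosis. The same person may be reused
across different index dates (standard risk-set sampling), but never
within one matched set. Partial sets are retained and reported, never
silently dropped.

**Two diagnosed cohorts.** People with an ID record at entry form the
`with_id` cohort; people without form `no_id`. A person whose ID record
post-dates their first diagnosis contributes to `no_id` until the ID
record and to `with_id` (with a fresh matched set) afterwards — ID tends
to be recorded later than the first diagnosis, and this split assigns
each person-day to the state it was observed in.

**Sensitivity flag.** Deaths carry a certainty label. "Possible" deaths
always *censor* follow-up at the death date; whether they also count as
events is a toggle (`include_possible_deaths`), so switching it changes
event counts only, never person-time.

## Person-time and rates

Follow-up is split by attained age (Lexis expansion): each calendar day
belongs to the person's completed age on that day, the birthday counting
towards the new age (a 29 February birthday falls on 1 March in non-leap
years). Days before the 18th birthday are dropped and ages above 100 are
pooled into an open stratum at 100. The split is exact in days; years are
days/365.25. A death is assigned to the completed age on the last day of
follow-up, which guarantees every death falls in a stratum where the
person contributed time (a death on a birthday would otherwise create a
zero-person-time stratum with an event).

Age-specific mortality in each group and sex is smoothed with a Poisson
model,

$$D_a \sim \text{Poisson}\{\exp(\beta_0 + \beta_1 a + \beta_2 a^2)\, Y_a\},$$

with deaths $D_a$, person-years $Y_a$ as a log offset, and age $a$
centred at 60 and scaled by 1/10 internally for conditioning
(coefficients are reported on the natural scale). Mortality rises
approximately exponentially with adult age, so the quadratic in log-rate
is a mild, power-adding smoothness assumption. Strata with zero
person-years are dropped; zero-death strata are retained (they carry
likelihood information). The fit is by iteratively reweighted least
squares (`glm.fit`), with the observed-information covariance mapped back
to the natural age scale.

Two mortality-ratio estimators are provided, because a published headline
ratio can arise from either:

* `standardised_mortality_ratio()` — indirect standardisation. Expected
  deaths $E = \sum_c \hat r_c\, Y^{exp}_c$ over (age, sex) cells, SMR
  $= O/E$, 95% CI by Byar's approximation on $O$. Cells with diagnosed
  person-time but no comparison person-time cannot contribute and are
  dropped and reported. The estimator is used with single-year cells at
  pipeline scale; at very small scale single-year cells become so thin
  that near-empty comparison cells destabilise $E$, and coarser (e.g.
  5-year) cells should be aggregated first — the validation suite does
  exactly that for its small replicate cohorts.
* `adjusted_rate_ratio()` — a Poisson model with a group indicator, age
  terms, sex, and entry-covariate indicators, exponentiating the group
  coefficient with a Wald interval. This is the estimator for the
  comorbidity-adjusted sensitivity analysis, with covariates frozen at
  the entry date.

## Life tables and intervals

`build_life_table()` follows the national-statistics period life table
convention: $q_x = m_x/(1 + (1-a_x) m_x)$ with $a_x = 0.5$ (deaths
mid-year on average — adequate at adult ages; infant-age refinements are
irrelevant at 18+), a radix of 100,000 (results are radix-invariant), and
an open interval at 100 closed by $L_{100} = l_{100}/m_{100}$ under a
constant hazard. Life expectancy is reported as total expected age,
$18 + e_{18}$. Years of life lost is the difference of total expectancies
(comparison minus diagnosed).

Confidence intervals come from simulation: coefficient vectors are drawn
from $N(\hat\beta, \hat\Sigma)$ — independently per group, since the
matched design gives no joint model — rates and a life table are rebuilt
per draw, and 2.5/97.5 percentiles are taken (default `n_sim = 10000`;
1,000 suffices for exploratory runs). The point estimate is the plug-in
value at $\hat\beta$; if a percentile interval fails to bracket it the
estimate is flagged, never reordered. Extreme draws are handled by
capping rates at $10^{12}$/year and death probabilities at 1, and the
pipeline's life tables impose non-decreasing rates over age
(`cummax`): adult all-cause mortality is monotone, and without this a
noisy fit whose quadratic curves downward at old ages can drive the
open-interval rate towards zero and the expectancy towards infinity.
The constraint never binds for a well-behaved fit, whose rates are
already increasing over 18–100.

**A small-sample caution.** The plug-in life expectancy is a concave
functional of the fitted coefficients: sampling noise in the curvature
term biases it downward. With a few hundred deaths the bias is
negligible, but for a group with only ~100 deaths it can reach 1–3
years, and since diagnosed groups are typically ten times smaller than
their comparisons, a naive YLL is biased upward at small sizes. The
package's null-case validation therefore uses equal-sized arms, where
the bias cancels in the difference; results for very small diagnosed
groups should be read with their (wide, asymmetric) intervals, not their
points.

## The synthetic cohort generator

`simulate_population()` emulates the data-generating context the analysis
assumes: multiple practices with their own data-quality windows, a
rare diagnosed exposure (1 in 450 by default, the recorded-diagnosis
frequency in adult primary-care records), 10:1 matched comparison
sampling downstream, and censoring by deregistration (exponential) and
administrative end of follow-up.

Adult mortality follows a Gompertz–Makeham hazard
$h(a) = m\,(\lambda + \alpha e^{\beta a})$. The defaults
($\lambda = 5\times10^{-5}$, $\alpha = 2.674\times10^{-5}$,
$\beta = 0.095$ per year, female multiplier 0.754) were solved
numerically — once, before any validation was run — so that the
comparison group's total life expectancy at 18 is 80.0 years for men and
83.0 for women, matching national life tables. The hazard family is
deliberately *not* the quadratic-log family the analysis fits; the
mismatch is mild (≤ 0.05 years of life expectancy at realistic
person-time profiles), so tests exercise genuine, realistic
misspecification.

Multipliers compose as follows: the sex and comorbidity hazard ratios
apply lifelong, while the *group* hazard ratio applies from the diagnosis
age onward (survivors to diagnosis redraw their remaining lifetime under
the multiplied hazard, valid by the Markov property of hazards). Applying
the group effect from birth would contaminate comparison groups — people
who serve as comparisons before their own later diagnosis would already
carry excess mortality — and would make the configured hazard ratio
unequal to the SMR estimand. Ages at death are drawn by
inverse-transform sampling of the cumulative hazard (closed forms for the
pure-exponential and pure-Gompertz cases, vectorised bisection
otherwise), conditional on survival to registration, since people who die
before registering never appear in a practice database.

Comorbidity flags (epilepsy, genetic disorders, severe mobility / visual
/ hearing impairments, ADHD, severe mental illness, self-harm) are
assigned at generation with group-specific prevalences patterned on
primary-care participant tables, independent within person (their joint
distribution is not characterised in the literature this emulates), with
onset ages uniform below 40. Their hazard ratios (2 for epilepsy and
genetic disorders, 1.5 for mobility, severe mental illness and
self-harm, 1 otherwise) are deliberate round values: they give the
adjusted-model stage a real mediated pathway to adjust away. The default
*direct* group hazard ratios (1.531 without ID, 2.002 with) were chosen
so that the *marginal* ratios — direct effect times the groups' relative
comorbidity burden — are approximately 1.71 and 2.83, and the
adjusted-to-unadjusted gap mirrors what comorbidity adjustment typically
does to such estimates. A fraction (2%) of deaths is flagged "possible";
the default analysis censors them, and including them perturbs event
counts by about that fraction while leaving person-time untouched.

Determinism: one root seed spawns a child stream per practice, so
practice *i*'s records do not change when practices are added. Identical
`(config, seed)` yields byte-identical tables, and the pipeline writes a
provenance block (seed, config hash, package version) with every bundle.

**What the generator does not emulate.** Calendar-time trends in
diagnostic ascertainment, the male-skewed sex ratio of diagnosed groups,
dependence between comorbidities, cause-of-death structure, and
area-level deprivation effects (the Townsend quintile is carried
descriptively only). Passing tests on this generator therefore shows the
*estimators* are correct under a realistic data-generating law, not that
any particular real-world estimate is unbiased — in real records,
exposure misclassification (most autistic adults are undiagnosed) can
dominate.

## Validation problem sizes

The test suite validates each stage against independent oracles
(day-iteration person-time, spreadsheet-style life-table recursion,
quadrature of the continuous survivor function, grid search over the
Poisson likelihood) and the pipeline end to end. The end-to-end
experiment uses three replicate populations of 200,000 persons (40
practices of 5,000; 2% diagnosed; comparison ratio 40 to use most of the
population as comparisons; quality windows open at study start and 0.5%
annual deregistration so comparison person-time is long), a direct group
hazard ratio of 2.0 and no comorbidity pathway: the mean recovered
comparison life expectancy must land within 0.5 years of the calibrated
80/83, YLL must be positive, and the SMR interval must cover 2.0.
Interval calibration uses 200 small replicate cohorts (SMR coverage
≥ 93% with 5-year standardisation cells) and 200 rate-surface
simulations (life-expectancy interval coverage between 90% and 99%).
The worked-example checks reproduce printed descriptive percentages
exactly from their numerator/denominator pairs. `scripts/acceptance.R`
re-runs the full pipeline on a 500,000-person population with the
default mortality calibration and a 5% diagnosed fraction, sized so the
sparsest group (women with an ID record) still carries a few hundred
deaths while a desk machine completes the run in about two minutes.

## Known limitations

* The quadratic log-rate model is the only rate smoother (no splines or
  overdispersion), by design; badly non-Gompertz hazards would be
  smoothed away rather than flagged.
* Period life expectancy summarises today's age-specific rates as a
  hypothetical cohort quantity; it is not a forecast of when anyone
  alive today will die.
* Exposed and comparison coefficient draws are independent in
  `simulate_ci()`; the matched design induces some dependence that the
  intervals ignore (they are, if anything, slightly conservative for
  YLL).
* Indirect standardisation with single-year cells needs large comparison
  groups; aggregate cells first when comparisons are scarce.
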