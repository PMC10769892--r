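# lifegap

Life expectancy gaps from matched primary-care cohorts.

`lifegap` is an R package for epidemiologists who want to quantify excess
mortality in a diagnosed subpopulation using primary-care electronic
health records: how much higher are the group's mortality rates than
those of matched comparison participants, and how many years of life
expectancy at age 18 does that excess translate into? It implements the
complete analysis chain and a seeded synthetic-cohort generator so the
chain can be tested and validated end to end where the underlying
patient-level records cannot be shared.

## The method

1. **Cohort construction.** Diagnosed people enter follow-up at the
   latest of diagnosis, practice data-quality start, registration + 6
   months, and the study start (no immortal time); everyone exits at the
   earliest of death, deregistration, the practice's last data
   collection, and the administrative study end. For each diagnosed
   person, *exposure density sampling* draws k = 10 comparison
   participants of the same sex, birth year, and practice who are
   under follow-up and undiagnosed at the index date, and assigns them
   the same entry date.
2. **Lexis expansion.** Follow-up is split by attained age into
   single-year strata (ages 18–100, exact in days), giving deaths
   \(D_a\) and person-years \(Y_a\) per group, sex, and age.
3. **Rate smoothing.** A Poisson model
   \(D_a \sim \mathrm{Poisson}\{\exp(\beta_0+\beta_1 a+\beta_2 a^2)\,Y_a\}\)
   smooths the age-specific mortality curve per group and sex.
   Standardised mortality ratios (indirect standardisation, Byar
   intervals) and covariate-adjusted Poisson rate ratios (Wald
   intervals) compare the groups.
4. **Life tables.** Smoothed rates become an ONS-style period life
   table (\(q_x = m_x/(1+\tfrac12 m_x)\), open interval at 100), giving
   total expected age \(18 + e_{18}\) and years of life lost (YLL,
   comparison minus diagnosed). Confidence intervals are simulated by
   redrawing coefficients from \(N(\hat\beta,\hat\Sigma)\) and
   rebuilding the life table per draw.

The synthetic generator produces multi-practice populations with
Gompertz–Makeham adult mortality (calibrated so comparison life
expectancy at 18 is ~80 years for men and ~83 for women), a rare
diagnosed group with configurable direct hazard ratios, group-specific
comorbidity flags that mediate part of the excess, deregistration, and
"possible" death flags for the sensitivity analysis.

## Worked example

```r
library(lifegap)

cfg <- sim_config(n_practices = 20, persons_per_practice = 5000,
                  exposure_prevalence = 0.05,
                  diagnosis_age_min = 25, diagnosis_age_mean = 50,
                  diagnosis_age_max = 80,
                  deregistration_rate = 0.02, seed = 42)
pop <- simulate_population(cfg)          # 100,000 persons, 4,538 diagnosed
cohort <- build_cohort(pop, k = 10, seed = 43)
strata <- aggregate_strata(cohort)

s <- strata[strata$cohort == "no_id", ]  # diagnosed without an ID record
standardised_mortality_ratio(s[s$group != "comparison", ],
                             s[s$group == "comparison", ])
#> standardised rate ratio: 1.719 (95% CI 1.448-2.026)
#>   observed 142, expected 82.62 deaths

fit_e <- fit_poisson_quadratic(subset(s, group != "comparison" & sex == "male"))
fit_c <- fit_poisson_quadratic(subset(s, group == "comparison" & sex == "male"))
simulate_ci(fit_e, fit_c, n_sim = 2000, seed = 7)
#> life expectancy at table start (n_sim = 2000, seed = 7):
#>   diagnosed    72.46 (61.06-75.20)
#>   comparison   80.01 (78.85-81.28)
#>   YLL           7.55 (4.46-18.67)
```

Read: diagnosed men in this synthetic cohort have 1.72 times the
mortality rate of their matched comparisons; their life expectancy at 18
is 72.5 years of total age against 80.0 for comparisons, an apparent
loss of 7.5 years (the generating truth for this configuration is a
direct hazard ratio of 1.531 with additional comorbidity-mediated
excess, i.e. a marginal ratio near 1.71). `run_pipeline()` orchestrates
all stages, writes every intermediate table (CSV), fit (JSON) and a
provenance block, and is byte-reproducible from `(config, seed)`.

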