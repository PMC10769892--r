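# Small configuration used by many tests: larger practices so matching
# pools are realistic, moderate exposure so diagnosed groups are non-empty.
quick_config <- function(seed = 42L, ...) {
  sim_config(n_practices = 3, persons_per_practice = 1200,
             exposure_prevalence = 0.02, seed = seed, ...)
}

# A configuration with no differential mortality mechanisms: all group and
# comorbidity hazard ratios 1, so every death age is a draw from the same
# sex-specific Gompertz-Makeham law.
null_config <- function(...) {
  sim_config(group_hazard_ratios = c(comparison = 1, exposed_no_id = 1,
                                     exposed_with_id = 1),
             comorbidity_hazard_ratios = c(epilepsy = 1, genetic = 1,
                                           mobility = 1, visual = 1,
                                           hearing = 1, adhd = 1, smi = 1,
                                           self_harm = 1),
             sex_hazard_ratio = 1, ...)
}

# Config for end-to-end recovery runs: known direct group effect, no
# comorbidity pathway, adult diagnosis ages so comparison groups accrue
# informative person-time across the whole adult age range.
recovery_config <- function(hr = 2, n_practices = 8,
                            persons_per_practice = 2500, seed = 1L,
                            exposure_prevalence = 0.02,
                            quality_start_range = c(-4, 0),
                            deregistration_rate = 0.005,
                            possible_death_fraction = 0, ...) {
  sim_config(n_practices = n_practices,
             persons_per_practice = persons_per_practice,
             exposure_prevalence = exposure_prevalence,
             group_hazard_ratios = c(comparison = 1, exposed_no_id = hr,
                                     exposed_with_id = hr),
             comorbidity_hazard_ratios = c(epilepsy = 1, genetic = 1,
                                           mobility = 1, visual = 1,
                                           hearing = 1, adhd = 1, smi = 1,
                                           self_harm = 1),
             quality_start_range = quality_start_range,
             deregistration_rate = deregistration_rate,
             possible_death_fraction = possible_death_fraction,
             seed = seed, ...)
}

# minimal interval block: n persons, the first n_deaths of them dying
make_group_intervals <- function(n, n_deaths, cohort, group, sex) {
  entry <- as.Date("2005-01-01")
  died <- seq_len(n) <= n_deaths
  data.frame(person_id = paste(cohort, group, sex, seq_len(n), sep = "_"),
             practice_id = 1L, matched_set_id = 1L, cohort = cohort,
             group = group, sex = sex,
             birth_date = as.Date("1970-06-01"),
             entry_date = entry,
             exit_date = as.Date(ifelse(died, "2010-01-01", "2015-01-01")),
             died = died,
             death_certainty = ifelse(died, "definite", NA),
             townsend_quintile = 3L, stringsAsFactors = FALSE)
}

with_seed_test <- function(seed, expr) {
  withr::local_seed(seed)
  expr
}

# hand-built patient record; every field overridable
make_patient <- function(person_id = "x1", practice_id = 1L, sex = "male",
                         birth_date = "1970-01-01",
                         registration_date = "1990-01-01",
                         deregistration_date = NA,
                         practice_quality_start = "1989-01-01",
                         practice_last_collection = "2019-01-16",
                         exposure_diagnosis_date = NA,
                         id_diagnosis_date = NA,
                         death_date = NA, death_certainty = NA,
                         townsend_quintile = 3L, ...) {
  com <- list(...)
  row <- data.frame(person_id = person_id, practice_id = practice_id,
                    sex = sex, birth_date = as.Date(birth_date),
                    registration_date = as.Date(registration_date),
                    deregistration_date = as.Date(deregistration_date),
                    practice_quality_start = as.Date(practice_quality_start),
                    practice_last_collection = as.Date(practice_last_collection),
                    exposure_diagnosis_date = as.Date(exposure_diagnosis_date),
                    id_diagnosis_date = as.Date(id_diagnosis_date),
                    stringsAsFactors = FALSE)
  for (cc in paste0("com_", lifegap:::CONDITIONS, "_date"))
    row[[cc]] <- as.Date(if (cc %in% names(com)) com[[cc]] else NA)
  row$death_date <- as.Date(death_date)
  row$death_certainty <- if (is.na(death_date)) NA_character_
                         else (if (is.na(death_certainty)) "definite"
                               else death_certainty)
  row$townsend_quintile <- townsend_quintile
  row
}

# a stratum table with exact Poisson expectations deaths = rate * py
make_strata <- function(ages, rates, person_years, sex = "male",
                        group = "comparison") {
  data.frame(group = group, sex = sex, age = ages,
             deaths = rates * person_years, person_years = person_years)
}
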