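AGE_BANDS <- c("<18" = -Inf, "18-24" = 18, "25-34" = 25, "35-44" = 35,
               "45-54" = 45, "55-64" = 55, "65+" = 65)

age_band <- function(age) {
  cut(age, breaks = c(unname(AGE_BANDS), Inf), labels = names(AGE_BANDS),
      right = FALSE)
}

entry_period <- function(date) {
  y <- as.integer(format(as.Date(date), "%Y"))
  cut(y, breaks = c(-Inf, 1999, 2009, Inf),
      labels = c("1989-1999", "2000-2009", "2010-2019"))
}

#' Descriptive cohort summary in the shape of a participant table
#'
#' Per (cohort, group, sex): numbers of individuals, practices, and
#' deaths; percentage of deaths (rounded half-up to 2 decimals); median
#' and interquartile range of age at death among decedents, of age at
#' entry, and of follow-up length; entry-age bands; covariate prevalences
#' at entry; and entry-period bands. Quantiles use the default linear
#' interpolation definition (type 7), recorded in the result's
#' `quantile_type` attribute. Empty groups report `NA`, not zero.
#'
#' Persons appearing in more than one follow-up interval within a group
#' (e.g. a comparison later censored) are counted once, at their first
#' interval.
#'
#' @param cohort a [build_cohort()] result or its `intervals` data.frame.
#' @return data.frame of class `cohort_summary`, one row per
#'   cohort-group-sex.
#' @export
summarise_cohort <- function(cohort) {
  iv <- if (inherits(cohort, "matched_cohort")) cohort$intervals else cohort
  if (!nrow(iv)) {
    out <- data.frame()
    class(out) <- c("cohort_summary", "data.frame")
    return(out)
  }
  cov_cols <- grep("^cov_", names(iv), value = TRUE)
  keys <- c(intersect(c("cohort", "group"), names(iv)), "sex")
  parts <- split(iv, iv[keys], drop = TRUE)
  rows <- lapply(parts, function(d) {
    # one row per person: first interval for entry facts, any death counts
    first <- d[order(d$entry_date), ]
    persons <- first[!duplicated(first$person_id), , drop = FALSE]
    n <- nrow(persons)
    died_ids <- unique(d$person_id[d$died])
    n_deaths <- length(died_ids)
    death_rows <- d[d$died, , drop = FALSE]
    age_death <- days_to_years(death_rows$exit_date - death_rows$birth_date)
    entry_age <- days_to_years(persons$entry_date - persons$birth_date)
    fu <- days_to_years(persons$exit_date - persons$entry_date)
    med_iqr <- function(x) {
      if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
      unname(stats::quantile(x, c(0.5, 0.25, 0.75)))
    }
    mad_ <- med_iqr(age_death); mea <- med_iqr(entry_age); mfu <- med_iqr(fu)
    bands <- table(age_band(floor(entry_age)))
    periods <- table(entry_period(persons$entry_date))
    base <- data.frame(
      n_individuals = n,
      n_practices = length(unique(persons$practice_id)),
      n_deaths = n_deaths,
      pct_deaths = percentage(n_deaths, n),
      median_age_death = mad_[1], q1_age_death = mad_[2], q3_age_death = mad_[3],
      median_entry_age = mea[1], q1_entry_age = mea[2], q3_entry_age = mea[3],
      median_follow_up = mfu[1], q1_follow_up = mfu[2], q3_follow_up = mfu[3])
    for (b in names(bands)) base[[paste0("entry_", b)]] <- as.integer(bands[[b]])
    for (p in names(periods)) base[[paste0("period_", p)]] <- as.integer(periods[[p]])
    for (cc in cov_cols) {
      base[[paste0("n_", sub("^cov_", "", cc))]] <- sum(persons[[cc]])
      base[[paste0("pct_", sub("^cov_", "", cc))]] <-
        percentage(sum(persons[[cc]]), n)
    }
    base
  })
  keydf <- do.call(rbind, lapply(strsplit(names(parts), ".", fixed = TRUE),
                                 function(v) as.data.frame(as.list(stats::setNames(v, keys)))))
  out <- cbind(keydf, do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "quantile_type") <- 7
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Death percentage as printed in participant tables
#'
#' `100 * numerator / denominator`, rounded half-up to two decimals; `NA`
#' for an empty denominator.
#'
#' @param numerator,denominator counts.
#' @return numeric percentage.
#' @export
percentage <- function(numerator, denominator) {
  ifelse(denominator > 0, round_half_up(100 * numerator / denominator, 2),
         NA_real_)
}

#' Mortality rates per 100,000 person-years by age band
#'
#' Aggregates single-year strata into the reporting bands 18-24, 25-34,
#' 35-44, 45-54, 55-64 and 65+, with exact (Garwood) Poisson confidence
#' intervals on the death counts via chi-square quantiles.
#'
#' @param strata stratum table from [aggregate_strata()].
#' @param per rate scale (default 100,000).
#' @param conf_level confidence level.
#' @return data.frame with group keys, `band`, `deaths`, `person_years`,
#'   `rate`, `ci_low`, `ci_high`.
#' @export
banded_rate_table <- function(strata, per = 1e5, conf_level = 0.95) {
  if (!nrow(strata)) stop("empty stratum table")
  keys <- intersect(c("cohort", "group", "sex"), names(strata))
  band <- age_band(strata$age)
  agg <- stats::aggregate(strata[c("deaths", "person_years")],
                          by = c(strata[keys], list(band = band)), FUN = sum)
  agg <- agg[agg$person_years > 0, , drop = FALSE]
  a <- 1 - conf_level
  agg$rate <- agg$deaths / agg$person_years * per
  agg$ci_low <- ifelse(agg$deaths == 0, 0,
                       stats::qchisq(a / 2, 2 * agg$deaths) / 2 /
                         agg$person_years * per)
  agg$ci_high <- stats::qchisq(1 - a / 2, 2 * (agg$deaths + 1)) / 2 /
    agg$person_years * per
  agg <- agg[do.call(order, agg[c(keys, "band")]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Run the full analysis pipeline on a simulated or supplied population
#'
#' simulate (unless a population is supplied) -> build matched cohorts ->
#' Lexis expansion -> Poisson rate models per cohort, group and sex ->
#' life tables, life expectancy with Monte-Carlo intervals, years of life
#' lost -> standardised and covariate-adjusted mortality ratios ->
#' descriptive tables. All intermediate tables are written as CSV, fits
#' and estimates as JSON, together with a provenance block (seed, config
#' hash, package version), so a bundle is reproducible from
#' `(config, seed)` alone.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param population optional patient table; when given the simulation
#'   stage is skipped and `config` supplies the analysis settings only.
#' @param n_sim Monte-Carlo draws for interval estimation.
#' @param include_possible_deaths sensitivity toggle for "possible" deaths.
#' @param adjust_covariates covariate set for the adjusted rate ratios.
#' @param quiet suppress stage-boundary messages.
#' @return report bundle (list) with elements `population`, `cohort`,
#'   `strata`, `fits`, `life_tables`, `estimates`, `smr`, `adjusted`,
#'   `summary`, `banded_rates`, `provenance`, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, population = NULL,
                         n_sim = 1000,
                         include_possible_deaths = FALSE,
                         adjust_covariates = paste0("cov_", c(
                           "epilepsy", "mobility", "visual", "hearing",
                           "genetic", "adhd")),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[lifegap] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  validate_sim_config(config)

  if (is.null(population)) {
    population <- stage("simulate", simulate_population(config))
    say("simulate: ", nrow(population), " persons, ",
        sum(!is.na(population$exposure_diagnosis_date)), " diagnosed")
  }
  cohort <- stage("build-cohort", build_cohort(
    population, k = config$comparison_ratio,
    study_start = config$study_start, study_end = config$study_end,
    include_possible_deaths = include_possible_deaths,
    seed = config$seed + 1L))
  say("build-cohort: ", nrow(cohort$intervals), " intervals in ",
      nrow(cohort$match_report), " matched sets")

  strata <- stage("split", aggregate_strata(cohort))
  strata_cov <- stage("split", aggregate_strata(cohort,
                                                covariates = adjust_covariates))
  say("split: ", nrow(strata), " age strata, ", sum(strata$deaths),
      " deaths, ", round(sum(strata$person_years)), " person-years")

  cohorts <- unique(strata$cohort)
  fits <- list(); life_tables <- list(); estimates <- list()
  smr <- list(); adjusted <- list()
  for (ch in cohorts) {
    s <- strata[strata$cohort == ch, ]
    for (sx in unique(s$sex)) {
      for (g in unique(s$group)) {
        lbl <- paste(ch, g, sx, sep = ".")
        fits[[lbl]] <- stage("fit", fit_poisson_quadratic(
          s[s$group == g & s$sex == sx, ], group = c(ch, g, sx)))
        life_tables[[lbl]] <- stage("lifetable", build_life_table(
          cummax(predict_rates(fits[[lbl]]))))   # monotone adult mortality
      }
      exp_lbl <- paste(ch, paste0("exposed_", ch), sx, sep = ".")
      estimates[[paste(ch, sx, sep = ".")]] <- stage("lifetable", simulate_ci(
        fits[[exp_lbl]], fits[[paste(ch, "comparison", sx, sep = ".")]],
        n_sim = n_sim, seed = config$seed + 2L))
    }
    smr[[ch]] <- stage("fit", standardised_mortality_ratio(
      s[s$group != "comparison", ], s[s$group == "comparison", ]))
    for (sx in unique(s$sex))
      smr[[paste(ch, sx, sep = ".")]] <- stage("fit", standardised_mortality_ratio(
        s[s$group != "comparison" & s$sex == sx, ],
        s[s$group == "comparison" & s$sex == sx, ]))
    sc <- strata_cov[strata_cov$cohort == ch, ]
    adjusted[[ch]] <- stage("fit", adjusted_rate_ratio(sc, adjust_covariates))
  }
  say("fit: ", length(fits), " rate models")

  summary_tab <- stage("report", summarise_cohort(cohort))
  banded <- stage("report", banded_rate_table(strata))

  provenance <- list(package_version = as.character(utils::packageVersion("lifegap")),
                     seed = config$seed,
                     n_sim = n_sim,
                     include_possible_deaths = include_possible_deaths,
                     config_hash = config_hash(config))
  bundle <- list(population = population, cohort = cohort, strata = strata,
                 fits = fits, life_tables = life_tables,
                 estimates = estimates, smr = smr, adjusted = adjusted,
                 summary = summary_tab, banded_rates = banded,
                 provenance = provenance)
  if (!is.null(out_dir)) stage("report", write_bundle(bundle, config, out_dir))
  say("done")
  invisible(bundle)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_sim_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_sim_config(config, fp("config.yaml"))
  write_population(bundle$population, fp("population.csv"))
  iv <- bundle$cohort$intervals
  for (cc in c("birth_date", "entry_date", "exit_date"))
    iv[[cc]] <- format(iv[[cc]])
  utils::write.csv(iv, fp("intervals.csv"), row.names = FALSE, na = "")
  rep <- bundle$cohort$match_report
  rep$entry_date <- format(rep$entry_date)
  utils::write.csv(rep, fp("match_report.csv"), row.names = FALSE, na = "")
  utils::write.csv(bundle$strata, fp("strata.csv"), row.names = FALSE, na = "")
  for (lbl in names(bundle$fits))
    write_fit(bundle$fits[[lbl]], fp(paste0("fit_", lbl, ".json")))
  for (lbl in names(bundle$life_tables))
    utils::write.csv(as.data.frame(bundle$life_tables[[lbl]]),
                     fp(paste0("lifetable_", lbl, ".csv")), row.names = FALSE)
  est <- lapply(bundle$estimates, function(e)
    list(exposed = e$exposed, comparison = e$comparison, yll = e$yll,
         n_sim = e$n_sim, seed = e$seed))
  ratios <- lapply(c(bundle$smr, stats::setNames(
    bundle$adjusted, paste0(names(bundle$adjusted), ".adjusted"))),
    function(r) list(estimate = r$estimate, ci_low = r$ci_low,
                     ci_high = r$ci_high, method = r$method))
  jsonlite::write_json(list(life_expectancy = est, rate_ratios = ratios,
                            provenance = bundle$provenance),
                       fp("estimates.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(bundle$summary), fp("summary.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(bundle$banded_rates, fp("banded_rates.csv"),
                   row.names = FALSE, na = "")
  invisible(out_dir)
}
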