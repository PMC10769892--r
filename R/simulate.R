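#' Generate a synthetic primary-care population
#'
#' Produces one patient record per registered person across a set of
#' general practices, with the statistical structure the downstream
#' analysis assumes: a rare diagnosed exposure group, optional co-occurring
#' intellectual-disability records, comorbidity flags with group-specific
#' prevalences, Gompertz-Makeham adult mortality acting multiplicatively
#' with group, sex, and comorbidity hazard ratios (sex and comorbidity
#' multipliers apply lifelong; the group hazard ratio applies from the
#' diagnosis onward, so pre-diagnosis mortality matches the comparison
#' population), exponential
#' deregistration, and a small fraction of deaths recorded only as
#' "possible". Ages at death are sampled conditional on survival to
#' registration (people who die before ever registering are not in a
#' practice database).
#'
#' Each practice has its own child random stream derived from the root
#' seed, so the records of practice `i` do not change when practices are
#' added or removed. Identical `(config, seed)` gives identical output.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per person: identifiers, sex, key dates
#'   (ISO, `Date` class), comorbidity onset dates (`com_*_date`), death
#'   date and certainty, and Townsend deprivation quintile.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  out <- vector("list", config$n_practices)
  for (i in seq_len(config$n_practices)) {
    child <- (config$seed + 982451653 * i) %% 2147483647
    out[[i]] <- with_seed(child, simulate_practice(i, config))
  }
  pop <- do.call(rbind, out)
  rownames(pop) <- NULL
  pop
}

simulate_practice <- function(practice_id, cfg) {
  n <- cfg$persons_per_practice
  day <- function(y) as.Date(round(y * 365.25), origin = "1970-01-01")
  window_days <- as.numeric(cfg$study_end - cfg$study_start)

  # practice-level data-quality window
  qr <- cfg$quality_start_range * 365.25
  quality_start <- cfg$study_start +
    round(stats::runif(1, qr[1], min(qr[2], window_days * 0.55)))
  last_collection <- cfg$study_end - round(stats::runif(1, 0, 7 * 365.25))

  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  birth_year <- stats::runif(n, cfg$birth_year_range[1], cfg$birth_year_range[2])
  birth_date <- as.Date(paste0(floor(birth_year), "-01-01")) +
    round((birth_year - floor(birth_year)) * 365)
  reg_age <- stats::runif(n, cfg$registration_age_range[1],
                          cfg$registration_age_range[2])
  registration_date <- birth_date + pmax(1, round(reg_age * 365.25))
  reg_age_exact <- as.numeric(registration_date - birth_date) / 365.25

  # exposure and intellectual-disability records
  exposed <- stats::runif(n) < cfg$exposure_prevalence
  with_id <- exposed & stats::runif(n) < cfg$id_fraction
  diag_age <- cfg$diagnosis_age_min +
    stats::rexp(n, 1 / (cfg$diagnosis_age_mean - cfg$diagnosis_age_min))
  diag_age <- pmin(diag_age, cfg$diagnosis_age_max)
  id_age <- diag_age + stats::rexp(n, 1 / cfg$id_delay_mean)

  # comorbidity flags, group-specific prevalence, onset uniform before 40
  group <- ifelse(!exposed, "comparison",
                  ifelse(with_id, "exposed_with_id", "exposed_no_id"))
  com_age <- matrix(NA_real_, n, length(CONDITIONS),
                    dimnames = list(NULL, CONDITIONS))
  mult <- ifelse(sex == "female", cfg$sex_hazard_ratio, 1)
  for (cc in CONDITIONS) {
    p <- vapply(group, function(g) cfg$comorbidity_prevalences[[g]][[cc]], 0)
    has <- stats::runif(n) < p
    com_age[has, cc] <- stats::runif(sum(has), 0, 40)
    mult[has] <- mult[has] * cfg$comorbidity_hazard_ratios[[cc]]
  }

  # baseline (pre-diagnosis) mortality for everyone ...
  death_age <- sample_death_age(n, age0 = reg_age_exact,
                                lambda = cfg$makeham_lambda,
                                alpha = cfg$gompertz_alpha,
                                beta = cfg$gompertz_beta,
                                multiplier = mult)
  # ... then the group hazard ratio applies from the diagnosis onward:
  # survivors to the diagnosis age redraw their remaining lifetime under
  # the multiplied hazard (valid by the Markov property of the hazard)
  ghr <- unname(cfg$group_hazard_ratios[group])
  brk <- pmax(diag_age, reg_age_exact)
  redo <- exposed & ghr != 1 & death_age > brk
  if (any(redo))
    death_age[redo] <- sample_death_age(sum(redo), age0 = brk[redo],
                                        lambda = cfg$makeham_lambda,
                                        alpha = cfg$gompertz_alpha,
                                        beta = cfg$gompertz_beta,
                                        multiplier = mult[redo] * ghr[redo])
  death_date <- pmax(birth_date + round(death_age * 365.25),
                     registration_date)
  certainty <- ifelse(stats::runif(n) < cfg$possible_death_fraction,
                      "possible", "definite")

  # diagnoses and comorbidity onsets only exist if they precede death
  diag_date <- birth_date + round(diag_age * 365.25)
  diag_date[!exposed | diag_date >= death_date] <- NA
  id_date <- birth_date + round(id_age * 365.25)
  id_date[!with_id | is.na(diag_date) | id_date >= death_date] <- NA
  com_date <- lapply(CONDITIONS, function(cc) {
    d <- birth_date + round(com_age[, cc] * 365.25)
    d[!is.na(d) & d > death_date] <- NA
    d
  })
  names(com_date) <- paste0("com_", CONDITIONS, "_date")

  # deregistration: exponential after registration, dropped if after death
  if (cfg$deregistration_rate > 0) {
    dereg <- registration_date +
      pmax(1, round(stats::rexp(n, cfg$deregistration_rate) * 365.25))
    dereg[dereg >= death_date] <- NA
  } else dereg <- as.Date(rep(NA, n))

  townsend <- sample(1:5, n, replace = TRUE)
  townsend[stats::runif(n) < cfg$townsend_missing] <- NA

  cbind(
    data.frame(person_id = sprintf("p%03d_%06d", practice_id, seq_len(n)),
               practice_id = practice_id,
               sex = sex,
               birth_date = birth_date,
               registration_date = registration_date,
               deregistration_date = dereg,
               practice_quality_start = rep(quality_start, n),
               practice_last_collection = rep(last_collection, n),
               exposure_diagnosis_date = diag_date,
               id_diagnosis_date = id_date,
               stringsAsFactors = FALSE),
    as.data.frame(com_date),
    data.frame(death_date = death_date,
               death_certainty = certainty,
               townsend_quintile = townsend))
}

POP_DATE_COLS <- c("birth_date", "registration_date", "deregistration_date",
                   "practice_quality_start", "practice_last_collection",
                   "exposure_diagnosis_date", "id_diagnosis_date",
                   paste0("com_", CONDITIONS, "_date"), "death_date")

#' Read and write patient tables as CSV
#'
#' RFC 4180 CSV with ISO-8601 dates; missing values are empty strings.
#' `read_population()` validates record-level invariants on load.
#'
#' @param population data.frame as from [simulate_population()].
#' @param path file path.
#' @export
write_population <- function(population, path) {
  out <- population
  for (cc in intersect(POP_DATE_COLS, names(out)))
    out[[cc]] <- format(out[[cc]])   # ISO-8601
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_population
#' @return `read_population()`: validated data.frame with `Date` columns.
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  for (cc in intersect(POP_DATE_COLS, names(pop)))
    pop[[cc]] <- as.Date(pop[[cc]])
  validate_population(pop)
  pop
}

#' Validate patient-record invariants
#'
#' Checks, row by row: `birth_date < registration_date <=
#' deregistration_date` (when present); `death_date >= registration_date`;
#' no diagnosis or comorbidity onset after death; death certainty present
#' exactly when a death date is. Errors name the offending `person_id`.
#'
#' @param population patient table.
#' @return the table, invisibly, if valid.
#' @export
validate_population <- function(population) {
  req <- c("person_id", "practice_id", "sex", "birth_date",
           "registration_date", "death_date", "death_certainty")
  miss <- setdiff(req, names(population))
  if (length(miss)) stop("population table lacks columns: ",
                         paste(miss, collapse = ", "))
  fail <- function(bad, why) {
    if (any(bad, na.rm = TRUE))
      stop("invalid patient record(s) [", why, "]: ",
           paste(utils::head(population$person_id[which(bad)], 5), collapse = ", "),
           call. = FALSE)
  }
  p <- population
  fail(!p$sex %in% c("male", "female"), "sex must be male/female")
  fail(p$birth_date >= p$registration_date, "birth_date < registration_date")
  if ("deregistration_date" %in% names(p))
    fail(!is.na(p$deregistration_date) &
           p$registration_date > p$deregistration_date,
         "registration_date <= deregistration_date")
  has_death <- !is.na(p$death_date)
  fail(has_death & p$death_date < p$registration_date,
       "death_date >= registration_date")
  fail(xor(has_death, !is.na(p$death_certainty)),
       "death_certainty defined iff death_date present")
  for (cc in intersect(c("exposure_diagnosis_date", "id_diagnosis_date",
                         paste0("com_", CONDITIONS, "_date")), names(p)))
    fail(has_death & !is.na(p[[cc]]) & p[[cc]] > p$death_date,
         paste("no", cc, "after death_date"))
  invisible(population)
}
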