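#' Cohort entry date under the latest-of rule
#'
#' The entry date is the latest of: the diagnosis date (when
#' `use_diagnosis`), the practice data-quality start, registration plus six
#' calendar months, and the study start. Follow-up before diagnosis is
#' never included, so diagnosed participants contribute no immortal time.
#' Returns `NA` where the entry date falls on or after the person's exit
#' bound (no follow-up).
#'
#' @param population patient table (see [simulate_population()] for the schema).
#' @param study_start,study_end study window dates.
#' @param use_diagnosis include the exposure diagnosis date in the
#'   latest-of rule (`TRUE` for diagnosed participants, `FALSE` when
#'   computing the earliest date a person could enter as a comparison).
#' @param include_possible_deaths passed to [compute_exit_date()] for the
#'   exit bound (it affects the event flag only, never the date).
#' @return `Date` vector, `NA` where no follow-up is possible.
#' @export
compute_entry_date <- function(population,
                               study_start = as.Date("1989-01-01"),
                               study_end = as.Date("2019-01-16"),
                               use_diagnosis = TRUE) {
  entry <- entry_bound(population, study_start)
  if (use_diagnosis)
    entry <- pmax_date(entry, population$exposure_diagnosis_date)
  exit <- compute_exit_date(population, study_end)$exit_date
  entry[entry >= exit] <- NA
  entry
}

entry_bound <- function(population, study_start) {
  pmax_date(population$practice_quality_start,
            add_months(population$registration_date, 6),
            as.Date(study_start))
}

#' Cohort exit date under the earliest-of rule
#'
#' Exit is the earliest of death, deregistration, the practice's last data
#' collection, and the administrative end of the study. The death flag is
#' `TRUE` only when exit is a death and the death is definite (or
#' `include_possible_deaths` is set); a "possible" death otherwise censors
#' at the death date without counting as an event, so toggling the
#' sensitivity flag never changes person-time.
#'
#' @inheritParams compute_entry_date
#' @param include_possible_deaths count "possible" deaths as events.
#' @return data.frame with `exit_date` and logical `died`.
#' @export
compute_exit_date <- function(population,
                              study_end = as.Date("2019-01-16"),
                              include_possible_deaths = FALSE) {
  exit <- pmin_date(population$death_date,
                    population$deregistration_date,
                    population$practice_last_collection,
                    as.Date(study_end))
  died <- !is.na(population$death_date) & exit == population$death_date &
    (population$death_certainty == "definite" | include_possible_deaths)
  died[is.na(died)] <- FALSE
  data.frame(exit_date = exit, died = died)
}

# Eligibility of pool members as comparisons at a given index date:
# same sex / birth year / practice as the diagnosed person, able to
# contribute follow-up at the index date, and no exposure or ID record on
# or before it.
comparison_eligible <- function(pool_pre, index_date, sex, birth_year,
                                practice_id, exclude_id = NULL) {
  ok <- pool_pre$sex == sex &
    pool_pre$birth_year == birth_year &
    pool_pre$practice_id == practice_id &
    pool_pre$entry_bound <= index_date &
    pool_pre$exit_bound > index_date &
    (is.na(pool_pre$first_diag) | pool_pre$first_diag > index_date)
  if (!is.null(exclude_id)) ok <- ok & pool_pre$person_id != exclude_id
  ok
}

precompute_pool <- function(population, study_start, study_end) {
  data.frame(person_id = population$person_id,
             practice_id = population$practice_id,
             sex = population$sex,
             birth_year = as.integer(format(population$birth_date, "%Y")),
             entry_bound = entry_bound(population, study_start),
             exit_bound = compute_exit_date(population, study_end)$exit_date,
             first_diag = pmin_date(population$exposure_diagnosis_date,
                                    population$id_diagnosis_date),
             stringsAsFactors = FALSE)
}

#' Exposure density sampling of matched comparisons for one diagnosed person
#'
#' Samples up to `k` comparison participants, uniformly without
#' replacement, from pool members of the same sex, birth year, and practice
#' who are under follow-up at the diagnosed person's entry (index) date and
#' have no exposure or intellectual-disability record on or before it. The
#' selected comparisons are assigned the index date as their cohort entry
#' date. If fewer than `k` candidates are eligible, all are returned and
#' the shortfall is visible in the result; the diagnosed person is never
#' dropped for lack of matches.
#'
#' @param exposed single patient record (one-row data.frame).
#' @param pool patient table to sample comparisons from.
#' @param k number of comparisons requested.
#' @param index_date the diagnosed person's entry date; computed via
#'   [compute_entry_date()] when omitted.
#' @inheritParams compute_entry_date
#' @return character vector of selected `person_id`s (length `<= k`), with
#'   attributes `index_date` and `n_eligible`.
#' @export
exposure_density_match <- function(exposed, pool, k = 10, index_date = NULL,
                                   study_start = as.Date("1989-01-01"),
                                   study_end = as.Date("2019-01-16")) {
  stopifnot(nrow(exposed) == 1, k >= 1)
  if (is.null(index_date))
    index_date <- compute_entry_date(exposed, study_start, study_end)
  if (is.na(index_date)) stop("exposed person has no valid entry date")
  pre <- precompute_pool(pool, study_start, study_end)
  ok <- comparison_eligible(pre, index_date,
                            exposed$sex,
                            as.integer(format(exposed$birth_date, "%Y")),
                            exposed$practice_id,
                            exclude_id = exposed$person_id)
  cand <- pre$person_id[which(ok)]
  sel <- if (length(cand) <= k) cand else sample(cand, k)
  structure(sel, index_date = index_date, n_eligible = length(cand))
}

#' Build the matched cohorts from a patient table
#'
#' Applies the eligibility and follow-up rules and performs exposure
#' density sampling of `k` comparison participants per diagnosed
#' participant. Two exposure cohorts are built: people with a diagnosis but
#' no intellectual-disability (ID) record at entry (`no_id`), and people
#' with both (`with_id`), each with its own comparison group.
#'
#' A person whose ID record post-dates their first diagnosis contributes
#' follow-up to the `no_id` cohort from their entry date until the ID
#' record, and to the `with_id` cohort (with a fresh matched set) from the
#' ID record onward. Comparison participants are censored at their own
#' first exposure or ID record, after which they may re-enter as diagnosed.
#' Covariate flags are frozen at each interval's entry date. Follow-up
#' intervals are half-open `[entry, exit)` and zero-length rows are
#' dropped.
#'
#' @inheritParams compute_entry_date
#' @inheritParams compute_exit_date
#' @param population patient table.
#' @param k matched comparisons per diagnosed participant.
#' @param seed optional seed for the sampling stream (restores the
#'   caller's RNG state afterwards).
#' @return object of class `matched_cohort`: a list with `intervals` (one
#'   row per follow-up interval), `k`, `match_report` (per matched set:
#'   requested and achieved size), and counts of diagnosed persons excluded
#'   for lack of follow-up.
#' @export
build_cohort <- function(population, k = 10,
                         study_start = as.Date("1989-01-01"),
                         study_end = as.Date("2019-01-16"),
                         include_possible_deaths = FALSE,
                         seed = NULL) {
  validate_population(population)
  if (!is.null(seed)) return(with_seed(seed, build_cohort(
    population, k, study_start, study_end, include_possible_deaths)))
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)

  pre <- precompute_pool(population, study_start, study_end)
  exits <- compute_exit_date(population, study_end, include_possible_deaths)
  ebound <- entry_bound(population, study_start)

  exp_idx <- which(!is.na(population$exposure_diagnosis_date))
  episodes <- list(); n_excluded <- 0L
  for (j in exp_idx) {
    entry <- max(ebound[j], population$exposure_diagnosis_date[j])
    exit <- exits$exit_date[j]
    if (entry >= exit) { n_excluded <- n_excluded + 1L; next }
    i_date <- population$id_diagnosis_date[j]
    if (is.na(i_date) || i_date >= exit) {
      episodes[[length(episodes) + 1L]] <- list(j = j, cohort = "no_id",
                                                entry = entry, exit = exit)
    } else if (i_date <= entry) {
      episodes[[length(episodes) + 1L]] <- list(j = j, cohort = "with_id",
                                                entry = entry, exit = exit)
    } else {
      episodes[[length(episodes) + 1L]] <- list(j = j, cohort = "no_id",
                                                entry = entry, exit = i_date)
      episodes[[length(episodes) + 1L]] <- list(j = j, cohort = "with_id",
                                                entry = i_date, exit = exit)
    }
  }

  # hash the pool by (practice, sex, birth year) for fast candidate lookup
  key <- paste(pre$practice_id, pre$sex, pre$birth_year, sep = "|")
  by_key <- split(seq_len(nrow(pre)), key)

  com_cols <- paste0("com_", CONDITIONS, "_date")
  n_ep <- length(episodes)
  rows <- vector("list", n_ep)
  report <- data.frame(matched_set_id = seq_len(n_ep),
                       cohort = character(n_ep),
                       entry_date = rep(as.Date(NA), n_ep),
                       n_requested = rep(as.integer(k), n_ep),
                       n_matched = integer(n_ep))
  for (s in seq_len(n_ep)) {
    ep <- episodes[[s]]; j <- ep$j
    idx <- by_key[[paste(pre$practice_id[j], pre$sex[j], pre$birth_year[j],
                         sep = "|")]]
    idx <- idx[idx != j]
    ok <- pre$entry_bound[idx] <= ep$entry &
      pre$exit_bound[idx] > ep$entry &
      (is.na(pre$first_diag[idx]) | pre$first_diag[idx] > ep$entry)
    cand <- idx[ok]
    sel <- if (length(cand) <= k) cand else sample(cand, k)
    report$cohort[s] <- ep$cohort
    report$entry_date[s] <- ep$entry
    report$n_matched[s] <- length(sel)

    # the diagnosed episode, then its comparisons censored at own diagnosis
    e_died <- exits$died[j] & exits$exit_date[j] == ep$exit
    c_exit <- pmin_date(pre$exit_bound[sel], pre$first_diag[sel])
    c_died <- exits$died[sel] & exits$exit_date[sel] == c_exit
    all_idx <- c(j, sel)
    rows[[s]] <- data.frame(
      person_id = population$person_id[all_idx],
      practice_id = population$practice_id[all_idx],
      matched_set_id = s,
      cohort = ep$cohort,
      group = c(paste0("exposed_", ep$cohort), rep("comparison", length(sel))),
      sex = population$sex[all_idx],
      birth_date = population$birth_date[all_idx],
      entry_date = ep$entry,
      exit_date = c(ep$exit, c_exit),
      died = c(e_died, c_died),
      death_certainty = population$death_certainty[all_idx],
      townsend_quintile = population$townsend_quintile[all_idx],
      stringsAsFactors = FALSE)
  }

  intervals <- if (n_ep) do.call(rbind, rows) else empty_intervals()
  intervals <- intervals[intervals$entry_date < intervals$exit_date, ,
                         drop = FALSE]
  # covariate status frozen at the interval's entry date
  if (nrow(intervals)) {
    m <- match(intervals$person_id, population$person_id)
    for (cc in CONDITIONS) {
      d <- population[[paste0("com_", cc, "_date")]][m]
      intervals[[paste0("cov_", cc)]] <- !is.na(d) & d <= intervals$entry_date
    }
  } else {
    for (cc in CONDITIONS) intervals[[paste0("cov_", cc)]] <- logical(0)
  }
  rownames(intervals) <- NULL

  structure(list(intervals = intervals,
                 k = as.integer(k),
                 match_report = report,
                 n_excluded_exposed = n_excluded,
                 include_possible_deaths = include_possible_deaths,
                 study_start = study_start, study_end = study_end,
                 notes = paste("comparison follow-up censored at own first",
                               "exposure or ID record; diagnosed persons with",
                               "a later ID record contribute to no_id before",
                               "and with_id after that record")),
            class = "matched_cohort")
}

empty_intervals <- function() {
  data.frame(person_id = character(0), practice_id = integer(0),
             matched_set_id = integer(0), cohort = character(0),
             group = character(0), sex = character(0),
             birth_date = as.Date(character(0)),
             entry_date = as.Date(character(0)),
             exit_date = as.Date(character(0)),
             died = logical(0), death_certainty = character(0),
             townsend_quintile = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.matched_cohort <- function(x, ...) {
  iv <- x$intervals
  cat("matched_cohort: ", nrow(iv), " follow-up intervals, k = ", x$k, "\n",
      sep = "")
  if (nrow(iv)) {
    tb <- table(iv$cohort, iv$group)
    print(tb)
    full <- sum(x$match_report$n_matched == x$match_report$n_requested)
    cat(sprintf("matched sets: %d (%d full, %d partial); %d diagnosed excluded (no follow-up)\n",
                nrow(x$match_report), full, nrow(x$match_report) - full,
                x$n_excluded_exposed))
  }
  invisible(x)
}
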