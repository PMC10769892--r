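#' Split follow-up intervals into single-year-of-age segments
#'
#' Lexis expansion by attained age: every day of each half-open interval
#' `[entry, exit)` is assigned the person's completed age on that day (the
#' birthday counts towards the new age). Days before the `age_min`-th
#' birthday are dropped; ages above `age_max` are pooled into the open
#' stratum at `age_max`. Exact in days: within the modelled age range the
#' segment lengths sum to the interval length.
#'
#' @param entry,exit,birth_date `Date` vectors of equal length; `entry < exit`.
#' @param age_min,age_max modelled age range (defaults 18 and 100).
#' @return data.frame with `interval` (index into the input), `age`
#'   (completed years), and `days` spent at that age.
#' @export
split_person_time <- function(entry, exit, birth_date,
                              age_min = 18, age_max = 100) {
  entry <- as.Date(entry); exit <- as.Date(exit)
  birth_date <- as.Date(birth_date)
  stopifnot(length(exit) == length(entry),
            length(birth_date) == length(entry))
  if (!length(entry))
    return(data.frame(interval = integer(0), age = integer(0),
                      days = integer(0)))
  if (any(entry >= exit)) stop("entry must precede exit for every interval")

  age_start <- age_completed(entry, birth_date)
  age_end <- age_completed(exit - 1L, birth_date)   # age on the last day lived
  n_seg <- age_end - age_start + 1L
  idx <- rep.int(seq_along(entry), n_seg)
  age <- age_start[idx] + sequence(n_seg) - 1L
  seg_start <- pmax(entry[idx], nth_birthday(birth_date[idx], age))
  seg_end <- pmin(exit[idx], nth_birthday(birth_date[idx], age + 1L))
  out <- data.frame(interval = idx, age = age,
                    days = as.integer(seg_end - seg_start))
  out <- out[out$age >= age_min, , drop = FALSE]
  out$age[out$age > age_max] <- age_max
  # merge pooled open-age rows belonging to the same interval
  if (any(duplicated(out[c("interval", "age")]))) {
    agg <- stats::aggregate(days ~ interval + age, data = out, FUN = sum)
    out <- agg[order(agg$interval, agg$age), c("interval", "age", "days")]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate deaths and person-years by group, sex, and single year of age
#'
#' Runs the Lexis expansion over every follow-up interval of a matched
#' cohort and sums person-time (in days, converted to years as days/365.25)
#' and deaths per (cohort, group, sex, age) stratum. A death is assigned to
#' the completed age on the last day of follow-up, so each death falls in a
#' stratum where the person contributed time. Optionally stratifies
#' additionally by entry-covariate columns for adjusted modelling.
#'
#' @param cohort a [build_cohort()] result, or a data.frame of follow-up
#'   intervals with columns `cohort`, `group`, `sex`, `birth_date`,
#'   `entry_date`, `exit_date`, `died`.
#' @param age_min,age_max modelled age range.
#' @param covariates optional character vector of interval columns (e.g.
#'   `"cov_epilepsy"`) to carry into the stratification.
#' @return data.frame with columns `cohort`, `group`, `sex`, `age`,
#'   any covariates, `deaths`, and `person_years`.
#' @export
aggregate_strata <- function(cohort, age_min = 18, age_max = 100,
                             covariates = NULL) {
  iv <- if (inherits(cohort, "matched_cohort")) cohort$intervals else cohort
  base_cols <- intersect(c("cohort", "group", "sex"), names(iv))
  if (!nrow(iv)) {
    out <- iv[, base_cols, drop = FALSE]
    out$age <- integer(0); out$deaths <- integer(0)
    out$person_years <- numeric(0)
    return(out)
  }
  seg <- split_person_time(iv$entry_date, iv$exit_date, iv$birth_date,
                           age_min, age_max)
  keys <- c(base_cols, covariates)
  seg_keys <- iv[seg$interval, keys, drop = FALSE]
  py <- stats::aggregate(seg$days,
                         by = c(seg_keys, list(age = seg$age)), FUN = sum)
  names(py)[ncol(py)] <- "days"

  death_age <- age_completed(iv$exit_date - 1L, iv$birth_date)
  dk <- which(iv$died & death_age >= age_min)
  deaths <- data.frame()
  if (length(dk)) {
    dage <- pmin(death_age[dk], age_max)
    deaths <- stats::aggregate(rep(1L, length(dk)),
                               by = c(iv[dk, keys, drop = FALSE],
                                      list(age = dage)), FUN = sum)
    names(deaths)[ncol(deaths)] <- "deaths"
  }
  out <- if (nrow(deaths)) merge(py, deaths, by = c(keys, "age"), all = TRUE)
         else cbind(py, deaths = 0L)
  out$deaths[is.na(out$deaths)] <- 0L
  out$days[is.na(out$days)] <- 0L
  out$person_years <- days_to_years(out$days)
  out$days <- NULL
  out <- out[do.call(order, out[c(keys, "age")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crude mortality rates per stratum
#'
#' @param strata output of [aggregate_strata()].
#' @param per scale of the reported rate (default per 100,000 person-years).
#' @return the strata with a `rate` column appended.
#' @export
crude_rates <- function(strata, per = 1e5) {
  strata$rate <- ifelse(strata$person_years > 0,
                        strata$deaths / strata$person_years * per, NA_real_)
  strata
}
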