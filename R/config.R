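CONDITIONS <- c("epilepsy", "genetic", "mobility", "visual", "hearing",
                "adhd", "smi", "self_harm")

GROUPS <- c("comparison", "exposed_no_id", "exposed_with_id")

#' Simulation configuration for the synthetic-cohort generator
#'
#' Bundles and validates every parameter of [simulate_population()]. The
#' defaults describe a UK-primary-care-like population: a rare diagnosed
#' exposure (about 1 in 450), ten matched comparison participants per
#' diagnosed participant, Gompertz-Makeham adult mortality calibrated so
#' that comparison-group total life expectancy at age 18 is about 80 years
#' for men and 83 for women, and group hazard ratios whose marginal
#' (comorbidity-inclusive) values are about 1.71 for the diagnosed group
#' without intellectual disability and 2.83 with.
#'
#' @param n_practices number of general practices.
#' @param persons_per_practice persons registered per practice.
#' @param exposure_prevalence probability a person is ever diagnosed.
#' @param id_fraction fraction of diagnosed persons who also acquire an
#'   intellectual-disability record.
#' @param comparison_ratio `k`, comparison participants sampled per
#'   diagnosed participant.
#' @param study_start,study_end study window (administrative censoring at
#'   `study_end`).
#' @param makeham_lambda,gompertz_alpha,gompertz_beta baseline (male,
#'   comparison) Gompertz-Makeham hazard parameters, per year.
#' @param group_hazard_ratios named multipliers for
#'   `comparison`, `exposed_no_id`, `exposed_with_id`. These are the
#'   *direct* effects; comorbidity effects multiply on top.
#' @param sex_hazard_ratio hazard multiplier for women relative to men.
#' @param comorbidity_prevalences named list (one numeric vector per group)
#'   of lifetime flag probabilities for the eight recorded conditions.
#' @param comorbidity_hazard_ratios named hazard multipliers per condition.
#' @param deregistration_rate exponential practice-leaving rate per year.
#' @param possible_death_fraction fraction of deaths flagged "possible"
#'   rather than "definite".
#' @param quality_start_range years, relative to `study_start`, between
#'   which each practice's data-quality window opens (uniform).
#' @param birth_year_range calendar years births are drawn from (uniform).
#' @param registration_age_range age at practice registration (uniform).
#' @param diagnosis_age_min,diagnosis_age_mean,diagnosis_age_max age at
#'   first diagnosis: `min + Exp(mean - min)` truncated at `max`.
#' @param id_delay_mean mean years between first diagnosis and the
#'   intellectual-disability record.
#' @param townsend_missing probability the deprivation quintile is missing.
#' @param seed root random seed; practice-level child streams are derived
#'   from it, so records of practice `i` do not depend on `n_practices`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_practices = 20,
                       persons_per_practice = 500,
                       exposure_prevalence = 1 / 450,
                       id_fraction = 0.274,
                       comparison_ratio = 10,
                       study_start = as.Date("1989-01-01"),
                       study_end = as.Date("2019-01-16"),
                       makeham_lambda = 5e-5,
                       gompertz_alpha = 2.674351e-05,
                       gompertz_beta = 0.095,
                       group_hazard_ratios = c(comparison = 1,
                                               exposed_no_id = 1.531,
                                               exposed_with_id = 2.002),
                       sex_hazard_ratio = 0.7536403,
                       comorbidity_prevalences = default_comorbidity_prevalences(),
                       comorbidity_hazard_ratios = c(epilepsy = 2, genetic = 2,
                                                     mobility = 1.5, visual = 1,
                                                     hearing = 1, adhd = 1,
                                                     smi = 1.5, self_harm = 1.5),
                       deregistration_rate = 0.05,
                       possible_death_fraction = 0.02,
                       quality_start_range = c(-4, 16),
                       birth_year_range = c(1929, 2000),
                       registration_age_range = c(0, 40),
                       diagnosis_age_min = 2,
                       diagnosis_age_mean = 14,
                       diagnosis_age_max = 70,
                       id_delay_mean = 4,
                       townsend_missing = 0.2,
                       seed = 1L) {
  cfg <- list(n_practices = as.integer(n_practices),
              persons_per_practice = as.integer(persons_per_practice),
              exposure_prevalence = exposure_prevalence,
              id_fraction = id_fraction,
              comparison_ratio = as.integer(comparison_ratio),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              makeham_lambda = makeham_lambda,
              gompertz_alpha = gompertz_alpha,
              gompertz_beta = gompertz_beta,
              group_hazard_ratios = group_hazard_ratios,
              sex_hazard_ratio = sex_hazard_ratio,
              comorbidity_prevalences = comorbidity_prevalences,
              comorbidity_hazard_ratios = comorbidity_hazard_ratios,
              deregistration_rate = deregistration_rate,
              possible_death_fraction = possible_death_fraction,
              quality_start_range = quality_start_range,
              birth_year_range = birth_year_range,
              registration_age_range = registration_age_range,
              diagnosis_age_min = diagnosis_age_min,
              diagnosis_age_mean = diagnosis_age_mean,
              diagnosis_age_max = diagnosis_age_max,
              id_delay_mean = id_delay_mean,
              townsend_missing = townsend_missing,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

default_comorbidity_prevalences <- function() {
  list(
    comparison      = c(epilepsy = 0.010, genetic = 0.005, mobility = 0.0025,
                        visual = 0.003, hearing = 0.017, adhd = 0.017,
                        smi = 0.005, self_harm = 0.025),
    exposed_no_id   = c(epilepsy = 0.051, genetic = 0.015, mobility = 0.009,
                        visual = 0.007, hearing = 0.021, adhd = 0.145,
                        smi = 0.056, self_harm = 0.092),
    exposed_with_id = c(epilepsy = 0.213, genetic = 0.083, mobility = 0.042,
                        visual = 0.020, hearing = 0.034, adhd = 0.114,
                        smi = 0.109, self_harm = 0.062))
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) stop("invalid sim_config field '", field, "': ", why,
                                   call. = FALSE)
  probs <- c(exposure_prevalence = cfg$exposure_prevalence,
             id_fraction = cfg$id_fraction,
             possible_death_fraction = cfg$possible_death_fraction,
             townsend_missing = cfg$townsend_missing)
  for (p in names(probs))
    if (!is.finite(probs[[p]]) || probs[[p]] < 0 || probs[[p]] > 1)
      bad(p, "must be a probability in [0, 1]")
  if (cfg$n_practices < 1) bad("n_practices", "must be >= 1")
  if (cfg$persons_per_practice < 1) bad("persons_per_practice", "must be >= 1")
  if (cfg$comparison_ratio < 1) bad("comparison_ratio", "k must be >= 1")
  if (cfg$study_start >= cfg$study_end) bad("study_start", "must precede study_end")
  for (h in c("makeham_lambda", "gompertz_alpha", "gompertz_beta",
              "deregistration_rate"))
    if (!is.finite(cfg[[h]]) || cfg[[h]] < 0) bad(h, "must be finite and >= 0")
  if (cfg$makeham_lambda == 0 && cfg$gompertz_alpha == 0)
    bad("makeham_lambda", "hazard is identically zero")
  if (!all(GROUPS %in% names(cfg$group_hazard_ratios)))
    bad("group_hazard_ratios", paste("must name", paste(GROUPS, collapse = ", ")))
  if (any(cfg$group_hazard_ratios <= 0)) bad("group_hazard_ratios", "must be > 0")
  if (cfg$sex_hazard_ratio <= 0) bad("sex_hazard_ratio", "must be > 0")
  if (!all(GROUPS %in% names(cfg$comorbidity_prevalences)))
    bad("comorbidity_prevalences", "must have one entry per group")
  for (g in GROUPS) {
    p <- cfg$comorbidity_prevalences[[g]]
    if (!all(CONDITIONS %in% names(p)))
      bad("comorbidity_prevalences", paste0("group '", g, "' must name all of: ",
                                            paste(CONDITIONS, collapse = ", ")))
    if (any(p < 0 | p > 1))
      bad("comorbidity_prevalences", paste0("group '", g, "' outside [0, 1]"))
  }
  if (!all(CONDITIONS %in% names(cfg$comorbidity_hazard_ratios)))
    bad("comorbidity_hazard_ratios", "must name every condition")
  if (any(cfg$comorbidity_hazard_ratios <= 0))
    bad("comorbidity_hazard_ratios", "must be > 0")
  if (cfg$diagnosis_age_min >= cfg$diagnosis_age_max)
    bad("diagnosis_age_min", "must be < diagnosis_age_max")
  if (length(cfg$quality_start_range) != 2 ||
      cfg$quality_start_range[1] > cfg$quality_start_range[2])
    bad("quality_start_range", "must be an ordered pair of years")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_practices, "practices x", x$persons_per_practice, "persons;",
      sprintf("exposure prevalence %.4g;", x$exposure_prevalence),
      "k =", x$comparison_ratio, "\n")
  cat(sprintf("  Gompertz-Makeham: lambda=%.3g alpha=%.3g beta=%.3g; sex HR %.3f\n",
              x$makeham_lambda, x$gompertz_alpha, x$gompertz_beta,
              x$sex_hazard_ratio))
  cat("  group hazard ratios:",
      paste(names(x$group_hazard_ratios), round(x$group_hazard_ratios, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  window:", format(x$study_start), "to", format(x$study_end),
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$comorbidity_prevalences))
    raw$comorbidity_prevalences <- lapply(raw$comorbidity_prevalences, unlist)
  for (f in c("group_hazard_ratios", "comorbidity_hazard_ratios"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$study_start <- format(out$study_start)
  out$study_end <- format(out$study_end)
  out$group_hazard_ratios <- as.list(out$group_hazard_ratios)
  out$comorbidity_hazard_ratios <- as.list(out$comorbidity_hazard_ratios)
  out$comorbidity_prevalences <- lapply(out$comorbidity_prevalences, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
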