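# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: day-by-day loops, scalar recursions, quadrature.

# continuous Gompertz-Makeham survival, S(t | alive at a0), by quadrature
oracle_gm_survival <- function(t, a0, lambda, alpha, beta, mult = 1) {
  sapply(t, function(tt) {
    H <- stats::integrate(function(a) mult * (lambda + alpha * exp(beta * a)),
                          a0, tt, rel.tol = 1e-10)$value
    exp(-H)
  })
}

# remaining life expectancy at a0 by quadrature of the survival curve
oracle_gm_expectancy <- function(a0, lambda, alpha, beta, mult = 1,
                                 horizon = 150) {
  stats::integrate(function(t)
    oracle_gm_survival(t, a0, lambda, alpha, beta, mult),
    a0, horizon, rel.tol = 1e-9, subdivisions = 500L)$value
}

# completed age of one calendar day, computed without the package helpers:
# count whole years by stepping the year number and comparing month/day.
oracle_age_on_day <- function(day, birth) {
  dy <- as.integer(format(day, "%Y")); by <- as.integer(format(birth, "%Y"))
  dmd <- as.integer(format(day, "%m")) * 100L + as.integer(format(day, "%d"))
  bmd <- as.integer(format(birth, "%m")) * 100L + as.integer(format(birth, "%d"))
  dy - by - as.integer(dmd < bmd)
}

# brute-force Lexis split: iterate every day of [entry, exit)
oracle_split_days <- function(entry, exit, birth, age_min = 18, age_max = 100) {
  days <- seq(entry, exit - 1, by = "day")
  ages <- oracle_age_on_day(days, birth)
  ages <- ages[ages >= age_min]
  if (!length(ages)) return(data.frame(age = integer(0), days = integer(0)))
  ages[ages > age_max] <- age_max
  tb <- table(ages)
  data.frame(age = as.integer(names(tb)), days = as.integer(tb))
}

# spreadsheet-style scalar life-table recursion
oracle_life_table <- function(m, ages = 18:100, radix = 1e5) {
  n <- length(ages)
  l <- numeric(n); q <- numeric(n); d <- numeric(n); L <- numeric(n)
  l[1] <- radix
  for (i in seq_len(n)) {
    q[i] <- if (i == n) 1 else m[i] / (1 + 0.5 * m[i])
    d[i] <- l[i] * q[i]
    L[i] <- if (i == n) l[i] / m[i] else l[i] - 0.5 * d[i]
    if (i < n) l[i + 1] <- l[i] - d[i]
  }
  Tx <- numeric(n)
  for (i in n:1) Tx[i] <- L[i] + if (i < n) Tx[i + 1] else 0
  list(l = l, q = q, d = d, L = L, T = Tx, e = Tx / l,
       e_total = ages[1] + Tx[1] / l[1])
}

# six calendar months later, clamping to the last day of the target month,
# written as trial-and-error date construction rather than field arithmetic
oracle_plus_6_months <- function(date) {
  y <- as.integer(format(date, "%Y")); m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  m <- m + 6L
  if (m > 12L) { m <- m - 12L; y <- y + 1L }
  repeat {
    out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
    if (!is.na(out)) return(out)
    d <- d - 1L
  }
}

# independently coded eligibility predicate for comparison sampling
oracle_eligible <- function(pool, exposed, index,
                            study_start = as.Date("1989-01-01"),
                            study_end = as.Date("2019-01-16")) {
  ok <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    p <- pool[i, ]
    if (p$person_id == exposed$person_id) next
    if (p$sex != exposed$sex) next
    if (format(p$birth_date, "%Y") != format(exposed$birth_date, "%Y")) next
    if (p$practice_id != exposed$practice_id) next
    entry_b <- max(p$practice_quality_start,
                   oracle_plus_6_months(p$registration_date),
                   study_start)
    if (entry_b > index) next
    exit_b <- min(p$death_date, study_end, na.rm = TRUE)
    if (!is.na(p$deregistration_date)) exit_b <- min(exit_b, p$deregistration_date)
    exit_b <- min(exit_b, p$practice_last_collection)
    if (exit_b <= index) next
    if (!is.na(p$exposure_diagnosis_date) && p$exposure_diagnosis_date <= index) next
    if (!is.na(p$id_diagnosis_date) && p$id_diagnosis_date <= index) next
    ok[i] <- TRUE
  }
  ok
}
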