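#' Round half away from zero
#'
#' Display rounding used for percentages in descriptive tables: ties are
#' rounded up (0.625 -> 0.63) rather than to even as [base::round()] does.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Completed age in years on a given date
#'
#' Age as demographers count it: the number of birthdays that have passed.
#' The birthday itself counts towards the new age. A person born on 29
#' February reaches the next age on 1 March in non-leap years.
#'
#' @param date,birth_date `Date` vectors (recycled to common length).
#' @return integer vector of completed ages.
#' @export
age_completed <- function(date, birth_date) {
  n <- max(length(date), length(birth_date))
  date <- rep_len(as.Date(date), n)
  birth_date <- rep_len(as.Date(birth_date), n)
  d <- as.POSIXlt(date)
  b <- as.POSIXlt(birth_date)
  ydiff <- d$year - b$year
  # has this year's birthday occurred? compare (month, day) lexicographically
  before <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  as.integer(ydiff - before)
}

# Date of the b-th birthday. 29 Feb maps to 1 Mar in non-leap years, which
# keeps age_completed() and nth_birthday() mutually consistent.
nth_birthday <- function(birth_date, b) {
  n <- max(length(birth_date), length(b))
  birth_date <- rep_len(as.Date(birth_date), n)
  b <- rep_len(as.integer(b), n)
  lt <- as.POSIXlt(birth_date)
  y <- lt$year + 1900L + b
  m <- lt$mon + 1L
  d <- lt$mday
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(y)   # 29 Feb in a non-leap target year
  if (any(bad)) out[bad] <- as.Date(sprintf("%04d-03-01", y[bad]))
  out
}

# Add calendar months, clamping the day of month (31 Aug + 6 months -> 28/29 Feb).
add_months <- function(date, n) {
  lt <- as.POSIXlt(as.Date(date))
  tot <- lt$year * 12L + lt$mon + as.integer(n)
  y <- tot %/% 12L + 1900L
  m <- tot %% 12L + 1L
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  last[m == 2L & leap] <- 29L
  as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(lt$mday, last)))
}

# days -> years under the 365.25-day convention used throughout
days_to_years <- function(days) as.numeric(days) / 365.25

# pmax/pmin over date columns where NA means "no such event"
pmax_date <- function(...) {
  args <- lapply(list(...), as.Date)
  out <- Reduce(function(a, b) {
    r <- pmax(a, b, na.rm = TRUE)
    r[is.na(a) & is.na(b)] <- NA
    r
  }, args)
  as.Date(out, origin = "1970-01-01")
}

pmin_date <- function(...) {
  args <- lapply(list(...), as.Date)
  out <- Reduce(function(a, b) {
    r <- pmin(a, b, na.rm = TRUE)
    r[is.na(a) & is.na(b)] <- NA
    r
  }, args)
  as.Date(out, origin = "1970-01-01")
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
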