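#' Gompertz-Makeham hazard and related quantities
#'
#' The adult mortality model used by the synthetic-cohort generator:
#' \deqn{h(a) = m \left(\lambda + \alpha e^{\beta a}\right)}
#' where `a` is age in years, `lambda` a constant background hazard,
#' `alpha` the senescent hazard at age 0, `beta` the log-hazard slope per
#' year of age, and `m` a proportional multiplier (group, sex and
#' comorbidity effects combined).
#'
#' @param age age in years (vector).
#' @param lambda,alpha,beta Gompertz-Makeham parameters; `lambda, alpha >= 0`,
#'   not both zero, `beta > 0` (or `alpha = 0`).
#' @param multiplier proportional hazard multiplier, `> 0`.
#' @return `gm_hazard()`: hazard per person-year; `gm_cumhaz()`: integrated
#'   hazard from age 0; `gm_survival()`: probability of surviving from age
#'   `from` to `age`.
#' @export
gm_hazard <- function(age, lambda, alpha, beta, multiplier = 1) {
  check_gm(lambda, alpha, beta, multiplier)
  multiplier * (lambda + alpha * exp(beta * age))
}

#' @rdname gm_hazard
#' @export
gm_cumhaz <- function(age, lambda, alpha, beta, multiplier = 1) {
  check_gm(lambda, alpha, beta, multiplier)
  if (alpha == 0) return(multiplier * lambda * age)
  multiplier * (lambda * age + alpha / beta * (exp(beta * age) - 1))
}

#' @rdname gm_hazard
#' @param from age survival is conditioned on (default 0).
#' @export
gm_survival <- function(age, lambda, alpha, beta, multiplier = 1, from = 0) {
  exp(-(gm_cumhaz(age, lambda, alpha, beta, multiplier) -
          gm_cumhaz(from, lambda, alpha, beta, multiplier)))
}

check_gm <- function(lambda, alpha, beta, multiplier) {
  vals <- c(lambda = lambda, alpha = alpha, beta = beta, multiplier = multiplier)
  if (any(!is.finite(vals)))
    stop("non-finite hazard parameter: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (lambda < 0 || alpha < 0) stop("lambda and alpha must be >= 0")
  if (lambda == 0 && alpha == 0) stop("hazard is identically zero")
  if (alpha > 0 && beta <= 0) stop("beta must be > 0 when alpha > 0")
  if (any(multiplier <= 0)) stop("multiplier must be > 0")
  invisible(TRUE)
}

#' Sample ages at death from a Gompertz-Makeham hazard
#'
#' Inverse-transform sampling of the age at death conditional on survival
#' to `age0`: draws solve \eqn{H(T) - H(a_0) = E/m} with `E` standard
#' exponential and `H` the unit-multiplier cumulative hazard. The general
#' case is solved by vectorised bisection (the cumulative hazard is strictly
#' increasing); the pure-exponential (`alpha = 0`) and pure-Gompertz
#' (`lambda = 0`) cases use their closed forms.
#'
#' @param n number of draws.
#' @param age0 age(s) survival is conditioned on; recycled to length `n`.
#' @inheritParams gm_hazard
#' @return numeric vector of length `n`, ages at death, all `> age0`.
#' @export
sample_death_age <- function(n, age0 = 0, lambda, alpha, beta, multiplier = 1) {
  check_gm(lambda, alpha, beta, max(multiplier))
  if (any(multiplier <= 0) || any(!is.finite(multiplier)))
    stop("multiplier must be finite and > 0")
  age0 <- rep_len(age0, n)
  multiplier <- rep_len(multiplier, n)
  target <- gm_cumhaz(age0, lambda, alpha, beta) + stats::rexp(n) / multiplier
  if (alpha == 0) return(target / lambda)
  if (lambda == 0) return(log(1 + beta * target / alpha) / beta)
  # bisection: expand upper bound, then ~60 halvings (precision ~1e-9 years)
  lo <- age0
  span <- rep(120, n)
  repeat {
    hi <- lo + span
    short <- gm_cumhaz(hi, lambda, alpha, beta) < target
    if (!any(short)) break
    span[short] <- span[short] * 2
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- gm_cumhaz(mid, lambda, alpha, beta) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}
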