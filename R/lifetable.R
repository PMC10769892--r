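#' Build a period life table from age-specific mortality rates
#'
#' ONS-style period life table over single years of age. Within each
#' closed age interval deaths are assumed to occur on average mid-year
#' (`ax = 0.5`), giving \eqn{q_x = m_x / (1 + (1 - a_x) m_x)}; the final
#' age is an open interval closed under a constant hazard,
#' \eqn{L_{x^+} = l_{x^+} / m_{x^+}}. The summary statistic is the total
#' expected age at the first table age: `ages[1] + e_{ages[1]}`.
#'
#' @param m central mortality rates per person-year, one per age in `ages`,
#'   all `>= 0`; the open-age rate must be `> 0`.
#' @param ages integer ages (default 18 to 100; the last is the open
#'   interval).
#' @param radix size of the synthetic birth cohort at `ages[1]`.
#' @param ax average fraction of the year lived by those dying within a
#'   closed interval.
#' @return data.frame of class `life_table` with columns `age`, `m`, `q`,
#'   `l`, `d`, `L`, `T`, `e`; the total expectancy is available via
#'   [total_life_expectancy()] or `attr(, "e_total")`.
#' @export
build_life_table <- function(m, ages = 18:100, radix = 1e5, ax = 0.5) {
  n <- length(ages)
  if (length(m) != n) stop("need one rate per age (", n, ")")
  if (any(!is.finite(m)) || any(m < 0)) stop("rates must be finite and >= 0")
  if (m[n] <= 0) stop("the open-interval rate m[", ages[n],
                      "] must be > 0 to close the table")
  q <- pmin(m / (1 + (1 - ax) * m), 1)   # q = 1 caps very high rates
  q[n] <- 1
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- l - (1 - ax) * d
  L[n] <- l[n] / m[n]
  Tx <- rev(cumsum(rev(L)))
  e <- Tx / l
  out <- data.frame(age = ages, m = m, q = q, l = l, d = d, L = L,
                    T = Tx, e = e)
  attr(out, "radix") <- radix
  attr(out, "e_total") <- ages[1] + e[1]
  class(out) <- c("life_table", "data.frame")
  out
}

#' Total expected age from a life table
#'
#' The table's starting age plus remaining life expectancy at that age
#' (reported on the "age 18 + e18" convention when the table starts at 18).
#'
#' @param lt a [build_life_table()] result.
#' @return total expected age in years.
#' @export
total_life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  attr(lt, "e_total")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("life_table: ages %d-%d (open), radix %s, total expectancy at %d: %.2f years\n",
              min(x$age), max(x$age), format(attr(x, "radix")),
              min(x$age), attr(x, "e_total")))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4, ...)
  cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Years of life lost at the table's starting age
#'
#' Difference in total expectancy between the comparison and the diagnosed
#' group's life tables (positive when the diagnosed group's expectancy is
#' lower; may be negative).
#'
#' @param lt_exposed,lt_comparison life tables on the same age range.
#' @return years of life lost (scalar).
#' @export
years_of_life_lost <- function(lt_exposed, lt_comparison) {
  stopifnot(inherits(lt_exposed, "life_table"),
            inherits(lt_comparison, "life_table"))
  if (!identical(lt_exposed$age, lt_comparison$age))
    stop("life tables must share the same age range")
  total_life_expectancy(lt_comparison) - total_life_expectancy(lt_exposed)
}

# vectorised life-expectancy over rows of a rate matrix (draws x ages)
e_total_from_rate_matrix <- function(R, ages, ax = 0.5) {
  n <- ncol(R)
  R <- pmin(R, 1e12)   # guard against overflow in extreme coefficient draws
  q <- pmin(R / (1 + (1 - ax) * R), 1)
  q[, n] <- 1
  lp <- log1p(-q[, -n, drop = FALSE])
  l <- cbind(1, exp(t(apply(lp, 1, cumsum))))          # l_x / radix
  d <- l * q
  L <- l - (1 - ax) * d
  L[, n] <- l[, n] / R[, n]
  ages[1] + rowSums(L)
}

#' Monte-Carlo confidence intervals for life expectancy and YLL
#'
#' Propagates the uncertainty of the fitted Poisson mortality models into
#' the life-table summary: coefficient vectors are drawn from the
#' multivariate normal \eqn{N(\hat\beta, \hat\Sigma)} independently for
#' the diagnosed and comparison fits, rates and a life table are rebuilt
#' for every draw, and percentile (2.5/97.5) intervals are taken over the
#' simulated total expectancies and their differences. Point estimates
#' come from the fitted coefficients themselves. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param fit [fit_poisson_quadratic()] result for the diagnosed group.
#' @param comparison_fit optional fit for the comparison group; when
#'   given, years-of-life-lost draws (comparison minus diagnosed, paired
#'   across independent draws) are summarised too.
#' @param n_sim number of simulations (default 10,000; at least 1,000 is
#'   recommended for reported intervals).
#' @param seed integer seed.
#' @param ages life-table age range.
#' @param conf_level confidence level.
#' @return object of class `life_expectancy_estimate`: per group a list
#'   with `point`, `ci_low`, `ci_high`, and `bracket_ok` (FALSE flags a
#'   percentile interval that fails to bracket the point estimate; the
#'   interval is never reordered), plus `yll` when two fits are given,
#'   and `n_sim`, `seed`.
#' @export
simulate_ci <- function(fit, comparison_fit = NULL, n_sim = 10000,
                        seed = 1L, ages = 18:100, conf_level = 0.95) {
  stopifnot(inherits(fit, "rate_model_fit"), n_sim >= 1)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  X <- cbind(1, ages, ages^2)

  draw_e <- function(f) {
    b <- f$coefficients[1:3]
    V <- as.matrix(f$vcov)[1:3, 1:3]
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("coefficient covariance is not positive semi-definite ",
           "(min eigenvalue ", format(min(ev)), ")")
    B <- MASS::mvrnorm(n_sim, mu = b, Sigma = V, tol = 1e-6)
    if (n_sim == 1) B <- matrix(B, nrow = 1)
    R <- exp(B %*% t(X))
    # adult all-cause mortality is non-decreasing in age: monotonise each
    # draw so a noisy downward-curving fit cannot explode the open interval
    R <- t(apply(R, 1, cummax))
    e_total_from_rate_matrix(R, ages)
  }
  point_e <- function(f)
    total_life_expectancy(build_life_table(cummax(predict_rates(f, ages)),
                                           ages))

  res <- with_seed(seed, {
    e_exp <- draw_e(fit)
    e_comp <- if (!is.null(comparison_fit)) draw_e(comparison_fit)
    list(e_exp = e_exp, e_comp = e_comp)
  })

  summarise <- function(point, draws) {
    point <- unname(point)
    ci <- unname(stats::quantile(draws, probs))
    tol <- 1e-9 * max(1, abs(point))
    list(point = point, ci_low = ci[1], ci_high = ci[2],
         bracket_ok = ci[1] <= point + tol && point <= ci[2] + tol)
  }
  out <- list(exposed = summarise(point_e(fit), res$e_exp),
              n_sim = n_sim, seed = seed, conf_level = conf_level)
  if (!is.null(comparison_fit)) {
    p_comp <- point_e(comparison_fit)
    out$comparison <- summarise(p_comp, res$e_comp)
    out$yll <- summarise(p_comp - point_e(fit), res$e_comp - res$e_exp)
  }
  class(out) <- "life_expectancy_estimate"
  out
}

#' @export
print.life_expectancy_estimate <- function(x, ...) {
  line <- function(lbl, s) {
    cat(sprintf("  %-11s %6.2f (%.2f-%.2f)%s\n", lbl, s$point, s$ci_low,
                s$ci_high, if (!s$bracket_ok) "  [interval fails to bracket point]" else ""))
  }
  cat(sprintf("life expectancy at table start (n_sim = %d, seed = %d):\n",
              x$n_sim, x$seed))
  line("diagnosed", x$exposed)
  if (!is.null(x$comparison)) {
    line("comparison", x$comparison)
    line("YLL", x$yll)
  }
  invisible(x)
}
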