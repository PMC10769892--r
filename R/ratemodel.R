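#' Fit a log-quadratic Poisson mortality model to age strata
#'
#' Maximum-likelihood fit of
#' \deqn{D_a \sim \mathrm{Poisson}\{\exp(\beta_0 + \beta_1 a + \beta_2 a^2
#'   + \gamma' z)\, Y_a\}}
#' where `D` are stratum death counts, `Y` person-years (log offset), `a`
#' single year of age, and `z` optional covariate columns. Internally age
#' is centred at 60 and scaled by 1/10 for conditioning; coefficients and
#' their covariance are reported on the natural age scale.
#'
#' @param strata data.frame with `age`, `deaths`, `person_years` (zero
#'   person-year strata are dropped before fitting) and any covariate
#'   columns; at least 3 informative strata and at least one death are
#'   required.
#' @param covariates character vector of additional design columns.
#' @param group optional label stored on the fit.
#' @return object of class `rate_model_fit`: natural-scale `coefficients`
#'   (`intercept`, `age`, `age2`, covariates), `vcov`, `deviance`,
#'   `n_strata`, `converged`, `group`.
#' @export
fit_poisson_quadratic <- function(strata, covariates = NULL, group = NULL) {
  strata <- strata[strata$person_years > 0, , drop = FALSE]
  if (nrow(strata) < 3)
    stop("need at least 3 strata with positive person-years")
  if (sum(strata$deaths) == 0)
    stop("all strata have zero deaths; the mortality rate is not ",
         "identifiable - pool more person-time before fitting")
  z <- (strata$age - 60) / 10
  X <- cbind(`(Intercept)` = 1, z = z, z2 = z^2)
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(strata))
    if (length(miss)) stop("missing covariate columns: ",
                           paste(miss, collapse = ", "))
    Z <- as.matrix(data.frame(lapply(strata[covariates], as.numeric)))
    constant <- apply(Z, 2, function(v) length(unique(v)) == 1)
    if (any(constant)) {   # a constant indicator is aliased with the intercept
      covariates <- covariates[!constant]
      Z <- Z[, !constant, drop = FALSE]
    }
    X <- cbind(X, Z)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, strata$deaths, family = stats::poisson(),
    offset = log(strata$person_years),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  if (!fit$converged && fit$deviance < 1e-8)
    fit$converged <- TRUE   # saturated-fit oscillation at machine precision
  if (!fit$converged)
    stop("Poisson fit did not converge after 100 IRLS iterations ",
         "(deviance ", format(fit$deviance), ", ",
         nrow(strata), " strata, ", sum(strata$deaths), " deaths)")
  if (any(is.na(fit$coefficients)))
    stop("collinear design: coefficients not estimable for ",
         paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
  # observed information on the working scale, then map to natural age scale
  w <- fit$weights
  V_scaled <- solve(crossprod(X * sqrt(w)))
  b <- fit$coefficients
  p <- length(b)
  # natural beta = T %*% b with age = 60 + 10 z
  T_mat <- diag(p)
  dimnames(T_mat) <- list(c("intercept", "age", "age2", colnames(X)[-(1:3)]),
                          colnames(X))
  T_mat[1, 1:3] <- c(1, -6, 36)
  T_mat[2, 2:3] <- c(1 / 10, -1.2)
  T_mat[3, 3] <- 1 / 100
  beta <- drop(T_mat %*% b)
  vcov <- T_mat %*% V_scaled %*% t(T_mat)
  structure(list(coefficients = beta, vcov = vcov,
                 coefficients_scaled = b, vcov_scaled = V_scaled,
                 deviance = fit$deviance, n_strata = nrow(strata),
                 n_deaths = sum(strata$deaths),
                 person_years = sum(strata$person_years),
                 converged = fit$converged, covariates = covariates,
                 group = group %||% unique(as.character(strata$group %||% NA))),
            class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat("rate_model_fit", if (!is.null(x$group) && !all(is.na(x$group)))
    paste0("[", paste(x$group, collapse = "/"), "]"), "\n")
  cat(sprintf("  log-rate = %.4f %+.4g*age %+.4g*age^2",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  if (length(x$coefficients) > 3) cat(" + covariates")
  cat(sprintf("\n  %d strata, %d deaths, %.0f person-years, deviance %.2f\n",
              x$n_strata, x$n_deaths, x$person_years, x$deviance))
  invisible(x)
}

#' Predicted mortality rates from a fitted quadratic model
#'
#' @param fit a [fit_poisson_quadratic()] result.
#' @param ages integer ages to predict at.
#' @return named numeric vector of rates per person-year (covariates at
#'   their reference level 0).
#' @export
predict_rates <- function(fit, ages = 18:100) {
  stopifnot(inherits(fit, "rate_model_fit"))
  b <- fit$coefficients
  r <- exp(b[1] + b[2] * ages + b[3] * ages^2)
  names(r) <- ages
  r
}

#' Serialise a fit to JSON (and back)
#'
#' @param fit a `rate_model_fit`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         vcov = unname(as.matrix(fit$vcov)),
         deviance = fit$deviance, n_strata = fit$n_strata,
         n_deaths = fit$n_deaths, person_years = fit$person_years,
         covariates = fit$covariates, group = fit$group),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(raw$coefficients)
  vcov <- matrix(unlist(raw$vcov), length(beta), length(beta),
                 dimnames = list(names(beta), names(beta)), byrow = FALSE)
  structure(list(coefficients = beta, vcov = vcov, deviance = raw$deviance,
                 n_strata = raw$n_strata, n_deaths = raw$n_deaths,
                 person_years = raw$person_years, converged = TRUE,
                 covariates = raw$covariates, group = raw$group),
            class = "rate_model_fit")
}

#' Age- and sex-standardised mortality ratio (indirect standardisation)
#'
#' Expected deaths are the comparison group's crude stratum rates applied
#' to the diagnosed group's person-years, summed over (age, sex) cells;
#' the SMR is observed over expected deaths, with a 95% confidence interval
#' from Byar's approximation to the Poisson distribution of the observed
#' count. Cells with diagnosed person-time but no comparison person-time
#' cannot contribute an expected count and are dropped (and reported).
#'
#' @param exposed_strata,comparison_strata stratum tables from
#'   [aggregate_strata()]; matched on `age` and, when present in both,
#'   `sex`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `rate_ratio_estimate` with `estimate`,
#'   `ci_low`, `ci_high`, `observed`, `expected`, `method`,
#'   `dropped_cells`.
#' @export
standardised_mortality_ratio <- function(exposed_strata, comparison_strata,
                                         conf_level = 0.95) {
  by <- intersect(intersect(c("sex", "age"), names(exposed_strata)),
                  names(comparison_strata))
  # collapse any finer stratification (cohort, covariates) onto the cells
  cells <- function(st) {
    agg <- stats::aggregate(st[c("deaths", "person_years")], by = st[by],
                            FUN = sum)
    agg[agg$person_years > 0, , drop = FALSE]
  }
  comp <- cells(comparison_strata)
  comp$comp_rate <- comp$deaths / comp$person_years
  m <- merge(cells(exposed_strata), comp[, c(by, "comp_rate")],
             by = by, all.x = TRUE)
  dropped <- m[is.na(m$comp_rate), by, drop = FALSE]
  kept <- m[!is.na(m$comp_rate), , drop = FALSE]
  E <- sum(kept$comp_rate * kept$person_years)
  O <- sum(kept$deaths)
  if (E == 0) stop("expected deaths are zero: comparison strata carry no ",
                   "events in the cells where diagnosed person-time exists")
  ci <- byar_ci(O, conf_level)
  structure(list(estimate = O / E, ci_low = ci[1] / E, ci_high = ci[2] / E,
                 observed = O, expected = E, method = "standardised",
                 conf_level = conf_level, covariates = NULL,
                 dropped_cells = dropped),
            class = "rate_ratio_estimate")
}

# Byar's approximation to the Poisson confidence limits for a count
byar_ci <- function(O, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- if (O == 0) 0 else O * (1 - 1 / (9 * O) - z / (3 * sqrt(O)))^3
  hi <- (O + 1) * (1 - 1 / (9 * (O + 1)) + z / (3 * sqrt(O + 1)))^3
  c(lo, hi)
}

#' Covariate-adjusted mortality rate ratio from a Poisson model
#'
#' Fits a Poisson model with a diagnosed-group indicator, linear and
#' quadratic age, sex (when both sexes are present), and the requested
#' entry-covariate indicators, with the log person-years offset; returns
#' the exponentiated group coefficient with a Wald confidence interval on
#' the log scale.
#'
#' @param strata stratum table containing both groups, with a `group`
#'   column (`"comparison"` is the reference; any other value is treated
#'   as diagnosed) and the covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty for the unadjusted model).
#' @param conf_level confidence level.
#' @return a `rate_ratio_estimate` with `method = "model_adjusted"` and the
#'   underlying `fit` attached.
#' @export
adjusted_rate_ratio <- function(strata, covariates = character(0),
                                conf_level = 0.95) {
  strata <- strata[strata$person_years > 0, , drop = FALSE]
  strata$exposed_group <- as.numeric(strata$group != "comparison")
  if (length(unique(strata$exposed_group)) < 2)
    stop("need strata from both the diagnosed and the comparison group")
  design <- "exposed_group"
  if ("sex" %in% names(strata) && length(unique(strata$sex)) > 1) {
    strata$sex_female <- as.numeric(strata$sex == "female")
    design <- c(design, "sex_female")
  }
  design <- c(design, covariates)
  fit <- fit_poisson_quadratic(strata, covariates = design)
  est <- fit$coefficients["exposed_group"]
  se <- sqrt(fit$vcov["exposed_group", "exposed_group"])
  if (abs(est) > 10)
    stop("apparent separation: group coefficient ", format(exp(est)),
         " on the rate-ratio scale; check covariates ",
         paste(covariates, collapse = ", "))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = unname(exp(est)),
                 ci_low = unname(exp(est - z * se)),
                 ci_high = unname(exp(est + z * se)),
                 method = "model_adjusted", conf_level = conf_level,
                 covariates = covariates, fit = fit),
            class = "rate_ratio_estimate")
}

#' @export
print.rate_ratio_estimate <- function(x, ...) {
  cat(sprintf("%s rate ratio: %.3f (%d%% CI %.3f-%.3f)\n",
              x$method, x$estimate, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  if (!is.null(x$observed))
    cat(sprintf("  observed %d, expected %.2f deaths\n",
                x$observed, x$expected))
  if (!is.null(x$dropped_cells) && nrow(x$dropped_cells))
    cat("  dropped", nrow(x$dropped_cells),
        "cells with no comparison person-time\n")
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
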