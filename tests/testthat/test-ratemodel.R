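# deaths simulated from a known log-quadratic rate surface
simulate_strata <- function(beta, ages = 18:100, py = NULL, sex = "male",
                            group = "comparison") {
  if (is.null(py)) py <- 5e4 * exp(-0.03 * (ages - 18))
  mu <- exp(beta[1] + beta[2] * ages + beta[3] * ages^2) * py
  data.frame(group = group, sex = sex, age = ages,
             deaths = stats::rpois(length(ages), mu), person_years = py)
}

# direct Poisson log-likelihood (dropping the factorial constant)
loglik_quadratic <- function(beta, strata) {
  mu <- exp(beta[1] + beta[2] * strata$age + beta[3] * strata$age^2) *
    strata$person_years
  sum(strata$deaths * log(mu) - mu)
}

test_that("counts equal to model expectations are recovered exactly", {
  st <- make_strata(ages = c(30, 45, 60, 75), rates = 0.5,
                    person_years = c(2, 4, 6, 8))
  fit <- fit_poisson_quadratic(st)
  expect_equal(unname(fit$coefficients),
               c(log(0.5), 0, 0), tolerance = 1e-8)
  # score at the optimum vanishes (centred/scaled design)
  z <- (st$age - 60) / 10
  X <- cbind(1, z, z^2)
  mu <- exp(X %*% fit$coefficients_scaled) * st$person_years
  expect_lt(max(abs(crossprod(X, st$deaths - mu))), 1e-6)
})

test_that("the reported covariance is symmetric positive semi-definite", {
  set.seed(52)
  st <- simulate_strata(c(-10, 0.1, 1e-4))
  fit <- fit_poisson_quadratic(st)
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
})

test_that("the fitted optimum dominates a surrounding likelihood grid", {
  set.seed(61)
  for (rep in 1:5) {
    ages <- sort(sample(20:90, 5))
    st <- data.frame(group = "comparison", sex = "male", age = ages,
                     deaths = rpois(5, 8), person_years = runif(5, 50, 500))
    if (sum(st$deaths) == 0) next
    fit <- fit_poisson_quadratic(st)
    b <- fit$coefficients
    ll_hat <- loglik_quadratic(b, st)
    grid <- expand.grid(d0 = seq(-0.3, 0.3, 0.15),
                        d1 = seq(-0.01, 0.01, 0.005),
                        d2 = seq(-1e-4, 1e-4, 5e-5))
    ll_grid <- apply(grid, 1, function(d)
      loglik_quadratic(b + as.numeric(d), st))
    expect_true(all(ll_grid <= ll_hat + 1e-8))
  }
})

test_that("estimates from one large simulation sit within 3 SE of truth", {
  set.seed(71)
  truth <- c(-10.2, 0.115, -1e-4)
  st <- simulate_strata(truth)
  fit <- fit_poisson_quadratic(st)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
})

test_that("degenerate stratum tables are rejected with clear errors", {
  st <- make_strata(ages = c(30, 40), rates = 0.1, person_years = 10)
  expect_error(fit_poisson_quadratic(st), "at least 3 strata")
  st0 <- make_strata(ages = c(30, 40, 50), rates = 0, person_years = 10)
  expect_error(fit_poisson_quadratic(st0), "zero deaths")
  # zero person-year strata are dropped before fitting
  st2 <- rbind(make_strata(ages = c(30, 45, 60, 75), rates = 0.5,
                           person_years = 4),
               data.frame(group = "comparison", sex = "male", age = 90,
                          deaths = 0, person_years = 0))
  expect_equal(fit_poisson_quadratic(st2)$n_strata, 4)
})

test_that("fits are invariant to disaggregating strata with equal totals", {
  set.seed(81)
  st <- simulate_strata(c(-10, 0.1, 0), ages = seq(20, 90, 5))
  split_row <- st[1, ]
  st_fine <- rbind(
    transform(split_row, deaths = floor(split_row$deaths / 2),
              person_years = split_row$person_years * 0.4),
    transform(split_row, deaths = ceiling(split_row$deaths / 2),
              person_years = split_row$person_years * 0.6),
    st[-1, ])
  f1 <- fit_poisson_quadratic(st)
  f2 <- fit_poisson_quadratic(st_fine)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("predicted rates are the exponentiated quadratic", {
  st <- make_strata(ages = c(30, 45, 60), rates = 0.01, person_years = 100)
  fit <- fit_poisson_quadratic(st)
  expect_equal(unname(predict_rates(fit, 18:100)), rep(0.01, 83),
               tolerance = 1e-6)
  # direct arithmetic oracle on a hand-set coefficient vector
  fit$coefficients <- c(intercept = -12, age = 0.2, age2 = -5e-4)
  ages <- 18:100
  expect_equal(unname(predict_rates(fit, ages)),
               exp(-12 + 0.2 * ages - 5e-4 * ages^2))
  # upward-opening quadratic with vertex below 18 is monotone increasing
  fit$coefficients <- c(intercept = -11, age = 0.01, age2 = 5e-4)
  r <- predict_rates(fit)
  expect_true(all(diff(r) > 0))
})

test_that("a group compared with itself has SMR exactly 1", {
  set.seed(91)
  st <- simulate_strata(c(-9, 0.09, 0))
  smr <- standardised_mortality_ratio(st, st)
  expect_equal(smr$estimate, 1)
  expect_equal(smr$observed, smr$expected)
})

test_that("single-stratum SMR matches the hand computation", {
  exposed <- data.frame(sex = "male", age = 50, deaths = 2, person_years = 100)
  comparison <- data.frame(sex = "male", age = 50, deaths = 100,
                           person_years = 10000)   # rate 0.01/py
  smr <- standardised_mortality_ratio(exposed, comparison)
  expect_equal(smr$expected, 1)
  expect_equal(smr$estimate, 2)
  # Byar limits for O = 2 from the closed-form expression
  z <- qnorm(0.975)
  expect_equal(smr$ci_low, 2 * (1 - 1 / 18 - z / (3 * sqrt(2)))^3)
  expect_equal(smr$ci_high, 3 * (1 - 1 / 27 + z / (3 * sqrt(3)))^3)
})

test_that("cells without comparison person-time are dropped and reported", {
  exposed <- data.frame(sex = "male", age = c(50, 51), deaths = c(2, 1),
                        person_years = c(100, 50))
  comparison <- data.frame(sex = "male", age = 50, deaths = 100,
                           person_years = 10000)
  smr <- standardised_mortality_ratio(exposed, comparison)
  expect_equal(smr$observed, 2)
  expect_equal(nrow(smr$dropped_cells), 1)
  expect_equal(smr$dropped_cells$age, 51)
  # expected deaths of zero is an error
  comp0 <- data.frame(sex = "male", age = 50, deaths = 0, person_years = 1000)
  expect_error(standardised_mortality_ratio(exposed, comp0), "zero")
})

test_that("the SMR is invariant to rescaling all person-time", {
  set.seed(101)
  e <- simulate_strata(c(-9, 0.09, 0), group = "exposed_no_id")
  c0 <- simulate_strata(c(-9.5, 0.09, 0))
  s1 <- standardised_mortality_ratio(e, c0)
  e2 <- transform(e, person_years = person_years * 7)
  c2 <- transform(c0, person_years = person_years * 7)
  s2 <- standardised_mortality_ratio(e2, c2)
  expect_equal(s1$estimate, s2$estimate)
})

test_that("with all-zero covariates the adjusted ratio is the unadjusted one", {
  set.seed(111)
  st <- rbind(simulate_strata(c(-10, 0.1, 0)),
              simulate_strata(c(-10 + log(2), 0.1, 0), group = "exposed_no_id"))
  st$cov_epilepsy <- 0
  plain <- adjusted_rate_ratio(st, character(0))
  adj <- adjusted_rate_ratio(st, "cov_epilepsy")
  expect_equal(adj$estimate, plain$estimate)
  expect_equal(adj$ci_low, plain$ci_low)
  expect_true(plain$ci_low < 2 && 2 < plain$ci_high)
})

test_that("excess hazard flowing through a comorbidity is adjusted away", {
  set.seed(121)
  base <- c(-10, 0.1, 0)
  ages <- seq(20, 90, 2)
  make <- function(group, p_com, hr_direct) {
    rbind(
      within(simulate_strata(base + c(log(hr_direct * 3), 0, 0), ages,
                             py = 4e4 * p_com * exp(-0.03 * (ages - 18)),
                             group = group), cov_x <- 1),
      within(simulate_strata(base + c(log(hr_direct), 0, 0), ages,
                             py = 4e4 * (1 - p_com) * exp(-0.03 * (ages - 18)),
                             group = group), cov_x <- 0))
  }
  # no direct effect: all excess via the comorbidity (hr 3, prevalence 40% vs 2%)
  st <- rbind(make("exposed_no_id", 0.40, 1), make("comparison", 0.02, 1))
  unadj <- adjusted_rate_ratio(st, character(0))
  adj <- adjusted_rate_ratio(st, "cov_x")
  expect_gt(unadj$estimate, 1.5)
  expect_lt(abs(adj$estimate - 1), 0.05)
  # direct effect 1.5 on top of the comorbidity pathway is recovered
  st2 <- rbind(make("exposed_no_id", 0.40, 1.5), make("comparison", 0.02, 1))
  adj2 <- adjusted_rate_ratio(st2, "cov_x")
  expect_true(adj2$ci_low < 1.5 && 1.5 < adj2$ci_high)
})

test_that("adjusted-model interval covers a known direct effect ~95% of the time", {
  set.seed(131)
  ages <- seq(20, 90, 5)
  base <- c(-10, 0.1, 0)
  hits <- 0L
  n_rep <- 600
  for (rep in seq_len(n_rep)) {
    exp_st <- rbind(
      within(simulate_strata(base + c(log(1.5 * 2), 0, 0), ages,
                             py = 3000 * exp(-0.03 * (ages - 18)),
                             group = "exposed_no_id"), cov_x <- 1),
      within(simulate_strata(base + c(log(1.5), 0, 0), ages,
                             py = 7000 * exp(-0.03 * (ages - 18)),
                             group = "exposed_no_id"), cov_x <- 0))
    comp_st <- rbind(
      within(simulate_strata(base + c(log(2), 0, 0), ages,
                             py = 2000 * exp(-0.03 * (ages - 18))), cov_x <- 1),
      within(simulate_strata(base, ages,
                             py = 98000 * exp(-0.03 * (ages - 18))), cov_x <- 0))
    a <- adjusted_rate_ratio(rbind(exp_st, comp_st), "cov_x")
    hits <- hits + (a$ci_low < 1.5 && 1.5 < a$ci_high)
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("fit JSON serialisation round-trips", {
  set.seed(141)
  st <- simulate_strata(c(-10, 0.1, 1e-4))
  fit <- fit_poisson_quadratic(st, group = "comparison")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$vcov, fit$vcov, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(predict_rates(back), predict_rates(fit))
})
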