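test_that("entry date is the latest of the candidate dates", {
  p <- make_patient(registration_date = "1994-01-01",
                    practice_quality_start = "2000-03-01",
                    exposure_diagnosis_date = "1995-06-01")
  expect_equal(compute_entry_date(p), as.Date("2000-03-01"))

  # all candidate dates coincide
  p2 <- make_patient(birth_date = "1960-01-01",
                     registration_date = "1988-07-01",
                     practice_quality_start = "1989-01-01",
                     exposure_diagnosis_date = "1989-01-01")
  expect_equal(compute_entry_date(p2), as.Date("1989-01-01"))

  # diagnosis after deregistration: no follow-up
  p3 <- make_patient(deregistration_date = "1999-01-01",
                     exposure_diagnosis_date = "2005-01-01")
  expect_true(is.na(compute_entry_date(p3)))
})

test_that("exit date is the earliest of the candidate dates", {
  p <- make_patient(death_date = "2010-05-05",
                    deregistration_date = "2012-01-01")
  expect_equal(compute_exit_date(p),
               data.frame(exit_date = as.Date("2010-05-05"), died = TRUE))

  # possible deaths censor unless the sensitivity flag is on
  p2 <- make_patient(death_date = "2010-05-05", death_certainty = "possible")
  expect_equal(compute_exit_date(p2),
               data.frame(exit_date = as.Date("2010-05-05"), died = FALSE))
  expect_true(compute_exit_date(p2, include_possible_deaths = TRUE)$died)

  # no events: administrative censoring
  p3 <- make_patient()
  expect_equal(compute_exit_date(p3),
               data.frame(exit_date = as.Date("2019-01-16"), died = FALSE))
})

test_that("a pool with exactly k eligible candidates is selected in full", {
  exposed <- make_patient("e1", birth_date = "1970-03-03",
                          exposure_diagnosis_date = "2000-01-01")
  pool <- do.call(rbind, lapply(1:5, function(i)
    make_patient(paste0("c", i), birth_date = "1970-07-07")))
  s1 <- with_seed_test(1, exposure_density_match(exposed, pool, k = 5))
  s2 <- with_seed_test(999, exposure_density_match(exposed, pool, k = 5))
  expect_setequal(as.character(s1), pool$person_id)
  expect_setequal(as.character(s2), pool$person_id)
  expect_equal(attr(s1, "index_date"), as.Date("2000-01-01"))
})

test_that("candidates diagnosed on or before the index date are excluded", {
  exposed <- make_patient("e1", exposure_diagnosis_date = "2000-06-15")
  day_before <- make_patient("cb", exposure_diagnosis_date = "2000-06-14")
  on_day <- make_patient("cd", exposure_diagnosis_date = "2000-06-15")
  day_after <- make_patient("ca", exposure_diagnosis_date = "2000-06-16")
  sel <- exposure_density_match(exposed, rbind(day_before, on_day, day_after),
                                k = 10)
  expect_identical(as.character(sel), "ca")
  expect_equal(attr(sel, "n_eligible"), 1L)
})

test_that("sampled comparisons agree with an independently coded predicate", {
  set.seed(314)
  rdate <- function(n, from, to)
    as.Date(from) + sample.int(as.integer(as.Date(to) - as.Date(from)), n,
                               replace = TRUE)
  for (scenario in 1:1000) {
    n_pool <- 25
    birth <- rdate(n_pool + 1, "1965-01-01", "1975-12-31")
    reg <- birth + sample.int(12000, n_pool + 1, replace = TRUE)
    has_death <- runif(n_pool + 1) < 0.3
    pool <- do.call(rbind, lapply(seq_len(n_pool), function(i)
      make_patient(
        paste0("c", i), practice_id = sample(1:2, 1),
        sex = sample(c("male", "female"), 1),
        birth_date = birth[i], registration_date = reg[i],
        deregistration_date = if (runif(1) < 0.3)
          reg[i] + sample.int(9000, 1) else NA,
        practice_quality_start = rdate(1, "1988-01-01", "2002-01-01"),
        practice_last_collection = rdate(1, "2010-01-01", "2019-01-16"),
        exposure_diagnosis_date = if (runif(1) < 0.25)
          reg[i] + sample.int(8000, 1) else NA,
        death_date = if (has_death[i]) reg[i] + sample.int(10000, 1) else NA)))
    exposed <- make_patient("e0", practice_id = 1,
                            birth_date = birth[n_pool + 1],
                            registration_date = reg[n_pool + 1],
                            exposure_diagnosis_date =
                              rdate(1, "1995-01-01", "2015-01-01"))
    index <- compute_entry_date(exposed)
    if (is.na(index)) next
    k <- sample(1:12, 1)
    sel <- exposure_density_match(exposed, pool, k = k)
    ok <- oracle_eligible(pool, exposed, index)
    expect_true(all(as.character(sel) %in% pool$person_id[ok]))
    expect_equal(length(sel), min(k, sum(ok)))
    expect_equal(attr(sel, "n_eligible"), sum(ok))
  }
})

test_that("matched sets are homogeneous and free of immortal time", {
  for (seed in c(2, 9)) {
    pop <- simulate_population(quick_config(seed = seed))
    co <- build_cohort(pop, k = 10, seed = seed + 1)
    iv <- co$intervals
    expect_true(all(iv$entry_date < iv$exit_date))
    expect_true(all(iv$exit_date <= co$study_end))
    # homogeneity within every matched set
    by_set <- split(iv, iv$matched_set_id)
    for (s in by_set) {
      expect_equal(length(unique(s$sex)), 1)
      expect_equal(length(unique(format(s$birth_date, "%Y"))), 1)
      expect_equal(length(unique(s$practice_id)), 1)
      expect_equal(length(unique(s$entry_date)), 1)
    }
    # no comparison member diagnosed on or before the set entry date
    m <- match(iv$person_id, pop$person_id)
    cmp <- iv$group == "comparison"
    first_diag <- pmin(pop$exposure_diagnosis_date[m],
                       pop$id_diagnosis_date[m], na.rm = TRUE)
    expect_true(all(is.na(first_diag[cmp]) |
                      first_diag[cmp] > iv$entry_date[cmp]))
    # exposed intervals never precede the diagnosis date
    expect_true(all(iv$entry_date[!cmp] >=
                      pop$exposure_diagnosis_date[m][!cmp]))
    # death flag implies exit at the death date
    expect_true(all(iv$exit_date[iv$died] == pop$death_date[m][iv$died]))
    # set sizes match the report
    sizes <- table(iv$matched_set_id[cmp])
    rep <- co$match_report
    expect_true(all(rep$n_matched <= rep$n_requested))
    expect_equal(unname(sizes[as.character(rep$matched_set_id[rep$n_matched > 0])]),
                 rep$n_matched[rep$n_matched > 0], ignore_attr = TRUE)
  }
})

test_that("a late intellectual-disability record splits the follow-up", {
  pop <- rbind(
    make_patient("e1", birth_date = "1980-01-01",
                 registration_date = "1990-01-01",
                 exposure_diagnosis_date = "2000-01-01",
                 id_diagnosis_date = "2005-06-01"),
    make_patient("c1", birth_date = "1980-05-05",
                 registration_date = "1990-01-01"),
    make_patient("c2", birth_date = "1980-09-09",
                 registration_date = "1990-01-01"))
  co <- build_cohort(pop, k = 2, seed = 1)
  e <- co$intervals[co$intervals$person_id == "e1", ]
  e <- e[order(e$entry_date), ]
  expect_equal(e$group, c("exposed_no_id", "exposed_with_id"))
  expect_equal(e$entry_date, as.Date(c("2000-01-01", "2005-06-01")))
  expect_equal(e$exit_date, as.Date(c("2005-06-01", "2019-01-16")))
  expect_false(any(e$died))
  # each episode has its own comparison set in the matching cohort
  expect_equal(sort(unique(co$intervals$cohort)), c("no_id", "with_id"))
})

test_that("an ID record at or before entry classifies the whole follow-up", {
  pop <- rbind(
    make_patient("e1", exposure_diagnosis_date = "2000-01-01",
                 id_diagnosis_date = "2000-01-01"),
    make_patient("c1", birth_date = "1970-05-05"))
  co <- build_cohort(pop, k = 1, seed = 1)
  e <- co$intervals[co$intervals$person_id == "e1", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$group, "exposed_with_id")
})

test_that("comparison follow-up is censored at the person's own diagnosis", {
  pop <- rbind(
    make_patient("e1", exposure_diagnosis_date = "2000-01-01"),
    make_patient("c1", birth_date = "1970-06-06",
                 exposure_diagnosis_date = "2010-03-04"))
  co <- build_cohort(pop, k = 5, seed = 1)
  iv <- co$intervals
  c_as_comparison <- iv[iv$person_id == "c1" & iv$group == "comparison", ]
  expect_equal(c_as_comparison$exit_date, as.Date("2010-03-04"))
  expect_false(c_as_comparison$died)
  # and they later enter as a diagnosed participant themselves
  expect_true(any(iv$person_id == "c1" & iv$group == "exposed_no_id"))
})

test_that("the possible-deaths toggle changes event flags only", {
  pop <- simulate_population(quick_config(possible_death_fraction = 0.3,
                                          seed = 15))
  off <- build_cohort(pop, k = 10, seed = 4, include_possible_deaths = FALSE)
  on <- build_cohort(pop, k = 10, seed = 4, include_possible_deaths = TRUE)
  expect_identical(off$intervals$entry_date, on$intervals$entry_date)
  expect_identical(off$intervals$exit_date, on$intervals$exit_date)
  expect_identical(off$intervals$person_id, on$intervals$person_id)
  expect_gt(sum(on$intervals$died), sum(off$intervals$died))
  # every extra event is a "possible" death
  extra <- on$intervals$died & !off$intervals$died
  expect_true(all(on$intervals$death_certainty[extra] == "possible"))
})

test_that("a population with no diagnosed persons yields an empty cohort", {
  pop <- simulate_population(sim_config(n_practices = 1,
                                        persons_per_practice = 100,
                                        exposure_prevalence = 0, seed = 2))
  co <- build_cohort(pop, k = 10, seed = 1)
  expect_equal(nrow(co$intervals), 0)
  expect_equal(nrow(co$match_report), 0)
})
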