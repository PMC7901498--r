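test_that("smoking status takes the most recent record", {
  ev <- dplyr::bind_rows(
    make_event("p1", "2005-01-01", "SMK-CUR"),
    make_event("p1", "2010-01-01", "SMK-EX"),
    make_event("p2", "2003-01-01", "H1"))
  out <- smoking_status(ev, patient_ids = c("p1", "p2"))
  expect_equal(out$smoking[out$patient_id == "p1"], "EX")
  expect_equal(out$smoking[out$patient_id == "p2"], "NO_RECORDS")
})

test_that("same-day smoking ties resolve CURRENT > EX > NEVER", {
  combos <- list(c("SMK-CUR", "SMK-NEV"), c("SMK-NEV", "SMK-CUR"),
                 c("SMK-CUR", "SMK-EX"), c("SMK-EX", "SMK-NEV"))
  want <- c("CURRENT", "CURRENT", "CURRENT", "EX")
  for (i in seq_along(combos)) {
    ev <- dplyr::bind_rows(lapply(combos[[i]], function(code)
      make_event("p1", "2005-01-01", code)))
    expect_equal(smoking_status(ev)$smoking, want[i], info = i)
  }
})

test_that("smoking status is invariant to record order", {
  ev <- dplyr::bind_rows(
    make_event("p1", "2002-05-05", "SMK-NEV"),
    make_event("p1", "2008-01-01", "SMK-CUR"),
    make_event("p1", "2005-01-01", "SMK-EX"))
  out1 <- smoking_status(ev)
  out2 <- smoking_status(ev[c(3, 1, 2), ])
  expect_equal(out1, out2)
  expect_equal(out1$smoking, "CURRENT")
})

test_that("history flags are lifetime, including after exit", {
  ev <- dplyr::bind_rows(
    make_event("p1", "2015-06-01", "PRS001"),  # after the exit below
    make_event("p2", "2003-01-01", "H1"))
  out <- history_flags(ev, patient_ids = c("p1", "p2"))
  expect_true(out$prison[out$patient_id == "p1"])
  expect_false(out$prison[out$patient_id == "p2"])
  expect_false(any(out$homelessness))
})

test_that("baseline table blocks partition the cohort", {
  members <- dplyr::bind_rows(
    make_member("m1", age_at_entry = 20L, sex = "M"),
    make_member("m2", age_at_entry = 30L, sex = "M"),
    make_member("m3", age_at_entry = 40L, sex = "M"),
    make_member("m4", age_at_entry = 50L, sex = "M"))
  bl <- baseline_table(members)
  for (v in c("age_group", "sex", "region", "imd_quintile")) {
    expect_equal(sum(bl$n[bl$variable == v]), 4, info = v)
  }
  expect_equal(bl$n[bl$variable == "sex" & bl$level == "M"], 4L)
  expect_equal(bl$pct[bl$variable == "sex" & bl$level == "M"], 100)
  expect_equal(bl$n[bl$variable == "sex" & bl$level == "F"], 0L)
  cont <- attr(bl, "continuous")
  expect_equal(cont$median[cont$measure == "age_at_entry"], 35)
  # percentages recomputed from counts agree to rounding
  expect_equal(bl$pct, round(100 * bl$n / 4, 1))
})

test_that("the generator's cohort reproduces its configured male share", {
  sim <- simulate_ehr(sim_config(seed = 31, n_patients = 20000,
                                 phenotype_prevalence = 1,
                                 confusable_rx_prob = 0,
                                 n_hospital_cases = 0))
  co <- build_cohort(sim$patients, sim$events, sim$prescriptions,
                     sim$codelist)
  bl <- baseline_table(co, sim$events)
  male_pct <- bl$pct[bl$variable == "sex" & bl$level == "M"]
  expect_lt(abs(male_pct - 69), 1)
  # smoking block exists and sums to cohort size
  expect_equal(sum(bl$n[bl$variable == "smoking"]), nrow(co))
  smoking_cur <- bl$pct[bl$variable == "smoking" & bl$level == "CURRENT"]
  expect_gt(smoking_cur, 70)
  # deprivation skew: most deprived quintile dominates
  imd5 <- bl$pct[bl$variable == "imd_quintile" & bl$level == "5"]
  expect_gt(imd5, 35)
})

test_that("entry-age trend reports one row per entry year", {
  single <- make_member("m1", entry = "2001-06-01", exit = "2003-01-01",
                        age_at_entry = 30L)
  tr <- entry_age_trend(single)
  expect_equal(tr$entry_year, 2001)
  expect_equal(tr$mean_age, 30)

  rising <- dplyr::bind_rows(lapply(0:9, function(k)
    make_member(paste0("m", k), entry = sprintf("%d-06-01", 2000 + k),
                exit = sprintf("%d-06-01", 2001 + k),
                age_at_entry = 30L + k)))
  tr <- entry_age_trend(rising)
  slope <- coef(lm(mean_age ~ entry_year, data = tr))[2]
  expect_equal(unname(slope), 1.0, tolerance = 1e-8)
})

test_that("the generator's configured ageing drift is recovered", {
  sim <- simulate_ehr(sim_config(seed = 12, n_patients = 8000,
                                 phenotype_prevalence = 1,
                                 entry_age_drift = 0.5,
                                 confusable_rx_prob = 0,
                                 n_hospital_cases = 0))
  co <- build_cohort(sim$patients, sim$events, sim$prescriptions,
                     sim$codelist)
  tr <- entry_age_trend(co)
  slope <- unname(coef(lm(mean_age ~ entry_year, weights = n,
                          data = tr))[2])
  expect_gt(slope, 0.2)
})
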