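test_that("entry is the latest of study start, data start and first code", {
  expect_equal(compute_entry("1997-01-01", "1995-06-01", "1996-03-01"),
               as.Date("1997-01-01"))
  expect_equal(compute_entry("1997-01-01", "2001-02-03", "1999-01-01"),
               as.Date("2001-02-03"))
  expect_equal(compute_entry("2000-05-05", "2000-05-05", "2000-05-05"),
               as.Date("2000-05-05"))
})

test_that("exit is the earliest of data end and death, in any ordering", {
  expect_equal(compute_exit("2010-01-01", "2008-05-05"),
               as.Date("2008-05-05"))
  expect_equal(compute_exit("2010-01-01", NA), as.Date("2010-01-01"))
  # enumerate orderings of the two dates
  d1 <- as.Date("2005-01-01"); d2 <- as.Date("2007-01-01")
  expect_equal(compute_exit(d1, d2), d1)
  expect_equal(compute_exit(d2, d1), d1)
  expect_equal(compute_exit(d1, d1), d1)
})

cohort_fixture <- function() {
  patients <- dplyr::bind_rows(
    make_patient("a1", year_of_birth = 1970L),                  # eligible
    make_patient("a2", sex = "F", year_of_birth = 1975L),       # eligible
    make_patient("a3", year_of_birth = 1985L,
                 data_start = "2001-01-01"),                    # eligible
    make_patient("a4", year_of_birth = 1960L,
                 death_date = "2006-06-06"),                    # eligible,dies
    make_patient("b1", year_of_birth = 1988L),                  # age 17
    make_patient("b2", year_of_birth = 1935L),                  # age 65+
    make_patient("b3", year_of_birth = 1970L, region = "Wales"),
    make_patient("b4", year_of_birth = 1970L,
                 data_end = "2003-01-01"),     # code after data end
    make_patient("c1", year_of_birth = 1970L), # no code at all
    make_patient("c2", year_of_birth = 1970L))
  events <- dplyr::bind_rows(
    make_event("a1", "2003-05-01", "H1"),
    make_event("a2", "2004-01-01", "O1"),
    make_event("a4", "2002-02-02", "H1"),
    make_event("b1", "2005-06-01", "H1"),  # aged 17 then (born 1988)
    make_event("b2", "2003-01-01", "H1"),  # aged 67 then
    make_event("b3", "2003-01-01", "H1"),
    make_event("b4", "2005-01-01", "H1"))  # after their data_end
  rx <- tibble::tibble(patient_id = "a3", date = as.Date("2004-08-01"),
                       product_code = "METH")
  list(patients = patients, events = events, rx = rx)
}

test_that("cohort assembly applies exclusions in flow-chart order", {
  f <- cohort_fixture()
  co <- build_cohort(f$patients, f$events, f$rx, tiny_codelist())
  tally <- exclusion_tally(co)
  expect_equal(tally$n[tally$step == "phenotype_positive"], 8L)
  expect_equal(tally$n[tally$step == "outside_region"], 1L)   # b3
  expect_equal(tally$n[tally$step == "no_follow_up"], 1L)     # b4
  expect_equal(tally$n[tally$step == "age_ineligible"], 2L)   # b1, b2
  expect_setequal(co$patient_id, c("a1", "a2", "a3", "a4"))
  # tally conserves: positives = excluded + final
  expect_equal(tally$n[tally$step == "phenotype_positive"],
               sum(tally$n[tally$step %in%
                             c("outside_region", "no_follow_up",
                               "age_ineligible", "final_cohort")]))
})

test_that("member dates respect the study window and death handling", {
  f <- cohort_fixture()
  co <- build_cohort(f$patients, f$events, f$rx, tiny_codelist(),
                     study_end = as.Date("2008-12-31"))
  expect_true(all(co$entry >= as.Date("1997-01-01")))
  expect_true(all(co$exit <= as.Date("2008-12-31")))
  expect_true(all(co$entry < co$exit))
  a4 <- co[co$patient_id == "a4", ]
  expect_true(a4$died)
  expect_equal(a4$exit, as.Date("2006-06-06"))
  # a3 entered at the later of data start and first code
  a3 <- co[co$patient_id == "a3", ]
  expect_equal(a3$entry, as.Date("2004-08-01"))
})

test_that("a death recorded after data end does not extend follow-up", {
  p <- make_patient("z1", year_of_birth = 1970L, data_end = "2005-01-01",
                    death_date = "2006-01-01")
  ev <- make_event("z1", "2001-01-01", "H1")
  co <- build_cohort(p, ev, NULL, tiny_codelist())
  expect_equal(co$exit, as.Date("2005-01-01"))
  expect_false(co$died)
})

test_that("cohort assembly is invariant to input row order", {
  f <- cohort_fixture()
  co1 <- build_cohort(f$patients, f$events, f$rx, tiny_codelist())
  set.seed(9)
  co2 <- build_cohort(f$patients[sample(nrow(f$patients)), ],
                      f$events[sample(nrow(f$events)), ],
                      f$rx, tiny_codelist())
  expect_equal(tidy(co1), tidy(co2))
})

test_that("duplicate registry ids are a hard error", {
  f <- cohort_fixture()
  expect_error(
    build_cohort(dplyr::bind_rows(f$patients, f$patients[1, ]),
                 f$events, f$rx, tiny_codelist()),
    "Duplicate")
})

test_that("overlap summary partitions the cohort", {
  f <- cohort_fixture()
  co <- build_cohort(f$patients, f$events, f$rx, tiny_codelist())
  ov <- overlap_summary(co, f$events, f$rx, tiny_codelist())
  expect_equal(sum(ov$n), nrow(co))
  expect_equal(ov$n[ov$group == "product_only"], 1L)   # a3
  expect_equal(ov$n[ov$group == "clinical_only"], 3L)
  expect_equal(ov$n[ov$group == "both"], 0L)
})
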