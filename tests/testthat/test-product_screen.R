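# Brute-force linear-interpolation quantile oracle (independent of
# stats::quantile): h = (n-1)p + 1, interpolate between order statistics.
interp_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

test_that("first prescriptions pick the earliest date per product/patient", {
  patients <- dplyr::bind_rows(
    make_patient("p1", sex = "M", year_of_birth = 1970L),
    make_patient("p2", sex = "F", year_of_birth = 1980L))
  rx <- tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    date = as.Date(c("2000-01-11", "2001-02-15", "2002-06-01")),
    product_code = c("P", "P", "Q"))
  out <- first_prescriptions(rx, patients)
  expect_equal(nrow(out), 2)
  p1 <- out[out$patient_id == "p1", ]
  expect_equal(p1$product_code, "P")
  # age on 2000-01-11 against imputed birth date 1970-07-01 -> 29
  expect_equal(p1$age_at_first_prescription, 29L)
})

test_that("prescriptions for unknown patients are skipped with a warning", {
  patients <- make_patient("p1")
  rx <- tibble::tibble(patient_id = c("p1", "ghost"),
                       date = as.Date("2001-01-01"),
                       product_code = "P")
  expect_warning(out <- first_prescriptions(rx, patients), "unknown")
  expect_equal(out$patient_id, "p1")
})

test_that("a prescription before the imputed birth date is an error", {
  patients <- make_patient("p1", year_of_birth = 2005L)
  rx <- tibble::tibble(patient_id = "p1", date = as.Date("2001-01-01"),
                       product_code = "P")
  expect_error(first_prescriptions(rx, patients), "p1")
})

test_that("product summaries match the quantile oracle", {
  frx <- tibble::tibble(
    product_code = "P", patient_id = sprintf("p%d", 1:4),
    sex = c("F", "M", "M", "M"),
    age_at_first_prescription = c(20, 30, 40, 50))
  s <- summarize_products(frx)
  expect_equal(s$fraction_female, 0.25)
  expect_equal(s$age_q1, interp_quantile(c(20, 30, 40, 50), 0.25))
  expect_equal(s$age_q3, interp_quantile(c(20, 30, 40, 50), 0.75))
  expect_equal(s$age_q1, 27.5)
  expect_equal(s$age_q3, 42.5)

  set.seed(3)
  for (i in 1:5) {
    ages <- sample(18:80, sample(2:30, 1), replace = TRUE)
    s <- summarize_products(tibble::tibble(
      product_code = "X", patient_id = seq_along(ages),
      sex = "M", age_at_first_prescription = ages))
    expect_equal(s$age_q1, interp_quantile(ages, 0.25))
    expect_equal(s$age_q3, interp_quantile(ages, 0.75))
  }
})

test_that("degenerate product summaries behave", {
  one <- summarize_products(tibble::tibble(
    product_code = "P", patient_id = "p1", sex = "M",
    age_at_first_prescription = 30))
  expect_equal(one$fraction_female, 0)
  expect_equal(one$age_q1, 30)
  expect_equal(one$age_q3, 30)

  fem <- summarize_products(tibble::tibble(
    product_code = "P", patient_id = c("a", "b"), sex = "F",
    age_at_first_prescription = c(30, 40)))
  expect_equal(fem$fraction_female, 1)

  expect_error(summarize_products(tibble::tibble(
    product_code = character(), patient_id = character(),
    sex = character(), age_at_first_prescription = numeric())),
    "zero rows")
})

test_that("the OAT screen applies strict demographic cut-offs", {
  mk <- function(ff, q1, q3) {
    tibble::tibble(product_code = "P", n_patients = 100L,
                   fraction_female = ff, age_q1 = q1, age_q3 = q3)
  }
  expect_equal(screen_products(mk(0.60, 25, 50))$decision, "EXCLUDED")
  expect_equal(screen_products(mk(0.25, 25, 50))$decision, "OAT_PRODUCT")
  # boundary values pass: the rules use strict inequalities
  expect_equal(screen_products(mk(0.50, 18, 64))$decision, "OAT_PRODUCT")
  expect_equal(screen_products(mk(0.25, 17.9, 50))$decision, "EXCLUDED")
  expect_equal(screen_products(mk(0.25, 25, 64.1))$decision, "EXCLUDED")
})

test_that("screen decisions partition products and are monotone", {
  set.seed(21)
  base <- tibble::tibble(
    product_code = sprintf("P%02d", 1:40),
    n_patients = 50L,
    fraction_female = runif(40),
    age_q1 = runif(40, 10, 40),
    age_q3 = runif(40, 40, 80))
  dec <- screen_products(base)
  expect_true(all(dec$decision %in% c("OAT_PRODUCT", "EXCLUDED")))
  # worsen each product's demographics: nothing may flip EXCLUDED -> OAT
  worse <- dplyr::mutate(base,
                         fraction_female = pmin(1, fraction_female + 0.2),
                         age_q1 = age_q1 - 3, age_q3 = age_q3 + 3)
  dec2 <- screen_products(worse)
  flipped <- dec$decision == "EXCLUDED" & dec2$decision == "OAT_PRODUCT"
  expect_false(any(flipped))
})

test_that("overrides model the clinician review", {
  s <- tibble::tibble(product_code = c("A", "B"), n_patients = c(10L, 10L),
                      fraction_female = c(0.7, 0.2),
                      age_q1 = c(30, 30), age_q3 = c(50, 50))
  out <- screen_products(s, overrides = c(A = "OAT_PRODUCT"))
  expect_equal(out$decision[out$product_code == "A"], "OAT_PRODUCT")
  expect_true(out$override_applied[out$product_code == "A"])
  expect_false(out$override_applied[out$product_code == "B"])
  expect_error(screen_products(s, overrides = c(ZZ = "EXCLUDED")), "ZZ")
})

test_that("products below the screening minimum are flagged for review", {
  s <- tibble::tibble(product_code = "tiny", n_patients = 3L,
                      fraction_female = 0.9, age_q1 = 70, age_q3 = 80)
  expect_equal(screen_products(s, min_patients = 5)$decision, "REVIEW")
})

test_that("a planted analgesic patch product is excluded on simulated data", {
  sim <- simulate_ehr(sim_config(seed = 5, n_patients = 3000,
                                 phenotype_prevalence = 0.3,
                                 confusable_rx_prob = 0.3,
                                 n_hospital_cases = 0))
  screen <- screen_products(summarize_products(
    first_prescriptions(sim$prescriptions, sim$patients)))
  expect_equal(screen$decision[screen$product_code == "ANL-BUP-PATCH"],
               "EXCLUDED")
  expect_true(all(screen$decision[grepl("^OAT-", screen$product_code)] ==
                    "OAT_PRODUCT"))
})
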