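#' First prescription of each product per patient
#'
#' Methadone and buprenorphine are licensed both for opioid agonist therapy
#' (OAT) and for pain, so a product code alone does not identify the
#' phenotype. The demographic screen starts from the earliest prescription of
#' each product for each patient, with age at that date in completed years.
#'
#' @param prescriptions Tibble: `patient_id`, `date`, `product_code`.
#' @param patients Registry tibble with `patient_id`, `sex`, `year_of_birth`.
#' @return Tibble: `product_code`, `patient_id`, `sex`,
#'   `age_at_first_prescription`; one row per (product, patient).
#' @seealso [summarize_products()], [screen_products()]
#' @export
first_prescriptions <- function(prescriptions, patients) {
  check_columns(prescriptions, c("patient_id", "date", "product_code"),
                "prescriptions")
  check_columns(patients, c("patient_id", "sex", "year_of_birth"), "patients")
  rx <- tibble(patient_id = as.character(prescriptions$patient_id),
               date = as_date_strict(prescriptions$date, "prescription date"),
               product_code = as.character(prescriptions$product_code))
  reg <- tibble(patient_id = as.character(patients$patient_id),
                sex = as.character(patients$sex),
                birth_date = impute_birth_date(patients$year_of_birth))
  unknown <- !rx$patient_id %in% reg$patient_id
  if (any(unknown)) {
    warn(sprintf("Skipped %d prescription(s) for unknown patient(s)",
                 sum(unknown)))
    rx <- rx[!unknown, ]
  }
  out <- rx |>
    group_by(.data$product_code, .data$patient_id) |>
    summarise(date = min(.data$date), .groups = "drop") |>
    inner_join(reg, by = "patient_id")
  if (any(out$date < out$birth_date)) {
    bad <- out$patient_id[out$date < out$birth_date]
    abort(sprintf("Prescription predates imputed birth date for patient(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  out |>
    mutate(age_at_first_prescription =
             age_completed(.data$date, .data$birth_date)) |>
    select("product_code", "patient_id", "sex",
           "age_at_first_prescription") |>
    arrange(.data$product_code, .data$patient_id)
}

#' Age/sex demographics of first prescriptions, per product
#'
#' For each product: number of distinct patients, fraction female, and the
#' 25th/75th percentiles of age at first prescription (linear interpolation
#' between order statistics, the `stats::quantile()` default).
#'
#' @param first_rx Output of [first_prescriptions()].
#' @return Tibble: `product_code`, `n_patients`, `fraction_female`,
#'   `age_q1`, `age_q3`.
#' @export
summarize_products <- function(first_rx) {
  check_columns(first_rx, c("product_code", "patient_id", "sex",
                            "age_at_first_prescription"), "first_rx")
  if (nrow(first_rx) == 0) abort("first_rx has zero rows")
  first_rx |>
    group_by(.data$product_code) |>
    summarise(
      n_patients = n(),
      fraction_female = mean(.data$sex == "F"),
      age_q1 = stats::quantile(.data$age_at_first_prescription, 0.25,
                               names = FALSE, type = 7),
      age_q3 = stats::quantile(.data$age_at_first_prescription, 0.75,
                               names = FALSE, type = 7),
      .groups = "drop")
}

#' Screen products for OAT specificity
#'
#' Populations in OAT are predominantly younger and male; analgesic
#' methadone/buprenorphine users are predominantly older and female. A
#' product is `EXCLUDED` when more than half of its patients are female, or
#' its lower age quartile is below 18, or its upper age quartile is above 64
#' (strict inequalities: ties at 0.5 / 18 / 64 pass). Products with fewer
#' than `min_patients` first prescriptions are flagged `REVIEW` rather than
#' auto-classified. `overrides` models the final clinician review: a named
#' character vector (`product_code = "OAT_PRODUCT"` or `"EXCLUDED"`) applied
#' last and recorded in `override_applied`.
#'
#' @param summaries Output of [summarize_products()].
#' @param overrides Optional named character vector of forced decisions.
#' @param min_patients Minimum patients needed to auto-classify (default 1).
#' @return `summaries` plus `decision` (`OAT_PRODUCT` / `EXCLUDED` /
#'   `REVIEW`) and `override_applied` (logical).
#' @export
screen_products <- function(summaries, overrides = NULL, min_patients = 1) {
  check_columns(summaries, c("product_code", "n_patients", "fraction_female",
                             "age_q1", "age_q3"), "summaries")
  out <- summaries |>
    mutate(decision = case_when(
      .data$n_patients < min_patients ~ "REVIEW",
      .data$fraction_female > 0.5 ~ "EXCLUDED",
      .data$age_q1 < 18 ~ "EXCLUDED",
      .data$age_q3 > 64 ~ "EXCLUDED",
      TRUE ~ "OAT_PRODUCT"),
      override_applied = FALSE)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("overrides must be a named character vector")
    }
    unknown <- setdiff(names(overrides), out$product_code)
    if (length(unknown)) {
      abort(sprintf("Override(s) for unknown product(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    bad <- !overrides %in% c("OAT_PRODUCT", "EXCLUDED")
    if (any(bad)) {
      abort(sprintf("Override decisions must be OAT_PRODUCT or EXCLUDED, got: %s",
                    paste(unique(overrides[bad]), collapse = ", ")))
    }
    idx <- match(names(overrides), out$product_code)
    out$decision[idx] <- unname(overrides)
    out$override_applied[idx] <- TRUE
  }
  out
}
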