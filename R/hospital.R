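#' First hospital admission with an opioid-disorder diagnosis
#'
#' Finds each patient's earliest admission carrying at least one diagnosis
#' whose ICD-10 code starts with `code_prefix` (default `"F11"`, mental and
#' behavioural disorders due to use of opioids), in any diagnostic position.
#' Prefix matching is dialect-tolerant: `F11`, `F11.2` and `F112` all match.
#'
#' @param admissions Tibble: `patient_id`, `admission_date`,
#'   `diagnosis_codes` (semicolon-joined string or list-column of character
#'   vectors).
#' @param code_prefix ICD-10 prefix to match (default `"F11"`).
#' @return Tibble: `patient_id`, `first_admission` (patients with no
#'   qualifying admission are absent).
#' @export
first_f11_admission <- function(admissions, code_prefix = "F11") {
  check_columns(admissions, c("patient_id", "admission_date",
                              "diagnosis_codes"), "admissions")
  codes <- admissions$diagnosis_codes
  if (!is.list(codes)) codes <- strsplit(as.character(codes), ";", fixed = TRUE)
  hit <- vapply(codes, function(x) {
    any(startsWith(toupper(trimws(x)), toupper(code_prefix)))
  }, logical(1))
  if (!any(hit)) {
    return(tibble(patient_id = character(),
                  first_admission = as.Date(character())))
  }
  admissions[hit, ] |>
    mutate(patient_id = as.character(.data$patient_id),
           admission_date = as_date_strict(.data$admission_date,
                                           "admission date")) |>
    group_by(.data$patient_id) |>
    summarise(first_admission = min(.data$admission_date), .groups = "drop")
}

#' Timing of the primary care code relative to first hospital admission
#'
#' Records appearing shortly after a hospital admission may simply transcribe
#' the discharge summary, so the timing of the first primary care code
#' relative to the first qualifying admission matters for interpreting
#' sensitivity. Windows: `BEFORE` (code strictly before admission),
#' `WITHIN_30_AFTER` (admission day through 30 days after, inclusive —
#' same-day records count as day 0 of the post-admission window), `LATER`.
#'
#' @param first_code_date,first_admission_date Date vectors.
#' @param window_days Width of the post-admission window (default 30).
#' @return Character vector: `BEFORE`, `WITHIN_30_AFTER`, `LATER`.
#' @export
classify_timing <- function(first_code_date, first_admission_date,
                            window_days = 30) {
  code <- as_date_strict(first_code_date, "first_code_date")
  adm <- as_date_strict(first_admission_date, "first_admission_date")
  dplyr::case_when(
    code < adm ~ "BEFORE",
    code <= adm + window_days ~ "WITHIN_30_AFTER",
    TRUE ~ "LATER")
}

#' Hospital-based sensitivity check of the phenotype
#'
#' Among patients with at least one hospital admission carrying an
#' opioid-disorder (F11) diagnosis: what fraction also have a primary care
#' phenotype code, and how does the first code's date relate to the first
#' admission? The timing proportions (of all hospital cases) partition the
#' code-holding fraction.
#'
#' @param admissions Hospital admissions table (see
#'   [first_f11_admission()]).
#' @param events,prescriptions Primary care records.
#' @param codelist A [codelist()].
#' @param code_prefix ICD-10 prefix (default `"F11"`).
#' @param include_probable Passed to [match_patient_codes()].
#' @return One-row tibble: `n_hospital_cases`,
#'   `fraction_with_primary_care_code`, `prop_before`,
#'   `prop_within_30_after`, `prop_later` (all `NA` when there are no
#'   hospital cases).
#' @export
validation_summary <- function(admissions, events, prescriptions, codelist,
                               code_prefix = "F11",
                               include_probable = FALSE) {
  cases <- first_f11_admission(admissions, code_prefix)
  n_cases <- nrow(cases)
  if (n_cases == 0) {
    return(tibble(n_hospital_cases = 0L,
                  fraction_with_primary_care_code = NA_real_,
                  prop_before = NA_real_, prop_within_30_after = NA_real_,
                  prop_later = NA_real_))
  }
  matches <- match_patient_codes(bind_events(events, prescriptions),
                                 codelist, include_probable)
  first_code <- matches |>
    group_by(.data$patient_id) |>
    summarise(first_code = min(.data$date), .groups = "drop")
  joined <- left_join(cases, first_code, by = "patient_id")
  with_code <- filter(joined, !is.na(.data$first_code))
  timing <- classify_timing(with_code$first_code, with_code$first_admission)
  tibble(
    n_hospital_cases = n_cases,
    fraction_with_primary_care_code = nrow(with_code) / n_cases,
    prop_before = sum(timing == "BEFORE") / n_cases,
    prop_within_30_after = sum(timing == "WITHIN_30_AFTER") / n_cases,
    prop_later = sum(timing == "LATER") / n_cases)
}
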