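#' Cohort entry and exit dates
#'
#' Entry is the latest of the study start, the patient's first date of
#' good-quality data, and the date of their first phenotype code — so
#' patients whose opioid-use history predates registration still enter when
#' observation begins. Exit is the earliest of the end of data collection and
#' death. Both are vectorised.
#'
#' @param study_start,data_start,first_code_date,data_end Dates (or
#'   coercible).
#' @param death_date Date or `NA`.
#' @return Date vector.
#' @export
compute_entry <- function(study_start, data_start, first_code_date) {
  pmax(as_date_strict(study_start, "study_start"),
       as_date_strict(data_start, "data_start"),
       as_date_strict(first_code_date, "first_code_date"))
}

#' @rdname compute_entry
#' @export
compute_exit <- function(data_end, death_date = NA) {
  data_end <- as_date_strict(data_end, "data_end")
  death_date <- as_date_strict(death_date, "death_date")
  out <- pmin(data_end, death_date, na.rm = TRUE)
  out
}

#' Assemble the phenotype-positive cohort
#'
#' Applies, in order: (1) at least one phenotype code match; (2) region in
#' the configured set (patients with missing region are retained); (3)
#' positive follow-up, i.e. entry strictly before the earlier of exit and
#' the study end; (4) age 18-64 at entry. Counts removed at each step are
#' kept as a flow-chart-style exclusion tally. Exit is capped at
#' `study_end`; follow-up is the half-open interval `[entry, exit)`.
#'
#' @param patients Registry: `patient_id`, `sex`, `year_of_birth`, `region`,
#'   `imd_quintile`, `data_start`, `data_end`, `death_date`.
#' @param events Clinical events (`patient_id`, `date`, `code_id`,
#'   `terminology`); may be `NULL`.
#' @param prescriptions Prescriptions (`patient_id`, `date`,
#'   `product_code`); may be `NULL`.
#' @param codelist A [codelist()].
#' @param study_start,study_end Study window (dates).
#' @param regions Character vector of admissible regions (default: the nine
#'   English regions).
#' @param include_probable Passed to [match_patient_codes()].
#' @return Tibble of class `opicohort_cohort`, one row per member:
#'   `patient_id`, `sex`, `entry`, `exit`, `index_code_date`,
#'   `age_at_entry`, `died`, `death_date`, `year_of_birth`, `region`,
#'   `imd_quintile`. The exclusion tally is attached as attribute
#'   `"exclusions"`; retrieve it with [exclusion_tally()].
#' @export
build_cohort <- function(patients, events, prescriptions, codelist,
                         study_start = as.Date("1997-01-01"),
                         study_end = as.Date("2018-12-31"),
                         regions = english_regions(),
                         include_probable = FALSE) {
  check_columns(patients, c("patient_id", "sex", "year_of_birth", "region",
                            "data_start", "data_end"), "patients")
  study_start <- as_date_strict(study_start, "study_start")
  study_end <- as_date_strict(study_end, "study_end")
  if (study_end < study_start) abort("study_end must be >= study_start")

  reg <- tibble(
    patient_id = as.character(patients$patient_id),
    sex = as.character(patients$sex),
    year_of_birth = as.integer(patients$year_of_birth),
    region = as.character(patients$region),
    imd_quintile = if ("imd_quintile" %in% names(patients))
      as.integer(patients$imd_quintile) else NA_integer_,
    data_start = as_date_strict(patients$data_start, "data_start"),
    data_end = as_date_strict(patients$data_end, "data_end"),
    death_date = if ("death_date" %in% names(patients))
      as_date_strict(patients$death_date, "death_date") else
        as.Date(NA))
  if (anyDuplicated(reg$patient_id)) {
    abort(sprintf("Duplicate patient_id in registry: %s",
                  paste(utils::head(unique(
                    reg$patient_id[duplicated(reg$patient_id)]), 5),
                    collapse = ", ")))
  }
  if (any(reg$data_end < reg$data_start)) {
    abort("data_end before data_start for some patients")
  }

  matches <- match_patient_codes(bind_events(events, prescriptions),
                                 codelist, include_probable)
  first_code <- matches |>
    group_by(.data$patient_id) |>
    summarise(index_code_date = min(.data$date), .groups = "drop")

  n0 <- nrow(first_code)  # phenotype-positive patients
  cand <- inner_join(reg, first_code, by = "patient_id")

  in_region <- cand$region %in% regions | is.na(cand$region)
  n_region <- sum(!in_region)
  cand <- cand[in_region, ]

  cand <- cand |>
    mutate(entry = compute_entry(study_start, .data$data_start,
                                 .data$index_code_date),
           exit = pmin(compute_exit(.data$data_end, .data$death_date),
                       study_end))
  has_followup <- cand$entry < cand$exit
  n_followup <- sum(!has_followup)
  cand <- cand[has_followup, ]

  cand <- mutate(cand,
                 age_at_entry = age_completed(
                   .data$entry, impute_birth_date(.data$year_of_birth)))
  age_ok <- cand$age_at_entry >= 18 & cand$age_at_entry <= 64
  n_age <- sum(!age_ok)
  cand <- cand[age_ok, ]

  members <- cand |>
    mutate(died = !is.na(.data$death_date) & .data$death_date <= .data$exit) |>
    select("patient_id", "sex", "entry", "exit", "index_code_date",
           "age_at_entry", "died", "death_date", "year_of_birth",
           "region", "imd_quintile") |>
    arrange(.data$patient_id)

  tally <- tibble(
    step = c("phenotype_positive", "outside_region", "no_follow_up",
             "age_ineligible", "final_cohort"),
    n = c(n0, n_region, n_followup, n_age, nrow(members)))
  structure(members,
            class = c("opicohort_cohort", class(members)),
            exclusions = tally,
            study_start = study_start, study_end = study_end)
}

#' @rdname build_cohort
#' @param cohort A cohort from [build_cohort()].
#' @export
exclusion_tally <- function(cohort) {
  attr(cohort, "exclusions") %||%
    abort("cohort carries no exclusion tally; was it built by build_cohort()?")
}

#' Overlap between clinical-code and OAT-prescription routes into the cohort
#'
#' Partitions members by whether their phenotype evidence is an OAT product
#' prescription only, a clinical code only, or both (the Venn-diagram view of
#' the phenotype).
#'
#' @inheritParams build_cohort
#' @param members A cohort from [build_cohort()].
#' @return Tibble: `group` (`product_only`, `clinical_only`, `both`), `n`.
#'   Counts sum to the cohort size.
#' @export
overlap_summary <- function(members, events, prescriptions, codelist,
                            include_probable = FALSE) {
  matches <- match_patient_codes(bind_events(events, prescriptions),
                                 codelist, include_probable)
  kinds <- matches |>
    filter(.data$patient_id %in% members$patient_id) |>
    group_by(.data$patient_id) |>
    summarise(has_product = any(.data$category == "OAT_PRODUCT"),
              has_clinical = any(.data$category != "OAT_PRODUCT"),
              .groups = "drop") |>
    mutate(group = case_when(
      .data$has_product & .data$has_clinical ~ "both",
      .data$has_product ~ "product_only",
      TRUE ~ "clinical_only"))
  counts <- table(factor(kinds$group,
                         levels = c("product_only", "clinical_only", "both")))
  tibble(group = names(counts), n = as.integer(counts))
}

#' @method glance opicohort_cohort
#' @export
glance.opicohort_cohort <- function(x, ...) {
  tibble(n = nrow(x),
         n_male = sum(x$sex == "M"),
         n_died = sum(x$died),
         median_age_at_entry = stats::median(x$age_at_entry),
         total_follow_up_years =
           as.numeric(sum(x$exit - x$entry)) / 365.25)
}

#' @method tidy opicohort_cohort
#' @export
tidy.opicohort_cohort <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "opicohort_cohort")
  out
}
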