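# Shared fixtures, built in code.

tiny_codelist <- function() {
  codelist(tibble::tibble(
    code_id = c("H1", "O1", "INJ", "METH", "PATCH"),
    terminology = c("READ", "READ", "READ", "PRODUCT", "PRODUCT"),
    description = c("Heroin dependence", "Opioid overdose",
                    "Injecting drug user",
                    "Methadone oral solution",
                    "Buprenorphine transdermal patch"),
    category = c("CLINICAL_DEFINITE", "CLINICAL_DEFINITE",
                 "CLINICAL_PROBABLE", "OAT_PRODUCT", "EXCLUDED"),
    source = "test"))
}

make_patient <- function(patient_id = "p1", sex = "M",
                         year_of_birth = 1970L, region = "London",
                         imd_quintile = 3L, data_start = "2000-01-01",
                         data_end = "2010-12-31", death_date = NA) {
  tibble::tibble(patient_id = patient_id, sex = sex,
                 year_of_birth = year_of_birth, region = region,
                 imd_quintile = imd_quintile,
                 data_start = as.Date(data_start),
                 data_end = as.Date(data_end),
                 death_date = as.Date(death_date))
}

make_event <- function(patient_id, date, code_id, terminology = "READ") {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 code_id = code_id, terminology = terminology)
}

make_member <- function(patient_id = "m1", sex = "M",
                        year_of_birth = 1970L, entry = "2000-03-01",
                        exit = "2005-03-01", died = FALSE,
                        death_date = NA, age_at_entry = NULL,
                        region = "London", imd_quintile = 3L) {
  entry <- as.Date(entry)
  tibble::tibble(
    patient_id = patient_id, sex = sex, entry = entry,
    exit = as.Date(exit), index_code_date = entry,
    age_at_entry = age_at_entry %||%
      opicohort:::age_completed(entry,
                                opicohort:::impute_birth_date(year_of_birth)),
    died = died, death_date = as.Date(death_date),
    year_of_birth = year_of_birth, region = region,
    imd_quintile = imd_quintile)
}

`%||%` <- rlang::`%||%`

# Independent day-by-day oracle for the Lexis expansion: loops over every
# follow-up day (death day included for decedents) and tallies cells.
naive_expand <- function(members) {
  rows <- list()
  for (i in seq_len(nrow(members))) {
    m <- members[i, ]
    exit <- m$exit
    if (isTRUE(m$died) && !is.na(m$death_date)) {
      exit <- max(exit, m$death_date + 1)
    }
    days <- seq(m$entry, exit - 1, by = "day")
    birth <- opicohort:::impute_birth_date(m$year_of_birth)
    rows[[i]] <- tibble::tibble(
      sex = m$sex,
      age = opicohort:::age_completed(days, birth),
      year = as.integer(format(days, "%Y")))
  }
  out <- dplyr::count(dplyr::bind_rows(rows), sex, age, year, name = "days")
  dplyr::arrange(out, sex, age, year)
}

# Random members spanning birthdays, year ends and leap years.
random_members <- function(n, seed) {
  set.seed(seed)
  entry <- as.Date("1997-01-01") + sample.int(6000, n, replace = TRUE)
  len <- sample.int(2000, n, replace = TRUE)
  death_offset <- ifelse(runif(n) < 0.3,
                         sample.int(2000, n, replace = TRUE), NA)
  exit <- entry + pmin(len, ifelse(is.na(death_offset), Inf, death_offset))
  tibble::tibble(
    patient_id = sprintf("r%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    entry = entry, exit = exit,
    year_of_birth = sample(1950:1985, n, replace = TRUE),
    died = !is.na(death_offset) & death_offset <= len,
    death_date = dplyr::if_else(!is.na(death_offset) & death_offset <= len,
                                exit, as.Date(NA)))
}
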