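#' Codelists: the vocabulary that defines the phenotype
#'
#' A codelist is a tibble with one row per code and columns `code_id`,
#' `terminology` (`"READ"`, `"SNOMED"` or `"PRODUCT"`), `description`,
#' `category` and `source`. Categories mean:
#'
#' * `CLINICAL_DEFINITE` — clinical codes that unambiguously indicate a
#'   history of illicit opioid use (e.g. "heroin dependence");
#' * `CLINICAL_PROBABLE` — codes that likely but not certainly indicate it
#'   (e.g. injecting drug use); matched only on request, to trade
#'   specificity for sensitivity;
#' * `OAT_PRODUCT` — prescription product codes specific to opioid agonist
#'   therapy (methadone / buprenorphine formulations used for dependence);
#' * `EXCLUDED` — codes reviewed and rejected (analgesic products,
#'   ambiguous tests/reactions); retained for audit, never matched.
#'
#' `codelist()` validates and stamps a tibble; `read_codelist()` /
#' `write_codelist()` round-trip the CSV representation losslessly.
#'
#' @param entries Data frame with columns `code_id`, `terminology`,
#'   `description`, `category`, `source` (missing `source` is filled with
#'   `""`).
#' @param name,version Optional metadata stored as attributes.
#' @return A tibble of class `opicohort_codelist`.
#' @examples
#' cl <- codelist(tibble::tibble(
#'   code_id = "H1", terminology = "READ",
#'   description = "Heroin dependence", category = "CLINICAL_DEFINITE",
#'   source = "illustrative"
#' ))
#' @export
codelist <- function(entries, name = "codelist", version = "0") {
  entries <- as_tibble(entries)
  if (!"source" %in% names(entries)) entries$source <- ""
  check_columns(entries, c("code_id", "terminology", "description",
                           "category", "source"), "codelist")
  entries <- mutate(entries,
    code_id = as.character(.data$code_id),
    terminology = toupper(as.character(.data$terminology)),
    description = as.character(.data$description),
    category = toupper(as.character(.data$category)),
    source = as.character(.data$source))

  bad_term <- setdiff(unique(entries$terminology), valid_terminologies())
  if (length(bad_term)) {
    abort(sprintf("Unknown terminology: %s", paste(bad_term, collapse = ", ")))
  }
  bad_cat <- which(!entries$category %in% valid_categories())
  if (length(bad_cat)) {
    abort(sprintf(
      "Unknown category '%s' in codelist row %d (code_id '%s')",
      entries$category[bad_cat[1]], bad_cat[1], entries$code_id[bad_cat[1]]))
  }
  if (any(!nzchar(entries$code_id))) abort("code_id must be non-empty")
  dup <- duplicated(entries[c("terminology", "code_id")])
  if (any(dup)) {
    abort(sprintf("Duplicate (terminology, code_id): %s",
                  paste(unique(sprintf("(%s, %s)",
                    entries$terminology[dup], entries$code_id[dup])),
                    collapse = ", ")))
  }
  structure(entries,
            class = c("opicohort_codelist", class(entries)),
            codelist_name = name, codelist_version = version)
}

valid_terminologies <- function() c("READ", "SNOMED", "PRODUCT")
valid_categories <- function() {
  c("CLINICAL_DEFINITE", "CLINICAL_PROBABLE", "OAT_PRODUCT", "EXCLUDED")
}

#' @rdname codelist
#' @param path Path to a codelist CSV (UTF-8, header required).
#' @export
read_codelist <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  df$source <- df$source %||% ""
  df$source[is.na(df$source)] <- ""
  codelist(df, name = basename(path))
}

#' @rdname codelist
#' @param x A codelist.
#' @export
write_codelist <- function(x, path) {
  stopifnot(inherits(x, "opicohort_codelist"))
  readr::write_csv(as_tibble(unclass_codelist(x)), path, progress = FALSE)
  invisible(path)
}

unclass_codelist <- function(x) {
  class(x) <- setdiff(class(x), "opicohort_codelist")
  x[c("code_id", "terminology", "description", "category", "source")]
}

#' Keyword search over a code dictionary
#'
#' Curation aid: scans a terminology dictionary for descriptions matching any
#' of a set of keyword patterns, case-insensitively. A trailing `*` means
#' "this stem followed by any word characters" (`dependen*` matches
#' "dependence" and "dependent"); multi-word patterns match as contiguous
#' substrings. Returns candidate rows with `category` unset (`NA`) for manual
#' classification.
#'
#' @param dictionary Data frame with columns `code_id`, `terminology`,
#'   `description`.
#' @param patterns Character vector of keyword patterns.
#' @return Tibble of matching rows (`code_id`, `terminology`, `description`,
#'   `category = NA`, `source`), deduplicated.
#' @examples
#' d <- tibble::tibble(code_id = c("a", "b"), terminology = "READ",
#'                     description = c("Heroin dependence", "Hypertension"))
#' keyword_search(d, c("heroin", "dependen*"))
#' @export
keyword_search <- function(dictionary, patterns) {
  if (length(patterns) == 0) abort("patterns must be non-empty")
  dictionary <- as_tibble(dictionary)
  check_columns(dictionary, c("code_id", "terminology", "description"),
                "dictionary")
  bad <- grepl("\\*", sub("\\*$", "", patterns)) | patterns == "*" |
    !nzchar(patterns)
  if (any(bad)) {
    abort(sprintf("Malformed pattern(s): %s (wildcard '*' is only allowed at the end of a non-empty stem)",
                  paste(sQuote(patterns[bad]), collapse = ", ")))
  }
  if (nrow(dictionary) == 0) {
    return(tibble(code_id = character(), terminology = character(),
                  description = character(), category = character(),
                  source = character()))
  }
  regexes <- vapply(patterns, function(p) {
    if (endsWith(p, "*")) {
      paste0(gsub("([][{}()+?.^$\\\\|])", "\\\\\\1", sub("\\*$", "", p)), "\\w*")
    } else {
      gsub("([][{}()+?.^$\\\\|])", "\\\\\\1", p)
    }
  }, character(1))
  hit <- Reduce(`|`, lapply(regexes, function(rx) {
    grepl(rx, dictionary$description, ignore.case = TRUE, perl = TRUE)
  }))
  out <- dictionary[hit, c("code_id", "terminology", "description")]
  out <- distinct(out)
  mutate(out, category = NA_character_, source = "keyword_search")
}

#' Combine clinical events and prescriptions into one event table
#'
#' Prescriptions (`patient_id`, `date`, `product_code`) are recoded with
#' `terminology = "PRODUCT"` so both record types can be matched against one
#' codelist.
#'
#' @param events Clinical events: `patient_id`, `date`, `code_id`,
#'   `terminology`.
#' @param prescriptions Prescriptions: `patient_id`, `date`, `product_code`.
#' @return Tibble with columns `patient_id`, `date`, `code_id`, `terminology`.
#' @export
bind_events <- function(events = NULL, prescriptions = NULL) {
  parts <- list()
  if (!is.null(events) && nrow(events)) {
    check_columns(events, c("patient_id", "date", "code_id", "terminology"),
                  "events")
    parts$ev <- tibble(patient_id = as.character(events$patient_id),
                       date = as_date_strict(events$date, "event date"),
                       code_id = as.character(events$code_id),
                       terminology = toupper(as.character(events$terminology)))
  }
  if (!is.null(prescriptions) && nrow(prescriptions)) {
    check_columns(prescriptions, c("patient_id", "date", "product_code"),
                  "prescriptions")
    parts$rx <- tibble(patient_id = as.character(prescriptions$patient_id),
                       date = as_date_strict(prescriptions$date, "prescription date"),
                       code_id = as.character(prescriptions$product_code),
                       terminology = "PRODUCT")
  }
  if (!length(parts)) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  code_id = character(), terminology = character()))
  }
  bind_rows(parts)
}

#' Match patient events against a phenotype codelist
#'
#' Returns the dated records whose code appears in the codelist as
#' `CLINICAL_DEFINITE` or `OAT_PRODUCT` (and `CLINICAL_PROBABLE` when
#' `include_probable = TRUE`). `EXCLUDED` entries never match. Events using a
#' terminology the codelist has never seen are skipped with one warning
#' reporting the count.
#'
#' @param events Event table as produced by [bind_events()] (or clinical
#'   events alone).
#' @param codelist A [codelist()].
#' @param include_probable Also match `CLINICAL_PROBABLE` codes? Default
#'   `FALSE`: the default phenotype maximises specificity.
#' @return Tibble (`patient_id`, `date`, `code_id`, `terminology`,
#'   `category`, `description`), sorted by patient then date.
#' @export
match_patient_codes <- function(events, codelist, include_probable = FALSE) {
  stopifnot(inherits(codelist, "opicohort_codelist"))
  check_columns(events, c("patient_id", "date", "code_id", "terminology"),
                "events")
  events <- tibble(patient_id = as.character(events$patient_id),
                   date = as_date_strict(events$date, "event date"),
                   code_id = as.character(events$code_id),
                   terminology = toupper(as.character(events$terminology)))
  unknown <- !events$terminology %in% valid_terminologies()
  if (any(unknown)) {
    warn(sprintf("Skipped %d event(s) with unknown terminology (%s)",
                 sum(unknown),
                 paste(unique(events$terminology[unknown]), collapse = ", ")))
    events <- events[!unknown, ]
  }
  keep <- c("CLINICAL_DEFINITE", "OAT_PRODUCT",
            if (include_probable) "CLINICAL_PROBABLE")
  active <- filter(as_tibble(unclass_codelist(codelist)),
                   .data$category %in% keep)
  out <- inner_join(events, active, by = c("terminology", "code_id"))
  arrange(out[c("patient_id", "date", "code_id", "terminology",
                "category", "description")],
          .data$patient_id, .data$date)
}

#' Illustrative built-in codelists
#'
#' Small, synthetic codelists matching the code vocabulary emitted by
#' [simulate_ehr()]: the phenotype codelist (`example_codelist()`), a
#' smoking-status codelist where each code carries a `status` tag
#' (`CURRENT` / `EX` / `NEVER`), and lifetime-history flag codelists for
#' homelessness, prison and alcohol dependence. They demonstrate the format;
#' real analyses substitute curated lists for the target database.
#'
#' @return `example_codelist()`: a [codelist()]. `smoking_codelist()` and
#'   `flag_codelists()`: tibbles with a `status`/`flag` column alongside the
#'   code identity.
#' @export
example_codelist <- function() {
  codelist(tibble(
    code_id = c("OPI001", "OPI002", "OPI003", "OPI004",
                "INJ001", "MIS001",
                "OAT-METH-1MG-ML", "OAT-BUP-8MG-TAB",
                "ANL-BUP-PATCH", "XRX001"),
    terminology = c(rep("READ", 6), rep("PRODUCT", 3), "READ"),
    description = c(
      "Heroin dependence", "Opioid dependence syndrome",
      "Opiate misuse", "Accidental heroin overdose",
      "Injecting drug user", "Misuse of codeine tablets",
      "Methadone 1mg/ml oral solution sugar free",
      "Buprenorphine 8mg sublingual tablet",
      "Buprenorphine 5micrograms/hour transdermal patch",
      "Adverse reaction to methadone, indication unclear"),
    category = c("CLINICAL_DEFINITE", "CLINICAL_DEFINITE",
                 "CLINICAL_DEFINITE", "CLINICAL_DEFINITE",
                 "CLINICAL_PROBABLE", "CLINICAL_PROBABLE",
                 "OAT_PRODUCT", "OAT_PRODUCT",
                 "EXCLUDED", "EXCLUDED"),
    source = "bundled illustrative list"),
    name = "illustrative-opioid-phenotype", version = "1")
}

#' @rdname example_codelist
#' @export
smoking_codelist <- function() {
  tibble(code_id = c("SMK-CUR", "SMK-EX", "SMK-NEV"),
         terminology = "READ",
         description = c("Current smoker", "Ex-smoker", "Never smoked"),
         status = c("CURRENT", "EX", "NEVER"))
}

#' @rdname example_codelist
#' @export
flag_codelists <- function() {
  tibble(code_id = c("HML001", "PRS001", "ALC001"),
         terminology = "READ",
         description = c("Homeless", "History of imprisonment",
                         "Alcohol dependence syndrome"),
         flag = c("homelessness", "prison", "alcohol_dependence"))
}
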