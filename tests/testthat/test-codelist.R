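test_that("keyword search matches stems, wildcards and multi-word patterns", {
  dict <- tibble::tibble(
    code_id = c("a", "b", "c", "d", "e"),
    terminology = "READ",
    description = c("Heroin dependence",
                    "Misuse of Codeine tablets",
                    "Hypertension annual review",
                    "DRUG USER - INJECTING",
                    "Methadone prescription"))
  full_patterns <- c("methadone", "buprenorphine", "abus*", "addict",
                     "dependen*", "drug user", "heroin", "inject",
                     "misus*", "opiate", "opioid", "overdose")

  expect_true("a" %in% keyword_search(dict, "heroin")$code_id)
  expect_true("b" %in% keyword_search(dict, "misus*")$code_id)
  hits <- keyword_search(dict, full_patterns)
  expect_false("c" %in% hits$code_id)
  expect_setequal(hits$code_id, c("a", "b", "d", "e"))
  expect_true(all(is.na(hits$category)))
})

test_that("keyword search is case-invariant and deduplicated", {
  dict <- tibble::tibble(code_id = "x", terminology = "READ",
                         description = "HEROIN ABUSE ongoing")
  up <- keyword_search(dict, c("heroin", "abus*"))
  dict$description <- tolower(dict$description)
  lo <- keyword_search(dict, c("HEROIN", "ABUS*"))
  expect_equal(nrow(up), 1)
  expect_equal(up$code_id, lo$code_id)
})

test_that("keyword search rejects malformed patterns and handles empty input", {
  dict <- tibble::tibble(code_id = "x", terminology = "READ",
                         description = "anything")
  expect_error(keyword_search(dict, "he*roin"), "he\\*roin")
  expect_error(keyword_search(dict, character(0)), "non-empty")
  empty <- keyword_search(dict[0, ], "heroin")
  expect_equal(nrow(empty), 0)
})

test_that("matching respects categories and sorts by date", {
  cl <- tiny_codelist()
  ev <- dplyr::bind_rows(
    make_event("p1", "2003-05-05", "H1"),
    make_event("p1", "2001-02-02", "METH", terminology = "PRODUCT"),
    make_event("p1", "2002-03-03", "INJ"),
    make_event("p1", "2004-01-01", "PATCH", terminology = "PRODUCT"))

  strict <- match_patient_codes(ev, cl)
  expect_equal(strict$code_id, c("METH", "H1"))
  expect_equal(strict$date[1], as.Date("2001-02-02"))

  loose <- match_patient_codes(ev, cl, include_probable = TRUE)
  expect_true(all(paste(strict$code_id, strict$date) %in%
                    paste(loose$code_id, loose$date)))
  expect_true("INJ" %in% loose$code_id)
  expect_false("PATCH" %in% loose$code_id)  # EXCLUDED never matches
})

test_that("probable-inclusive matching is a superset on random event sets", {
  cl <- tiny_codelist()
  set.seed(11)
  for (i in 1:5) {
    ev <- tibble::tibble(
      patient_id = sample(c("p1", "p2", "p3"), 30, replace = TRUE),
      date = as.Date("2000-01-01") + sample.int(3000, 30, replace = TRUE),
      code_id = sample(c("H1", "O1", "INJ", "METH", "PATCH", "ZZZ"), 30,
                       replace = TRUE),
      terminology = sample(c("READ", "PRODUCT"), 30, replace = TRUE))
    strict <- match_patient_codes(ev, cl)
    loose <- match_patient_codes(ev, cl, include_probable = TRUE)
    key <- function(d) paste(d$patient_id, d$date, d$code_id, d$terminology)
    expect_true(all(key(strict) %in% key(loose)))
  }
})

test_that("events with unknown terminology are skipped with a warning", {
  ev <- make_event("p1", "2001-01-01", "H1", terminology = "ICD10")
  expect_warning(out <- match_patient_codes(ev, tiny_codelist()),
                 "unknown terminology")
  expect_equal(nrow(out), 0)
})

test_that("codelist CSV round-trip is lossless for generated codelists", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(1:20, 1)
    entries <- tibble::tibble(
      code_id = sprintf("C%03d-%d", sample.int(999, n), seq_len(n)),
      terminology = sample(c("READ", "SNOMED", "PRODUCT"), n,
                           replace = TRUE),
      description = replicate(n, paste(sample(letters, 12, TRUE),
                                       collapse = "")),
      category = sample(c("CLINICAL_DEFINITE", "CLINICAL_PROBABLE",
                          "OAT_PRODUCT", "EXCLUDED"), n, replace = TRUE),
      source = "prop-test")
    cl <- codelist(entries)
    path <- withr::local_tempfile(fileext = ".csv")
    write_codelist(cl, path)
    back <- read_codelist(path)
    expect_equal(tibble::as_tibble(opicohort:::unclass_codelist(back)),
                 tibble::as_tibble(opicohort:::unclass_codelist(cl)),
                 ignore_attr = TRUE)
  }
})

test_that("codelist loading enforces the contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("code_id,terminology,description,category,source", path)
  expect_equal(nrow(read_codelist(path)), 0)

  writeLines(c("code_id,terminology,description,category,source",
               "A,READ,thing,MAYBE,src"), path)
  expect_error(read_codelist(path), "MAYBE")

  writeLines(c("code_id,terminology,description,category,source",
               "A,READ,thing,EXCLUDED,src",
               "A,READ,thing again,OAT_PRODUCT,src"), path)
  expect_error(read_codelist(path), "Duplicate")
})
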