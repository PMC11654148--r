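write_lines_to <- function(lines, dir, name) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

make_mini_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  list(
    demo = write_lines_to(c(
      "primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$reporter_country",
      "1001$100$1$20230110$F$730$DY$US",
      "2001$200$1$20230215$M$65$YR$JP"
    ), dir, "DEMO23Q1.txt"),
    drug = write_lines_to(c(
      "primaryid$drug_seq$drugname$prod_ai$role_cod",
      "1001$1$Imlygic$TALIMOGENE LAHERPAREPVEC$PS",
      "2001$1$aspirin$$PS"
    ), dir, "DRUG23Q1.txt"),
    reac = write_lines_to(c(
      "primaryid$pt",
      "1001$Pyrexia",
      "2001$HEADACHE"
    ), dir, "REAC23Q1.txt"),
    outc = write_lines_to(c(
      "primaryid$outc_cod",
      "1001$HO"
    ), dir, "OUTC23Q1.txt"),
    dir = dir
  )
}

test_that("a quarter parses with canonical fields and verbatim age storage", {
  f <- make_mini_files()
  q <- read_faers_quarter(f$demo, f$drug, f$reac, f$outc)
  expect_s3_class(q, "faers_quarter")
  expect_equal(nrow(q$demo), 2)
  # age/age_cod stored verbatim; conversion deferred to assembly
  expect_equal(q$demo$age, c(730, 65))
  expect_equal(q$demo$age_cod, c("DY", "YR"))
  # codes and PTs canonicalised to upper case
  expect_equal(q$reac$pt, c("PYREXIA", "HEADACHE"))
  expect_equal(q$drug$role_cod, c("PS", "PS"))
})

test_that("a missing mandatory column is a hard error naming file and column", {
  dir <- withr::local_tempdir()
  demo_bad <- write_lines_to(c(
    "primaryid$caseversion$sex", "1001$1$F"
  ), dir, "DEMO_bad.txt")
  f <- make_mini_files(dir)
  expect_error(read_faers_quarter(demo_bad, f$drug, f$reac, f$outc),
               "caseid")
  expect_error(read_faers_quarter(demo_bad, f$drug, f$reac, f$outc),
               "DEMO_bad")
})

test_that("unparseable numeric age keeps the row with the field missing", {
  dir <- withr::local_tempdir()
  f <- make_mini_files(dir)
  demo <- write_lines_to(c(
    "primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$reporter_country",
    "1001$100$1$20230110$F$unknown$YR$US"
  ), dir, "DEMO_age.txt")
  q <- suppressWarnings(read_faers_quarter(demo, f$drug, f$reac, f$outc))
  expect_equal(nrow(q$demo), 1)
  expect_true(is.na(q$demo$age))
  expect_equal(unname(q$audit$unparseable_numeric[q$audit$table == "demo"]), 1L)
})

test_that("LAERS-era column subsets are tolerated as missing fields", {
  dir <- withr::local_tempdir()
  f <- make_mini_files(dir)
  demo <- write_lines_to(c(
    "primaryid$caseid$gndr_cod",  # no caseversion/fda_dt/age; legacy sex name
    "1001$100$f"
  ), dir, "DEMO_laers.txt")
  q <- suppressWarnings(read_faers_quarter(demo, f$drug, f$reac, f$outc))
  expect_true(is.na(q$demo$caseversion))
  expect_true(is.na(q$demo$fda_dt))
  expect_equal(q$demo$sex, "F")
})

test_that("write -> read round-trips the parsed content field-for-field", {
  f <- make_mini_files()
  q <- read_faers_quarter(f$demo, f$drug, f$reac, f$outc)
  out <- withr::local_tempdir()
  write_faers_quarter(q, out, "23Q1")
  q2 <- read_faers_dir(out)[[1]]
  for (tb in c("demo", "drug", "reac", "outc")) {
    expect_equal(q2[[tb]], q[[tb]], ignore_attr = TRUE)
  }
})

test_that("age conversion covers every unit code and is total", {
  expect_equal(convert_age(730, "DY"), 730 / 365.25)
  expect_equal(convert_age(6.5, "DEC"), 65)
  expect_equal(convert_age(24, "MON"), 2)
  expect_equal(convert_age(52.1429, "WK"), 1)
  expect_equal(convert_age(8766, "HR"), 1)
  expect_true(is.na(convert_age(200, "YR")))    # out of [0, 150]
  expect_true(is.na(convert_age(-1, "YR")))
  expect_equal(convert_age(70, NA), 70)          # missing unit: years
  expect_true(is.na(convert_age(70, "XX")))      # unknown unit
  expect_true(is.na(convert_age(NA, "YR")))
})

test_that("deduplication keeps the most recent case version", {
  q <- toy_quarter(caseid = c("100", "100", "100"),
                   primaryid = c("1001", "1002", "1003"),
                   caseversion = c(1L, 2L, 3L),
                   pts = list("PYREXIA", "PYREXIA", c("PYREXIA", "CHILLS")),
                   drugname = list("A", "A", "A"),
                   role = list("PS", "PS", "PS"))
  db <- deduplicate_cases(q)
  expect_equal(nrow(db$reports), 1)
  expect_equal(db$reports$primaryid, "1003")
  expect_setequal(db$reactions$pt, c("PYREXIA", "CHILLS"))
  expect_equal(db$audit$duplicates_removed, 2)
})

test_that("deduplication is the identity on unduplicated cases", {
  q <- toy_quarter(caseid = as.character(1:5),
                   pts = as.list(paste0("PT", 1:5)),
                   drugname = as.list(letters[1:5]),
                   role = as.list(rep("PS", 5)))
  db <- deduplicate_cases(q)
  expect_equal(nrow(db$reports), 5)
  expect_equal(db$audit$duplicates_removed, 0)
})

test_that("version ties break on fda_dt then primaryid, deterministically", {
  q <- toy_quarter(caseid = c("100", "100", "200", "200"),
                   primaryid = c("1001", "1002", "2002", "2001"),
                   caseversion = c(2L, 2L, 1L, 1L),
                   fda_dt = c(20230101L, 20230301L, 20230101L, 20230101L),
                   pts = list("A", "B", "C", "D"),
                   drugname = as.list(letters[1:4]),
                   role = as.list(rep("PS", 4)))
  db <- suppressMessages(deduplicate_cases(q))
  got <- setNames(db$reports$primaryid, db$reports$caseid)
  expect_equal(got[["100"]], "1002")  # later fda_dt wins
  expect_equal(got[["200"]], "2002")  # equal dates: larger primaryid wins
})

test_that("deduplication matches the brute-force oracle and is idempotent", {
  sim <- simulate_faers(synthetic_config(
    n_reports = 1000, duplication_rate = 0.2, seed = 42))
  demo_all <- dplyr::bind_rows(lapply(sim$quarters, `[[`, "demo"))
  db <- deduplicate_cases(sim$quarters)
  expect_equal(sort(db$reports$primaryid), oracle_dedup(demo_all))
  expect_equal(nrow(db$reports), length(unique(demo_all$caseid)))

  # idempotence: re-deduplicating the retained versions changes nothing
  q2 <- new_faers_quarter(
    demo = tibble::tibble(primaryid = db$reports$primaryid,
                          caseid = db$reports$caseid,
                          caseversion = db$reports$caseversion,
                          fda_dt = NA_integer_, sex = db$reports$sex,
                          age = db$reports$age_years, age_cod = "YR",
                          reporter_country = db$reports$reporter_country),
    drug = dplyr::inner_join(db$drugs,
                             db$reports[, c("caseid", "primaryid")],
                             by = "caseid")[, c("primaryid", "drug_seq",
                                                "drugname", "prod_ai",
                                                "role_cod")],
    reac = dplyr::inner_join(db$reactions,
                             db$reports[, c("caseid", "primaryid")],
                             by = "caseid")[, c("primaryid", "pt")],
    outc = dplyr::inner_join(db$outcomes,
                             db$reports[, c("caseid", "primaryid")],
                             by = "caseid")[, c("primaryid", "outc_cod")])
  db2 <- deduplicate_cases(q2)
  expect_equal(db2$audit$duplicates_removed, 0)
  expect_setequal(db2$reports$caseid, db$reports$caseid)
  expect_equal(dplyr::arrange(db2$reactions, caseid, pt),
               dplyr::arrange(db$reactions, caseid, pt))
})

test_that("primary-suspect cohorting partitions on normalised name and PS role", {
  q <- toy_quarter(
    caseid = c("1", "2", "3", "4"),
    drugname = list("IMLYGIC", "  talimogene   laherparepvec ",
                    "IMLYGIC", "OTHER"),
    role = list("PS", "PS", "C", "PS"),
    pts = list("A", "B", "C", "D"))
  db <- deduplicate_cases(q)
  db <- cohort_primary_suspect(db, c("IMLYGIC", "TALIMOGENE LAHERPAREPVEC"))
  expect_setequal(db$reports$caseid[db$reports$is_target], c("1", "2"))
  # concomitant role does not cohort; partition is exhaustive and disjoint
  expect_setequal(db$reports$caseid[!db$reports$is_target], c("3", "4"))
  expect_equal(sum(db$reports$is_target) + sum(!db$reports$is_target),
               nrow(db$reports))
})

test_that("cohorting matches on the active-ingredient field too", {
  q <- toy_quarter(caseid = "1", drugname = list("BRANDNAME"),
                   role = list("PS"), pts = list("A"))
  q$drug$prod_ai <- "TALIMOGENE LAHERPAREPVEC"
  db <- deduplicate_cases(q)
  db <- cohort_primary_suspect(db, "talimogene laherparepvec")
  expect_true(all(db$reports$is_target))
})

test_that("an empty target cohort warns but does not error", {
  q <- toy_quarter(caseid = "1", drugname = list("X"), role = list("PS"),
                   pts = list("A"))
  db <- deduplicate_cases(q)
  expect_warning(cohort_primary_suspect(db, "ABSENT"), "no reports matched")
})
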