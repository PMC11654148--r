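#' Convert FAERS age values to years
#'
#' FAERS stores patient age with a unit code: `DEC` decades, `YR` years,
#' `MON` months, `WK` weeks, `DY` days, `HR` hours. A missing unit with a
#' non-missing value is taken to mean years. Results outside \[0, 150\] years
#' are set missing (and counted by the caller's audit), so the function is
#' total: it never errors.
#'
#' @param age Numeric vector of raw age values.
#' @param age_cod Character vector of unit codes (recycled if length 1).
#' @return Numeric vector of ages in years, `NA` where unknown or implausible.
#' @export
#' @examples
#' convert_age(c(730, 6.5, 200), c("DY", "DEC", "YR"))
convert_age <- function(age, age_cod) {
  if (length(age_cod) == 1) age_cod <- rep(age_cod, length(age))
  stopifnot(length(age) == length(age_cod))
  factor_per_year <- c(DEC = 0.1, YR = 1, MON = 12, WK = 52.1429,
                       DY = 365.25, HR = 8766)
  cod <- toupper(age_cod)
  div <- unname(factor_per_year[cod])
  div[is.na(cod) | cod == ""] <- 1  # missing unit: assume years
  years <- age / div
  years[is.na(div) & !(is.na(cod) | cod == "")] <- NA_real_  # unknown unit code
  years[!is.na(years) & (years < 0 | years > 150)] <- NA_real_
  years
}

#' Normalise a drug name for matching
#'
#' Trims, collapses internal whitespace and uppercases. Matching elsewhere in
#' the package is exact on the normalised string (no fuzzy matching):
#' synonyms such as brand and active-ingredient names are handled by passing
#' a name list.
#'
#' @param x Character vector of drug names.
#' @return Normalised character vector.
#' @export
#' @examples
#' normalize_drug_name("  talimogene   laherparepvec ")
normalize_drug_name <- function(x) {
  toupper(stringr::str_squish(x))
}

#' Deduplicate multi-version case reports across quarters
#'
#' A FAERS case (`caseid`) may be submitted repeatedly as follow-up versions,
#' each with its own `primaryid`; analyses must count each patient-case once.
#' This keeps, per `caseid`, the row with the highest `caseversion` across
#' all supplied quarters (missing `caseversion` is treated as 1). Ties on
#' `caseversion` are broken by latest `fda_dt`, then lexicographically
#' largest `primaryid`, so the result is deterministic. Drug, reaction and
#' outcome rows are attached from the retained `primaryid` only.
#'
#' @param quarters A `faers_quarter` or (possibly named) list of them.
#' @return A `faers_db`: list with tibbles
#'   * `reports` — one row per case: `caseid`, `primaryid`, `caseversion`,
#'     `sex`, `age_years`, `reporter_country`, `fda_year`, `n_pts`;
#'   * `drugs` — `caseid`, `drug_seq`, `drugname`, `prod_ai`, `role_cod`
#'     plus normalised `drugname_norm`, `prod_ai_norm`;
#'   * `reactions` — distinct `caseid`, `pt` pairs (PTs uppercased);
#'   * `outcomes` — distinct `caseid`, `outc_cod` pairs;
#'   * `audit` — versions in, cases out, duplicates removed, version
#'     tie-breaks, implausible ages dropped, reports with no reactions.
#' @seealso [cohort_primary_suspect()], [detect_signals()]
#' @export
deduplicate_cases <- function(quarters) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  stopifnot(length(quarters) >= 1,
            all(vapply(quarters, inherits, logical(1), "faers_quarter")))

  demo <- bind_rows(lapply(quarters, `[[`, "demo"))
  drug <- bind_rows(lapply(quarters, `[[`, "drug"))
  reac <- bind_rows(lapply(quarters, `[[`, "reac"))
  outc <- bind_rows(lapply(quarters, `[[`, "outc"))

  demo <- mutate(demo,
                 caseversion = if_else(is.na(.data$caseversion), 1L, .data$caseversion))

  # retained version per caseid: max caseversion, tie-break latest fda_dt,
  # then largest primaryid; radix sort + first-per-case keeps this O(n log n)
  fda_filled <- ifelse(is.na(demo$fda_dt), -1L, demo$fda_dt)
  ord <- order(demo$caseid, demo$caseversion, fda_filled, demo$primaryid,
               method = "radix",
               decreasing = c(FALSE, TRUE, TRUE, TRUE))
  sorted <- demo[ord, , drop = FALSE]
  keep <- !duplicated(sorted$caseid)
  nxt_same_case <- c(sorted$caseid[-1] == sorted$caseid[-nrow(sorted)], FALSE)
  nxt_same_version <- c(sorted$caseversion[-1] == sorted$caseversion[-nrow(sorted)], FALSE)
  n_tiebreaks <- sum(keep & nxt_same_case & nxt_same_version)
  ranked <- sorted[keep, , drop = FALSE]
  if (n_tiebreaks > 0) {
    inform(sprintf(
      "%d caseid(s) had multiple rows at the same caseversion; kept latest fda_dt then largest primaryid",
      n_tiebreaks))
  }

  age_years <- convert_age(ranked$age, ranked$age_cod)
  n_age_dropped <- sum(!is.na(ranked$age) & is.na(age_years))

  reports <- tibble(
    caseid = ranked$caseid,
    primaryid = ranked$primaryid,
    caseversion = ranked$caseversion,
    sex = if_else(ranked$sex %in% c("F", "M"), ranked$sex, NA_character_),
    age_years = age_years,
    reporter_country = ranked$reporter_country,
    fda_year = ifelse(is.na(ranked$fda_dt), NA_integer_, ranked$fda_dt %/% 10000L)
  )

  keep_pid <- reports[, c("caseid", "primaryid")]
  drugs <- drug |>
    inner_join(keep_pid, by = "primaryid") |>
    mutate(drugname_norm = normalize_drug_name(.data$drugname),
           prod_ai_norm = if_else(is.na(.data$prod_ai), NA_character_,
                                  normalize_drug_name(.data$prod_ai))) |>
    select("caseid", "drug_seq", "drugname", "prod_ai", "role_cod",
           "drugname_norm", "prod_ai_norm")
  reactions <- reac |>
    inner_join(keep_pid, by = "primaryid") |>
    distinct(.data$caseid, .data$pt) |>
    filter(!is.na(.data$pt))
  outcomes <- outc |>
    inner_join(keep_pid, by = "primaryid") |>
    distinct(.data$caseid, .data$outc_cod) |>
    filter(!is.na(.data$outc_cod))

  pt_counts <- count(reactions, .data$caseid, name = "n_pts")
  reports <- reports |>
    left_join(pt_counts, by = "caseid") |>
    mutate(n_pts = if_else(is.na(.data$n_pts), 0L, .data$n_pts))

  audit <- tibble(
    versions_in = nrow(demo),
    cases_out = nrow(reports),
    duplicates_removed = nrow(demo) - nrow(reports),
    version_tiebreaks = n_tiebreaks,
    ages_implausible = n_age_dropped,
    reports_without_reactions = sum(reports$n_pts == 0L)
  )
  new_faers_db(reports, drugs, reactions, outcomes, audit)
}

new_faers_db <- function(reports, drugs, reactions, outcomes, audit) {
  structure(list(reports = reports, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, audit = audit),
            class = "faers_db")
}

#' @export
print.faers_db <- function(x, ...) {
  cat(sprintf("<faers_db> %d case reports (%d drug rows, %d reactions, %d outcomes)\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  if ("is_target" %in% names(x$reports)) {
    cat(sprintf("  cohorted: %d target / %d background\n",
                sum(x$reports$is_target), sum(!x$reports$is_target)))
  }
  invisible(x)
}

#' Split a database into target-drug and background cohorts
#'
#' A report belongs to the target cohort when at least one of its drug rows
#' names a target drug (exact match after [normalize_drug_name()], against
#' both the verbatim drug name and the active ingredient) *and* that row's
#' role code is `PS` (primary suspect). Everything else is background, so
#' the partition is exhaustive and disjoint.
#'
#' @param db A `faers_db` from [deduplicate_cases()].
#' @param target_names Character vector of target-drug synonyms (brand and
#'   active-ingredient names).
#' @return `db` with a logical `is_target` column added to `db$reports`.
#' @export
#' @examples
#' # db <- deduplicate_cases(quarters)
#' # db <- cohort_primary_suspect(db, c("IMLYGIC", "TALIMOGENE LAHERPAREPVEC"))
cohort_primary_suspect <- function(db, target_names) {
  stopifnot(inherits(db, "faers_db"), length(target_names) > 0)
  targets <- normalize_drug_name(target_names)
  hit_cases <- db$drugs |>
    filter(.data$role_cod == "PS",
           .data$drugname_norm %in% targets |
             (!is.na(.data$prod_ai_norm) & .data$prod_ai_norm %in% targets)) |>
    pull(.data$caseid) |>
    unique()
  db$reports$is_target <- db$reports$caseid %in% hit_cases
  if (length(hit_cases) == 0) {
    warn("no reports matched the target drug as primary suspect; downstream analyses will be empty")
  }
  db
}

#' Which reports contain a drug (any role)?
#'
#' Helper used by the combination-therapy analysis: returns the caseids whose
#' drug list contains any of `names` in any role code.
#'
#' @param db A `faers_db`.
#' @param names Character vector of drug synonyms.
#' @return Character vector of caseids.
#' @export
cases_with_drug <- function(db, names) {
  nm <- normalize_drug_name(names)
  db$drugs |>
    filter(.data$drugname_norm %in% nm |
             (!is.na(.data$prod_ai_norm) & .data$prod_ai_norm %in% nm)) |>
    pull(.data$caseid) |>
    unique()
}
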