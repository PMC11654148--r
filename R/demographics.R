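#' Default severity order for seriousness outcomes
#'
#' FAERS outcome codes ranked from most to least severe; a report with
#' several outcome codes is tabulated once, under its most severe one.
#' `CA` (congenital anomaly), `RI` (required intervention) and `OT` (other
#' serious) all collapse to "Other serious events".
#' @export
outcome_precedence_default <- c(DE = "Death", LT = "Life-threatening",
                                HO = "Hospitalization", DS = "Disability",
                                CA = "Other serious events",
                                RI = "Other serious events",
                                OT = "Other serious events")

.usa_codes <- c("US", "USA", "UNITED STATES", "UNITED STATES OF AMERICA")

#' Table-1-style demographic summary of a cohort
#'
#' Tabulates a deduplicated cohort by sex, reporting country (collapsed to
#' USA / Rest of the world / Unknown), reporting year (FDA receipt year of
#' the retained version), age band and most severe seriousness outcome.
#' Every report contributes exactly one row per section, so within each
#' section the counts sum to the cohort total; percentages are
#' `round(100 * n / total, 1)`.
#'
#' @param db A `faers_db`; if it has been cohorted, `which` selects the
#'   cohort summarised.
#' @param which `"target"` (default when cohorted), `"background"` or
#'   `"all"`.
#' @param age_breaks Increasing numeric vector of left-closed bin edges in
#'   years; the default `c(0, 18, 45, 60, Inf)` gives the bands
#'   `< 18`, `18 ~ 44`, `45 ~ 59`, `>= 60`.
#' @param outcome_precedence Named character vector mapping outcome codes to
#'   labels, in decreasing severity (see [outcome_precedence_default]).
#' @return A `faers_demographics` tibble (`section`, `label`, `n`, `pct`)
#'   with attribute `total`; an empty cohort gives zero rows and total 0.
#' @export
summarize_demographics <- function(db,
                                   which = c("target", "all", "background"),
                                   age_breaks = c(0, 18, 45, 60, Inf),
                                   outcome_precedence = outcome_precedence_default) {
  stopifnot(inherits(db, "faers_db"))
  which <- match.arg(which)
  reports <- db$reports
  if (which != "all") {
    if (!"is_target" %in% names(reports)) {
      if (which == "target") {
        which <- "all"  # uncohorted database: summarise everything
      } else {
        abort("database is not cohorted; cannot select the background cohort")
      }
    } else {
      reports <- filter(reports,
                        if (which == "target") .data$is_target else !.data$is_target)
    }
  }
  total <- nrow(reports)
  if (total == 0) {
    res <- tibble(section = character(), label = character(),
                  n = integer(), pct = numeric())
    return(structure(res, class = c("faers_demographics", class(res)),
                     total = 0L))
  }

  sex_lab <- dplyr::case_when(reports$sex == "F" ~ "Female",
                              reports$sex == "M" ~ "Male",
                              .default = "Unknown")

  country <- toupper(stringr::str_squish(reports$reporter_country))
  country_lab <- dplyr::case_when(is.na(country) | country == "" ~ "Unknown",
                                  country %in% .usa_codes ~ "USA",
                                  .default = "Rest of the world")

  year_lab <- ifelse(is.na(reports$fda_year), "Unknown",
                     as.character(reports$fda_year))

  age_lab <- .age_band(reports$age_years, age_breaks)

  # most severe outcome per report; no outcome rows -> Unknown
  sev <- db$outcomes |>
    filter(.data$caseid %in% reports$caseid,
           .data$outc_cod %in% names(outcome_precedence)) |>
    mutate(rank = match(.data$outc_cod, names(outcome_precedence)))
  sev <- if (nrow(sev) == 0) {
    tibble(caseid = character(), rank = integer())
  } else {
    summarise(group_by(sev, .data$caseid), rank = min(.data$rank),
              .groups = "drop")
  }
  outcome_lab <- rep("Unknown", total)
  hit <- match(reports$caseid, sev$caseid)
  outcome_lab[!is.na(hit)] <-
    unname(outcome_precedence[sev$rank[hit[!is.na(hit)]]])

  tab_section <- function(section, labels, order) {
    tibble(section = section, label = labels) |>
      count(.data$section, .data$label, name = "n") |>
      mutate(pct = round(100 * .data$n / total, 1)) |>
      arrange(match(.data$label, order))
  }
  year_order <- c(sort(unique(year_lab[year_lab != "Unknown"]),
                       decreasing = TRUE), "Unknown")
  res <- bind_rows(
    tab_section("Sex", sex_lab, c("Female", "Male", "Unknown")),
    tab_section("Reporting country", country_lab,
                c("USA", "Rest of the world", "Unknown")),
    tab_section("Reporting year", year_lab, year_order),
    tab_section("Age at onset", age_lab,
                c(.age_band_labels(age_breaks), "Unknown")),
    tab_section("Outcome", outcome_lab,
                c(unique(unname(outcome_precedence)), "Unknown"))
  )
  structure(res, class = c("faers_demographics", class(res)), total = total)
}

.age_band_labels <- function(breaks) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ifelse(is.infinite(hi), sprintf(">= %g years", lo),
         ifelse(lo == min(lo) & lo == 0, sprintf("< %g years", hi),
                sprintf("%g ~ %g years", lo, hi - 1)))
}

.age_band <- function(age_years, breaks) {
  labels <- .age_band_labels(breaks)
  idx <- findInterval(age_years, breaks, rightmost.closed = FALSE)
  lab <- rep("Unknown", length(age_years))
  ok <- !is.na(age_years) & idx >= 1 & idx <= length(labels)
  lab[ok] <- labels[idx[ok]]
  lab
}

#' @export
print.faers_demographics <- function(x, ...) {
  cat(sprintf("<faers_demographics> total = %d reports\n", attr(x, "total")))
  NextMethod()
}
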