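#' Reporting odds ratio with 95% confidence interval
#'
#' For a drug-event 2x2 table (`a` = reports with the event among reports of
#' the suspect drug, `b` = suspect-drug reports without the event, `c` =
#' comparator reports with the event, `d` = comparator reports without it):
#' \deqn{ROR = ad/bc, \quad CI = ROR \cdot e^{\pm z\sqrt{1/a+1/b+1/c+1/d}}}
#' with `z = 1.96` for a two-sided 95% interval. When any cell is zero the
#' estimate and interval are computed on the Haldane–Anscombe corrected table
#' (0.5 added to all four cells) and flagged in `zero_cell_corrected`; an
#' all-zero table is undefined and errors.
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to common length).
#' @param z Normal quantile for the interval (default 1.96).
#' @return Tibble with columns `ror`, `ror025`, `ror975`,
#'   `zero_cell_corrected`.
#' @export
#' @examples
#' ror_with_ci(10, 20, 30, 240)  # ROR 4.0, CI ~ (1.71, 9.35)
ror_with_ci <- function(a, b, c, d, z = 1.96) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(a) | is.na(b) | is.na(c) | is.na(d)) ||
      any(a < 0 | b < 0 | c < 0 | d < 0)) {
    abort("contingency cells must be non-negative and non-missing")
  }
  if (any(a + b + c + d == 0)) {
    abort("all-zero contingency table: ROR is undefined")
  }
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected; d <- d + 0.5 * corrected
  ror <- (a * d) / (b * c)
  se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(ror = ror,
         ror025 = ror * exp(-z * se_log),
         ror975 = ror * exp(z * se_log),
         zero_cell_corrected = corrected)
}

#' Bayesian information component with 95% credibility bounds
#'
#' The information component compares the observed count of a drug-event
#' pair with the count expected from the database margins,
#' `N_expected = N_drug * N_effect / N_total`, on a log2 scale with +0.5
#' shrinkage:
#' \deqn{IC = \log_2\frac{N_{obs}+0.5}{N_{exp}+0.5}}
#' The 95% credibility bounds use the closed-form approximations
#' \deqn{IC_{025} = IC - 3.3(N_{obs}+0.5)^{-1/2} - 2(N_{obs}+0.5)^{-3/2}}
#' \deqn{IC_{975} = IC + 2.4(N_{obs}+0.5)^{-1/2} - 0.5(N_{obs}+0.5)^{-3/2}}
#' No zero-cell correction is needed: the +0.5 shrinkage is part of the
#' formula, and `N_obs = N_exp = 0` yields IC = 0 with wide, asymmetric
#' bounds.
#'
#' @param n_observed Observed reports of the drug-event pair.
#' @param n_drug Reports of the drug, regardless of event.
#' @param n_effect Reports of the event, regardless of drug.
#' @param n_total Reports in the whole database (must be positive).
#' @return Tibble with columns `ic`, `ic025`, `ic975` (bits).
#' @export
#' @examples
#' ic_with_bounds(10, 100, 1000, 100000)  # IC = log2(7) ~ 2.81
ic_with_bounds <- function(n_observed, n_drug, n_effect, n_total) {
  n <- max(length(n_observed), length(n_drug), length(n_effect), length(n_total))
  n_observed <- rep_len(as.numeric(n_observed), n)
  n_drug <- rep_len(as.numeric(n_drug), n)
  n_effect <- rep_len(as.numeric(n_effect), n)
  n_total <- rep_len(as.numeric(n_total), n)
  if (any(n_total <= 0)) abort("n_total must be positive to compute the IC")
  if (any(n_observed > n_drug | n_observed > n_effect)) {
    abort("n_observed cannot exceed n_drug or n_effect")
  }
  n_expected <- n_drug * n_effect / n_total
  shrunk <- n_observed + 0.5
  ic <- log2(shrunk / (n_expected + 0.5))
  tibble(ic = ic,
         ic025 = ic - 3.3 * shrunk^(-0.5) - 2 * shrunk^(-1.5),
         ic975 = ic + 2.4 * shrunk^(-0.5) - 0.5 * shrunk^(-1.5))
}

#' Apply the signal-detection rule
#'
#' A drug-event pair is a signal when all three hold: the lower bound of the
#' ROR 95% CI exceeds 1.00, the lower bound of the IC 95% credibility
#' interval exceeds 0, and the observed count is at least `min_a` (default
#' 4). The conjunction guards against disproportionality driven by a handful
#' of reports.
#'
#' @param n Observed count (cell `a`).
#' @param ror025 Lower ROR confidence bound.
#' @param ic025 Lower IC credibility bound (set `-Inf`/`NULL` semantics are
#'   not supported; pass `ic025 = Inf` to ignore in ROR-only screens).
#' @param min_a Minimum observed count (default 4).
#' @return Logical vector.
#' @export
flag_signal <- function(n, ror025, ic025, min_a = 4) {
  n >= min_a & ror025 > 1 & ic025 > 0
}

#' Build drug-event contingency tables for a cohorted database
#'
#' For every term observed at least once in the target cohort, counts the
#' report-level 2x2 table against the background cohort: `a` = target
#' reports containing the term, `b` = target reports without it, `c` =
#' background reports containing it, `d` = background reports without it.
#' Under this (default) counting unit `a + b + c + d` equals the number of
#' reports in the database, and the IC margins are `n_drug` = target
#' reports, `n_effect = a + c`, `n_total` = all reports. The alternative
#' `counting = "pair"` uses report-term pairs as the unit (`b` = other
#' pairs in the target cohort, `d` = other pairs in the background).
#'
#' Reports with no reaction rows cannot contribute an event and are excluded
#' from the denominators (they are counted in the dedup audit).
#'
#' @param db A cohorted `faers_db` (see [cohort_primary_suspect()]).
#' @param level `"pt"` (preferred term) or `"soc"` (system organ class
#'   rollup; requires `map`). At SOC level a report contributes once per
#'   SOC however many of its PTs fall in it.
#' @param map A `pt_soc_map`, required for `level = "soc"` and used at PT
#'   level to annotate each PT with its SOC.
#' @param counting `"report"` (default) or `"pair"`.
#' @return Tibble with columns `term`, `soc`, `a`, `b`, `c`, `d`,
#'   `n_observed`, `n_drug`, `n_effect`, `n_total`.
#' @export
build_contingency_tables <- function(db, level = c("pt", "soc"), map = NULL,
                                     counting = c("report", "pair")) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  stopifnot(inherits(db, "faers_db"))
  if (!"is_target" %in% names(db$reports)) {
    abort("database is not cohorted; call cohort_primary_suspect() first")
  }
  if (level == "soc" && is.null(map)) abort("level = \"soc\" requires a pt_soc_map")

  reports <- filter(db$reports, .data$n_pts > 0)
  if (level == "soc") {
    events <- .rollup_long(db$reactions, map)
  } else {
    events <- tibble(caseid = db$reactions$caseid, term = db$reactions$pt)
  }
  events <- semi_join(events, reports, by = "caseid")
  events <- left_join(events,
                      select(reports, "caseid", "is_target"), by = "caseid")

  n_target <- sum(reports$is_target)
  n_background <- sum(!reports$is_target)

  counts <- events |>
    group_by(.data$term) |>
    summarise(a = sum(.data$is_target), c_ = sum(!.data$is_target),
              .groups = "drop") |>
    filter(.data$a > 0)

  if (counting == "report") {
    tab <- counts |>
      mutate(b = n_target - .data$a,
             c = .data$c_,
             d = n_background - .data$c_,
             n_total = n_target + n_background)
  } else {
    pairs_target <- sum(events$is_target)
    pairs_background <- sum(!events$is_target)
    tab <- counts |>
      mutate(b = pairs_target - .data$a,
             c = .data$c_,
             d = pairs_background - .data$c_,
             n_total = pairs_target + pairs_background)
  }
  tab <- tab |>
    mutate(n_observed = .data$a,
           n_drug = .data$a + .data$b,
           n_effect = .data$a + .data$c) |>
    select(-"c_")

  if (level == "pt" && !is.null(map)) {
    soc <- map$soc[match(tab$term, map$pt)]
    tab$soc <- ifelse(is.na(soc), "UNMAPPED", soc)
  } else if (level == "soc") {
    tab$soc <- tab$term
  } else {
    tab$soc <- NA_character_
  }
  select(tab, "term", "soc", "a", "b", "c", "d",
         "n_observed", "n_drug", "n_effect", "n_total")
}

#' Screen a cohorted database for disproportionality signals
#'
#' Runs the full screen at PT or SOC level: builds the contingency tables
#' with [build_contingency_tables()], computes ROR with its 95% CI and the
#' IC with its 95% credibility bounds, and applies the signal rule
#' (ROR025 > 1, IC025 > 0, n >= `min_a`). Rows are ordered by SOC and then
#' by descending case count. No multiplicity adjustment is applied — the
#' conjunction of thresholds *is* the decision rule, a deliberately simple
#' hypothesis-generating screen, and this is recorded in the result's
#' attributes.
#'
#' @inheritParams build_contingency_tables
#' @param min_a Minimum case count for a signal (default 4).
#' @param z Normal quantile for the ROR interval (default 1.96).
#' @return A `faers_signals` tibble: `level`, `term`, `soc`, `n`, `a`–`d`,
#'   `ror`, `ror025`, `ror975`, `ic`, `ic025`, `ic975`, `signal`,
#'   `zero_cell_corrected`.
#' @seealso [combo_signals()], [autoplot.faers_signals()]
#' @export
detect_signals <- function(db, level = c("pt", "soc"), map = NULL,
                           min_a = 4, z = 1.96,
                           counting = c("report", "pair")) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  tab <- build_contingency_tables(db, level = level, map = map,
                                  counting = counting)
  if (nrow(tab) == 0) {
    res <- tibble(level = character(), term = character(), soc = character(),
                  n = integer(), a = numeric(), b = numeric(), c = numeric(),
                  d = numeric(), ror = numeric(), ror025 = numeric(),
                  ror975 = numeric(), ic = numeric(), ic025 = numeric(),
                  ic975 = numeric(), signal = logical(),
                  zero_cell_corrected = logical())
  } else {
    ror_tab <- ror_with_ci(tab$a, tab$b, tab$c, tab$d, z = z)
    ic_tab <- ic_with_bounds(tab$n_observed, tab$n_drug, tab$n_effect,
                             tab$n_total)
    res <- tibble(level = level, term = tab$term, soc = tab$soc,
                  n = as.integer(tab$a),
                  a = tab$a, b = tab$b, c = tab$c, d = tab$d) |>
      dplyr::bind_cols(ror_tab[c("ror", "ror025", "ror975")], ic_tab) |>
      mutate(signal = flag_signal(.data$n, .data$ror025, .data$ic025,
                                  min_a = min_a),
             zero_cell_corrected = ror_tab$zero_cell_corrected) |>
      arrange(.data$soc, desc(.data$n), .data$term)
  }
  structure(res,
            class = c("faers_signals", class(res)),
            level = level, min_a = min_a, z = z, counting = counting,
            n_total = if (nrow(tab)) tab$n_total[1] else 0L,
            n_drug = if (nrow(tab)) tab$n_drug[1] else 0L,
            multiplicity_adjustment = "none (threshold rule only)")
}

#' Combination-therapy comparator analysis
#'
#' Asks whether an adverse event is differentially reported when the target
#' drug is co-reported with a given immune checkpoint inhibitor (ICI),
#' relative to a comparator regimen. For each ICI the exposure group is the
#' target-cohort reports that also list that ICI in any role. The comparator
#' depends on `comparator_mode`:
#' * `"other-target-regimens"` (default): target-cohort reports *without*
#'   that ICI (i.e. the target drug in other regimens, including
#'   monotherapy);
#' * `"other-ici-regimens"`: reports listing that ICI but not in the target
#'   cohort.
#'
#' This screen is ROR-only; a pair is flagged when ROR025 > 1 and the case
#' count is at least `min_a`.
#'
#' @param db A cohorted `faers_db`.
#' @param ici_groups Named list: ICI label -> character vector of drug-name
#'   synonyms.
#' @param comparator_mode See above.
#' @param min_a Minimum case count (default 4).
#' @param z Normal quantile for the CI (default 1.96).
#' @return A `faers_combo_signals` tibble: `ici`, `term`, `n`, `a`–`d`,
#'   `ror`, `ror025`, `ror975`, `signal`, `zero_cell_corrected`. ICIs with
#'   no co-exposed reports are skipped with a warning.
#' @export
combo_signals <- function(db, ici_groups,
                          comparator_mode = c("other-target-regimens",
                                              "other-ici-regimens"),
                          min_a = 4, z = 1.96) {
  comparator_mode <- match.arg(comparator_mode)
  stopifnot(inherits(db, "faers_db"), length(ici_groups) > 0,
            !is.null(names(ici_groups)))
  if (!"is_target" %in% names(db$reports)) {
    abort("database is not cohorted; call cohort_primary_suspect() first")
  }
  reports <- filter(db$reports, .data$n_pts > 0)
  target_ids <- reports$caseid[reports$is_target]

  out <- purrr::imap(ici_groups, function(names_k, ici) {
    with_ici <- cases_with_drug(db, names_k)
    exposure <- intersect(target_ids, with_ici)
    if (length(exposure) == 0) {
      warn(sprintf("ICI '%s' has no co-exposed target reports; skipped", ici))
      return(NULL)
    }
    comparator <- switch(comparator_mode,
      "other-target-regimens" = setdiff(target_ids, with_ici),
      "other-ici-regimens" = setdiff(
        intersect(reports$caseid, with_ici), target_ids))
    if (length(comparator) == 0) {
      warn(sprintf("ICI '%s' has an empty comparator group under mode '%s'; skipped",
                   ici, comparator_mode))
      return(NULL)
    }
    ev <- filter(db$reactions, .data$caseid %in% c(exposure, comparator))
    counts <- ev |>
      mutate(exposed = .data$caseid %in% exposure) |>
      group_by(.data$pt) |>
      summarise(a = sum(.data$exposed), c = sum(!.data$exposed),
                .groups = "drop") |>
      filter(.data$a > 0)
    if (nrow(counts) == 0) return(NULL)
    counts <- mutate(counts,
                     b = length(exposure) - .data$a,
                     d = length(comparator) - .data$c)
    ror_tab <- ror_with_ci(counts$a, counts$b, counts$c, counts$d, z = z)
    tibble(ici = ici, term = counts$pt, n = as.integer(counts$a),
           a = counts$a, b = counts$b, c = counts$c, d = counts$d) |>
      dplyr::bind_cols(ror_tab[c("ror", "ror025", "ror975")]) |>
      mutate(signal = .data$ror025 > 1 & .data$n >= min_a,
             zero_cell_corrected = ror_tab$zero_cell_corrected)
  })
  res <- bind_rows(out) |>
    arrange(.data$ici, desc(.data$n), .data$term)
  structure(res, class = c("faers_combo_signals", class(res)),
            comparator_mode = comparator_mode, min_a = min_a, z = z)
}
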