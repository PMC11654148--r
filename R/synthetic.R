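#' Configuration for the synthetic FAERS generator
#'
#' Describes a FAERS-shaped database to simulate: database size, a toy
#' PT/SOC ontology, a target drug reported as primary suspect in a fraction
#' of reports, background preferred-term reporting probabilities, planted
#' drug-event associations of known relative reporting rate, immune
#' checkpoint inhibitor co-reporting, case-version duplication and per-field
#' missingness. The generator is fully seeded: the same config produces
#' byte-identical quarter files.
#'
#' Planting multiplies the baseline PT probability within target reports
#' (`min(1, lambda * p)`), so for modest `p` the design reporting odds ratio
#' is close to `lambda`, which gives closed-form expectations for tests.
#'
#' @param n_reports Number of distinct cases (>= 1).
#' @param n_background_drugs Size of the background drug vocabulary.
#' @param n_pts,n_socs Size of the toy ontology (PTs are assigned to SOCs
#'   round-robin; each PT gets exactly one SOC).
#' @param target_drug_prob Probability a report lists the target drug as
#'   primary suspect.
#' @param background_pt_prob Baseline per-PT reporting probability; scalar
#'   or vector of length `n_pts`.
#' @param planted Named numeric vector: preferred term -> relative reporting
#'   rate lambda (> 0) applied within target reports. Terms named here are
#'   prepended to the PT vocabulary.
#' @param ici_probs Named numeric vector: ICI drug name -> probability of
#'   co-reporting (role SS or C) within a target report.
#' @param ici_background_prob Probability a background report lists each ICI.
#' @param duplication_rate Fraction of cases emitted in 2-4 versions (the
#'   highest version is the truth; earlier versions have perturbed
#'   reactions).
#' @param missing_rates Named list with elements `sex`, `age`, `country`,
#'   `fda_dt`: per-field missingness probabilities.
#' @param outcome_probs Named probabilities over
#'   `DE`, `LT`, `HO`, `DS`, `OT`, `none` for the primary seriousness
#'   outcome; defaults loosely follow the outcome mix of published FAERS
#'   cohorts for an oncology biologic (10% death, 21% hospitalisation, a
#'   large "other serious" share, and about a quarter of reports with no
#'   outcome code).
#' @param n_quarters Number of quarterly files to spread the reports over.
#' @param target_drug_name,target_prod_ai Names used for the target drug
#'   rows (verbatim drug name and active-ingredient field).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 10000,
                             n_background_drugs = 25,
                             n_pts = 50,
                             n_socs = 10,
                             target_drug_prob = 0.01,
                             background_pt_prob = 0.02,
                             planted = c(PLANTED_1 = 5),
                             ici_probs = c(PEMBROLIZUMAB = 0.06,
                                           NIVOLUMAB = 0.05,
                                           IPILIMUMAB = 0.04,
                                           ATEZOLIZUMAB = 0.02),
                             ici_background_prob = 0.02,
                             duplication_rate = 0.1,
                             missing_rates = list(sex = 0.25, age = 0.35,
                                                  country = 0.05,
                                                  fda_dt = 0.01),
                             outcome_probs = c(DE = 0.10, LT = 0.02,
                                               HO = 0.21, DS = 0.01,
                                               OT = 0.38, none = 0.28),
                             n_quarters = 4,
                             target_drug_name = "ONCOVIRELEC",
                             target_prod_ai = "ONCOVIRELEC INJECTION",
                             seed = 1L) {
  cfg <- list(n_reports = as.integer(n_reports),
              n_background_drugs = as.integer(n_background_drugs),
              n_pts = as.integer(n_pts), n_socs = as.integer(n_socs),
              target_drug_prob = target_drug_prob,
              background_pt_prob = background_pt_prob,
              planted = planted, ici_probs = ici_probs,
              ici_background_prob = ici_background_prob,
              duplication_rate = duplication_rate,
              missing_rates = missing_rates,
              outcome_probs = outcome_probs,
              n_quarters = as.integer(n_quarters),
              target_drug_name = target_drug_name,
              target_prod_ai = target_prod_ai,
              seed = as.integer(seed))
  probs <- c(cfg$target_drug_prob, cfg$background_pt_prob, cfg$ici_probs,
             cfg$ici_background_prob, cfg$duplication_rate,
             unlist(cfg$missing_rates))
  stopifnot(cfg$n_reports >= 1, cfg$n_pts >= 1, cfg$n_socs >= 1,
            all(probs >= 0 & probs <= 1),
            is.null(cfg$planted) || all(cfg$planted > 0),
            length(cfg$background_pt_prob) %in% c(1L, cfg$n_pts),
            abs(sum(cfg$outcome_probs) - 1) < 1e-8)
  if (!is.null(cfg$planted) && is.null(names(cfg$planted))) {
    abort("'planted' must be a named numeric vector (pt -> lambda)")
  }
  if (cfg$n_reports * cfg$target_drug_prob < 5) {
    warn("config implies fewer than 5 expected target reports; disproportionality estimates will be unstable")
  }
  structure(cfg, class = "synthetic_config")
}

# run expr with the RNG seeded from `seed`, restoring global RNG state after
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a FAERS-shaped database with planted associations
#'
#' Draws `n_reports` cases: Bernoulli target-drug exposure, per-PT Bernoulli
#' reaction inclusion (baseline probability, multiplied by lambda for
#' planted terms within target reports), demographics with configured
#' missingness, seriousness outcomes, concomitant background drugs and ICI
#' co-medication. Reports that would carry no reaction are redrawn until
#' they have at least one. A configurable fraction of cases is emitted in
#' 2-4 versions with perturbed earlier-version reactions, exercising the
#' deduplication stage; the highest version is the ground truth. The
#' returned truth table records, per preferred term, the exact realised
#' report-level contingency counts among final versions, against which the
#' pipeline's tables can be checked cell-for-cell.
#'
#' @param config A [synthetic_config()].
#' @return A `faers_simulation`: list with
#'   * `quarters` — named list of `faers_quarter` objects;
#'   * `truth` — tibble `pt`, `soc`, `lambda`, `planted`, `a`, `b`, `c`,
#'     `d`, `n_target`, `n_background`, `n_total`;
#'   * `pt_soc_map` — the toy ontology as a `pt_soc_map`;
#'   * `config` — the input configuration.
#' @seealso [write_simulation()], [deduplicate_cases()]
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, .simulate_faers_impl(config))
}

.simulate_faers_impl <- function(cfg) {
  n <- cfg$n_reports

  # ontology: planted PTs first, background PTs after, SOCs round-robin
  planted <- cfg$planted %||% setNames(numeric(0), character(0))
  pt_names <- toupper(names(planted))
  n_bg_pts <- cfg$n_pts - length(pt_names)
  if (n_bg_pts < 0) abort("more planted terms than n_pts")
  pt_names <- c(pt_names, sprintf("PT_%04d", seq_len(n_bg_pts)))
  soc_names <- sprintf("SOC_%02d", seq_len(cfg$n_socs))
  pt_soc <- pt_soc_map(tibble(pt = pt_names,
                              soc = soc_names[(seq_along(pt_names) - 1L) %% cfg$n_socs + 1L]),
                       version_label = sprintf("synthetic toy ontology (seed %d)", cfg$seed))

  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  is_target <- runif(n) < cfg$target_drug_prob

  base_p <- rep_len(cfg$background_pt_prob, cfg$n_pts)
  lambda <- rep(1, cfg$n_pts)
  lambda[seq_along(planted)] <- unname(planted)

  draw_block <- function(rows) {
    m <- matrix(FALSE, length(rows), cfg$n_pts)
    for (k in seq_len(cfg$n_pts)) {
      p <- rep(base_p[k], length(rows))
      if (lambda[k] != 1) p[is_target[rows]] <- pmin(1, lambda[k] * base_p[k])
      m[, k] <- runif(length(rows)) < p
    }
    m
  }
  membership <- draw_block(seq_len(n))
  repeat {  # every report needs >= 1 reaction
    empty <- which(rowSums(membership) == 0L)
    if (length(empty) == 0) break
    membership[empty, ] <- draw_block(empty)
  }
  idx <- which(membership, arr.ind = TRUE)
  reac_final <- tibble(report = idx[, 1L], pt = pt_names[idx[, 2L]]) |>
    arrange(.data$report, .data$pt)

  # demographics
  sex <- sample(c("F", "M"), n, TRUE, prob = c(0.48, 0.52))
  sex[runif(n) < cfg$missing_rates$sex] <- NA
  age_years <- round(pmin(pmax(rnorm(n, 61, 16), 1), 99))
  age_cod <- sample(c("YR", "DEC", "MON"), n, TRUE, prob = c(0.92, 0.05, 0.03))
  age <- dplyr::case_when(age_cod == "YR" ~ age_years,
                          age_cod == "DEC" ~ age_years / 10,
                          age_cod == "MON" ~ age_years * 12)
  miss_age <- runif(n) < cfg$missing_rates$age
  age[miss_age] <- NA; age_cod[miss_age] <- NA
  country <- sample(c("US", "CA", "GB", "DE", "JP", "FR"), n, TRUE,
                    prob = c(0.70, 0.07, 0.06, 0.06, 0.05, 0.06))
  country[runif(n) < cfg$missing_rates$country] <- NA

  quarter_idx <- sample.int(cfg$n_quarters, n, TRUE)
  fda_dt <- .quarter_date(quarter_idx)
  fda_dt[runif(n) < cfg$missing_rates$fda_dt] <- NA

  # seriousness outcomes: primary code by configured mix, occasional second
  prim <- sample(names(cfg$outcome_probs), n, TRUE, prob = cfg$outcome_probs)
  outc_final <- tibble(report = which(prim != "none"),
                       outc_cod = prim[prim != "none"])
  extra <- which(runif(n) < 0.05)
  if (length(extra) > 0) {
    outc_final <- bind_rows(outc_final,
                            tibble(report = extra,
                                   outc_cod = sample(c("HO", "OT", "CA", "RI", "LT"),
                                                     length(extra), TRUE))) |>
      distinct() |> arrange(.data$report, .data$outc_cod)
  }

  # drugs: one PS row per report, 0-2 background concomitants, ICI co-meds
  bg_vocab <- sprintf("DRUG_%03d", seq_len(cfg$n_background_drugs))
  ps_name <- ifelse(is_target, cfg$target_drug_name,
                    sample(bg_vocab, n, TRUE))
  drug_final <- tibble(report = seq_len(n), drugname = ps_name,
                       prod_ai = ifelse(is_target, cfg$target_prod_ai,
                                        NA_character_),
                       role_cod = "PS")
  n_extra <- sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2))
  for (j in 1:2) {
    has <- which(n_extra >= j)
    if (length(has) == 0) next
    drug_final <- bind_rows(drug_final,
                            tibble(report = has,
                                   drugname = sample(bg_vocab, length(has), TRUE),
                                   prod_ai = NA_character_,
                                   role_cod = sample(c("C", "SS"), length(has),
                                                     TRUE, prob = c(0.7, 0.3))))
  }
  for (ici in names(cfg$ici_probs)) {
    p_ici <- ifelse(is_target, cfg$ici_probs[[ici]], cfg$ici_background_prob)
    has <- which(runif(n) < p_ici)
    if (length(has) == 0) next
    drug_final <- bind_rows(drug_final,
                            tibble(report = has, drugname = ici,
                                   prod_ai = NA_character_,
                                   role_cod = sample(c("SS", "C"), length(has), TRUE)))
  }
  drug_final <- drug_final |>
    arrange(.data$report, .data$role_cod != "PS", .data$drugname) |>
    group_by(.data$report) |>
    mutate(drug_seq = row_number()) |>
    ungroup()

  # versioning: duplicated cases appear as versions 1..k, final version k
  n_dup <- round(cfg$duplication_rate * n)
  dup_report <- sort(sample.int(n, n_dup))
  k_final <- rep(1L, n)
  k_final[dup_report] <- sample(2:4, n_dup, TRUE)
  versions <- tibble(report = seq_len(n), version = k_final,
                     is_final = TRUE, quarter = quarter_idx)
  if (n_dup > 0) {
    earlier <- tibble(report = rep(dup_report, k_final[dup_report] - 1L)) |>
      group_by(.data$report) |>
      mutate(version = row_number()) |>
      ungroup() |>
      mutate(is_final = FALSE,
             quarter = pmax(1L, quarter_idx[.data$report] -
                              (k_final[.data$report] - .data$version)))
    versions <- bind_rows(versions, earlier) |>
      arrange(.data$report, .data$version)
  }
  versions <- versions |>
    mutate(caseid = caseid[.data$report],
           primaryid = paste0(.data$caseid, .data$version),
           fda_dt = if_else(.data$is_final, fda_dt[.data$report],
                            .quarter_date(.data$quarter)))

  # earlier versions carry a perturbed reaction list: drop the last PT when
  # the case has several, otherwise add one extra random PT
  reac_earlier <- NULL
  if (n_dup > 0) {
    base <- filter(reac_final, .data$report %in% dup_report)
    multi <- base |>
      group_by(.data$report) |>
      filter(n() > 1, .data$pt != max(.data$pt)) |>
      ungroup()
    single_rep <- setdiff(dup_report, unique(multi$report))
    singles <- bind_rows(
      filter(base, .data$report %in% single_rep),
      tibble(report = single_rep,
             pt = sample(pt_names, length(single_rep), TRUE))
    ) |> distinct()
    perturbed <- bind_rows(multi, singles)
    reac_earlier <- filter(versions, !.data$is_final) |>
      select("report", "primaryid") |>
      inner_join(perturbed, by = "report",
                 relationship = "many-to-many")
  }

  demo_of <- function(v) {
    tibble(primaryid = v$primaryid, caseid = v$caseid,
           caseversion = v$version, fda_dt = v$fda_dt,
           sex = sex[v$report], age = age[v$report],
           age_cod = age_cod[v$report],
           reporter_country = country[v$report])
  }
  attach_pid <- function(final_tbl, v) {
    inner_join(select(v, "report", "primaryid"), final_tbl,
               by = "report", relationship = "many-to-many")
  }
  demo_all <- demo_of(versions)
  drug_all <- attach_pid(drug_final, versions)
  outc_all <- attach_pid(outc_final, versions)
  reac_all <- bind_rows(
    attach_pid(reac_final, filter(versions, .data$is_final)),
    reac_earlier
  )

  quarters <- lapply(seq_len(cfg$n_quarters), function(q) {
    pids <- versions$primaryid[versions$quarter == q]
    new_faers_quarter(
      demo = filter(demo_all, .data$primaryid %in% pids),
      drug = drug_all |> filter(.data$primaryid %in% pids) |>
        select("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod"),
      reac = reac_all |> filter(.data$primaryid %in% pids) |>
        select("primaryid", "pt"),
      outc = outc_all |> filter(.data$primaryid %in% pids) |>
        select("primaryid", "outc_cod")
    )
  })
  names(quarters) <- .quarter_label(seq_len(cfg$n_quarters))

  # realised report-level contingency truth among final versions
  n_target <- sum(is_target)
  a <- colSums(membership & is_target)
  c_ <- colSums(membership & !is_target)
  truth <- tibble(pt = pt_names, soc = pt_soc$soc[match(pt_names, pt_soc$pt)],
                  lambda = lambda, planted = lambda != 1,
                  a = as.numeric(a), b = n_target - as.numeric(a),
                  c = as.numeric(c_), d = (n - n_target) - as.numeric(c_),
                  n_target = n_target, n_background = n - n_target,
                  n_total = n)

  structure(list(quarters = quarters, truth = truth, pt_soc_map = pt_soc,
                 config = cfg),
            class = "faers_simulation")
}

# quarter index -> label ("22Q1", ...) and a reproducible in-quarter date
.quarter_label <- function(q) {
  sprintf("%02dQ%d", (2022L + (q - 1L) %/% 4L) %% 100L, (q - 1L) %% 4L + 1L)
}
.quarter_date <- function(q) {
  year <- 2022L + (q - 1L) %/% 4L
  month <- 3L * ((q - 1L) %% 4L) + sample(1:3, length(q), TRUE)
  year * 10000L + month * 100L + sample(1:28, length(q), TRUE)
}

#' @export
print.faers_simulation <- function(x, ...) {
  cat(sprintf("<faers_simulation> %d reports over %d quarter(s), %d PTs (%d planted), seed %d\n",
              x$config$n_reports, length(x$quarters), nrow(x$truth),
              sum(x$truth$planted), x$config$seed))
  invisible(x)
}

#' Write a simulation to disk in the FAERS dialect
#'
#' Emits one DEMO/DRUG/REAC/OUTC file set per quarter plus the toy ontology
#' (`pt_soc_map.tsv`) and the ground-truth table (`truth.tsv`).
#'
#' @param sim A `faers_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "faers_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (lb in names(sim$quarters)) {
    write_faers_quarter(sim$quarters[[lb]], dir, lb)
  }
  readr::write_tsv(as_tibble(sim$pt_soc_map), file.path(dir, "pt_soc_map.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
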