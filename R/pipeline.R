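#' Configuration for a full analysis run
#'
#' Bundles everything a full pipeline run needs: where the quarter files
#' live, the target-drug synonym list, ICI groups for the combination
#' analysis, the PT-to-SOC map, an optional exclusion term list (the place
#' where externally curated non-drug-related terms, e.g. disease
#' progression, are removed — the package itself makes no clinical
#' judgments), thresholds and output location.
#'
#' @param input_dir Directory of FAERS-dialect quarter files.
#' @param target_drug_names Character vector of target-drug synonyms.
#' @param pt_soc_map_path Path to the PT/SOC map (see [load_pt_soc_map()]).
#' @param ici_groups Named list of ICI synonym vectors; empty list skips the
#'   combination analysis.
#' @param exclusion_terms_path Optional path to a text file of PTs (one per
#'   line, `#` comments allowed) to drop from the final PT table.
#' @param min_a Minimum case count in the signal rule (default 4).
#' @param z Normal quantile for the ROR interval (default 1.96).
#' @param comparator_mode Comparator for the combination analysis, see
#'   [combo_signals()].
#' @param counting Contingency counting unit, see
#'   [build_contingency_tables()].
#' @param output_dir Optional directory where result tables, the audit log
#'   and a manifest echoing this configuration are written.
#' @return A list of class `faers_run_config`.
#' @export
faers_run_config <- function(input_dir, target_drug_names, pt_soc_map_path,
                             ici_groups = list(),
                             exclusion_terms_path = NULL,
                             min_a = 4, z = 1.96,
                             comparator_mode = "other-target-regimens",
                             counting = "report",
                             output_dir = NULL) {
  stopifnot(length(target_drug_names) > 0, min_a >= 1, z > 0)
  structure(list(input_dir = input_dir,
                 target_drug_names = target_drug_names,
                 pt_soc_map_path = pt_soc_map_path,
                 ici_groups = ici_groups,
                 exclusion_terms_path = exclusion_terms_path,
                 min_a = min_a, z = z,
                 comparator_mode = comparator_mode,
                 counting = counting,
                 output_dir = output_dir),
            class = "faers_run_config")
}

#' Read an exclusion term list
#'
#' One preferred term per line; blank lines and `#` comments ignored; terms
#' uppercased.
#'
#' @param path Text file path.
#' @return Character vector of terms.
#' @export
read_exclusion_terms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_squish(sub("#.*$", "", lines))
  toupper(lines[lines != ""])
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full pharmacovigilance pipeline
#'
#' Orchestrates parse, deduplication, target-drug cohorting, demographics,
#' SOC-level and PT-level disproportionality screens, exclusion-list
#' filtering and the ICI combination analysis. Every stage failure aborts
#' naming the stage; per-stage row counts are collected in a run log. The
#' pipeline is deterministic: re-running on the same inputs and
#' configuration reproduces the outputs byte for byte.
#'
#' @param config A [faers_run_config()].
#' @param quarters Optional pre-read list of `faers_quarter` objects; when
#'   supplied, `config$input_dir` is not read.
#' @return A `faers_analysis`: list with `demographics`, `soc_signals`,
#'   `pt_signals` (exclusions applied), `pt_signals_unfiltered`,
#'   `combo_signals` (or `NULL`), `dedup_audit`, `run_log` and the echoed
#'   `config`.
#' @export
run_faers_analysis <- function(config, quarters = NULL) {
  stopifnot(inherits(config, "faers_run_config"))
  log <- list()
  note <- function(stage, detail, n) {
    log[[length(log) + 1]] <<- tibble(stage = stage, detail = detail,
                                      n = as.numeric(n))
  }

  if (is.null(quarters)) {
    quarters <- .stage("read", read_faers_dir(config$input_dir))
  }
  note("read", "quarters read", length(quarters))
  note("read", "demo rows read", sum(vapply(quarters, function(q) nrow(q$demo), numeric(1))))

  db <- .stage("deduplicate", deduplicate_cases(quarters))
  note("deduplicate", "case versions in", db$audit$versions_in)
  note("deduplicate", "duplicates removed", db$audit$duplicates_removed)
  note("deduplicate", "cases out", db$audit$cases_out)
  note("deduplicate", "reports without reactions", db$audit$reports_without_reactions)

  db <- .stage("cohort", cohort_primary_suspect(db, config$target_drug_names))
  note("cohort", "target reports", sum(db$reports$is_target))
  note("cohort", "background reports", sum(!db$reports$is_target))

  map <- .stage("pt_soc_map", load_pt_soc_map(config$pt_soc_map_path))
  note("pt_soc_map", "mapped preferred terms", nrow(map))

  demo <- .stage("demographics", summarize_demographics(db, which = "target"))
  note("demographics", "cohort total", attr(demo, "total"))

  soc <- .stage("soc_signals",
                detect_signals(db, level = "soc", map = map,
                               min_a = config$min_a, z = config$z,
                               counting = config$counting))
  note("soc_signals", "SOCs tested", nrow(soc))
  note("soc_signals", "SOC signals", sum(soc$signal))

  pt_unf <- .stage("pt_signals",
                   detect_signals(db, level = "pt", map = map,
                                  min_a = config$min_a, z = config$z,
                                  counting = config$counting))
  note("pt_signals", "PTs tested", nrow(pt_unf))
  note("pt_signals", "PT signals (unfiltered)", sum(pt_unf$signal))

  exclusions <- character(0)
  if (!is.null(config$exclusion_terms_path)) {
    exclusions <- .stage("exclusions",
                         read_exclusion_terms(config$exclusion_terms_path))
  }
  pt <- pt_unf[!pt_unf$term %in% exclusions, ]
  note("exclusions", "exclusion terms supplied", length(exclusions))
  note("exclusions", "PT rows excluded", nrow(pt_unf) - nrow(pt))
  note("exclusions", "PT signals (final)", sum(pt$signal))

  combo <- NULL
  if (length(config$ici_groups) > 0) {
    combo <- .stage("combo",
                    combo_signals(db, config$ici_groups,
                                  comparator_mode = config$comparator_mode,
                                  min_a = config$min_a, z = config$z))
    note("combo", "ICI-PT pairs tested", nrow(combo))
    note("combo", "combination signals", sum(combo$signal))
  }

  res <- structure(list(demographics = demo, soc_signals = soc,
                        pt_signals = pt, pt_signals_unfiltered = pt_unf,
                        combo_signals = combo, dedup_audit = db$audit,
                        run_log = bind_rows(log), config = config),
                   class = "faers_analysis")
  if (!is.null(config$output_dir)) .stage("write", .write_analysis(res))
  res
}

.write_analysis <- function(res) {
  dir <- res$config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(as_tibble(x), file.path(dir, name))
  }
  w(res$demographics, "demographics.tsv")
  w(res$soc_signals, "soc_signals.tsv")
  w(res$pt_signals, "pt_signals.tsv")
  w(res$pt_signals_unfiltered, "pt_signals_unfiltered.tsv")
  w(res$combo_signals, "combo_signals.tsv")
  w(res$dedup_audit, "dedup_audit.tsv")
  w(res$run_log, "run_log.tsv")
  cfg <- res$config
  cfg_list <- unclass(cfg)
  cfg_list$ici_groups <- lapply(cfg_list$ici_groups, as.list)
  yaml::write_yaml(list(tool = "faersignal",
                        version = as.character(utils::packageVersion("faersignal")),
                        config = cfg_list,
                        multiplicity_adjustment = "none (threshold rule only)"),
                   file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}

#' @export
print.faers_analysis <- function(x, ...) {
  cat("<faers_analysis>\n")
  cat(sprintf("  cohort: %d target reports\n", attr(x$demographics, "total")))
  cat(sprintf("  SOC level: %d tested, %d signals\n",
              nrow(x$soc_signals), sum(x$soc_signals$signal)))
  cat(sprintf("  PT level: %d tested, %d signals (after exclusions)\n",
              nrow(x$pt_signals), sum(x$pt_signals$signal)))
  if (!is.null(x$combo_signals)) {
    cat(sprintf("  combination: %d ICI-PT pairs, %d signals\n",
                nrow(x$combo_signals), sum(x$combo_signals$signal)))
  }
  invisible(x)
}
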