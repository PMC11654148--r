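#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a signal screen into a plain tibble
#'
#' @param x A `faers_signals` object from [detect_signals()].
#' @param ... Unused.
#' @return A tibble, one row per term.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a signal screen
#'
#' @param x A `faers_signals` object.
#' @param ... Unused.
#' @return A one-row tibble: level, terms tested, signals flagged, cohort
#'   and database sizes, thresholds, counting unit.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(level = attr(x, "level"),
         terms_tested = nrow(x),
         signals = sum(x$signal),
         n_drug = as.numeric(attr(x, "n_drug")),
         n_total = as.numeric(attr(x, "n_total")),
         min_a = attr(x, "min_a"),
         z = attr(x, "z"),
         counting = attr(x, "counting"),
         multiplicity_adjustment = attr(x, "multiplicity_adjustment"))
}

#' @rdname tidy.faers_signals
#' @method tidy faers_combo_signals
#' @export
tidy.faers_combo_signals <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of the combination-therapy screen
#'
#' @param x A `faers_combo_signals` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance faers_combo_signals
#' @export
glance.faers_combo_signals <- function(x, ...) {
  tibble(icis = length(unique(x$ici)),
         pairs_tested = nrow(x),
         signals = sum(x$signal),
         comparator_mode = attr(x, "comparator_mode"),
         min_a = attr(x, "min_a"),
         z = attr(x, "z"))
}

#' @rdname tidy.faers_signals
#' @method tidy faers_demographics
#' @export
tidy.faers_demographics <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a demographics table
#'
#' @param x A `faers_demographics` object.
#' @param ... Unused.
#' @return A one-row tibble with the cohort total and section count.
#' @method glance faers_demographics
#' @export
glance.faers_demographics <- function(x, ...) {
  tibble(total = attr(x, "total"),
         sections = length(unique(x$section)))
}

#' Tidy a full pipeline run
#'
#' Returns the PT-level signal table (exclusions applied); use the
#' components of the `faers_analysis` list for the other outputs.
#'
#' @param x A `faers_analysis` from [run_faers_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy faers_analysis
#' @export
tidy.faers_analysis <- function(x, ...) {
  tidy(x$pt_signals)
}

#' One-row summary of a full pipeline run
#'
#' @param x A `faers_analysis`.
#' @param ... Unused.
#' @return A one-row tibble of the headline stage counts.
#' @method glance faers_analysis
#' @export
glance.faers_analysis <- function(x, ...) {
  tibble(cases = x$dedup_audit$cases_out,
         duplicates_removed = x$dedup_audit$duplicates_removed,
         target_reports = attr(x$demographics, "total"),
         soc_signals = sum(x$soc_signals$signal),
         pt_signals = sum(x$pt_signals$signal),
         combo_signals = if (is.null(x$combo_signals)) NA_integer_
                         else sum(x$combo_signals$signal))
}

# drop the package's subclass (and its attributes) from a tibble subclass
unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!cls %in% c("faers_signals", "faers_combo_signals",
                              "faers_demographics", "pt_soc_map")]
  for (at in c("level", "min_a", "z", "counting", "n_total", "n_drug",
               "multiplicity_adjustment", "comparator_mode", "total",
               "version_label")) {
    attr(x, at) <- NULL
  }
  x
}
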