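#' FAERS quarterly-extract dialect
#'
#' The public FAERS quarterly data extract ships one ASCII table per file
#' (`DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`, `OUTCyyQq.txt`), fields
#' separated by `$`, first line a header, no quoting. `faers_dialect()`
#' captures the knobs a reader needs so that synthetic and real extracts are
#' parsed identically.
#'
#' @param delim Field delimiter (default `"$"`).
#' @param encoding Text encoding of the files.
#' @param na Strings treated as missing on input.
#' @return A list of class `faers_dialect`.
#' @export
#' @examples
#' faers_dialect()
faers_dialect <- function(delim = "$", encoding = "UTF-8", na = c("", "NA")) {
  structure(list(delim = delim, encoding = encoding, na = na),
            class = "faers_dialect")
}

# canonical column sets per table; mandatory columns cause a hard error when
# absent, the rest (the pre-2012 LAERS subset problem) are filled with NA
.faers_schema <- list(
  demo = list(cols = c("primaryid", "caseid", "caseversion", "fda_dt", "sex",
                       "age", "age_cod", "reporter_country"),
              mandatory = c("primaryid", "caseid")),
  drug = list(cols = c("primaryid", "drug_seq", "drugname", "prod_ai",
                       "role_cod"),
              mandatory = c("primaryid", "drugname", "role_cod")),
  reac = list(cols = c("primaryid", "pt"),
              mandatory = c("primaryid", "pt")),
  outc = list(cols = c("primaryid", "outc_cod"),
              mandatory = c("primaryid", "outc_cod"))
)

# legacy header names seen in older extracts
.faers_aliases <- c(gndr_cod = "sex", reporter_country_cod = "reporter_country")

.read_faers_table <- function(path, table, dialect) {
  schema <- .faers_schema[[table]]
  raw <- readr::read_delim(
    path, delim = dialect$delim, quote = "",
    col_types = readr::cols(.default = readr::col_character()),
    na = dialect$na, trim_ws = TRUE, progress = FALSE,
    locale = readr::locale(encoding = dialect$encoding)
  )
  n_malformed <- nrow(readr::problems(raw))
  names(raw) <- tolower(names(raw))
  hit <- names(raw) %in% names(.faers_aliases)
  names(raw)[hit] <- .faers_aliases[names(raw)[hit]]

  missing_mand <- setdiff(schema$mandatory, names(raw))
  if (length(missing_mand) > 0) {
    abort(sprintf("file '%s' lacks mandatory column(s): %s",
                  path, paste(missing_mand, collapse = ", ")))
  }
  for (col in setdiff(schema$cols, names(raw))) raw[[col]] <- NA_character_
  out <- raw[schema$cols]

  bad_key <- is.na(out$primaryid)
  n_malformed <- n_malformed + sum(bad_key)
  out <- out[!bad_key, , drop = FALSE]

  n_bad_num <- 0L
  coerce_num <- function(x) {
    y <- suppressWarnings(as.numeric(x))
    n_bad_num <<- n_bad_num + sum(is.na(y) & !is.na(x))
    y
  }
  if (table == "demo") {
    out$caseversion <- {
      v <- suppressWarnings(as.integer(out$caseversion))
      v
    }
    out$fda_dt <- suppressWarnings(as.integer(out$fda_dt))
    out$age <- coerce_num(out$age)
    out$sex <- toupper(out$sex)
    out$age_cod <- toupper(out$age_cod)
  }
  if (table == "drug") {
    out$drug_seq <- suppressWarnings(as.integer(out$drug_seq))
    out$role_cod <- toupper(out$role_cod)
  }
  if (table == "reac") out$pt <- toupper(out$pt)
  if (table == "outc") out$outc_cod <- toupper(out$outc_cod)

  attr(out, "n_malformed") <- n_malformed
  attr(out, "n_unparseable_numeric") <- n_bad_num
  out
}

#' Read one FAERS quarter (DEMO/DRUG/REAC/OUTC)
#'
#' Parses the four dollar-delimited tables of a quarterly extract into a
#' `faers_quarter` object. Header names are matched case-insensitively and
#' canonicalised; columns absent from older (LAERS-era) extracts are filled
#' with `NA`; rows with unparseable numeric fields are kept with the field
#' set missing; malformed rows are counted in the parse audit, never silently
#' dropped. A missing mandatory column (e.g. `caseid` in DEMO) is a hard
#' error naming the file and column.
#'
#' @param demo_path,drug_path,reac_path,outc_path Paths to the four tables.
#' @param dialect A [faers_dialect()].
#' @return A `faers_quarter`: list with tibbles `demo`, `drug`, `reac`,
#'   `outc` and a parse `audit` tibble (rows read and malformed per table).
#' @seealso [write_faers_quarter()], [read_faers_dir()], [deduplicate_cases()]
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path, outc_path,
                               dialect = faers_dialect()) {
  paths <- c(demo = demo_path, drug = drug_path, reac = reac_path,
             outc = outc_path)
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("input file does not exist: %s", p))
  }
  tabs <- lapply(names(paths), function(tb) .read_faers_table(paths[[tb]], tb, dialect))
  names(tabs) <- names(paths)
  audit <- tibble(
    table = names(paths),
    rows = unname(vapply(tabs, nrow, integer(1))),
    malformed = unname(vapply(tabs, function(x) as.integer(attr(x, "n_malformed")), integer(1))),
    unparseable_numeric = unname(vapply(tabs, function(x) as.integer(attr(x, "n_unparseable_numeric")), integer(1)))
  )
  orphans <- vapply(tabs[c("drug", "reac", "outc")], function(x) {
    sum(!x$primaryid %in% tabs$demo$primaryid)
  }, numeric(1))
  if (any(orphans > 0)) {
    warn(sprintf("quarter has rows keyed to primaryids absent from DEMO (drug=%d, reac=%d, outc=%d)",
                 orphans[1], orphans[2], orphans[3]))
  }
  new_faers_quarter(tabs$demo, tabs$drug, tabs$reac, tabs$outc,
                    dialect = dialect, audit = audit)
}

#' Construct a `faers_quarter` from in-memory tables
#'
#' Used by the synthetic generator and by tests; applies the same
#' canonicalisation as [read_faers_quarter()] (lowercase names, uppercase
#' codes and preferred terms).
#'
#' @param demo,drug,reac,outc Data frames in the canonical column layout.
#' @param dialect A [faers_dialect()].
#' @param audit Optional parse-audit tibble.
#' @return A `faers_quarter`.
#' @export
new_faers_quarter <- function(demo, drug, reac, outc,
                              dialect = faers_dialect(), audit = NULL) {
  structure(
    list(demo = as_tibble(demo), drug = as_tibble(drug),
         reac = as_tibble(reac), outc = as_tibble(outc),
         dialect = dialect,
         audit = audit %||% tibble(table = character(), rows = integer(),
                                   malformed = integer(),
                                   unparseable_numeric = integer())),
    class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat(sprintf("<faers_quarter> demo: %d rows, drug: %d, reac: %d, outc: %d\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$outc)))
  invisible(x)
}

#' Write one quarter back out in the FAERS dialect
#'
#' Emits `DEMO<label>.txt`, `DRUG<label>.txt`, `REAC<label>.txt` and
#' `OUTC<label>.txt` in the same dollar-delimited layout the reader consumes,
#' so that `read -> write -> read` is the identity on parsed content.
#'
#' @param quarter A `faers_quarter`.
#' @param dir Output directory (created if needed).
#' @param label Quarter label spliced into file names, e.g. `"23Q1"`.
#' @param dialect A [faers_dialect()].
#' @return Invisibly, the four file paths written.
#' @export
write_faers_quarter <- function(quarter, dir, label,
                                dialect = quarter$dialect %||% faers_dialect()) {
  stopifnot(inherits(quarter, "faers_quarter"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(toupper(names(.faers_schema)), label, ".txt"))
  names(paths) <- names(.faers_schema)
  for (tb in names(.faers_schema)) {
    readr::write_delim(quarter[[tb]], paths[[tb]], delim = dialect$delim,
                       na = "", quote = "none", escape = "none")
  }
  invisible(paths)
}

#' Read every quarter found in a directory
#'
#' Discovers quarter labels from `DEMO<label>.txt` files and reads each
#' DEMO/DRUG/REAC/OUTC set.
#'
#' @param dir Directory holding the quarter files.
#' @param dialect A [faers_dialect()].
#' @return A named list of `faers_quarter` objects (one per label).
#' @export
read_faers_dir <- function(dir, dialect = faers_dialect()) {
  demo_files <- list.files(dir, pattern = "^DEMO.+\\.[tT][xX][tT]$")
  if (length(demo_files) == 0) {
    abort(sprintf("no DEMO*.txt files found in '%s'", dir))
  }
  labels <- sub("^DEMO(.+)\\.[tT][xX][tT]$", "\\1", demo_files)
  out <- lapply(labels, function(lb) {
    read_faers_quarter(
      file.path(dir, paste0("DEMO", lb, ".txt")),
      file.path(dir, paste0("DRUG", lb, ".txt")),
      file.path(dir, paste0("REAC", lb, ".txt")),
      file.path(dir, paste0("OUTC", lb, ".txt")),
      dialect = dialect
    )
  })
  names(out) <- labels
  out[order(labels)]
}
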