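#' Load a preferred-term to system-organ-class mapping
#'
#' MedDRA is licensed, so no terminology ships with the package; the user
#' supplies a two-column delimited file (`pt`, `soc`) giving each preferred
#' term's primary system organ class. Duplicate rows with the same SOC are
#' collapsed; a PT mapped to two different SOCs is a hard error (the primary
#' SOC convention requires a single parent).
#'
#' @param path Path to the delimited map file (delimiter sniffed from the
#'   header among tab, comma and `$`).
#' @param version_label Free-text label stored with the map (e.g. the
#'   terminology version it was exported from).
#' @return A tibble with columns `pt` (uppercased) and `soc`, of class
#'   `pt_soc_map`, with attribute `version_label`.
#' @export
load_pt_soc_map <- function(path, version_label = "user-supplied") {
  if (!file.exists(path)) abort(sprintf("pt/soc map file does not exist: %s", path))
  header <- readLines(path, n = 1)
  if (length(header) == 0) abort(sprintf("pt/soc map file '%s' is empty", path))
  delim <- c("\t", ",", "$")[which(c(grepl("\t", header), grepl(",", header),
                                     grepl("$", header, fixed = TRUE)))[1]]
  if (is.na(delim)) abort(sprintf("cannot find a delimiter in the header of '%s'", path))
  raw <- readr::read_delim(path, delim = delim, quote = "",
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("pt", "soc") %in% names(raw))) {
    abort(sprintf("pt/soc map '%s' must have columns 'pt' and 'soc'", path))
  }
  pt_soc_map(raw[c("pt", "soc")], version_label = version_label)
}

#' Construct a PT to SOC map from a data frame
#'
#' @param x Data frame with columns `pt`, `soc`.
#' @param version_label Free-text label.
#' @return A `pt_soc_map` tibble.
#' @export
pt_soc_map <- function(x, version_label = "user-supplied") {
  x <- as_tibble(x)[c("pt", "soc")]
  if (nrow(x) == 0) abort("pt/soc map has no entries")
  x$pt <- toupper(stringr::str_squish(x$pt))
  x$soc <- stringr::str_squish(x$soc)
  x <- distinct(x)
  dup <- x$pt[duplicated(x$pt)]
  if (length(dup) > 0) {
    abort(sprintf("preferred term(s) mapped to more than one SOC: %s",
                  paste(sort(unique(dup)), collapse = ", ")))
  }
  structure(x, class = c("pt_soc_map", class(x)),
            version_label = version_label)
}

#' Roll a set of preferred terms up to system organ classes
#'
#' Returns the distinct SOCs covering the given PTs. Lookup is
#' case-insensitive; a PT absent from the map is routed to the sentinel SOC
#' `"UNMAPPED"` rather than dropped, so coverage gaps stay visible. Because a
#' report contributes once per SOC regardless of how many of its PTs fall in
#' it, `length(rollup_to_soc(S)) <= length(S)` always.
#'
#' @param pts Character vector of preferred terms (a set; duplicates ignored).
#' @param map A `pt_soc_map`.
#' @return Character vector of distinct SOC names (empty for empty input).
#' @export
#' @examples
#' m <- pt_soc_map(data.frame(
#'   pt = c("PYREXIA", "CHILLS"),
#'   soc = "General disorders and administration site conditions"))
#' rollup_to_soc(c("Pyrexia", "CHILLS"), m)
rollup_to_soc <- function(pts, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  if (length(pts) == 0) return(character(0))
  key <- toupper(stringr::str_squish(pts))
  soc <- map$soc[match(key, map$pt)]
  soc[is.na(soc)] <- "UNMAPPED"
  unique(soc)
}

# vectorised variant for the pipeline: long (caseid, pt) -> (caseid, soc),
# distinct per case; returns the unmapped-PT audit as an attribute
.rollup_long <- function(reactions, map) {
  soc <- map$soc[match(reactions$pt, map$pt)]
  n_unmapped <- sum(is.na(soc))
  soc[is.na(soc)] <- "UNMAPPED"
  out <- distinct(tibble(caseid = reactions$caseid, term = soc))
  attr(out, "n_unmapped_pt_rows") <- n_unmapped
  out
}
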