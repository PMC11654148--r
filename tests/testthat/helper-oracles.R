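# Independent single-value evaluators of the printed disproportionality
# formulas, kept deliberately scalar and transcription-like so they share no
# code path with the vectorised implementations they check.

oracle_ror <- function(a, b, c, d, z = 1.96) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, ror025 = ror * exp(-z * se), ror975 = ror * exp(z * se))
}

oracle_ic <- function(nobs, ndrug, neff, ntot) {
  nexp <- (ndrug * neff) / ntot
  ic <- log2((nobs + 0.5) / (nexp + 0.5))
  c(ic = ic,
    ic025 = ic - 3.3 * (nobs + 0.5)^(-1 / 2) - 2 * (nobs + 0.5)^(-3 / 2),
    ic975 = ic + 2.4 * (nobs + 0.5)^(-1 / 2) - 0.5 * (nobs + 0.5)^(-3 / 2))
}

# Brute-force deduplication: plain loop over caseids, argmax of caseversion
# with the latest-fda_dt / largest-primaryid tie-break.
oracle_dedup <- function(demo) {
  demo$caseversion[is.na(demo$caseversion)] <- 1L
  keep <- character(0)
  for (cid in unique(demo$caseid)) {
    rows <- demo[demo$caseid == cid, ]
    rows <- rows[rows$caseversion == max(rows$caseversion), ]
    if (nrow(rows) > 1) {
      dt <- ifelse(is.na(rows$fda_dt), -1, rows$fda_dt)
      rows <- rows[dt == max(dt), ]
    }
    if (nrow(rows) > 1) rows <- rows[rows$primaryid == max(rows$primaryid), ]
    keep <- c(keep, rows$primaryid[1])
  }
  sort(keep)
}

# Naive per-report membership count of the drug-event 2x2 tables.
oracle_tables <- function(case_pts, is_target, terms) {
  n_t <- sum(is_target)
  n_b <- sum(!is_target)
  out <- lapply(terms, function(tm) {
    has <- vapply(case_pts, function(p) tm %in% p, logical(1))
    a <- sum(has & is_target)
    c_ <- sum(has & !is_target)
    data.frame(term = tm, a = a, b = n_t - a, c = c_, d = n_b - c_)
  })
  do.call(rbind, out)
}

# A small hand-buildable database: one quarter from compact per-report specs.
# reports: data.frame with caseid, drugs (list of name=role), pts (chr vec),
# plus optional demo fields.
toy_quarter <- function(caseid, drugname, role, pts,
                        sex = NULL, age = NULL, age_cod = NULL,
                        country = NULL, fda_dt = NULL, outc = NULL,
                        caseversion = NULL, primaryid = NULL) {
  n <- length(caseid)
  primaryid <- primaryid %||% paste0(caseid, "1")
  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid,
    caseversion = caseversion %||% rep(1L, n),
    fda_dt = fda_dt %||% rep(20230115L, n),
    sex = sex %||% rep("F", n),
    age = age %||% rep(60, n),
    age_cod = age_cod %||% rep("YR", n),
    reporter_country = country %||% rep("US", n))
  drug <- tibble::tibble(primaryid = rep(primaryid, lengths(drugname)),
                         drug_seq = unlist(lapply(lengths(drugname), seq_len)),
                         drugname = unlist(drugname),
                         prod_ai = NA_character_,
                         role_cod = unlist(role))
  reac <- tibble::tibble(primaryid = rep(primaryid, lengths(pts)),
                         pt = unlist(pts))
  outc_tbl <- if (is.null(outc)) {
    tibble::tibble(primaryid = character(), outc_cod = character())
  } else {
    tibble::tibble(primaryid = rep(primaryid, lengths(outc)),
                   outc_cod = unlist(outc))
  }
  new_faers_quarter(demo, drug, reac, outc_tbl)
}

`%||%` <- rlang::`%||%`
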