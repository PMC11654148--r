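# Build a deduplicated database whose marginal counts match a published
# melanoma-cohort demographic table (total 1138; sex 373 F / 401 M / 364
# unknown; country 894 USA / 243 elsewhere / 1 unknown; ages 3 / 54 / 167 /
# 391 per band with 523 unknown; outcomes 116 DE / 23 LT / 234 HO / 11 DS /
# 437 OT / 317 none). Sections are assigned independently, which is all the
# per-section tabulation sees.
table1_cohort <- function() {
  n <- 1138
  rep_na <- function(counts, values) {
    stopifnot(sum(counts) <= n)
    c(rep(values, counts), rep(NA, n - sum(counts)))
  }
  caseid <- sprintf("C%04d", seq_len(n))
  demo <- tibble::tibble(
    primaryid = paste0(caseid, "1"),
    caseid = caseid,
    caseversion = 1L,
    fda_dt = 20200615L,
    sex = rep_na(c(373, 401), c("F", "M")),
    age = rep_na(c(3, 54, 167, 391), c(10, 30, 50, 70)),
    age_cod = "YR",
    reporter_country = rep_na(c(894, 243), c("US", "GB")))
  outc_counts <- c(DE = 116, LT = 23, HO = 234, DS = 11, OT = 437)
  outc <- tibble::tibble(
    primaryid = paste0(caseid[seq_len(sum(outc_counts))], "1"),
    outc_cod = rep(names(outc_counts), outc_counts))
  q <- new_faers_quarter(
    demo = demo,
    drug = tibble::tibble(primaryid = demo$primaryid, drug_seq = 1L,
                          drugname = "TGT", prod_ai = NA_character_,
                          role_cod = "PS"),
    reac = tibble::tibble(primaryid = demo$primaryid, pt = "PYREXIA"),
    outc = outc)
  deduplicate_cases(q)
}

table1_pct <- function(summary, section, label) {
  summary$pct[summary$section == section & summary$label == label]
}
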