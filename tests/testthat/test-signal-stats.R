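test_that("the worked 2x2 example reproduces the closed-form ROR and CI", {
  r <- ror_with_ci(10, 20, 30, 240)
  expect_equal(r$ror, 4)
  # frozen from the scalar oracle: SE = sqrt(0.1875)
  expect_equal(r$ror025, 4 * exp(-1.96 * sqrt(0.1875)))
  expect_equal(r$ror975, 4 * exp(1.96 * sqrt(0.1875)))
  expect_equal(round(r$ror025, 3), 1.712)
  expect_equal(round(r$ror975, 3), 9.346)
  expect_false(r$zero_cell_corrected)
})

test_that("the worked IC example reproduces log2(7) with its credibility bounds", {
  ic <- ic_with_bounds(10, 100, 1000, 100000)  # N_expected = 1
  expect_equal(ic$ic, log2(7))
  o <- oracle_ic(10, 100, 1000, 100000)
  expect_equal(ic$ic025, o[["ic025"]])
  expect_equal(ic$ic975, o[["ic975"]])
  expect_equal(round(unlist(ic), 3),
               c(ic = 2.807, ic025 = 1.730, ic975 = 3.533))
})

test_that("ROR and IC match the independent oracle on 1000 random tables", {
  set.seed(202)
  cells <- matrix(sample(1:500, 4000, replace = TRUE), ncol = 4)
  got_ror <- ror_with_ci(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  n_tot <- rowSums(cells)
  got_ic <- ic_with_bounds(cells[, 1], cells[, 1] + cells[, 2],
                           cells[, 1] + cells[, 3], n_tot)
  for (i in seq_len(nrow(cells))) {
    o_r <- oracle_ror(cells[i, 1], cells[i, 2], cells[i, 3], cells[i, 4])
    o_i <- oracle_ic(cells[i, 1], cells[i, 1] + cells[i, 2],
                     cells[i, 1] + cells[i, 3], n_tot[i])
    expect_equal(got_ror$ror[i], o_r[["ror"]], tolerance = 1e-12)
    expect_equal(got_ror$ror025[i], o_r[["ror025"]], tolerance = 1e-12)
    expect_equal(got_ror$ror975[i], o_r[["ror975"]], tolerance = 1e-12)
    expect_equal(got_ic$ic[i], o_i[["ic"]], tolerance = 1e-12)
    expect_equal(got_ic$ic025[i], o_i[["ic025"]], tolerance = 1e-12)
    expect_equal(got_ic$ic975[i], o_i[["ic975"]], tolerance = 1e-12)
  }
})

test_that("ROR formula properties: null value, scale invariance, CI ordering", {
  expect_equal(ror_with_ci(5, 10, 10, 20)$ror, 1)  # ad = bc
  r1 <- ror_with_ci(10, 20, 30, 240)
  r10 <- ror_with_ci(100, 200, 300, 2400)
  expect_equal(r10$ror, r1$ror)
  expect_lt(r1$ror025, r10$ror025)  # tenfold counts narrow the interval
  expect_gt(r1$ror975, r10$ror975)
  expect_true(r10$ror025 <= r10$ror && r10$ror <= r10$ror975)
})

test_that("zero cells trigger the continuity correction and are flagged", {
  r <- ror_with_ci(5, 0, 3, 90)
  expect_true(r$zero_cell_corrected)
  expect_equal(r$ror, (5.5 * 90.5) / (0.5 * 3.5))
  expect_error(ror_with_ci(0, 0, 0, 0), "undefined")
  expect_error(ror_with_ci(-1, 2, 3, 4), "non-negative")
})

test_that("IC degenerate inputs follow the +0.5 shrinkage exactly", {
  # N_observed equal to N_expected gives IC 0 for any magnitude
  expect_equal(ic_with_bounds(10, 100, 100, 1000)$ic, 0)
  expect_equal(ic_with_bounds(250, 500, 1000, 2000)$ic, 0)
  # both observed and expected zero: IC 0 with wide asymmetric bounds
  ic0 <- ic_with_bounds(0, 0, 0, 100)
  expect_equal(ic0$ic, 0)
  expect_equal(ic0$ic025, -3.3 * sqrt(2) - 2 * 2^1.5)
  expect_equal(ic0$ic975, 2.4 * sqrt(2) - 0.5 * 2^1.5)
  expect_lt(ic0$ic025, ic0$ic)
  expect_gt(ic0$ic975, ic0$ic)
  expect_error(ic_with_bounds(1, 2, 3, 0), "positive")
})

test_that("the signal rule is the strict three-way conjunction", {
  expect_false(flag_signal(3, 5, 2))            # strong but n < 4
  expect_true(flag_signal(4, 1.01, 0.01))       # just above every threshold
  expect_false(flag_signal(100, 0.99, 3))       # ROR bound fails
  expect_false(flag_signal(100, 5, 0))          # IC bound fails (not > 0)
  expect_false(flag_signal(100, 1, 1))          # ROR bound exactly 1 fails
  # moving n alone across the threshold flips the decision
  expect_false(flag_signal(3, 1.5, 0.5))
  expect_true(flag_signal(4, 1.5, 0.5))
})

test_that("degenerate one-sided tables count correctly", {
  q <- toy_quarter(
    caseid = as.character(1:100),
    drugname = as.list(c(rep("TGT", 10), rep("OTH", 90))),
    role = as.list(rep("PS", 100)),
    pts = c(rep(list("X"), 10), rep(list("Y"), 90)))
  db <- cohort_primary_suspect(deduplicate_cases(q), "TGT")
  tab <- build_contingency_tables(db, "pt")
  x <- tab[tab$term == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(10, 0, 0, 90))
})

test_that("a PT listed twice on a report counts once", {
  q <- toy_quarter(caseid = c("1", "2"),
                   drugname = list("TGT", "OTH"),
                   role = list("PS", "PS"),
                   pts = list(c("X", "X"), "Y"))
  db <- cohort_primary_suspect(deduplicate_cases(q), "TGT")
  tab <- build_contingency_tables(db, "pt")
  expect_equal(tab$a[tab$term == "X"], 1)
})

test_that("contingency tables equal a brute-force membership count", {
  sim <- simulate_faers(synthetic_config(n_reports = 3000,
                                         target_drug_prob = 0.05,
                                         duplication_rate = 0, seed = 77))
  db <- cohort_primary_suspect(deduplicate_cases(sim$quarters),
                               sim$config$target_drug_name)
  tab <- build_contingency_tables(db, "pt")
  case_pts <- split(db$reactions$pt, db$reactions$caseid)[db$reports$caseid]
  oracle <- oracle_tables(case_pts, db$reports$is_target, tab$term)
  m <- merge(tab, oracle, by = "term")
  expect_true(all(m$a.x == m$a.y & m$b.x == m$b.y &
                  m$c.x == m$c.y & m$d.x == m$d.y))
  # report-level counting: the four cells tile the database
  expect_true(all(tab$a + tab$b + tab$c + tab$d == tab$n_total))
  expect_true(all(tab$a >= 1))
})

test_that("ROR and IC increase together in a at fixed margins", {
  n_drug <- 40; n_effect <- 30; n_total <- 1000
  a <- 1:20
  r <- ror_with_ci(a, n_drug - a, n_effect - a,
                   n_total - n_drug - n_effect + a)
  ic <- ic_with_bounds(a, n_drug, n_effect, n_total)
  expect_true(all(diff(r$ror) > 0))
  expect_true(all(diff(ic$ic) > 0))
})

test_that("scaled-up tables approach the asymptotic IC with vanishing width", {
  a <- 10; b <- 20; c <- 30; d <- 240
  lim <- log2(a * (a + b + c + d) / ((a + b) * (a + c)))
  for (k in c(1, 10, 100, 1000)) {
    ic <- ic_with_bounds(k * a, k * (a + b), k * (a + c), k * (a + b + c + d))
    if (k == 1000) {
      expect_equal(ic$ic, lim, tolerance = 1e-3)
      expect_lt(ic$ic975 - ic$ic025, 0.06)
    }
  }
  widths <- vapply(c(1, 10, 100), function(k) {
    ic <- ic_with_bounds(k * a, k * (a + b), k * (a + c), k * (a + b + c + d))
    ic$ic975 - ic$ic025
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the screen orders by SOC then descending case count", {
  sim <- simulate_faers(synthetic_config(n_reports = 4000,
                                         target_drug_prob = 0.05, seed = 5))
  db <- cohort_primary_suspect(deduplicate_cases(sim$quarters),
                               sim$config$target_drug_name)
  s <- detect_signals(db, "pt", map = sim$pt_soc_map)
  expect_false(is.unsorted(s$soc))
  for (soc in unique(s$soc)) {
    expect_false(is.unsorted(-s$n[s$soc == soc]))
  }
})
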