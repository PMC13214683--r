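# 2x2 statistics, log-scale p-values, log-space BH and the signal rule.

random_tables <- function(n, min = 1, max = 500, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    a = sample(min:max, n, replace = TRUE),
    b = sample(min:max, n, replace = TRUE),
    c = sample(min:max, n, replace = TRUE),
    d = sample(min:max, n, replace = TRUE)
  )
}

test_that("build_contingency enumerates the four cells and matches set algebra", {
  tab <- build_contingency(eligible_ids = c("1", "2"), event_ids = c("2", "3"),
                           all_ids = as.character(1:4))
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  expect_error(build_contingency("a", "a", character(0)), "empty report universe")
  expect_error(build_contingency("x", character(0), c("a", "b")), "subsets")

  # brute-force oracle on random universes
  set.seed(11)
  for (i in 1:25) {
    ids <- as.character(sample(1:100, sample(5:50, 1)))
    elig <- sample(ids, sample(0:length(ids), 1))
    ev <- sample(ids, sample(0:length(ids), 1))
    tab <- build_contingency(elig, ev, ids)
    a <- sum(ids %in% elig & ids %in% ev)
    b <- sum(ids %in% elig & !ids %in% ev)
    c <- sum(!ids %in% elig & ids %in% ev)
    d <- sum(!ids %in% elig & !ids %in% ev)
    expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(a, b, c, d))
    expect_equal(tab$n, length(ids))
  }
})

test_that("PRR reproduces published values and handles edge tables", {
  expect_equal(round(prr(contingency_table(510, 1808, 31495, 921364)), 2), 6.66)
  expect_equal(round(prr(contingency_table(76, 476, 5641, 948984)), 2), 23.30)
  # exactly proportional table
  expect_equal(prr(contingency_table(10, 90, 100, 900)), 1.0)
  # no background cases: not evaluable, never infinite
  expect_true(is.na(prr(contingency_table(5, 10, 0, 100))))
})

test_that("Yates chi-squared matches published values, truncates, and is symmetric", {
  expect_equal(round(yates_chi2(contingency_table(7, 32, 34376, 920762)), 2), 19.19)
  expect_equal(round(yates_chi2(contingency_table(510, 1808, 31495, 921364)), 2),
               2490.21)
  # perfectly proportional: O = E in every cell
  expect_equal(yates_chi2(contingency_table(10, 90, 100, 900)), 0)
  # |O - E| below the correction: contribution truncated to zero, not negative
  expect_equal(yates_chi2(contingency_table(10, 90, 11, 97)), 0)
  expect_error(yates_chi2(contingency_table(0, 0, 3, 4)), "zero marginal")

  # invariance under simultaneous row and column swap
  tabs <- random_tables(50, seed = 7)
  for (i in seq_len(nrow(tabs))) {
    t1 <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    t2 <- contingency_table(tabs$d[i], tabs$c[i], tabs$b[i], tabs$a[i])
    expect_equal(yates_chi2(t1), yates_chi2(t2))
  }
})

test_that("closed-form Yates statistic agrees with the four-cell summation oracle", {
  four_cell <- function(a, b, c, d) {
    n <- a + b + c + d
    obs <- c(a, b, c, d)
    exp <- c((a + b) * (a + c), (a + b) * (b + d),
             (c + d) * (a + c), (c + d) * (b + d)) / n
    sum(pmax(abs(obs - exp) - 0.5, 0)^2 / exp)
  }
  tabs <- random_tables(200, seed = 23)
  for (i in seq_len(nrow(tabs))) {
    got <- yates_chi2(contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]))
    expect_equal(got, four_cell(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]),
                 tolerance = 1e-9)
  }
})

test_that("ROR reproduces published values with an ordered Woolf interval", {
  r <- ror_ci(contingency_table(510, 1808, 31495, 921364))
  expect_equal(round(r$ror, 2), 8.25)
  expect_true(r$lower < r$ror && r$ror < r$upper)
  expect_equal(round(ror_ci(contingency_table(305, 533, 98880, 855459))$ror, 2), 4.95)
  # ad = bc: odds ratio 1
  expect_equal(ror_ci(contingency_table(20, 50, 20, 50))$ror, 1.0)
  # zero cell: point and interval not evaluable (no continuity correction)
  r0 <- ror_ci(contingency_table(5, 0, 10, 100))
  expect_true(is.na(r0$ror) && is.na(r0$lower))
})

test_that("ROR/PRR identity holds and ROR exceeds PRR for disproportionate pairs", {
  tabs <- random_tables(100, seed = 31)
  for (i in seq_len(nrow(tabs))) {
    tab <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    p <- prr(tab); r <- ror_ci(tab)$ror
    expect_equal(r, p * ((tabs$a[i] + tabs$b[i]) / tabs$b[i]) *
                   (tabs$d[i] / (tabs$c[i] + tabs$d[i])), tolerance = 1e-12)
    if (tabs$a[i] / (tabs$a[i] + tabs$b[i]) > tabs$c[i] / (tabs$c[i] + tabs$d[i])) {
      expect_gt(r, p)
    }
  }
})

test_that("information component shrinks to zero at a = 0 and bounds order correctly", {
  # a = 0 with vanishing expected count: log2(0.5/0.5) = 0
  ic0 <- ic_ic025(contingency_table(0, 10, 0, 1000))
  expect_equal(ic0$ic, 0)
  v <- ic_ic025(contingency_table(510, 1808, 31495, 921364))
  expect_equal(round(v$ic, 2), 2.71)
  expect_equal(round(v$ic025, 2), 2.58)
  # lower credibility bound sits below the point estimate whenever a > 0
  tabs <- random_tables(200, seed = 41)
  for (i in seq_len(nrow(tabs))) {
    v <- ic_ic025(contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]))
    expect_lt(v$ic025, v$ic)
  }
})

test_that("log-scale chi-squared p-values match references and never underflow", {
  expect_equal(log_p_from_chi2(3.841459), log(0.05), tolerance = 1e-5)
  expect_equal(log_p_from_chi2(0), 0)
  # large-statistic asymptotics: ln p ~ -x/2 - 0.5 log(pi x / 2)
  x <- 5000
  expect_true(is.finite(log_p_from_chi2(x)))
  expect_equal(log_p_from_chi2(x), -x / 2 - 0.5 * log(pi * x / 2),
               tolerance = 1e-3)
  expect_error(log_p_from_chi2(-1), "non-negative")
})

test_that("log-space BH matches hand and reference adjustments and is monotone", {
  expect_equal(bh_adjust_log(log(0.03)), log(0.03)) # m = 1: adjusted = raw
  expect_equal(bh_adjust_log(numeric(0)), numeric(0))
  expect_equal(exp(bh_adjust_log(log(c(0.01, 0.02, 0.03, 0.04)))),
               rep(0.04, 4), tolerance = 1e-12)

  set.seed(51)
  p <- runif(100)^3
  got <- exp(bh_adjust_log(log(p)))
  expect_equal(got, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  # adjusted >= raw, monotone along the sorted order, capped at 1
  lp <- log(p); alp <- bh_adjust_log(lp)
  expect_true(all(alp >= lp))
  expect_true(all(alp <= 0))
  expect_true(!is.unsorted(alp[order(lp)]))
  expect_error(bh_adjust_log(c(-1, 0.1)), "<= 0")
})

test_that("the four-condition rule flags only fully qualifying pairs", {
  expect_true(detect_signal(prr = 6.66, chi2 = 2490.21, a = 510,
                            log_fdr_p = -1244.9))
  expect_false(detect_signal(prr = 5, chi2 = 10, a = 2, log_fdr_p = -20))
  expect_false(detect_signal(prr = 1.99, chi2 = 10, a = 10, log_fdr_p = -20))
  expect_false(detect_signal(prr = 5, chi2 = 3.99, a = 10, log_fdr_p = -20))
  expect_false(detect_signal(prr = 5, chi2 = 10, a = 10, log_fdr_p = log(0.05)))
  expect_true(detect_signal(prr = 2, chi2 = 4, a = 3, log_fdr_p = log(0.049)))
  expect_false(detect_signal(prr = NA, chi2 = 10, a = 10, log_fdr_p = -20))

  # scaling all cells up never demotes a signal
  base <- c(a = 9, b = 91, c = 30, d = 970)
  for (k in c(1, 2, 5, 10)) {
    tab <- contingency_table(base[1] * k, base[2] * k, base[3] * k, base[4] * k)
    chi <- yates_chi2(tab)
    lfdr <- bh_adjust_log(log_p_from_chi2(chi))
    expect_true(detect_signal(prr(tab), chi, tab$a, lfdr))
  }
})

test_that("run_screen scores pairs, applies per-drug BH and sorts by chi-squared", {
  rs <- fixture_report_set()
  m <- build_event_matrix(rs, level = "PT")
  scr <- run_screen(rs, m, drugs = "vancomycin",
                    routes = c("intravenous", "oral"))
  expect_s3_class(scr, "signal_screen")
  # C1 (iv suspected) and C4 (oral suspected) are eligible; C2 concomitant is not
  expect_true(all(scr$drug_total == 2))
  expect_true(!is.unsorted(rev(scr$chi2)))
  # every exported statistic is recomputable from the counts in its row
  for (i in seq_len(nrow(scr))) {
    tab <- contingency_table(scr$a[i], scr$b[i], scr$c[i], scr$d[i])
    expect_equal(scr$prr[i], prr(tab))
    expect_equal(scr$reporting_ratio[i], scr$a[i] / (scr$a[i] + scr$b[i]))
  }
})

test_that("a degenerate single-drug single-term screen has a BH family of one", {
  demo <- tibble::tibble(case_id = paste0("C", 1:6), version = "1",
                         sex = "male", age_band = ">=60", weight_band = "40-69")
  drug <- tibble::tibble(case_id = paste0("C", 1:3), version = "1",
                         drug_name = "vancomycin", role = "suspected",
                         route = "intravenous", start_date = "", end_date = "")
  reac <- tibble::tibble(case_id = c("C1", "C2", "C4"), version = "1",
                         pt_code = "p1", onset_date = "")
  rs <- as_report_set(demo, drug, reac, fixture_hist()[0, ])
  m <- build_event_matrix(rs, level = "PT")
  scr <- run_screen(rs, m, drugs = "vancomycin", routes = "intravenous")
  expect_equal(nrow(scr), 1)
  expect_equal(scr$log_fdr_p, scr$log_p) # family of size one: adjusted = raw
})

test_that("volcano coordinates transform PRR and chi-squared with size = reporting ratio", {
  rs <- fixture_report_set()
  m <- build_event_matrix(rs, level = "PT")
  scr <- run_screen(rs, m, drugs = "vancomycin", routes = c("intravenous", "oral"))
  vd <- volcano_data(scr)
  expect_equal(vd$x, log2(scr$prr[!is.na(scr$prr)]))
  expect_equal(vd$y, scr$chi2[!is.na(scr$prr)])
  # size ordering matches the reporting-ratio ordering
  expect_equal(order(vd$size), order(scr$reporting_ratio[!is.na(scr$prr)]))
  p <- volcano_plot(scr)
  expect_s3_class(p, "ggplot")
})
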