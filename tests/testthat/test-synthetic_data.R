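# Ground-truth synthetic SRS generator.

small_config <- function(seed = 1, ...) {
  synthetic_config(
    n_reports = 5000,
    drugs = tibble::tibble(name = c("vancomycin", "linezolid"), p = c(0.05, 0.03)),
    terms = tibble::tibble(pt_code = c("p1", "p2", "p3"), baseline = 0.02),
    signals = tibble::tibble(drug = "vancomycin", term = "p1", lambda = 8),
    seed = seed,
    ...
  )
}

test_that("configs are validated: seed mandatory, probabilities and rates bounded", {
  expect_error(synthetic_config(10, tibble::tibble(name = "a", p = 0.1),
                                tibble::tibble(pt_code = "p", baseline = 0.1)),
               "seed is mandatory")
  expect_error(
    synthetic_config(10, tibble::tibble(name = "a", p = 0.1),
                     tibble::tibble(pt_code = "p1", baseline = 1.5), seed = 1),
    "\\[0, 1\\]"
  )
  expect_error(
    synthetic_config(10, tibble::tibble(name = "a", p = 0.1),
                     tibble::tibble(pt_code = "p", baseline = 0.3),
                     signals = tibble::tibble(drug = "a", term = "p", lambda = 5),
                     seed = 1),
    "infeasible event probability for pair \\(a, p\\)"
  )
  expect_error(
    synthetic_config(10, tibble::tibble(name = "a", p = 0.1),
                     tibble::tibble(pt_code = "p", baseline = 0.1),
                     signals = tibble::tibble(drug = "a", term = "p", lambda = -1),
                     seed = 1),
    "lambda"
  )
})

test_that("n = 0 yields four empty tables with headers", {
  cfg <- synthetic_config(0, tibble::tibble(name = "a", p = 0.1),
                          tibble::tibble(pt_code = "p", baseline = 0.1), seed = 3)
  dir <- withr::local_tempdir()
  out <- generate_srs(cfg, dir = dir)
  for (tb in c("demo", "drug", "reac", "hist")) {
    expect_equal(nrow(out[[tb]]), 0)
    lines <- readLines(file.path(dir, paste0(tb, ".csv")))
    expect_length(lines, 1) # header only
  }
})

test_that("generation is bitwise reproducible under the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_srs(small_config(seed = 17), dir = d1)
  generate_srs(small_config(seed = 17), dir = d2)
  for (f in c("demo.csv", "drug.csv", "reac.csv", "hist.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  generate_srs(small_config(seed = 18), dir = d3)
  expect_false(identical(readLines(file.path(d1, "drug.csv")),
                         readLines(file.path(d3, "drug.csv"))))
})

test_that("injected duplicate versions are recovered exactly by deduplication", {
  cfg <- small_config(seed = 5, duplicate_fraction = 0.1)
  tabs <- generate_srs(cfg)
  expect_equal(tabs$ground_truth$n_duplicates, 500)
  rs <- as_report_set(tabs$demo, tabs$drug, tabs$reac, tabs$hist)
  expect_equal(n_reports(rs), 5500)
  expect_message(rs2 <- deduplicate_reports(rs), "removed 500")
  expect_equal(n_reports(rs2), 5000)
})

test_that("expected PRR has the closed-form limits and enumeration value", {
  cfg <- small_config()
  expect_equal(expected_prr(cfg, "linezolid", "p2"), 1)       # no signal: null
  expect_equal(expected_prr(cfg, "vancomycin", "p1"), 8)      # single-drug signal
  cfg0 <- synthetic_config(
    1000, tibble::tibble(name = "a", p = 0.1),
    tibble::tibble(pt_code = "p", baseline = 0.05),
    signals = tibble::tibble(drug = "a", term = "p", lambda = 0), seed = 1)
  expect_equal(expected_prr(cfg0, "a", "p"), 0)
  expect_error(expected_prr(cfg, "nope", "p1"), "unknown drug")

  # two drugs sharing a signal on one term: background inflated by the other
  # drug's exposures -- enumeration oracle over the joint exposure space
  cfg2 <- synthetic_config(
    1000, tibble::tibble(name = c("a", "b"), p = c(0.2, 0.4)),
    tibble::tibble(pt_code = "p", baseline = 0.01),
    signals = tibble::tibble(drug = c("a", "b"), term = "p", lambda = c(8, 3)),
    seed = 1)
  pa <- 0.2 * 0.7; pb <- 0.4 * 0.7 # exposure = marginal * suspected share
  p1 <- 0.01 * 8 * (pb * 3 + (1 - pb))
  p0 <- 0.01 * (pb * 3 + (1 - pb))
  expect_equal(expected_prr(cfg2, "a", "p"), p1 / p0)
  # capping: baseline * lambda_a * lambda_b would exceed 1
  cfg3 <- synthetic_config(
    1000, tibble::tibble(name = c("a", "b"), p = c(0.2, 0.4)),
    tibble::tibble(pt_code = "p", baseline = 0.05),
    signals = tibble::tibble(drug = c("a", "b"), term = "p", lambda = c(15, 10)),
    seed = 1)
  p1c <- pa * (pb * min(1, 0.05 * 150) + (1 - pb) * 0.75)
  p1c <- p1c / pa
  p0c <- pb * min(1, 0.05 * 10) + (1 - pb) * 0.05
  expect_equal(expected_prr(cfg3, "a", "p"), p1c / p0c)
})

test_that("a null generator produces empirical PRRs near 1 for every pair", {
  cfg <- synthetic_config(
    n_reports = 20000,
    drugs = tibble::tibble(name = c("vancomycin", "linezolid"), p = c(0.05, 0.04)),
    terms = tibble::tibble(pt_code = paste0("p", 1:4), baseline = 0.02),
    date_missing_fraction = 0, duplicate_fraction = 0,
    seed = 202
  )
  tabs <- generate_srs(cfg)
  rs <- as_report_set(tabs$demo, tabs$drug, tabs$reac, tabs$hist)
  m <- build_event_matrix(rs, level = "PT")
  scr <- run_screen(rs, m, drugs = c("vancomycin", "linezolid"),
                    routes = c("intravenous", "oral", "other"))
  for (i in seq_len(nrow(scr))) {
    se <- log_prr_se(scr$a[i], scr$b[i], scr$c[i], scr$d[i])
    expect_lt(abs(log(scr$prr[i])), 3 * se)
  }
})

test_that("a planted multiplier is recovered within 3 sigma of its expected PRR", {
  cfg <- synthetic_config(
    n_reports = 50000,
    drugs = tibble::tibble(name = "vancomycin", p = 0.03),
    terms = tibble::tibble(pt_code = c("p1", "p2"), baseline = 0.01),
    signals = tibble::tibble(drug = "vancomycin", term = "p1", lambda = 8),
    date_missing_fraction = 0, duplicate_fraction = 0,
    seed = 303
  )
  tabs <- generate_srs(cfg)
  rs <- as_report_set(tabs$demo, tabs$drug, tabs$reac, tabs$hist)
  m <- build_event_matrix(rs, level = "PT")
  scr <- run_screen(rs, m, drugs = "vancomycin",
                    routes = c("intravenous", "oral", "other"))
  row <- scr[scr$term_id == "p1", ]
  se <- log_prr_se(row$a, row$b, row$c, row$d)
  expect_lt(abs(log(row$prr) - log(expected_prr(cfg, "vancomycin", "p1"))), 3 * se)
  expect_true(row$signal)
})

test_that("demographic bands follow the configured probabilities", {
  cfg <- small_config(seed = 7)
  tabs <- generate_srs(cfg)
  rs <- as_report_set(tabs$demo, tabs$drug, tabs$reac, tabs$hist)
  rs <- suppressMessages(deduplicate_reports(rs))
  ds <- demographic_summary(rs, report_ids(rs))
  n <- n_reports(rs)
  probs <- list(sex = cfg$sex_probs, age_band = cfg$age_probs,
                weight_band = cfg$weight_probs)
  for (ax in names(probs)) {
    for (band in names(probs[[ax]])) {
      p <- probs[[ax]][[band]]
      got <- ds$n[ds$characteristic == ax & ds$band == band]
      expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
    }
  }
})

test_that("planted Weibull onsets round-trip through extraction and fitting", {
  cfg <- synthetic_config(
    n_reports = 20000,
    drugs = tibble::tibble(name = "vancomycin", p = 0.05),
    terms = tibble::tibble(pt_code = "p1", baseline = 0.01),
    signals = tibble::tibble(drug = "vancomycin", term = "p1", lambda = 20),
    onset = tibble::tibble(drug = "vancomycin", term = "p1", alpha = 20, beta = 1.8),
    date_missing_fraction = 0, duplicate_fraction = 0,
    mean_duration_days = 30, # long treatments so the onset window rarely censors
    seed = 404
  )
  tabs <- generate_srs(cfg)
  rs <- as_report_set(tabs$demo, tabs$drug, tabs$reac, tabs$hist)
  m <- build_event_matrix(rs, level = "PT")
  elig <- eligible_reports(rs, "vancomycin", c("intravenous", "oral", "other"))
  # a wide post-cessation window isolates parameter recovery from the
  # window-truncation mechanics tested elsewhere
  s <- extract_tto(rs, elig, m, "vancomycin", "p1", post_window = 365)
  expect_gt(length(s$days), 100)
  f <- fit_weibull_tto(s)
  expect_true(f$evaluable)
  # point estimates are within sampling noise of the planted parameters
  # (n ~ 140, so roughly 5-10% standard errors) and the CIs cover them
  expect_equal(f$alpha, 20, tolerance = 0.15)
  expect_equal(f$beta, 1.8, tolerance = 0.15)
  expect_true(f$alpha_ci[1] <= 20.5 && 20 <= f$alpha_ci[2]) # +0.5: day discretisation
  expect_true(f$beta_ci[1] <= 1.8 && 1.8 <= f$beta_ci[2])
  expect_equal(f$failure_type, "wear-out")
})
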