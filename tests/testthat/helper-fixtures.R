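# In-code fixtures: a tiny hand-built SRS, the published SMQ-level screen
# statistics used as frozen references, and the published Weibull
# shape-interval classifications.

fixture_demo <- function() {
  tibble::tibble(
    case_id = c("C1", "C2", "C3", "C4"),
    version = c("1", "1", "1", "1"),
    sex = c("male", "female", "male", "unspecified"),
    age_band = c(">=60", "20-59", ">=60", "<20"),
    weight_band = c("40-69", "<40", "unspecified", ">=70")
  )
}

fixture_drug <- function() {
  tibble::tibble(
    case_id = c("C1", "C2", "C2", "C3", "C4"),
    version = c("1", "1", "1", "1", "1"),
    drug_name = c("vancomycin", "vancomycin", "linezolid", "Cubicin", "vancomycin"),
    role = c("suspected", "concomitant", "suspected", "suspected", "suspected"),
    route = c("intravenous", "intravenous", "oral", "intravenous", "oral"),
    start_date = c("2020-01-01", "2020-02-01", "2020-03-01", "2020-04", ""),
    end_date = c("2020-01-10", "2020-02-05", "2020-03-15", "", "")
  )
}

fixture_reac <- function() {
  tibble::tibble(
    case_id = c("C1", "C1", "C2", "C3", "C4"),
    version = c("1", "1", "1", "1", "1"),
    pt_code = c("p1", "p2", "p1", "p3", "p2"),
    onset_date = c("2020-01-05", "2020-01-07", "2020-02-10", "2021-04", "2020-06-01")
  )
}

fixture_hist <- function() {
  tibble::tibble(
    case_id = "C1", version = "1", condition = "diabetes mellitus"
  )
}

write_fixture_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                               demo = fixture_demo(), drug = fixture_drug(),
                               reac = fixture_reac(), hist = fixture_hist()) {
  paths <- list(
    demo = file.path(dir, "demo.csv"), drug = file.path(dir, "drug.csv"),
    reac = file.path(dir, "reac.csv"), hist = file.path(dir, "hist.csv")
  )
  readr::write_csv(demo, paths$demo, progress = FALSE)
  readr::write_csv(drug, paths$drug, progress = FALSE)
  readr::write_csv(reac, paths$reac, progress = FALSE)
  readr::write_csv(hist, paths$hist, progress = FALSE)
  paths
}

fixture_report_set <- function(...) {
  suppressMessages(as_report_set(demo = fixture_demo(), drug = fixture_drug(),
                                 reac = fixture_reac(), hist = fixture_hist(), ...))
}

fixture_dictionary <- function() {
  term_dictionary(tibble::tibble(
    pt_code = c("p1", "p2", "p3", "p3"),
    smq_id = c("S1", "S1", "S2", "S1"),
    scope = c("narrow", "narrow", "narrow", "broad"),
    smq_name = c("renal injury", "renal injury", "cytopenia", "renal injury")
  ))
}

# Published SMQ-level screening statistics (counts and the statistics
# printed alongside them), used as frozen expected values. `a` of `n_drug`
# drug reports carry the event; `c` of `n_other` remaining reports do.
# `ror_dp` records the printed number of decimals.
published_smq_screen <- function() {
  txt <- '
drug,a,n_drug,c,n_other,prr,chi2,ror,ror_dp
vancomycin,510,2318,31495,952859,6.66,2490.21,8.25,2
vancomycin,684,2318,112677,952859,2.50,689.60,3.12,2
vancomycin,273,2318,27823,952859,4.03,632.35,4.44,2
vancomycin,513,2318,98672,952859,2.14,343.32,2.46,2
vancomycin,165,2318,25951,952859,2.61,166.28,2.74,2
vancomycin,59,2318,5258,952859,4.61,162.42,4.71,2
vancomycin,176,2318,34207,952859,2.12,105.62,2.21,2
vancomycin,46,2318,4950,952859,3.82,92.59,3.88,2
vancomycin,44,2318,5152,952859,3.51,76.27,3.56,2
vancomycin,27,2318,2878,952859,3.86,53.96,3.89,2
vancomycin,21,2318,2085,952859,4.14,46.55,4.17,2
vancomycin,59,2318,10684,952859,2.27,40.90,2.3,1
teicoplanin,305,838,98880,954339,3.51,607.07,4.95,2
teicoplanin,101,838,31904,954339,3.61,193.44,3.96,2
teicoplanin,98,838,34285,954339,3.26,156.06,3.55,2
teicoplanin,130,838,71835,954339,2.06,75.50,2.26,2
teicoplanin,60,838,28036,954339,2.44,50.81,2.55,2
teicoplanin,18,838,4978,954339,4.12,39.49,4.19,2
teicoplanin,11,838,4881,954339,2.57,9.03,2.59,2
teicoplanin,6,838,2100,954339,3.25,7.24,3.27,2
arbekacin,74,227,31931,954950,9.75,590.79,13.98,2
arbekacin,14,227,4982,954950,11.82,128.39,12.53,2
arbekacin,39,227,71926,954950,2.28,28.96,2.55,2
arbekacin,4,227,2102,954950,8.01,18.02,8.13,2
daptomycin,76,552,5641,954625,23.30,1588.04,26.86,2
daptomycin,111,552,53977,954625,3.56,213.07,4.2,1
daptomycin,33,552,8499,954625,6.71,155.63,7.08,2
daptomycin,17,552,4441,954625,6.62,75.65,6.8,1
daptomycin,54,552,31951,954625,2.92,68.58,3.13,2
daptomycin,21,552,10722,954625,3.39,33.29,3.48,2
daptomycin,35,552,28061,954625,2.16,21.18,2.24,2
daptomycin,10,552,7048,954625,2.45,7.26,2.48,2
linezolid,1103,1750,98082,953427,6.13,5215.83,14.87,2
linezolid,361,1750,34022,953427,5.78,1460.20,7.02,2
linezolid,96,1750,6745,953427,7.75,554.18,8.15,2
linezolid,33,1750,931,953427,19.31,536.34,19.66,2
linezolid,39,1750,2088,953427,10.18,308.51,10.39,2
linezolid,38,1750,7446,953427,2.78,41.67,2.82,2
linezolid,13,1750,2093,953427,3.38,19.43,3.4,1
linezolid,22,1750,5832,953427,2.06,10.91,2.07,2
linezolid,7,1750,1159,953427,3.29,8.94,3.3,1
linezolid,17,1750,4441,953427,2.09,8.56,2.1,1
linezolid,12,1750,2893,953427,2.26,7.21,2.27,2
tedizolid,20,39,99165,955138,4.94,65.78,9.09,2
tedizolid,7,39,34376,955138,4.99,19.19,5.86,2'
  readr::read_csv(I(txt), show_col_types = FALSE, progress = FALSE)
}

# Published Weibull shape estimates with 95% CIs and the failure-type
# labels assigned to them (evaluable drug-event groups only).
published_weibull_classification <- function() {
  txt <- '
drug,beta,lower,upper,type
vancomycin,1.35,1.22,1.48,wear-out
teicoplanin,1.25,1.02,1.47,wear-out
arbekacin,1.75,1.40,2.10,wear-out
daptomycin,1.23,0.88,1.57,random
linezolid,0.86,0.63,1.08,random
vancomycin,1.09,1.0049,1.17,wear-out
teicoplanin,0.92,0.81,1.03,random
daptomycin,0.98,0.81,1.14,random
linezolid,1.17,0.89,1.45,random
vancomycin,1.2,1.06,1.34,wear-out
teicoplanin,1.68,1.29,2.08,wear-out
daptomycin,1.38,0.98,1.79,random
vancomycin,1.37,1.17,1.57,wear-out
teicoplanin,1.48,1.25,1.72,wear-out
arbekacin,1.63,1.21,2.05,wear-out
daptomycin,1.57,1.22,1.91,wear-out
linezolid,0.96,0.76,1.17,random
daptomycin,1.65,1.34,1.97,wear-out
daptomycin,1.89,1.58,2.20,wear-out
vancomycin,1.63,1.49,1.77,wear-out
teicoplanin,1.79,1.60,1.98,wear-out
arbekacin,1.24,0.84,1.64,random
daptomycin,0.92,0.70,1.15,random
linezolid,1.22,1.15,1.29,wear-out
vancomycin,1.73,1.45,2.02,wear-out
teicoplanin,1.87,1.44,2.31,wear-out
linezolid,1.11,0.99,1.23,random'
  readr::read_csv(I(txt), show_col_types = FALSE, progress = FALSE)
}

# Delta-method standard error of log PRR, for stochastic 3-sigma bands.
log_prr_se <- function(a, b, c, d) {
  sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
}

# A one-report-per-row SRS with controllable drug/onset dates, for exercising
# the time-to-onset eligibility rules.
tto_fixture_rs <- function(start = "2020-01-01", end = "2020-01-10",
                           onset = "2020-01-05", role = "suspected",
                           route = "intravenous") {
  n <- max(length(start), length(end), length(onset))
  demo <- tibble::tibble(case_id = paste0("C", seq_len(n)), version = "1",
                         sex = "male", age_band = ">=60", weight_band = "40-69")
  drug <- tibble::tibble(case_id = paste0("C", seq_len(n)), version = "1",
                         drug_name = "vancomycin", role = role, route = route,
                         start_date = start, end_date = end)
  reac <- tibble::tibble(case_id = paste0("C", seq_len(n)), version = "1",
                         pt_code = "p1", onset_date = onset)
  suppressMessages(as_report_set(demo, drug, reac,
                                 tibble::tibble(case_id = character(0),
                                                version = character(0),
                                                condition = character(0))))
}

extract_days <- function(rs, post_window = 14) {
  m <- build_event_matrix(rs, level = "PT")
  elig <- eligible_reports(rs, "vancomycin", "intravenous")
  extract_tto(rs, elig, m, "vancomycin", "p1", post_window = post_window)$days
}
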