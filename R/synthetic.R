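# Synthetic JADER-schema SRS generator with planted ground truth. Every
# pipeline stage can be validated against known reporting-rate multipliers
# and onset distributions without any external data.

#' Configure a synthetic SRS database
#'
#' Defines the generative model behind [generate_srs()]:
#'
#' * each report independently includes each drug with its marginal
#'   probability; an included entry draws a role and a route from the
#'   configured distributions, a start date uniform over `start_window`,
#'   and a treatment duration that is geometric with mean
#'   `mean_duration_days` (so the post-cessation onset window is
#'   exercised);
#' * each report includes each event term as a Bernoulli draw with
#'   probability `baseline * prod(lambda)` over the report's suspected
#'   exposures to drugs with a planted signal on the term, capped at 1;
#'   `lambda = 1` everywhere yields a null database;
#' * onset dates are the generating drug's start plus a Weibull-distributed
#'   day count (planted per-pair `(alpha, beta)`, or `default_onset`),
#'   rounded up to whole days so same-day onset is day 1;
#' * a fraction of case numbers is duplicated as an extra report version,
#'   and a fraction of dates is blanked or truncated to year-month, so
#'   deduplication and date-eligibility filtering are exercised.
#'
#' Exposure for the signal mechanism means a suspected-role entry of the
#' drug, matching the eligibility rule of the screening stage.
#'
#' @param n_reports number of base reports (before duplicate versions).
#' @param drugs data frame with columns `name` and `p` (marginal inclusion
#'   probability per report).
#' @param terms data frame with columns `pt_code` and `baseline` (per-report
#'   event probability without any signal).
#' @param dictionary optional `term_dictionary` used when generating for
#'   SMQ-level analyses.
#' @param signals optional data frame `drug`, `term`, `lambda` of planted
#'   reporting-rate multipliers (`lambda >= 0`).
#' @param onset optional data frame `drug`, `term`, `alpha`, `beta` of
#'   planted Weibull onset distributions for signal pairs.
#' @param default_onset Weibull `c(alpha, beta)` for all other onsets; the
#'   default `c(10, 1)` is a constant-hazard onset with a 10-day scale,
#'   typical of antimicrobial adverse-event latencies.
#' @param role_probs,route_probs named probability vectors over drug roles
#'   and routes.
#' @param sex_probs,age_probs,weight_probs named probability vectors over
#'   the demographic bands.
#' @param start_window two dates bounding administration starts.
#' @param mean_duration_days mean treatment duration.
#' @param date_missing_fraction fraction of each date field corrupted
#'   (half blanked, half truncated to year-month).
#' @param duplicate_fraction fraction of case numbers receiving an extra
#'   report version.
#' @param seed mandatory integer seed; generation is bitwise reproducible.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             drugs,
                             terms,
                             dictionary = NULL,
                             signals = NULL,
                             onset = NULL,
                             default_onset = c(alpha = 10, beta = 1),
                             role_probs = c(suspected = 0.7, concomitant = 0.25,
                                            interacting = 0.05),
                             route_probs = c(intravenous = 0.5, oral = 0.2,
                                             other = 0.1, unspecified = 0.2),
                             sex_probs = c(male = 0.62, female = 0.355,
                                           unspecified = 0.025),
                             age_probs = c("<20" = 0.05, "20-59" = 0.25,
                                           ">=60" = 0.66, "unspecified" = 0.04),
                             weight_probs = c("<40" = 0.08, "40-69" = 0.45,
                                              ">=70" = 0.09, "unspecified" = 0.38),
                             start_window = as.Date(c("2015-01-01", "2023-12-31")),
                             mean_duration_days = 10,
                             date_missing_fraction = 0.1,
                             duplicate_fraction = 0.05,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_reports >= 0, length(seed) == 1)
  drugs <- tibble::as_tibble(drugs)
  check_columns(drugs, c("name", "p"), "drugs config")
  terms <- tibble::as_tibble(terms)
  check_columns(terms, c("pt_code", "baseline"), "terms config")
  check_probs <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  check_probs(drugs$p, "drug marginal probabilities")
  check_probs(terms$baseline, "term baseline probabilities")
  for (pv in list(role_probs, route_probs, sex_probs, age_probs, weight_probs)) {
    check_probs(pv, "distribution probabilities")
  }
  signals <- if (is.null(signals)) {
    tibble::tibble(drug = character(0), term = character(0), lambda = numeric(0))
  } else {
    tibble::as_tibble(signals)
  }
  if (nrow(signals) > 0) {
    check_columns(signals, c("drug", "term", "lambda"), "signals config")
    if (any(signals$lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
    stopifnot(all(signals$drug %in% drugs$name), all(signals$term %in% terms$pt_code))
    base <- terms$baseline[match(signals$term, terms$pt_code)]
    infeasible <- base * signals$lambda > 1
    if (any(infeasible)) {
      i <- which(infeasible)[1]
      stop(sprintf(
        "infeasible event probability for pair (%s, %s): baseline %.3g * lambda %.3g > 1",
        signals$drug[i], signals$term[i], base[i], signals$lambda[i]), call. = FALSE)
    }
  }
  onset <- if (is.null(onset)) {
    tibble::tibble(drug = character(0), term = character(0),
                   alpha = numeric(0), beta = numeric(0))
  } else {
    tibble::as_tibble(onset)
  }
  if (nrow(onset) > 0) {
    check_columns(onset, c("drug", "term", "alpha", "beta"), "onset config")
    if (any(onset$alpha <= 0 | onset$beta <= 0)) {
      stop("onset alpha and beta must be positive", call. = FALSE)
    }
  }
  stopifnot(default_onset[["alpha"]] > 0, default_onset[["beta"]] > 0,
            date_missing_fraction >= 0, date_missing_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            mean_duration_days > 0)
  structure(
    list(n_reports = as.integer(n_reports), drugs = drugs, terms = terms,
         dictionary = dictionary, signals = signals, onset = onset,
         default_onset = default_onset, role_probs = role_probs,
         route_probs = route_probs, sex_probs = sex_probs,
         age_probs = age_probs, weight_probs = weight_probs,
         start_window = as.Date(start_window),
         mean_duration_days = mean_duration_days,
         date_missing_fraction = date_missing_fraction,
         duplicate_fraction = duplicate_fraction,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# One RNG stream per generation block, derived from the single global seed,
# so adding a block never perturbs the draws of earlier blocks.
stream_seed <- function(config, k) {
  (config$seed * 101L + k) %% 2147483647L
}

#' Generate a synthetic SRS database
#'
#' Draws the four relational tables (DEMO, DRUG, REAC, HIST) from a
#' [synthetic_config()] together with the planted ground truth. Output is
#' bitwise reproducible for a given config.
#'
#' @param config a `synthetic_config`.
#' @param dir optional output directory; when given, `demo.csv`,
#'   `drug.csv`, `reac.csv`, `hist.csv` and `ground_truth.json` are
#'   written there.
#' @return Invisibly (when `dir` is given) or visibly, a list with the
#'   four tables as character tibbles in the loader schema, and
#'   `ground_truth`: per signal pair the expected 2x2 cell probabilities
#'   and expected PRR (see [expected_prr()]), the planted onset
#'   parameters, and the number of injected duplicate versions.
#' @export
generate_srs <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n <- cf$n_reports
  case_id <- sprintf("C%07d", seq_len(n))

  # stream 1: demographics
  set.seed(stream_seed(cf, 1L))
  draw <- function(probs, size) {
    if (size == 0) return(character(0))
    sample(names(probs), size, replace = TRUE, prob = probs)
  }
  demo <- tibble::tibble(
    case_id = case_id, version = rep("1", n),
    sex = draw(cf$sex_probs, n),
    age_band = draw(cf$age_probs, n),
    weight_band = draw(cf$weight_probs, n)
  )

  # stream 2: drug exposures
  set.seed(stream_seed(cf, 2L))
  window_len <- as.integer(cf$start_window[2] - cf$start_window[1]) + 1L
  n_drugs <- nrow(cf$drugs)
  exposure <- matrix(FALSE, nrow = n, ncol = n_drugs,
                     dimnames = list(NULL, cf$drugs$name))
  present <- matrix(FALSE, nrow = n, ncol = n_drugs,
                    dimnames = list(NULL, cf$drugs$name))
  start_num <- matrix(NA_real_, nrow = n, ncol = n_drugs,
                      dimnames = list(NULL, cf$drugs$name))
  drug_rows <- vector("list", n_drugs)
  for (j in seq_len(n_drugs)) {
    p <- cf$drugs$p[j]
    idx <- which(stats::runif(n) < p)
    k <- length(idx)
    role <- draw(cf$role_probs, k)
    route <- draw(cf$route_probs, k)
    start <- cf$start_window[1] + floor(stats::runif(k) * window_len)
    duration <- stats::rgeom(k, prob = 1 / (cf$mean_duration_days + 1))
    present[idx, j] <- TRUE
    exposure[idx, j] <- role == "suspected"
    start_num[idx, j] <- as.numeric(start)
    drug_rows[[j]] <- tibble::tibble(
      case_id = case_id[idx], version = "1",
      drug_name = cf$drugs$name[j], role = role, route = route,
      start_date = format(start, "%Y-%m-%d"),
      end_date = format(start + duration, "%Y-%m-%d")
    )
  }
  drug <- dplyr::bind_rows(drug_rows)
  if (is.null(drug) || nrow(drug) == 0) {
    drug <- tibble::tibble(case_id = character(0), version = character(0),
                           drug_name = character(0), role = character(0),
                           route = character(0), start_date = character(0),
                           end_date = character(0))
  }
  # reference start for background onsets: earliest present-drug start,
  # falling back to a fixed mid-window anchor for drug-free reports
  ref_start <- if (n_drugs > 0) {
    suppressWarnings(apply(start_num, 1, min, na.rm = TRUE))
  } else {
    rep(Inf, n)
  }
  anchor <- as.numeric(cf$start_window[1]) + window_len / 2
  ref_start[!is.finite(ref_start)] <- anchor

  # stream 3: events and onsets
  set.seed(stream_seed(cf, 3L))
  reac_rows <- vector("list", nrow(cf$terms))
  for (t in seq_len(nrow(cf$terms))) {
    term <- cf$terms$pt_code[t]
    p_event <- rep(cf$terms$baseline[t], n)
    sig <- cf$signals[cf$signals$term == term, , drop = FALSE]
    for (s in seq_len(nrow(sig))) {
      ex <- exposure[, sig$drug[s]]
      p_event[ex] <- p_event[ex] * sig$lambda[s]
    }
    p_event <- pmin(p_event, 1)
    idx <- which(stats::runif(n) < p_event)
    if (length(idx) == 0) next
    # generating drug: the first exposed signal drug of the term, else the
    # report's reference start with the default onset distribution
    g_start <- ref_start[idx]
    g_alpha <- rep(cf$default_onset[["alpha"]], length(idx))
    g_beta <- rep(cf$default_onset[["beta"]], length(idx))
    for (s in rev(seq_len(nrow(sig)))) { # reverse so the first listed drug wins
      hit <- exposure[idx, sig$drug[s]]
      on <- cf$onset[cf$onset$drug == sig$drug[s] & cf$onset$term == term, ,
                     drop = FALSE]
      g_start[hit] <- start_num[idx[hit], sig$drug[s]]
      if (nrow(on) == 1) {
        g_alpha[hit] <- on$alpha
        g_beta[hit] <- on$beta
      }
    }
    day <- ceiling(stats::rweibull(length(idx), shape = g_beta, scale = g_alpha))
    day <- pmax(day, 1)
    reac_rows[[t]] <- tibble::tibble(
      case_id = case_id[idx], version = "1", pt_code = term,
      onset_date = format(as.Date(g_start + day - 1,
                                  origin = "1970-01-01"), "%Y-%m-%d")
    )
  }
  reac <- dplyr::bind_rows(reac_rows)
  if (is.null(reac) || nrow(reac) == 0) {
    reac <- tibble::tibble(case_id = character(0), version = character(0),
                           pt_code = character(0), onset_date = character(0))
  }

  # history table: carried by the schema but unused by the statistics
  set.seed(stream_seed(cf, 4L))
  conditions <- c("diabetes mellitus", "chronic kidney disease",
                  "hypertension", "malignancy", "none reported")
  hist_idx <- which(stats::runif(n) < 0.2)
  hist <- tibble::tibble(
    case_id = case_id[hist_idx], version = rep("1", length(hist_idx)),
    condition = draw(stats::setNames(rep(0.2, 5), conditions), length(hist_idx))
  )

  # stream 5: duplicate case versions
  set.seed(stream_seed(cf, 5L))
  n_dup <- round(cf$duplicate_fraction * n)
  dup_cases <- if (n_dup > 0) sample(case_id, n_dup) else character(0)
  add_version <- function(df) {
    if (length(dup_cases) == 0 || nrow(df) == 0) return(df)
    extra <- df[df$case_id %in% dup_cases, , drop = FALSE]
    extra$version <- "2"
    dplyr::bind_rows(df, extra)
  }
  demo <- add_version(demo)
  drug <- add_version(drug)
  reac <- add_version(reac)
  hist <- add_version(hist)

  # stream 6: missing / partial dates
  set.seed(stream_seed(cf, 6L))
  corrupt <- function(x) {
    f <- cf$date_missing_fraction
    if (f == 0 || length(x) == 0) return(x)
    u <- stats::runif(length(x))
    x[u < f / 2] <- ""
    tr <- u >= f / 2 & u < f
    x[tr] <- substr(x[tr], 1, 7)
    x
  }
  drug$start_date <- corrupt(drug$start_date)
  drug$end_date <- corrupt(drug$end_date)
  reac$onset_date <- corrupt(reac$onset_date)

  ground_truth <- synthetic_ground_truth(cf, n_dup)
  out <- list(demo = demo, drug = drug, reac = reac, hist = hist,
              ground_truth = ground_truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(demo, file.path(dir, "demo.csv"), progress = FALSE)
    readr::write_csv(drug, file.path(dir, "drug.csv"), progress = FALSE)
    readr::write_csv(reac, file.path(dir, "reac.csv"), progress = FALSE)
    readr::write_csv(hist, file.path(dir, "hist.csv"), progress = FALSE)
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

synthetic_ground_truth <- function(cf, n_dup) {
  pairs <- cf$signals
  gt_pairs <- lapply(seq_len(nrow(pairs)), function(i) {
    dg <- pairs$drug[i]; tm <- pairs$term[i]
    pi_d <- exposure_prob(cf, dg)
    p1 <- event_prob_given_exposure(cf, dg, tm, exposed = TRUE)
    p0 <- event_prob_given_exposure(cf, dg, tm, exposed = FALSE)
    on <- cf$onset[cf$onset$drug == dg & cf$onset$term == tm, , drop = FALSE]
    list(
      drug = dg, term = tm, lambda = pairs$lambda[i],
      cell_probs = list(a = pi_d * p1, b = pi_d * (1 - p1),
                        c = (1 - pi_d) * p0, d = (1 - pi_d) * (1 - p0)),
      expected_prr = if (p0 > 0) p1 / p0 else NA_real_,
      onset_alpha = if (nrow(on) == 1) on$alpha else cf$default_onset[["alpha"]],
      onset_beta = if (nrow(on) == 1) on$beta else cf$default_onset[["beta"]]
    )
  })
  list(n_reports = cf$n_reports, n_duplicates = n_dup, seed = cf$seed,
       signals = gt_pairs)
}

exposure_prob <- function(cf, drug) {
  p <- cf$drugs$p[match(drug, cf$drugs$name)]
  unname(p * cf$role_probs[["suspected"]])
}

event_prob_given_exposure <- function(cf, drug, term, exposed) {
  sig <- cf$signals[cf$signals$term == term, , drop = FALSE]
  lam_target <- 1
  if (drug %in% sig$drug) {
    lam_target <- sig$lambda[match(drug, sig$drug)]
    sig <- sig[sig$drug != drug, , drop = FALSE]
  }
  base <- cf$terms$baseline[match(term, cf$terms$pt_code)]
  others <- seq_len(nrow(sig))
  # exact enumeration over the exposure states of the other signal drugs
  total <- 0
  n_o <- nrow(sig)
  for (mask in seq_len(2^n_o) - 1L) {
    prob <- 1
    lam <- if (exposed) lam_target else 1
    for (k in others) {
      pi_k <- exposure_prob(cf, sig$drug[k])
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0) {
        prob <- prob * pi_k
        lam <- lam * sig$lambda[k]
      } else {
        prob <- prob * (1 - pi_k)
      }
    }
    total <- total + prob * min(1, base * lam)
  }
  total
}

#' Closed-form expected PRR of a configured pair
#'
#' The expectation follows from the generative model by exhaustive
#' enumeration over the exposure states of every drug with a planted
#' signal on the term (drugs without a signal cancel out of the ratio):
#' the expected within-exposure event probability divided by the expected
#' background event probability. Capping of `baseline * prod(lambda)` at 1
#' is honoured exactly.
#'
#' @param config a `synthetic_config`.
#' @param drug,term the pair of interest; the drug must be configured, the
#'   term must exist.
#' @return The expected PRR (`1` for null pairs, `0` when `lambda = 0`).
#' @export
expected_prr <- function(config, drug, term) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!drug %in% config$drugs$name) {
    stop(sprintf("unknown drug '%s' in config", drug), call. = FALSE)
  }
  if (!term %in% config$terms$pt_code) {
    stop(sprintf("unknown term '%s' in config", term), call. = FALSE)
  }
  p1 <- event_prob_given_exposure(config, drug, term, exposed = TRUE)
  p0 <- event_prob_given_exposure(config, drug, term, exposed = FALSE)
  if (p0 == 0) return(NA_real_)
  p1 / p0
}
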