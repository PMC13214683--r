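# Whole-database disproportionality screen and volcano-plot coordinates.

#' Screen all drug-event pairs of a report set
#'
#' Runs the full disproportionality screen: for every requested drug, each
#' term of the event matrix with at least one co-occurring report is turned
#' into a case/non-case 2x2 table and scored with PRR, Yates-corrected
#' chi-squared, ROR (Woolf interval), IC/IC025, the natural-log chi-squared
#' p-value and its log-space Benjamini-Hochberg adjustment, and the
#' four-condition signal rule.
#'
#' The BH family is per drug and per level: `m` equals the number of terms
#' tested for that drug (those with `a >= 1` and an evaluable p-value).
#' Pass `fdr_family = "global"` to pool all drugs into a single family
#' instead. Within the sorted order, ties in the log p-value are broken by
#' term id, so results are reproducible.
#'
#' @param rs a (deduplicated) `report_set`.
#' @param matrix an `event_matrix` built on the same report universe.
#' @param drugs character vector of canonical drug names.
#' @param routes eligible administration routes: either a character vector
#'   applied to every drug, or a named list of per-drug route vectors.
#' @param alpha_fdr FDR level of the fourth signal condition.
#' @param prr_min,chi2_min,min_cases thresholds of the signal rule.
#' @param fdr_family `"per_drug"` (default) or `"global"`.
#' @param conf_level confidence level of the ROR interval.
#' @return A `signal_screen` tibble with one row per (drug, term) pair with
#'   `a >= 1`, sorted by chi-squared descending within drug: counts (`a`,
#'   `b`, `c`, `d`, `drug_total`, `event_total`), `reporting_ratio`
#'   (`a / drug_total`), all statistics, the four per-condition booleans
#'   (`cond_*`) and the `signal` flag.
#' @export
run_screen <- function(rs, matrix, drugs, routes = "intravenous",
                       alpha_fdr = 0.05, prr_min = 2, chi2_min = 4,
                       min_cases = 3, fdr_family = c("per_drug", "global"),
                       conf_level = 0.95) {
  stopifnot(inherits(rs, "report_set"), inherits(matrix, "event_matrix"))
  fdr_family <- match.arg(fdr_family)
  universe <- report_ids(rs)
  if (!setequal(universe, matrix$universe)) {
    stop("report_set and event_matrix are built on different report universes",
         call. = FALSE)
  }
  n_universe <- length(universe)
  route_for <- function(drug) {
    if (is.list(routes)) {
      routes[[drug]] %||% stop(sprintf("no routes given for drug '%s'", drug),
                               call. = FALSE)
    } else {
      routes
    }
  }
  term_totals <- dplyr::count(matrix$membership, .data$term_id, name = "event_total")

  per_drug <- lapply(drugs, function(dg) {
    elig <- eligible_reports(rs, dg, route_for(dg))
    in_drug <- matrix$membership[matrix$membership$report_id %in% elig, , drop = FALSE]
    counts <- dplyr::count(in_drug, .data$term_id, name = "a")
    if (nrow(counts) == 0) return(NULL)
    counts <- dplyr::left_join(counts, term_totals, by = "term_id")
    tibble::tibble(
      drug = dg,
      term_id = counts$term_id,
      level = matrix$level,
      a = as.numeric(counts$a),
      b = length(elig) - as.numeric(counts$a),
      c = as.numeric(counts$event_total) - as.numeric(counts$a),
      d = n_universe - length(elig) - (as.numeric(counts$event_total) - as.numeric(counts$a))
    )
  })
  res <- dplyr::bind_rows(per_drug)
  if (nrow(res) == 0) {
    message("run_screen: no drug-event pair with a >= 1")
    return(empty_screen(alpha_fdr, prr_min, chi2_min, min_cases, matrix$level))
  }

  res$drug_total <- res$a + res$b
  res$event_total <- res$a + res$c
  res$reporting_ratio <- res$a / res$drug_total
  res$prr <- prr_calc(res$a, res$b, res$c, res$d)
  res$chi2 <- yates_chi2_calc(res$a, res$b, res$c, res$d)
  ror <- ror_calc(res$a, res$b, res$c, res$d, conf_level)
  res$ror <- ror$ror
  res$ror_lower <- ror$lower
  res$ror_upper <- ror$upper
  ic <- ic_calc(res$a, res$b, res$c, res$d)
  res$ic <- ic$ic
  res$ic025 <- ic$ic025
  res$log_p <- ifelse(is.na(res$chi2), NA_real_,
                      stats::pchisq(res$chi2, df = 1, lower.tail = FALSE, log.p = TRUE))

  # reproducible BH order: log p ascending, ties broken by term id
  adjust_family <- function(df) {
    ord <- order(df$log_p, df$term_id, na.last = TRUE)
    df$log_fdr_p[ord] <- bh_adjust_log(df$log_p[ord])
    df
  }
  res$log_fdr_p <- NA_real_
  if (fdr_family == "per_drug") {
    res <- res |>
      dplyr::group_by(.data$drug) |>
      dplyr::group_modify(~ adjust_family(.x)) |>
      dplyr::ungroup()
  } else {
    res <- adjust_family(res)
  }

  cond <- signal_conditions(res$prr, res$chi2, res$a, res$log_fdr_p,
                            alpha_fdr, prr_min, chi2_min, min_cases)
  res$cond_prr <- cond$prr
  res$cond_chi2 <- cond$chi2
  res$cond_cases <- cond$cases
  res$cond_fdr <- cond$fdr
  res$signal <- cond$prr & cond$chi2 & cond$cases & cond$fdr

  res <- res |>
    dplyr::arrange(.data$drug, dplyr::desc(.data$chi2)) |>
    dplyr::relocate("drug", "term_id", "level")
  attr(res, "alpha_fdr") <- alpha_fdr
  attr(res, "thresholds") <- c(prr = prr_min, chi2 = chi2_min, cases = min_cases)
  attr(res, "fdr_family") <- fdr_family
  class(res) <- c("signal_screen", class(res))
  res
}

empty_screen <- function(alpha_fdr, prr_min, chi2_min, min_cases, level) {
  res <- tibble::tibble(
    drug = character(0), term_id = character(0), level = character(0),
    a = numeric(0), b = numeric(0), c = numeric(0), d = numeric(0),
    drug_total = numeric(0), event_total = numeric(0),
    reporting_ratio = numeric(0), prr = numeric(0), chi2 = numeric(0),
    ror = numeric(0), ror_lower = numeric(0), ror_upper = numeric(0),
    ic = numeric(0), ic025 = numeric(0), log_p = numeric(0),
    log_fdr_p = numeric(0), cond_prr = logical(0), cond_chi2 = logical(0),
    cond_cases = logical(0), cond_fdr = logical(0), signal = logical(0)
  )
  attr(res, "alpha_fdr") <- alpha_fdr
  attr(res, "thresholds") <- c(prr = prr_min, chi2 = chi2_min, cases = min_cases)
  class(res) <- c("signal_screen", class(res))
  res
}

#' Volcano-plot coordinates for a screen
#'
#' One point per evaluable pair: `x = log2(PRR)`, `y` the chi-squared
#' statistic, point `size` the reporting ratio `a / (a + b)` (the
#' within-drug proportion of the event). Pairs whose PRR or chi-squared is
#' not evaluable are omitted, with a logged count.
#'
#' @param results a `signal_screen`.
#' @return A tibble with columns `drug`, `label`, `x`, `y`, `size`,
#'   `signal`.
#' @export
volcano_data <- function(results) {
  stopifnot(inherits(results, "signal_screen"))
  ok <- !is.na(results$prr) & results$prr > 0 & !is.na(results$chi2)
  if (any(!ok)) {
    message(sprintf("volcano_data: omitted %d pair(s) with non-evaluable PRR or chi-squared",
                    sum(!ok)))
  }
  r <- results[ok, , drop = FALSE]
  tibble::tibble(
    drug = r$drug, label = r$term_id,
    x = log2(r$prr), y = r$chi2, size = r$reporting_ratio,
    signal = r$signal
  )
}

#' Volcano plot of a disproportionality screen
#'
#' Renders [volcano_data()] with ggplot2, one panel per drug. Points in the
#' upper right combine high disproportionality with high statistical
#' strength; flagged signals are coloured.
#'
#' @param results a `signal_screen` (or a precomputed [volcano_data()]
#'   tibble).
#' @return A ggplot object.
#' @export
volcano_plot <- function(results) {
  vd <- if (inherits(results, "signal_screen")) volcano_data(results) else results
  ggplot2::ggplot(vd, ggplot2::aes(x = .data$x, y = .data$y,
                                   size = .data$size, colour = .data$signal)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~drug, scales = "free") +
    ggplot2::labs(x = expression(log[2] ~ PRR), y = expression(chi^2 ~ statistic),
                  size = "reporting ratio", colour = "signal") +
    ggplot2::theme_bw()
}
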