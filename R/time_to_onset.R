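# Time-to-onset extraction, Weibull modelling, hazard-shape classification
# and box-plot summaries.

#' Extract the time-to-onset sample for a drug-event pair
#'
#' Time-to-onset is the number of days from the start of administration of
#' the suspected drug to the onset of the event, with same-day onset
#' counted as day 1 (the two-parameter Weibull requires positive support).
#' Only clearly dated records enter the sample:
#'
#' * the drug entry must have a complete (non-partial) start date; when a
#'   report carries several suspected entries of the drug, the earliest
#'   start is used, so each report contributes at most one value;
#' * the event onset must be complete, and `onset >= start` (earlier
#'   onsets are inconsistent and excluded);
#' * when the chosen entry has a complete end date, onsets after treatment
#'   cessation qualify only within `post_window` days of the end
#'   (default 14); a missing end date is treated as ongoing treatment, so
#'   `onset >= start` suffices;
#' * when several qualifying event rows map to the term (e.g. multiple PTs
#'   of one SMQ), the earliest qualifying onset is used.
#'
#' @param rs a `report_set`.
#' @param eligible_ids drug-eligible report ids from [eligible_reports()].
#' @param matrix an `event_matrix`; its level determines whether `term_id`
#'   is a PT code or an SMQ id.
#' @param drug canonical drug name.
#' @param term_id event term at the matrix level.
#' @param post_window days after treatment cessation within which an onset
#'   still qualifies.
#' @return A `tto_sample`: list with `drug`, `term_id`, `days` (positive
#'   integers) and `report_ids`.
#' @export
extract_tto <- function(rs, eligible_ids, matrix, drug, term_id,
                        post_window = 14) {
  stopifnot(inherits(rs, "report_set"), inherits(matrix, "event_matrix"))
  src <- matrix$source
  pts <- unique(src$pt_code[src$term_id == term_id])
  with_term <- unique(src$report_id[src$term_id == term_id])
  ids <- intersect(eligible_ids, with_term)

  starts <- rs$drug |>
    dplyr::filter(.data$report_id %in% ids,
                  .data$drug_name == drug,
                  .data$role == "suspected",
                  !is.na(.data$start_date), !.data$start_partial) |>
    dplyr::group_by(.data$report_id) |>
    dplyr::slice_min(.data$start_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$report_id, start = .data$start_date,
                     end = dplyr::if_else(.data$end_partial, as.Date(NA), .data$end_date))

  onsets <- rs$reac |>
    dplyr::filter(.data$report_id %in% starts$report_id,
                  .data$pt_code %in% pts,
                  !is.na(.data$onset_date), !.data$onset_partial) |>
    dplyr::select("report_id", onset = "onset_date")

  joined <- dplyr::inner_join(onsets, starts, by = "report_id")
  ok <- joined$onset >= joined$start &
    (is.na(joined$end) |
       as.numeric(joined$onset - joined$end) <= post_window)
  joined <- joined[ok, , drop = FALSE]
  if (nrow(joined) == 0) {
    return(structure(list(drug = drug, term_id = term_id,
                          days = integer(0), report_ids = character(0)),
                     class = "tto_sample"))
  }
  per_report <- joined |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(onset = min(.data$onset), start = min(.data$start),
                     .groups = "drop")
  days <- as.integer(per_report$onset - per_report$start) + 1L
  structure(
    list(drug = drug, term_id = term_id, days = days,
         report_ids = per_report$report_id),
    class = "tto_sample"
  )
}

#' @export
print.tto_sample <- function(x, ...) {
  cat(sprintf("<tto_sample> %s / %s: n = %d", x$drug, x$term_id, length(x$days)))
  if (length(x$days) > 0) {
    cat(sprintf(", median %.1f days", stats::median(x$days)))
  }
  cat("\n")
  invisible(x)
}

#' Fit a two-parameter Weibull model to a time-to-onset sample
#'
#' Maximum-likelihood estimation of the Weibull scale `alpha` (days) and
#' shape `beta` with Wald 95% confidence intervals from the observed
#' information matrix on the untransformed parameter scale (so intervals
#' can dip below 1 even when the point estimate exceeds 1). At least
#' `min_n` cases (default 20) are required for a stable fit; smaller or
#' degenerate (zero-variance) samples are returned as not evaluable, with
#' empirical median and interquartile range still reported. Goodness of
#' fit is assessed with [ad_weibull_test()] at the fitted parameters.
#'
#' The shape parameter characterises the hazard over time: `beta < 1`
#' early failures (risk concentrated after initiation), `beta ~ 1` random
#' failures (constant risk), `beta > 1` wear-out failures (risk increasing
#' with treatment duration); see [classify_failure()].
#'
#' @param sample a `tto_sample` (or a bare numeric vector of days).
#' @param min_n minimum sample size for fitting.
#' @param conf_level confidence level of the Wald intervals.
#' @return A `weibull_tto` list: `n`, `alpha`, `alpha_ci`, `beta`,
#'   `beta_ci`, `failure_type`, `ad_stat`, `ad_p`, `median`, `iqr`,
#'   `evaluable`, `reason`.
#' @export
fit_weibull_tto <- function(sample, min_n = 20, conf_level = 0.95) {
  days <- if (inherits(sample, "tto_sample")) sample$days else sample
  drug <- if (inherits(sample, "tto_sample")) sample$drug else NA_character_
  term <- if (inherits(sample, "tto_sample")) sample$term_id else NA_character_
  n <- length(days)
  base <- list(
    drug = drug, term_id = term, n = n,
    alpha = NA_real_, alpha_ci = c(NA_real_, NA_real_),
    beta = NA_real_, beta_ci = c(NA_real_, NA_real_),
    failure_type = "not-evaluable", ad_stat = NA_real_, ad_p = NA_real_,
    median = if (n > 0) unname(stats::median(days)) else NA_real_,
    iqr = if (n > 0) unname(stats::quantile(days, c(0.25, 0.75), type = 7))
          else c(NA_real_, NA_real_),
    evaluable = FALSE, reason = NA_character_
  )
  if (n < min_n) {
    base$reason <- sprintf("n = %d below the minimum of %d", n, min_n)
    return(structure(base, class = "weibull_tto"))
  }
  if (stats::var(days) == 0) {
    base$reason <- "degenerate sample (zero variance)"
    message(sprintf("fit_weibull_tto: %s", base$reason))
    return(structure(base, class = "weibull_tto"))
  }
  if (any(days <= 0)) stop("time-to-onset values must be positive days", call. = FALSE)

  fit <- tryCatch(
    fitdistrplus::fitdist(as.numeric(days), "weibull"),
    error = function(e) e
  )
  if (inherits(fit, "error") || any(is.na(fit$sd))) {
    base$reason <- if (inherits(fit, "error")) conditionMessage(fit)
                   else "information matrix not invertible"
    message(sprintf("fit_weibull_tto: fit not evaluable (%s)", base$reason))
    return(structure(base, class = "weibull_tto"))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- unname(fit$estimate["shape"])
  alpha <- unname(fit$estimate["scale"])
  beta_se <- unname(fit$sd["shape"])
  alpha_se <- unname(fit$sd["scale"])
  out <- base
  out$alpha <- alpha
  out$alpha_ci <- c(alpha - z * alpha_se, alpha + z * alpha_se)
  out$beta <- beta
  out$beta_ci <- c(beta - z * beta_se, beta + z * beta_se)
  out$failure_type <- classify_failure(out$beta_ci[1], out$beta_ci[2])
  ad <- ad_weibull_test(days, alpha = alpha, beta = beta)
  out$ad_stat <- ad$statistic
  out$ad_p <- ad$p_value
  out$evaluable <- TRUE
  structure(out, class = "weibull_tto")
}

#' @export
print.weibull_tto <- function(x, ...) {
  cat(sprintf("<weibull_tto> %s / %s, n = %d\n", x$drug, x$term_id, x$n))
  if (x$evaluable) {
    cat(sprintf("  alpha = %.2f [%.2f-%.2f] days, beta = %.2f [%.2f-%.2f]\n",
                x$alpha, x$alpha_ci[1], x$alpha_ci[2],
                x$beta, x$beta_ci[1], x$beta_ci[2]))
    cat(sprintf("  %s; AD p = %.3g; median %.1f [%.1f-%.1f]\n",
                x$failure_type, x$ad_p, x$median, x$iqr[1], x$iqr[2]))
  } else {
    cat(sprintf("  not evaluable (%s)\n", x$reason))
  }
  invisible(x)
}

#' Classify the hazard (failure) type from a shape-parameter interval
#'
#' The label follows the confidence interval of the Weibull shape `beta`:
#' `"wear-out"` when the whole interval lies above 1 (increasing hazard),
#' `"early"` when it lies entirely below 1 (decreasing hazard), and
#' `"random"` when the interval covers 1 (hazard compatible with constant
#' risk). Missing bounds give `"not-evaluable"`.
#'
#' @param lower,upper bounds of the `beta` confidence interval
#'   (vectorised).
#' @return Character vector of labels.
#' @export
classify_failure <- function(lower, upper) {
  out <- rep("random", length(lower))
  out[!is.na(lower) & lower > 1] <- "wear-out"
  out[!is.na(upper) & upper < 1] <- "early"
  out[is.na(lower) | is.na(upper)] <- "not-evaluable"
  out
}

#' Tukey box-plot statistics for time-to-onset samples
#'
#' Five-number box-plot summaries (median, quartiles, 1.5 IQR whiskers,
#' outliers) per drug-term group; empty groups are omitted.
#'
#' @param samples a `tto_sample` or a list of them.
#' @return A tibble with one row per non-empty group: `drug`, `term_id`,
#'   `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high` and a
#'   list-column `outliers`.
#' @export
tto_boxplot_data <- function(samples) {
  if (inherits(samples, "tto_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "tto_sample"))
    if (length(s$days) == 0) return(NULL)
    bs <- grDevices::boxplot.stats(s$days)
    q <- stats::quantile(s$days, c(0.25, 0.5, 0.75), type = 7)
    tibble::tibble(
      drug = s$drug, term_id = s$term_id, n = length(s$days),
      median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
      whisker_low = bs$stats[1], whisker_high = bs$stats[5],
      outliers = list(bs$out)
    )
  })
  dplyr::bind_rows(rows)
}
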