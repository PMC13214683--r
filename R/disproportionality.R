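# Case/non-case 2x2 statistics: PRR, Yates-corrected chi-squared, ROR with
# Woolf confidence interval, information component with IC025, log-scale
# p-values and log-space Benjamini-Hochberg adjustment.

#' Construct a case/non-case contingency table
#'
#' In the case/non-case design a "case" is a report containing both the
#' drug of interest and the event of interest; non-cases are all other
#' reports. The 2x2 table is `a` (drug and event), `b` (drug, no event),
#' `c` (event, no drug) and `d` (neither).
#'
#' @param a,b,c,d non-negative cell counts.
#' @return A `contingency_table` with the four cells and the derived
#'   margins `n` (total), `drug_total` (`a + b`), `nondrug_total`
#'   (`c + d`) and `event_total` (`a + c`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("all cell counts must be non-negative numbers", call. = FALSE)
  }
  n <- a + b + c + d
  if (n <= 0) stop("empty contingency table (N = 0)", call. = FALSE)
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c), d = as.numeric(d),
         n = as.numeric(n), drug_total = as.numeric(a + b),
         nondrug_total = as.numeric(c + d), event_total = as.numeric(a + c)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  cat("<contingency_table>\n")
  print(m)
  invisible(x)
}

#' Build a contingency table from report id sets
#'
#' @param eligible_ids report ids exposed to the drug of interest (from
#'   [eligible_reports()]).
#' @param event_ids report ids carrying the event of interest (from
#'   [term_reports()]).
#' @param all_ids the full post-deduplication report universe; both id sets
#'   must be subsets of it.
#' @return A `contingency_table`; the four cells always sum to
#'   `length(unique(all_ids))`.
#' @export
build_contingency <- function(eligible_ids, event_ids, all_ids) {
  all_ids <- unique(all_ids)
  if (length(all_ids) == 0) stop("empty report universe", call. = FALSE)
  eligible_ids <- unique(eligible_ids)
  event_ids <- unique(event_ids)
  if (!all(eligible_ids %in% all_ids) || !all(event_ids %in% all_ids)) {
    stop("eligible_ids and event_ids must be subsets of all_ids", call. = FALSE)
  }
  a <- length(intersect(eligible_ids, event_ids))
  b <- length(eligible_ids) - a
  c <- length(event_ids) - a
  d <- length(all_ids) - a - b - c
  contingency_table(a, b, c, d)
}

# Vectorised kernels ---------------------------------------------------------
# The S3 wrappers below operate on one contingency_table; run_screen() calls
# these kernels directly on count vectors.

prr_calc <- function(a, b, c, d) {
  out <- rep(NA_real_, length(a))
  ok <- (a + b) > 0 & (c + d) > 0 & c > 0
  out[ok] <- (a[ok] / (a[ok] + b[ok])) / (c[ok] / (c[ok] + d[ok]))
  out
}

yates_chi2_calc <- function(a, b, c, d) {
  # For a 2x2 table |O - E| is identical in all four cells (= |ad - bc| / N),
  # so the truncated Yates sum collapses to the closed form
  # N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)], zero when |ad - bc| <= N/2.
  n <- a + b + c + d
  out <- rep(NA_real_, length(a))
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  dev <- abs(a * d - b * c) - n / 2
  dev <- pmax(dev, 0)
  out[ok] <- n[ok] * dev[ok]^2 /
    ((a[ok] + b[ok]) * (c[ok] + d[ok]) * (a[ok] + c[ok]) * (b[ok] + d[ok]))
  out
}

ror_calc <- function(a, b, c, d, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- rep(NA_real_, length(a))
  ok <- b > 0 & c > 0
  est[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se_ok <- a > 0 & b > 0 & c > 0 & d > 0
  lo <- hi <- rep(NA_real_, length(a))
  se <- sqrt(1 / a[se_ok] + 1 / b[se_ok] + 1 / c[se_ok] + 1 / d[se_ok])
  lo[se_ok] <- exp(log(est[se_ok]) - z * se)
  hi[se_ok] <- exp(log(est[se_ok]) + z * se)
  list(ror = est, lower = lo, upper = hi)
}

ic_calc <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- log2(stats::qgamma(0.025, shape = a + 0.5, scale = 1) / (e + 0.5))
  list(ic = ic, ic025 = ic025)
}

#' Proportional reporting ratio
#'
#' `PRR = [a / (a + b)] / [c / (c + d)]`: the event's reporting proportion
#' among the drug's reports relative to its proportion among all other
#' reports. With no background cases (`c = 0`) the ratio is undefined and
#' `NA` is returned -- such pairs are reported as not evaluable, never as
#' infinite.
#'
#' @param tab a `contingency_table`.
#' @return The PRR, or `NA` when not evaluable.
#' @export
prr <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  prr_calc(tab$a, tab$b, tab$c, tab$d)
}

#' Yates continuity-corrected chi-squared statistic
#'
#' Pearson chi-squared for the 2x2 table with the Yates correction,
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` over the four cells; cells with
#' `|O - E| <= 0.5` contribute zero (truncation, not a negative
#' correction).
#'
#' @param tab a `contingency_table`.
#' @return The corrected statistic.
#' @export
yates_chi2 <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  out <- yates_chi2_calc(tab$a, tab$b, tab$c, tab$d)
  if (is.na(out)) stop("chi-squared undefined: zero marginal total", call. = FALSE)
  out
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d) / (b c)` with the Woolf (log-normal) interval
#' `exp(log(ROR) -/+ z * sqrt(1/a + 1/b + 1/c + 1/d))`. The point estimate
#' requires `b, c > 0`; the interval additionally requires all four cells
#' positive. Zero cells yield `NA` (no Haldane-Anscombe 0.5 correction is
#' applied: the screening rule's case-count floor makes corrected estimates
#' irrelevant to decisions).
#'
#' @param tab a `contingency_table`.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return A list with `ror`, `lower`, `upper`.
#' @export
ror_ci <- function(tab, conf_level = 0.95) {
  stopifnot(inherits(tab, "contingency_table"))
  ror_calc(tab$a, tab$b, tab$c, tab$d, conf_level)
}

#' Information component with lower credibility bound
#'
#' The Bayesian confidence propagation (shrinkage) observed-to-expected
#' measure: with expected count `E = (a + b)(a + c) / N`,
#' `IC = log2((a + 0.5) / (E + 0.5))`, and `IC025 = log2(q / (E + 0.5))`
#' where `q` is the 2.5% quantile of a Gamma distribution with shape
#' `a + 0.5` and unit scale. `IC025 > 0` is the conventional signal
#' criterion for this measure. Defined for `a = 0`.
#'
#' @param tab a `contingency_table`.
#' @return A list with `ic` and `ic025` (bits).
#' @export
ic_ic025 <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  ic_calc(tab$a, tab$b, tab$c, tab$d)
}

#' Natural-log upper-tail p-value of a chi-squared(1) statistic
#'
#' Evaluated through the log-scale survival function, never by
#' exponentiating and re-logging, so the result stays finite for
#' arbitrarily large statistics (a statistic of 5000 gives roughly
#' -2504.9, where a naive computation underflows to `-Inf`).
#'
#' @param chi2 non-negative statistic(s).
#' @return `log(p)` on the natural scale.
#' @export
log_p_from_chi2 <- function(chi2) {
  if (any(is.na(chi2)) || any(chi2 < 0)) {
    stop("chi2 must be non-negative", call. = FALSE)
  }
  stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
}

#' Benjamini-Hochberg adjustment in log space
#'
#' The step-up FDR adjustment computed entirely on natural-log p-values:
#' with the inputs sorted ascending, the candidate for rank `i` is
#' `log p_(i) + log(m / i)` and the adjusted value is the running minimum
#' of the candidates from the largest rank down, capped at `log(1) = 0`.
#' Equivalent to `log(p.adjust(exp(x), "BH"))` wherever the latter does not
#' underflow, but immune to underflow for extreme statistics.
#'
#' @param log_p natural-log p-values (all `<= 0`; `NA`s are passed through
#'   and excluded from the family size).
#' @return Adjusted natural-log p-values, in input order.
#' @export
bh_adjust_log <- function(log_p) {
  if (length(log_p) == 0) return(numeric(0))
  if (any(log_p > 0, na.rm = TRUE)) {
    stop("log_p must be natural-log p-values (<= 0)", call. = FALSE)
  }
  out <- rep(NA_real_, length(log_p))
  idx <- which(!is.na(log_p))
  m <- length(idx)
  if (m == 0) return(out)
  lp <- log_p[idx]
  ord <- order(lp)
  cand <- lp[ord] + log(m / seq_len(m))
  adj <- rev(cummin(rev(cand)))
  adj <- pmin(adj, 0)
  out[idx[ord]] <- adj
  out
}

#' Four-condition signal decision
#'
#' A drug-event pair is flagged as a signal when all four conditions hold:
#' `PRR >= prr_min` (default 2), chi-squared `>= chi2_min` (default 4), at
#' least `min_cases` cases (default 3), and BH-adjusted p-value below
#' `alpha_fdr` (default 0.05, compared on the log scale). Not-evaluable
#' statistics fail their condition.
#'
#' @param prr,chi2,a,log_fdr_p the pair's statistics (vectorised).
#' @param alpha_fdr FDR significance level.
#' @param prr_min,chi2_min,min_cases rule thresholds.
#' @return A logical vector (with attribute-free per-condition results
#'   available via [signal_conditions()]).
#' @export
detect_signal <- function(prr, chi2, a, log_fdr_p, alpha_fdr = 0.05,
                          prr_min = 2, chi2_min = 4, min_cases = 3) {
  cond <- signal_conditions(prr, chi2, a, log_fdr_p, alpha_fdr,
                            prr_min, chi2_min, min_cases)
  cond$prr & cond$chi2 & cond$cases & cond$fdr
}

#' @rdname detect_signal
#' @export
signal_conditions <- function(prr, chi2, a, log_fdr_p, alpha_fdr = 0.05,
                              prr_min = 2, chi2_min = 4, min_cases = 3) {
  list(
    prr = !is.na(prr) & prr >= prr_min,
    chi2 = !is.na(chi2) & chi2 >= chi2_min,
    cases = !is.na(a) & a >= min_cases,
    fdr = !is.na(log_fdr_p) & log_fdr_p < log(alpha_fdr)
  )
}
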