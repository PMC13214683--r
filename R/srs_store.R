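# Loading, validation, deduplication and eligibility filtering of the four
# relational SRS tables (DEMO, DRUG, REAC, HIST).

#' Load the four relational SRS tables into a report set
#'
#' Reads the DEMO, DRUG, REAC and HIST tables of a JADER-style spontaneous
#' reporting database from UTF-8 CSV files and assembles a validated
#' `report_set`. Reports are identified by a case number plus an integer
#' version; resubmissions of a case appear as higher versions and are
#' resolved by [deduplicate_reports()].
#'
#' Expected columns:
#' * DEMO: `case_id`, `version`, `sex`, `age_band`, `weight_band`
#' * DRUG: `case_id`, `version`, `drug_name`, `role`, `route`,
#'   `start_date`, `end_date`
#' * REAC: `case_id`, `version`, `pt_code`, `onset_date`
#' * HIST: `case_id`, `version`, `condition`
#'
#' Demographic bands, drug roles and routes must use the enumerated
#' vocabularies (see the package vignette); free text raises an error.
#' Dates are `YYYY-MM-DD`, or `YYYY-MM` for partial dates, which are
#' retained but flagged incomplete. DEMO rows with an unparseable report id
#' (empty case number or non-integer version) are rejected with a logged
#' count; DRUG/REAC/HIST rows that reference no surviving DEMO report are
#' dropped likewise. Drug entries whose end date precedes the start date are
#' kept, but both dates are blanked as inconsistent (and so never enter
#' time-to-onset samples).
#'
#' @param demo_path,drug_path,reac_path,hist_path paths to the four CSV
#'   tables.
#' @param alias_map optional drug-name normalisation: a data frame with
#'   columns `alias` and `canonical` (or a named character vector mapping
#'   alias to canonical). Brand or salt names in DRUG are replaced by their
#'   canonical active-ingredient name; unmatched names pass through.
#' @return A `report_set`: a list with tibbles `demo`, `drug`, `reac`,
#'   `hist`, keyed by `report_id` (`case_id` + `.` + `version`).
#' @seealso [deduplicate_reports()], [eligible_reports()]
#' @export
load_srs_tables <- function(demo_path, drug_path, reac_path, hist_path,
                            alias_map = NULL) {
  for (p in c(demo_path, drug_path, reac_path, hist_path)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  read_chr <- function(path) {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  as_report_set(read_chr(demo_path), read_chr(drug_path),
                read_chr(reac_path), read_chr(hist_path), alias_map = alias_map)
}

#' Assemble a report set from in-memory tables
#'
#' Same validation and schema as [load_srs_tables()], for tables that are
#' already in memory (e.g. straight from [generate_srs()]). All columns
#' are taken as character.
#'
#' @param demo,drug,reac,hist data frames in the four-table schema.
#' @inheritParams load_srs_tables
#' @return A `report_set`.
#' @export
as_report_set <- function(demo, drug, reac, hist, alias_map = NULL) {
  to_chr <- function(df) {
    df <- tibble::as_tibble(df)
    df[] <- lapply(df, as.character)
    df
  }
  demo <- check_columns(to_chr(demo),
                        c("case_id", "version", "sex", "age_band", "weight_band"), "DEMO")
  drug <- check_columns(to_chr(drug),
                        c("case_id", "version", "drug_name", "role", "route",
                          "start_date", "end_date"), "DRUG")
  reac <- check_columns(to_chr(reac),
                        c("case_id", "version", "pt_code", "onset_date"), "REAC")
  hist <- check_columns(to_chr(hist),
                        c("case_id", "version", "condition"), "HIST")

  parse_ids <- function(df) {
    version <- suppressWarnings(as.integer(df$version))
    ok <- !is.na(df$case_id) & nzchar(trimws(df$case_id)) & !is.na(version) &
      version >= 1 & grepl("^\\s*\\d+\\s*$", df$version %||% "")
    list(ok = ok, version = version)
  }

  ids <- parse_ids(demo)
  n_rejected <- sum(!ids$ok)
  if (n_rejected > 0) {
    message(sprintf("load_srs_tables: rejected %d DEMO row(s) with unparseable report ids",
                    n_rejected))
  }
  demo <- demo[ids$ok, , drop = FALSE]
  demo$version <- ids$version[ids$ok]
  if (anyDuplicated(demo[c("case_id", "version")]) > 0) {
    dup <- demo[duplicated(demo[c("case_id", "version")]), c("case_id", "version")]
    stop(sprintf("duplicate (case_id, version) row in DEMO: (%s, %d)",
                 dup$case_id[1], dup$version[1]), call. = FALSE)
  }
  demo$report_id <- paste(demo$case_id, demo$version, sep = ".")
  check_enum(demo$sex, srs_sex_levels, "sex", "DEMO")
  check_enum(demo$age_band, srs_age_levels, "age_band", "DEMO")
  check_enum(demo$weight_band, srs_weight_levels, "weight_band", "DEMO")
  demo <- tibble::as_tibble(demo[c("report_id", "case_id", "version",
                                   "sex", "age_band", "weight_band")])

  attach_report_id <- function(df, table) {
    ids <- parse_ids(df)
    df <- df[ids$ok, , drop = FALSE]
    df$version <- ids$version[ids$ok]
    df$report_id <- paste(df$case_id, df$version, sep = ".")
    known <- df$report_id %in% demo$report_id
    if (any(!known)) {
      message(sprintf("load_srs_tables: dropped %d %s row(s) referencing unknown reports",
                      sum(!known), table))
    }
    tibble::as_tibble(df[known, , drop = FALSE])
  }

  drug <- attach_report_id(drug, "DRUG")
  check_enum(drug$role, srs_role_levels, "role", "DRUG")
  check_enum(drug$route, srs_route_levels, "route", "DRUG")
  drug$drug_name <- normalize_drug_names(drug$drug_name, alias_map)
  sd <- parse_srs_date(drug$start_date)
  ed <- parse_srs_date(drug$end_date)
  # end before start: inconsistent date information -> blank both dates
  inconsistent <- !is.na(sd$date) & !is.na(ed$date) & ed$date < sd$date
  if (any(inconsistent)) {
    message(sprintf(
      "load_srs_tables: blanked dates on %d DRUG row(s) with end_date < start_date",
      sum(inconsistent)))
  }
  drug$start_date <- replace(sd$date, inconsistent, as.Date(NA))
  drug$start_partial <- sd$partial & !inconsistent
  drug$end_date <- replace(ed$date, inconsistent, as.Date(NA))
  drug$end_partial <- ed$partial & !inconsistent
  drug <- drug[c("report_id", "case_id", "version", "drug_name", "role", "route",
                 "start_date", "start_partial", "end_date", "end_partial")]

  reac <- attach_report_id(reac, "REAC")
  empty_pt <- is.na(reac$pt_code) | !nzchar(trimws(reac$pt_code))
  if (any(empty_pt)) {
    message(sprintf("load_srs_tables: dropped %d REAC row(s) with empty pt_code",
                    sum(empty_pt)))
    reac <- reac[!empty_pt, , drop = FALSE]
  }
  od <- parse_srs_date(reac$onset_date)
  reac$onset_date <- od$date
  reac$onset_partial <- od$partial
  reac <- reac[c("report_id", "case_id", "version", "pt_code",
                 "onset_date", "onset_partial")]

  hist <- attach_report_id(hist, "HIST")
  hist <- hist[c("report_id", "case_id", "version", "condition")]

  structure(
    list(demo = demo, drug = drug, reac = reac, hist = hist,
         deduplicated = FALSE),
    class = "report_set"
  )
}

normalize_drug_names <- function(x, alias_map) {
  if (is.null(alias_map)) return(x)
  if (is.data.frame(alias_map)) {
    check_columns(alias_map, c("alias", "canonical"), "alias map")
    map <- stats::setNames(as.character(alias_map$canonical),
                           as.character(alias_map$alias))
  } else {
    map <- alias_map
  }
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Report ids and report count of a report set
#'
#' @param rs a `report_set`.
#' @return `report_ids()` returns the character vector of report ids;
#'   `n_reports()` its length.
#' @export
report_ids <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  rs$demo$report_id
}

#' @rdname report_ids
#' @export
n_reports <- function(rs) length(report_ids(rs))

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d report(s)%s\n", nrow(x$demo),
              if (isTRUE(x$deduplicated)) ", deduplicated" else ""))
  cat(sprintf("  drug entries: %d | event entries: %d | history entries: %d\n",
              nrow(x$drug), nrow(x$reac), nrow(x$hist)))
  invisible(x)
}

#' Remove duplicate report versions
#'
#' Spontaneous reports are resubmitted as follow-up information arrives; each
#' resubmission shares the case number but carries a higher version. For
#' every case number only the highest version is retained, so the analysis
#' universe contains one report per case. The number of removed versions is
#' reported via `message()` so the reduction can be audited. The operation
#' is idempotent.
#'
#' @param rs a `report_set`.
#' @return A `report_set` with unique case numbers.
#' @export
deduplicate_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  keep <- rs$demo |>
    dplyr::group_by(.data$case_id) |>
    dplyr::slice_max(.data$version, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  removed <- nrow(rs$demo) - nrow(keep)
  if (removed > 0) {
    message(sprintf("deduplicate_reports: removed %d duplicate report version(s)",
                    removed))
  }
  keep_ids <- keep$report_id
  structure(
    list(
      demo = keep,
      drug = dplyr::filter(rs$drug, .data$report_id %in% keep_ids),
      reac = dplyr::filter(rs$reac, .data$report_id %in% keep_ids),
      hist = dplyr::filter(rs$hist, .data$report_id %in% keep_ids),
      deduplicated = TRUE
    ),
    class = "report_set"
  )
}

#' Reports eligible for a drug of interest
#'
#' A report qualifies if it contains at least one entry for the drug with
#' role `"suspected"` and an administration route in `allowed_routes`.
#' Reports in which the drug appears only as a concomitant or interacting
#' medication are excluded. Entries with route `"unspecified"` are treated
#' as eligible regardless of `allowed_routes`, because route fields in SRS
#' extracts are frequently blank; pass
#' `include_unspecified_route = FALSE` to require an explicit route.
#'
#' @param rs a `report_set`.
#' @param drug canonical (post-alias) ingredient name.
#' @param allowed_routes character vector of eligible routes, a subset of
#'   `c("intravenous", "oral", "other")`.
#' @param include_unspecified_route treat unspecified routes as eligible
#'   (default `TRUE`).
#' @return Character vector of eligible report ids. An unknown drug name
#'   yields an empty set with a warning.
#' @export
eligible_reports <- function(rs, drug,
                             allowed_routes = c("intravenous"),
                             include_unspecified_route = TRUE) {
  stopifnot(inherits(rs, "report_set"), length(drug) == 1)
  if (!drug %in% rs$drug$drug_name) {
    warning(sprintf("drug '%s' not present in the DRUG table", drug), call. = FALSE)
    return(character(0))
  }
  routes <- allowed_routes
  if (include_unspecified_route) routes <- union(routes, "unspecified")
  hits <- rs$drug$drug_name == drug &
    rs$drug$role == "suspected" &
    rs$drug$route %in% routes
  unique(rs$drug$report_id[hits])
}

#' Demographic summary of a set of reports
#'
#' Counts and percentages by sex, age band and weight band for the given
#' reports, with every enumerated band present (zero rows included).
#' Percentages are relative to the number of selected reports.
#'
#' @param rs a `report_set`.
#' @param ids report ids to summarise; must be a subset of
#'   `report_ids(rs)`.
#' @return A tibble with columns `characteristic`, `band`, `n`, `pct`.
#' @export
demographic_summary <- function(rs, ids) {
  stopifnot(inherits(rs, "report_set"))
  if (!all(ids %in% rs$demo$report_id)) {
    stop("ids must be a subset of report_ids(rs)", call. = FALSE)
  }
  sel <- rs$demo[rs$demo$report_id %in% ids, , drop = FALSE]
  total <- length(unique(ids))
  one_axis <- function(column, levels, label) {
    n <- vapply(levels, function(l) sum(sel[[column]] == l), integer(1))
    tibble::tibble(
      characteristic = label, band = levels, n = as.integer(n),
      pct = if (total > 0) 100 * n / total else rep(0, length(n))
    )
  }
  dplyr::bind_rows(
    one_axis("sex", srs_sex_levels, "sex"),
    one_axis("age_band", srs_age_levels, "age_band"),
    one_axis("weight_band", srs_weight_levels, "weight_band")
  )
}
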