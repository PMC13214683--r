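# PT -> SMQ term dictionary handling and report-level event aggregation.

#' Load a PT-to-SMQ term dictionary
#'
#' The dictionary maps MedDRA-style preferred term (PT) codes into
#' Standardized MedDRA Query (SMQ) groups, with a `narrow` or `broad` scope
#' flag per mapping. MedDRA content is licensed and therefore never shipped
#' with the package: the dictionary is a user-supplied artifact with the
#' same relational shape.
#'
#' @param path CSV file with columns `pt_code`, `smq_id`, `scope`
#'   (`narrow`/`broad`) and `smq_name`.
#' @return A `term_dictionary` tibble. A PT may map into several SMQs
#'   (many-to-many), but each `(pt_code, smq_id)` pair must be unique and
#'   each `smq_id` must carry a single label.
#' @export
load_term_dictionary <- function(path) {
  if (!file.exists(path)) stop(sprintf("dictionary file not found: %s", path), call. = FALSE)
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  term_dictionary(d)
}

#' @rdname load_term_dictionary
#' @param entries a data frame with the dictionary columns (in-memory
#'   construction, used e.g. by the synthetic generator).
#' @export
term_dictionary <- function(entries) {
  d <- tibble::as_tibble(entries)
  check_columns(d, c("pt_code", "smq_id", "scope", "smq_name"), "dictionary")
  bad_scope <- setdiff(unique(d$scope), c("narrow", "broad"))
  if (length(bad_scope) > 0) {
    stop(sprintf("invalid scope value(s) in dictionary: %s (expected narrow or broad)",
                 paste(bad_scope, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(d[c("pt_code", "smq_id")]) > 0) {
    dup <- d[duplicated(d[c("pt_code", "smq_id")]), ]
    stop(sprintf("duplicate (pt_code, smq_id) row in dictionary: (%s, %s)",
                 dup$pt_code[1], dup$smq_id[1]), call. = FALSE)
  }
  labels <- unique(d[c("smq_id", "smq_name")])
  if (anyDuplicated(labels$smq_id) > 0) {
    stop("conflicting smq_name labels for a single smq_id in dictionary", call. = FALSE)
  }
  class(d) <- c("term_dictionary", class(d))
  d
}

#' Build the report-by-term event membership
#'
#' Aggregates the REAC events of a report set to the requested level with
#' once-per-report counting: a report contributes at most one membership per
#' term, no matter how many qualifying event rows it carries.
#'
#' At `level = "PT"` the terms are the distinct PT codes of each report. At
#' `level = "SMQ"` a report belongs to an SMQ if at least one of its PTs
#' maps to that SMQ with the requested scope; narrow-scope searches are the
#' default, trading sensitivity for specificity. PTs absent from the
#' dictionary are silently unmapped at SMQ level (their count is reported
#' via `message()` as a coverage log) but always retained at PT level.
#'
#' @param rs a `report_set`.
#' @param dictionary a `term_dictionary`; required at SMQ level.
#' @param level `"PT"` or `"SMQ"`.
#' @param scope dictionary scope used at SMQ level: `"narrow"` (default) or
#'   `"broad"` (which uses narrow plus broad mappings).
#' @return An `event_matrix`: list with `level`, `scope`, `membership`
#'   (tibble of distinct `report_id`, `term_id` pairs), `source` (the
#'   per-PT pairs behind each membership, used for time-to-onset
#'   extraction) and `universe` (all report ids of `rs`).
#' @export
build_event_matrix <- function(rs, dictionary = NULL,
                               level = c("PT", "SMQ"), scope = c("narrow", "broad")) {
  stopifnot(inherits(rs, "report_set"))
  level <- match.arg(level)
  scope <- match.arg(scope)
  reac <- rs$reac
  if (level == "PT") {
    src <- tibble::tibble(report_id = reac$report_id,
                          term_id = reac$pt_code,
                          pt_code = reac$pt_code)
  } else {
    if (is.null(dictionary)) stop("a term_dictionary is required at SMQ level", call. = FALSE)
    stopifnot(inherits(dictionary, "term_dictionary"))
    scopes <- if (scope == "narrow") "narrow" else c("narrow", "broad")
    dict <- dictionary[dictionary$scope %in% scopes, c("pt_code", "smq_id")]
    unmapped <- setdiff(unique(reac$pt_code), dictionary$pt_code)
    if (length(unmapped) > 0) {
      message(sprintf(
        "build_event_matrix: %d PT code(s) not covered by the dictionary at SMQ level",
        length(unmapped)))
    }
    src <- dplyr::inner_join(reac[c("report_id", "pt_code")], dict,
                             by = "pt_code", relationship = "many-to-many")
    src <- tibble::tibble(report_id = src$report_id,
                          term_id = src$smq_id,
                          pt_code = src$pt_code)
  }
  src <- dplyr::distinct(src)
  membership <- dplyr::distinct(src[c("report_id", "term_id")])
  structure(
    list(level = level, scope = scope, membership = membership,
         source = src, universe = report_ids(rs)),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> level %s%s: %d membership pair(s), %d term(s), %d report universe\n",
              x$level, if (x$level == "SMQ") paste0(" (", x$scope, ")") else "",
              nrow(x$membership), length(unique(x$membership$term_id)),
              length(x$universe)))
  invisible(x)
}

#' Report ids carrying a given term
#'
#' @param matrix an `event_matrix`.
#' @param term_id a term identifier (PT code or SMQ id, matching the
#'   matrix level).
#' @return Character vector of report ids with the term.
#' @export
term_reports <- function(matrix, term_id) {
  stopifnot(inherits(matrix, "event_matrix"))
  matrix$membership$report_id[matrix$membership$term_id == term_id]
}
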