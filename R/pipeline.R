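# End-to-end orchestration from a structured run configuration: signal
# tables and volcano outputs, Weibull time-to-onset tables and box plots.
# Every exported artifact is a plain CSV whose statistics are recomputable
# from the 2x2 counts carried in the same row; figures are rendered from
# the exported coordinate tables, never from internal state.

#' Read and validate a run configuration
#'
#' The run configuration is a YAML key tree describing one analysis run.
#' All thresholds default to the conventional screening values, so a bare
#' configuration reproduces the standard rules:
#'
#' ```yaml
#' input:
#'   tables: {demo: demo.csv, drug: drug.csv, reac: reac.csv, hist: hist.csv}
#'   alias: alias.csv          # optional
#' dictionary: dict.csv        # required for SMQ level
#' drugs:
#'   - {name: vancomycin, routes: [intravenous]}
#'   - {name: linezolid,  routes: [intravenous, oral]}
#' level: SMQ                  # PT | SMQ | both
#' alpha_fdr: 0.05
#' thresholds: {prr: 2, chi2: 4, cases: 3}
#' tto: {window: 14, min_n: 20}
#' output: out/
#' figures: false
#' seed: 1
#' ```
#'
#' @param path path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a named list with the same structure (in-memory
#'   construction).
#' @export
run_config <- function(config) {
  cf <- config
  fail <- function(field, why) {
    stop(sprintf("invalid run config field '%s': %s", field, why), call. = FALSE)
  }
  if (is.null(cf$input)) fail("input", "missing")
  if (is.null(cf$input$tables) && is.null(cf$input$synthetic)) {
    fail("input", "needs either 'tables' paths or a 'synthetic' block")
  }
  if (!is.null(cf$input$tables)) {
    for (k in c("demo", "drug", "reac", "hist")) {
      if (is.null(cf$input$tables[[k]])) fail(paste0("input.tables.", k), "missing")
    }
  }
  if (is.null(cf$drugs) || length(cf$drugs) == 0) fail("drugs", "missing or empty")
  for (d in cf$drugs) {
    if (is.null(d$name)) fail("drugs", "every drug needs a 'name'")
  }
  cf$level <- cf$level %||% "SMQ"
  if (!cf$level %in% c("PT", "SMQ", "both")) fail("level", "must be PT, SMQ or both")
  cf$alpha_fdr <- cf$alpha_fdr %||% 0.05
  if (cf$alpha_fdr <= 0 || cf$alpha_fdr >= 1) fail("alpha_fdr", "must be in (0, 1)")
  cf$thresholds <- utils::modifyList(list(prr = 2, chi2 = 4, cases = 3),
                                     as.list(cf$thresholds %||% list()))
  if (any(unlist(cf$thresholds) <= 0)) fail("thresholds", "must be positive")
  cf$tto <- utils::modifyList(list(window = 14, min_n = 20),
                              as.list(cf$tto %||% list()))
  if (cf$tto$window < 0 || cf$tto$min_n < 1) fail("tto", "window >= 0 and min_n >= 1")
  if (is.null(cf$output)) fail("output", "missing output directory")
  cf$figures <- isTRUE(cf$figures)
  if (cf$level %in% c("SMQ", "both") && is.null(cf$dictionary) &&
      is.null(cf$input$synthetic$dictionary)) {
    fail("dictionary", "required for SMQ-level analysis")
  }
  structure(cf, class = "run_config")
}

load_config_inputs <- function(config) {
  cf <- config
  if (!is.null(cf$input$tables)) {
    alias <- if (!is.null(cf$input$alias)) {
      readr::read_csv(cf$input$alias,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    } else NULL
    rs <- load_srs_tables(cf$input$tables$demo, cf$input$tables$drug,
                          cf$input$tables$reac, cf$input$tables$hist,
                          alias_map = alias)
    dict <- if (!is.null(cf$dictionary)) load_term_dictionary(cf$dictionary) else NULL
  } else {
    sc <- synthetic_config_from_list(cf$input$synthetic, default_seed = cf$seed)
    dir <- file.path(cf$output, "synthetic")
    generate_srs(sc, dir = dir)
    rs <- load_srs_tables(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
                          file.path(dir, "reac.csv"), file.path(dir, "hist.csv"))
    dict <- if (!is.null(sc$dictionary)) sc$dictionary
            else if (!is.null(cf$dictionary)) load_term_dictionary(cf$dictionary)
            else NULL
  }
  n_loaded <- n_reports(rs)
  rs <- deduplicate_reports(rs)
  message(sprintf("pipeline: loaded %d report(s), %d after deduplication",
                  n_loaded, n_reports(rs)))
  list(rs = rs, dictionary = dict)
}

synthetic_config_from_list <- function(x, default_seed = NULL) {
  dict <- if (!is.null(x$dictionary)) {
    if (inherits(x$dictionary, "term_dictionary")) x$dictionary
    else if (is.character(x$dictionary)) load_term_dictionary(x$dictionary)
    else term_dictionary(tibble::as_tibble(x$dictionary))
  } else NULL
  synthetic_config(
    n_reports = x$n_reports,
    drugs = dplyr::bind_rows(lapply(x$drugs, tibble::as_tibble)),
    terms = dplyr::bind_rows(lapply(x$terms, tibble::as_tibble)),
    dictionary = dict,
    signals = if (!is.null(x$signals)) dplyr::bind_rows(lapply(x$signals, tibble::as_tibble)),
    onset = if (!is.null(x$onset)) dplyr::bind_rows(lapply(x$onset, tibble::as_tibble)),
    date_missing_fraction = x$date_missing_fraction %||% 0.1,
    duplicate_fraction = x$duplicate_fraction %||% 0.05,
    seed = x$seed %||% default_seed
  )
}

config_routes <- function(config) {
  routes <- lapply(config$drugs, function(d) unlist(d$routes %||% "intravenous"))
  names(routes) <- vapply(config$drugs, function(d) d$name, character(1))
  routes
}

#' Run the disproportionality screen of a configured analysis
#'
#' Loads (or generates) the database, deduplicates, builds the event
#' matrix at each configured level and screens every configured drug. Per
#' drug and level a signal table CSV (all counts and statistics, the four
#' per-condition booleans and the signal flag) and a volcano coordinate
#' CSV are written under the output directory; with `figures: true` a
#' volcano PNG per level is rendered from the coordinate file. Counts at
#' each filtering stage (loaded, deduplicated, eligible, tested) are
#' logged via `message()`.
#'
#' @param config a `run_config` (or path to one).
#' @return Invisibly, a named list of `signal_screen` objects, one per
#'   level.
#' @export
run_signal_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  inputs <- load_config_inputs(config)
  rs <- inputs$rs
  routes <- config_routes(config)
  levels <- if (config$level == "both") c("PT", "SMQ") else config$level
  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)

  screens <- list()
  for (lv in levels) {
    matrix <- build_event_matrix(rs, dictionary = inputs$dictionary, level = lv)
    screen <- run_screen(
      rs, matrix, drugs = names(routes), routes = routes,
      alpha_fdr = config$alpha_fdr,
      prr_min = config$thresholds$prr, chi2_min = config$thresholds$chi2,
      min_cases = config$thresholds$cases
    )
    for (dg in unique(screen$drug)) {
      sub <- screen[screen$drug == dg, , drop = FALSE]
      message(sprintf("pipeline: %s [%s]: %d eligible report(s), %d term(s) tested, %d signal(s)",
                      dg, lv, sub$drug_total[1], nrow(sub), sum(sub$signal)))
      slug <- gsub("[^A-Za-z0-9]+", "_", dg)
      readr::write_csv(as.data.frame(sub),
                       file.path(config$output, sprintf("signals_%s_%s.csv", slug, lv)),
                       progress = FALSE)
      vd <- suppressMessages(volcano_data(sub))
      readr::write_csv(vd,
                       file.path(config$output, sprintf("volcano_%s_%s.csv", slug, lv)),
                       progress = FALSE)
    }
    if (config$figures && nrow(screen) > 0) {
      vd_files <- list.files(config$output, sprintf("^volcano_.*_%s\\.csv$", lv),
                             full.names = TRUE)
      vd <- dplyr::bind_rows(lapply(vd_files, function(f) {
        readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      }))
      grDevices::png(file.path(config$output, sprintf("volcano_%s.png", lv)),
                     width = 1600, height = 1200, res = 150)
      print(volcano_plot(vd))
      grDevices::dev.off()
    }
    screens[[lv]] <- screen
  }
  invisible(screens)
}

#' Run the time-to-onset Weibull analysis of a configured analysis
#'
#' For each configured drug and each requested term, extracts the
#' time-to-onset sample ([extract_tto()]) and fits the Weibull model
#' ([fit_weibull_tto()]). The result table mirrors the conventional
#' presentation: n, median [IQR], alpha [CI], beta [CI], failure type and
#' Anderson-Darling p-value, with `NA` entries for groups below the
#' minimum sample size. Box-plot coordinates are exported alongside, and
#' with `figures: true` a box-plot PNG is rendered from them.
#'
#' @param config a `run_config` (or path to one). Terms are taken from
#'   `config$tto$terms`; when absent, the terms flagged as signals by
#'   [run_signal_screen()] at the first configured level are used.
#' @return Invisibly, a list with the results tibble (`table`) and the
#'   box-plot data (`boxplot`).
#' @export
run_tto_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  inputs <- load_config_inputs(config)
  rs <- inputs$rs
  routes <- config_routes(config)
  lv <- if (config$level == "both") "SMQ" else config$level
  matrix <- build_event_matrix(rs, dictionary = inputs$dictionary, level = lv)

  terms <- unlist(config$tto$terms %||% character(0))
  if (length(terms) == 0) {
    screen <- run_screen(rs, matrix, drugs = names(routes), routes = routes,
                         alpha_fdr = config$alpha_fdr,
                         prr_min = config$thresholds$prr,
                         chi2_min = config$thresholds$chi2,
                         min_cases = config$thresholds$cases)
    terms <- unique(screen$term_id[screen$signal])
  }
  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  samples <- list()
  for (dg in names(routes)) {
    elig <- eligible_reports(rs, dg, routes[[dg]])
    for (tm in terms) {
      s <- extract_tto(rs, elig, matrix, dg, tm, post_window = config$tto$window)
      f <- fit_weibull_tto(s, min_n = config$tto$min_n)
      samples[[paste(dg, tm, sep = "||")]] <- s
      rows[[paste(dg, tm, sep = "||")]] <- tibble::tibble(
        drug = dg, term_id = tm, n = f$n,
        median = f$median, q1 = f$iqr[1], q3 = f$iqr[2],
        alpha = f$alpha, alpha_lower = f$alpha_ci[1], alpha_upper = f$alpha_ci[2],
        beta = f$beta, beta_lower = f$beta_ci[1], beta_upper = f$beta_ci[2],
        failure_type = f$failure_type, ad_p = f$ad_p
      )
    }
  }
  table <- dplyr::bind_rows(rows)
  if (nrow(table) == 0) {
    warning("run_tto_analysis: no time-to-onset group to analyse", call. = FALSE)
  }
  readr::write_csv(table, file.path(config$output, sprintf("weibull_tto_%s.csv", lv)),
                   progress = FALSE)
  bp <- tto_boxplot_data(unname(samples))
  bp_flat <- if (nrow(bp) > 0) dplyr::select(bp, -"outliers") else bp
  readr::write_csv(bp_flat, file.path(config$output, sprintf("tto_boxplot_%s.csv", lv)),
                   progress = FALSE)
  if (config$figures && nrow(bp) > 0) {
    days <- dplyr::bind_rows(lapply(samples, function(s) {
      if (length(s$days) == 0) return(NULL)
      tibble::tibble(drug = s$drug, term_id = s$term_id, days = s$days)
    }))
    p <- ggplot2::ggplot(days, ggplot2::aes(x = .data$term_id, y = .data$days)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~drug, scales = "free_x") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "days from treatment initiation") +
      ggplot2::theme_bw()
    grDevices::png(file.path(config$output, sprintf("tto_boxplot_%s.png", lv)),
                   width = 1600, height = 1200, res = 150)
    print(p)
    grDevices::dev.off()
  }
  invisible(list(table = table, boxplot = bp))
}

#' Generate a configured synthetic database on disk
#'
#' Thin wrapper over [generate_srs()] for run configurations with a
#' `synthetic` input block: writes the four tables and the ground-truth
#' JSON under `dir`.
#'
#' @param config a `synthetic_config`, or a `run_config` whose input block
#'   is synthetic.
#' @param dir output directory (defaults to `<output>/synthetic` for a
#'   `run_config`).
#' @return Invisibly, the generated tables and ground truth.
#' @export
simulate_srs <- function(config, dir = NULL) {
  if (inherits(config, "run_config")) {
    if (is.null(config$input$synthetic)) {
      stop("run config has no synthetic input block", call. = FALSE)
    }
    dir <- dir %||% file.path(config$output, "synthetic")
    config <- synthetic_config_from_list(config$input$synthetic,
                                         default_seed = config$seed)
  }
  stopifnot(inherits(config, "synthetic_config"))
  generate_srs(config, dir = dir %||% ".")
}
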