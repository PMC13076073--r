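#' Configure an analysis run
#'
#' Bundles everything one disproportionality study needs: the input database
#' (a [faers_db()] or a directory holding the three-table CSV layout), the
#' synonym map, the analysis window, the endpoint list, the labelled drug
#' queries, and the statistical options forwarded to [signal_stats()].
#'
#' @param db A [faers_db()], or a path to a directory readable by
#'   [read_report_tables()].
#' @param synonyms A synonym map (see [synonym_map()]) or a path to its CSV.
#' @param endpoints List of [endpoint_set()]s, or a path to an endpoint
#'   JSON file (see [read_endpoints()]).
#' @param queries List of [drug_query()]s with unique labels.
#' @param window Closed receipt-date analysis window.
#' @param ic_mode,continuity,evans_metric Forwarded to [signal_stats()].
#' @param output_dir If non-`NULL`, [run_pipeline()] writes `results.csv`,
#'   `forest.csv`, `curation_report.json` and `run_metadata.json` there.
#' @param seed Recorded in the run metadata (the analysis itself is
#'   deterministic).
#' @return A validated `run_config` list.
#' @export
run_config <- function(db, synonyms = default_synonym_map(),
                       endpoints = default_endpoints(),
                       queries = default_queries(),
                       window = c("2003-12-01", "2024-12-31"),
                       ic_mode = "gamma", continuity = FALSE,
                       evans_metric = "ror",
                       output_dir = NULL, seed = NULL) {
  if (is.character(synonyms)) synonyms <- read_synonym_map(synonyms)
  if (is.character(endpoints)) endpoints <- read_endpoints(endpoints)
  if (length(endpoints) == 0) stop("empty endpoint list", call. = FALSE)
  if (length(queries) == 0) stop("empty query list", call. = FALSE)
  stopifnot(all(vapply(endpoints, inherits, TRUE, "endpoint_set")),
            all(vapply(queries, inherits, TRUE, "drug_query")))
  labels <- vapply(queries, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("query labels must be unique", call. = FALSE)
  if (is.character(db) && !dir.exists(db)) {
    stop("input directory does not exist: ", db, call. = FALSE)
  }
  structure(
    list(db = db, synonyms = synonyms, endpoints = endpoints,
         queries = queries, window = as.Date(window),
         ic_mode = ic_mode, continuity = continuity,
         evans_metric = evans_metric, output_dir = output_dir, seed = seed),
    class = "run_config"
  )
}

#' Run the full disproportionality pipeline
#'
#' Orchestrates curation, case selection and signal statistics for every
#' configured (query, endpoint) pair on one shared curated database:
#' one results row per pair, emitted in configuration order. Pairs with no
#' observed case are kept as `NOT_ESTIMABLE` rows rather than dropped -
#' absent-signal reporting is a result, not a gap. Deterministic given
#' identical inputs and configuration.
#'
#' @param config A [run_config()].
#' @return A `pv_run` object: `results` (tibble, one row per pair with the
#'   cells and the full [signal_stats()] panel), `curation` (the
#'   [curation_report()]), `config`. Use [generics::tidy()] /
#'   [generics::glance()] / [ggplot2::autoplot()] on it.
#' @examples
#' sim <- simulate_faers(default_sim_config(5000, seed = 7))
#' run <- run_pipeline(run_config(sim$db))
#' tidy(run)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  db <- config$db
  if (is.character(db)) {
    db <- with_stage("read", read_report_tables(db))
  }
  cur <- with_stage("curation", curate(db, config$synonyms, config$window))

  grid <- tidyr::expand_grid(
    query = config$queries, endpoint = config$endpoints
  )
  cells <- with_stage("query", purrr::pmap(grid, function(query, endpoint) {
    dplyr::mutate(build_contingency(cur$db, query, endpoint),
                  label = query$label, endpoint = endpoint$name,
                  .before = 1)
  }) |> purrr::list_rbind())
  results <- with_stage("stats", signal_stats(
    cells, ic_mode = config$ic_mode, continuity = config$continuity,
    evans_metric = config$evans_metric
  ))

  run <- structure(
    list(results = results, curation = cur$report, config = config),
    class = "pv_run"
  )
  if (!is.null(config$output_dir)) {
    with_stage("export", write_run_outputs(run, config$output_dir))
  }
  run
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  export_results_csv(run$results, file.path(dir, "results.csv"))
  export_forest_data(run$results, file.path(dir, "forest.csv"))
  cr <- run$curation
  jsonlite::write_json(
    list(n_input = cr$n_input, n_excluded_invalid = cr$n_excluded_invalid,
         n_removed_duplicates = cr$n_removed_duplicates,
         n_output = cr$n_output, reasons = cr$reasons),
    file.path(dir, "curation_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  cfg <- run$config
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("pvsignal")),
      window = as.character(cfg$window), ic_mode = cfg$ic_mode,
      continuity = cfg$continuity, evans_metric = cfg$evans_metric,
      seed = cfg$seed,
      queries = lapply(cfg$queries, function(q) {
        list(label = q$label, drugs = q$drugs, mode = q$mode,
             combination = q$combination)
      }),
      endpoints = lapply(cfg$endpoints, function(e) {
        list(name = e$name, terms = e$terms)
      }),
      multiplicity_adjustment = "none (each pair tested at nominal 0.05)"
    ),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

fmt_ratio <- function(x) ifelse(is.na(x), "NE", formatC(x, format = "f", digits = 2))

fmt_p <- function(p) {
  ifelse(is.na(p), "NE",
         ifelse(p < 1e-4, formatC(p, format = "e", digits = 2),
                formatC(p, format = "f", digits = 4)))
}

#' Export the study results table
#'
#' Writes one CSV row per (query, endpoint) pair with fixed column order:
#' label, endpoint, the four cells, ROR with its 95% CI, p, PRR, RRR,
#' chi-square, IC, IC025, the Evans flag and the signal classification.
#' Ratios are rendered with two decimals, p-values in scientific notation
#' below 1e-4, and not-estimable quantities as the literal `NE`.
#'
#' @param results Results tibble (from `run$results` or [signal_stats()]
#'   with `label` and `endpoint` columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_results_csv <- function(results, path) {
  if (nrow(results) == 0) stop("no results to export", call. = FALSE)
  out <- tibble::tibble(
    label = results$label, endpoint = results$endpoint,
    a = results$a, b = results$b, c = results$c, d = results$d,
    ror = fmt_ratio(results$ror),
    ror_ci_low = fmt_ratio(results$ror_ci_low),
    ror_ci_high = fmt_ratio(results$ror_ci_high),
    p_value = fmt_p(results$p_value),
    prr = fmt_ratio(results$prr), rrr = fmt_ratio(results$rrr),
    chi2 = fmt_ratio(results$chi2),
    ic = fmt_ratio(results$ic), ic025 = fmt_ratio(results$ic025),
    evans_met = results$evans_met, classification = results$classification
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Export forest-plot-ready data
#'
#' One record per (query, endpoint) pair: the ROR point estimate with its
#' interval, an `estimable` flag, the reference value (`ror = 1`) and the
#' recommended axis scale. Not-estimable pairs are kept as annotation-only
#' entries (no interval).
#'
#' @inheritParams export_results_csv
#' @return `path`, invisibly.
#' @export
export_forest_data <- function(results, path) {
  if (nrow(results) == 0) stop("no results to export", call. = FALSE)
  out <- tibble::tibble(
    label = results$label, endpoint = results$endpoint,
    ror = results$ror, ci_low = results$ror_ci_low,
    ci_high = results$ror_ci_high,
    estimable = !is.na(results$ror),
    annotation = ifelse(is.na(results$ror), "NE", ""),
    reference = 1, axis_scale = "log10"
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @export
print.pv_run <- function(x, ...) {
  cat("<pv_run> ", length(x$config$queries), " queries x ",
      length(x$config$endpoints), " endpoints on ",
      x$curation$n_output, " curated reports\n", sep = "")
  print(x$results[, c("label", "endpoint", "a", "ror", "p_value",
                      "ic025", "classification")])
  invisible(x)
}
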