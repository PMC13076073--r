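#' Normalize verbatim drug names against a synonym map
#'
#' Adds `normalized_name` and `unresolved` columns to the drug table: each
#' mention's verbatim name is case-folded, trimmed, and looked up in the
#' synonym map (USAN-style canonical names). Verbatims absent from the map
#' keep their case-folded spelling and are flagged `unresolved = TRUE`
#' rather than dropped - unresolved mentions still contribute to background
#' counts, so removing them would silently shrink the comparator population.
#' The operation is idempotent.
#'
#' @param db A [faers_db()].
#' @param map A synonym map from [synonym_map()] / [read_synonym_map()].
#' @return The database with an annotated drug table.
#' @export
normalize_drug_names <- function(db, map) {
  key <- casefold_trim(db$drug$verbatim_name)
  hit <- match(key, map$verbatim)
  db$drug$normalized_name <- ifelse(is.na(hit), key, map$normalized[hit])
  db$drug$unresolved <- is.na(hit)
  db
}

#' Exclude structurally invalid reports
#'
#' Drops reports that are incomplete, structurally invalid, or outside the
#' analysis window: missing receipt date or date outside the closed window;
#' empty drug list; empty reaction list; negative age. Each excluded report
#' is tallied under exactly one reason, assigned in the fixed precedence
#' date, drugs, reactions, demographics, so the exclusion tally is
#' deterministic.
#'
#' @param db A [faers_db()].
#' @param window Length-2 vector of the closed receipt-date window
#'   (coerced with `as.Date()`).
#' @return A list: `db` (retained reports), `report` (a [curation_report()]
#'   with the exclusion tally).
#' @export
validate_records <- function(db, window = c("2003-12-01", "2024-12-31")) {
  window <- as.Date(window)
  stopifnot(length(window) == 2, !anyNA(window))
  demo <- db$demo
  has_drug <- demo$report_id %in% db$drug$report_id
  has_reac <- demo$report_id %in% db$reac$report_id
  reason <- dplyr::case_when(
    is.na(demo$receipt_date) | demo$receipt_date < window[1] |
      demo$receipt_date > window[2] ~ "outside window",
    !has_drug ~ "no drugs",
    !has_reac ~ "no reactions",
    !is.na(demo$age_years) & demo$age_years < 0 ~ "invalid demographics",
    .default = NA_character_
  )
  keep <- is.na(reason)
  kept_ids <- demo$report_id[keep]
  out <- faers_db(
    demo[keep, ],
    db$drug[db$drug$report_id %in% kept_ids, ],
    db$reac[db$reac$report_id %in% kept_ids, ]
  )
  tally <- dplyr::count(
    tibble::tibble(reason = reason[!keep]), .data$reason, name = "n"
  )
  rep <- curation_report(
    n_input = nrow(demo), n_excluded_invalid = sum(!keep),
    n_removed_duplicates = 0L, n_output = sum(keep), reasons = tally
  )
  list(db = out, report = rep)
}

#' Remove duplicate cases
#'
#' Groups validated reports by a duplicate key and keeps exactly one report
#' per group. The key is the `case_id` when it is shared by several reports
#' (versions of one case); otherwise the tuple (sex, age rounded to whole
#' years, country, sorted normalized drug names, sorted case-folded reaction
#' terms) - the demographic and case-level variables a re-submission
#' preserves. Within a group the report with the latest receipt date wins,
#' ties broken by the lexicographically smallest `report_id`.
#'
#' @param db A validated, name-normalized [faers_db()].
#' @return A list: `db` (deduplicated), `report` (a [curation_report()]),
#'   and `removed` - a tibble mapping each removed `report_id` to the
#'   `kept_report_id` of its group, for audit against ground truth.
#' @export
deduplicate <- function(db) {
  demo <- db$demo
  if (is.null(db$drug$normalized_name)) {
    stop("run normalize_drug_names() before deduplicate()", call. = FALSE)
  }
  sep <- "\x1f"
  drug_key <- db$drug |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      k = paste(sort(unique(.data$normalized_name)), collapse = sep)
    )
  reac_key <- db$reac |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      k = paste(sort(unique(casefold_trim(.data$preferred_term))),
                collapse = sep)
    )
  tuple <- paste(
    demo$sex, round(demo$age_years), demo$country,
    drug_key$k[match(demo$report_id, drug_key$report_id)],
    reac_key$k[match(demo$report_id, reac_key$report_id)],
    sep = sep
  )
  shared_case <- demo$case_id %in% demo$case_id[duplicated(demo$case_id)]
  key <- ifelse(shared_case & !is.na(demo$case_id),
                paste0("case", sep, demo$case_id),
                paste0("tuple", sep, tuple))

  ord <- order(key, demo$receipt_date, demo$report_id,
               decreasing = c(FALSE, TRUE, FALSE), method = "radix")
  keep_first <- !duplicated(key[ord])
  keep <- logical(nrow(demo)); keep[ord[keep_first]] <- TRUE

  kept_of_key <- stats::setNames(demo$report_id[ord[keep_first]],
                                 key[ord[keep_first]])
  removed <- tibble::tibble(
    report_id = demo$report_id[!keep],
    kept_report_id = unname(kept_of_key[key[!keep]]),
    key_type = ifelse(startsWith(key[!keep], "case"), "case_id", "tuple")
  )
  kept_ids <- demo$report_id[keep]
  out <- faers_db(
    demo[keep, ],
    db$drug[db$drug$report_id %in% kept_ids, ],
    db$reac[db$reac$report_id %in% kept_ids, ]
  )
  rep <- curation_report(
    n_input = nrow(demo), n_excluded_invalid = 0L,
    n_removed_duplicates = sum(!keep), n_output = sum(keep),
    reasons = tibble::tibble(reason = character(), n = integer())
  )
  list(db = out, report = rep, removed = removed)
}

#' Run the full curation chain
#'
#' Name normalization, structural validation against the analysis window,
#' then case deduplication. The combined curation report satisfies the
#' conservation identity
#' `n_input = n_output + n_excluded_invalid + n_removed_duplicates`.
#'
#' @inheritParams normalize_drug_names
#' @inheritParams validate_records
#' @return A list: `db` (curated database), `report` (combined
#'   [curation_report()]), `removed` (dedup audit table).
#' @examples
#' sim <- simulate_faers(default_sim_config(1000, duplicate_rate = 0.05,
#'                                          invalid_rate = 0.02, seed = 1))
#' cur <- curate(sim$db, default_synonym_map())
#' cur$report
#' @export
curate <- function(db, map, window = c("2003-12-01", "2024-12-31")) {
  db <- normalize_drug_names(db, map)
  val <- validate_records(db, window)
  ded <- deduplicate(val$db)
  rep <- curation_report(
    n_input = val$report$n_input,
    n_excluded_invalid = val$report$n_excluded_invalid,
    n_removed_duplicates = ded$report$n_removed_duplicates,
    n_output = ded$report$n_output,
    reasons = val$report$reasons
  )
  list(db = ded$db, report = rep, removed = ded$removed)
}

#' Curation accounting
#'
#' Counts of reports entering and leaving the curation chain, with the
#' exclusion-reason tally. Always satisfies
#' `n_input = n_output + n_excluded_invalid + n_removed_duplicates`.
#'
#' @param n_input,n_excluded_invalid,n_removed_duplicates,n_output Counts.
#' @param reasons Tibble tallying exclusion reasons.
#' @return A `curation_report` list.
#' @export
curation_report <- function(n_input, n_excluded_invalid,
                            n_removed_duplicates, n_output, reasons) {
  stopifnot(n_input == n_output + n_excluded_invalid + n_removed_duplicates)
  structure(
    list(n_input = n_input, n_excluded_invalid = n_excluded_invalid,
         n_removed_duplicates = n_removed_duplicates, n_output = n_output,
         reasons = reasons),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n",
      "  input:              ", x$n_input, "\n",
      "  excluded (invalid): ", x$n_excluded_invalid, "\n",
      "  removed (dupes):    ", x$n_removed_duplicates, "\n",
      "  output:             ", x$n_output, "\n", sep = "")
  if (nrow(x$reasons)) {
    for (i in seq_len(nrow(x$reasons))) {
      cat("    - ", x$reasons$reason[i], ": ", x$reasons$n[i], "\n", sep = "")
    }
  }
  invisible(x)
}
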