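#' Define a drug query
#'
#' A drug query fixes the exposed (case) side of the 2x2 table: a set of
#' normalized drug names plus a role-filter mode. `"primary_suspect"`
#' restricts membership to reports naming one of the query drugs as the
#' primary suspect (PS) - the attribution-focused design. `"any_role"`
#' accepts the drug in any role (PS, SS, concomitant, interacting), the
#' sensitivity-maximising design used for co-reporting queries. With
#' `combination = TRUE` every query drug must appear on the report (in any
#' role), so combination queries require `mode = "any_role"`.
#'
#' @param drugs Non-empty character vector of normalized drug names.
#' @param mode `"primary_suspect"` or `"any_role"`.
#' @param combination If `TRUE`, all listed drugs must co-occur on a report.
#' @param label Display label; defaults to the drug names joined with `+`.
#' @return A `drug_query` list.
#' @export
drug_query <- function(drugs, mode = c("primary_suspect", "any_role"),
                       combination = FALSE, label = NULL) {
  mode <- match.arg(mode)
  drugs <- unique(casefold_trim(drugs))
  if (length(drugs) == 0 || any(!nzchar(drugs))) {
    stop("query needs at least one non-empty drug name", call. = FALSE)
  }
  if (combination && mode != "any_role") {
    stop("combination queries must use mode = \"any_role\"", call. = FALSE)
  }
  structure(
    list(drugs = drugs, mode = mode, combination = isTRUE(combination),
         label = label %||% paste(drugs, collapse = "+")),
    class = "drug_query"
  )
}

#' Define an outcome endpoint
#'
#' An endpoint is an outcome label plus the non-empty set of MedDRA
#' preferred terms that count toward it. Matching is exact string equality
#' after case-folding and whitespace trimming - no MedDRA hierarchy
#' expansion.
#'
#' @param name Outcome label.
#' @param terms Character vector of preferred terms.
#' @return An `endpoint_set` list.
#' @export
endpoint_set <- function(name, terms) {
  terms <- unique(casefold_trim(terms))
  if (length(terms) == 0 || any(!nzchar(terms))) {
    stop("endpoint needs at least one non-empty preferred term", call. = FALSE)
  }
  structure(list(name = name, terms = terms), class = "endpoint_set")
}

#' Which reports match a drug query?
#'
#' Report-level (not mention-level) evaluation: a report with the query drug
#' listed twice counts once.
#'
#' @param db A curated [faers_db()] with normalized drug names.
#' @param query A [drug_query()].
#' @return Logical vector aligned with the rows of `db$demo`.
#' @export
report_matches_query <- function(db, query) {
  stopifnot(inherits(query, "drug_query"))
  drug <- db$drug
  if (is.null(drug$normalized_name)) {
    stop("drug names are not normalized; run normalize_drug_names()",
         call. = FALSE)
  }
  ids <- db$demo$report_id
  if (query$mode == "primary_suspect") {
    hit <- drug$role == "PS" & drug$normalized_name %in% query$drugs
    ids %in% drug$report_id[hit]
  } else if (query$combination) {
    per_drug <- lapply(query$drugs, function(dg) {
      ids %in% drug$report_id[drug$normalized_name == dg]
    })
    Reduce(`&`, per_drug)
  } else {
    ids %in% drug$report_id[drug$normalized_name %in% query$drugs]
  }
}

#' Which reports match an endpoint?
#'
#' True for reports whose reaction set intersects the endpoint's preferred
#' terms (case-folded, trimmed).
#'
#' @param db A curated [faers_db()].
#' @param endpoint An [endpoint_set()].
#' @return Logical vector aligned with the rows of `db$demo`.
#' @export
report_matches_endpoint <- function(db, endpoint) {
  stopifnot(inherits(endpoint, "endpoint_set"))
  hit <- casefold_trim(db$reac$preferred_term) %in% endpoint$terms
  db$demo$report_id %in% db$reac$report_id[hit]
}

#' Build the 2x2 contingency table for a (query, endpoint) pair
#'
#' Partitions the curated database into the four cells every
#' disproportionality statistic consumes: `a` (query and endpoint), `b`
#' (query only), `c` (endpoint only), `d` (neither). Each report is counted
#' exactly once, and the comparator is all other reports in the curated
#' database - no restriction to a comparator drug class.
#'
#' @inheritParams report_matches_query
#' @inheritParams report_matches_endpoint
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @examples
#' sim <- simulate_faers(default_sim_config(2000, seed = 3))
#' db <- normalize_drug_names(sim$db, default_synonym_map())
#' build_contingency(db, drug_query("lithium"),
#'                   endpoint_set("AKI", "Acute kidney injury"))
#' @export
build_contingency <- function(db, query, endpoint) {
  if (nrow(db$demo) == 0) stop("empty database", call. = FALSE)
  q <- report_matches_query(db, query)
  e <- report_matches_endpoint(db, endpoint)
  tibble::tibble(
    a = sum(q & e), b = sum(q & !e), c = sum(!q & e), d = sum(!q & !e)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
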