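#' Study-shaped defaults: catalogs, endpoints, queries
#'
#' These objects encode the worked example the package ships: a mood
#' stabiliser with strongly elevated renal adverse-event reporting
#' (lithium), a GLP-1 receptor agonist with inverse renal reporting
#' (semaglutide), a handful of high-volume background drugs, and the five
#' renal MedDRA preferred terms used as outcome endpoints. The planted
#' odds multipliers in [default_effects()] mirror the reporting-odds
#' pattern such a pharmacovigilance study observes: theta well above 1 on
#' every renal endpoint for the nephrotoxic drug, theta at or below 1 for
#' the comparator.
#'
#' Baseline probabilities are per-report reaction frequencies typical of a
#' large spontaneous-report database (renal terms 0.4-3%, common
#' non-specific terms 5-12%); marketing probabilities put the two study
#' drugs on roughly 1% of reports so that study-sized simulations yield
#' hundreds of cases per endpoint.
#'
#' @return `default_drug_catalog()` / `default_event_catalog()`: tibbles in
#'   the [sim_config()] catalog layout. `default_effects()`: the planted
#'   effect table. `default_endpoints()`: list of [endpoint_set()]s.
#'   `default_queries()`: list of [drug_query()]s (primary-suspect queries
#'   for each study drug; the combination queried in any role).
#'   `default_synonym_map()`: synonym map covering every catalog alias.
#' @name study_defaults
NULL

#' @rdname study_defaults
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    name = c("lithium", "semaglutide", "metformin", "sertraline",
             "ibuprofen", "amlodipine", "omeprazole", "atorvastatin"),
    aliases = list(
      c("lithium", "LITHIUM CARBONATE", "Eskalith", "Lithobid",
        "lithium citrate"),
      c("semaglutide", "OZEMPIC", "WEGOVY", "RYBELSUS"),
      c("metformin", "GLUCOPHAGE", "metformin hydrochloride"),
      c("sertraline", "ZOLOFT", "sertraline hcl"),
      c("ibuprofen", "ADVIL", "MOTRIN"),
      c("amlodipine", "NORVASC", "amlodipine besylate"),
      c("omeprazole", "PRILOSEC"),
      c("atorvastatin", "LIPITOR", "atorvastatin calcium")
    ),
    marketing_prob = c(0.010, 0.008, 0.050, 0.040,
                       0.080, 0.050, 0.060, 0.060)
  )
}

#' @rdname study_defaults
#' @export
default_event_catalog <- function() {
  tibble::tibble(
    term = c("Acute kidney injury", "Renal failure", "Renal impairment",
             "Chronic kidney disease", "End stage renal disease",
             "Nausea", "Headache", "Dizziness", "Fatigue",
             "Diarrhoea", "Vomiting", "Rash"),
    baseline_prob = c(0.030, 0.020, 0.015, 0.012, 0.004,
                      0.120, 0.100, 0.080, 0.080, 0.070, 0.060, 0.050)
  )
}

#' @rdname study_defaults
#' @export
default_effects <- function() {
  renal <- c("Renal impairment", "Renal failure", "Chronic kidney disease",
             "End stage renal disease", "Acute kidney injury")
  tibble::tibble(
    drug = rep(c("lithium", "semaglutide"), each = 5),
    term = rep(renal, 2),
    theta = c(5.0, 4.0, 8.0, 9.5, 8.0,     # nephrotoxic pattern
              0.54, 0.51, 0.42, 0.25, 0.96) # inverse/neutral pattern
  )
}

#' @rdname study_defaults
#' @param n_reports,seed,duplicate_rate,invalid_rate,effects Forwarded to
#'   [sim_config()]; contamination defaults (5% near-duplicates, 2% invalid
#'   copies) are fixture choices representative of raw spontaneous-report
#'   extracts.
#' @export
default_sim_config <- function(n_reports = 50000, seed = 1L,
                               duplicate_rate = 0, invalid_rate = 0,
                               effects = default_effects()) {
  sim_config(
    n_reports = n_reports,
    drug_catalog = default_drug_catalog(),
    event_catalog = default_event_catalog(),
    effects = effects,
    duplicate_rate = duplicate_rate, invalid_rate = invalid_rate,
    seed = seed
  )
}

#' @rdname study_defaults
#' @export
default_synonym_map <- function() {
  cat <- default_drug_catalog()
  synonym_map(tibble::tibble(
    verbatim = unlist(cat$aliases),
    normalized = rep(cat$name, lengths(cat$aliases))
  ))
}

#' @rdname study_defaults
#' @export
default_endpoints <- function() {
  list(
    endpoint_set("Renal impairment", "Renal impairment"),
    endpoint_set("Renal failure", "Renal failure"),
    endpoint_set("Chronic kidney disease", "Chronic kidney disease"),
    endpoint_set("End-stage renal disease", "End stage renal disease"),
    endpoint_set("Acute kidney injury", "Acute kidney injury")
  )
}

#' @rdname study_defaults
#' @export
default_queries <- function() {
  list(
    drug_query("lithium", mode = "primary_suspect", label = "lithium"),
    drug_query("semaglutide", mode = "primary_suspect", label = "semaglutide"),
    drug_query(c("lithium", "semaglutide"), mode = "any_role",
               combination = TRUE, label = "lithium+semaglutide")
  )
}
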