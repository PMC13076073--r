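# Hand-enumerated six-report database: two lithium-PS reports (one with
# AKI), one semaglutide-PS report without AKI, three other-drug reports
# (one with AKI). Against the lithium PS-only query and the AKI endpoint
# the cells are (a, b, c, d) = (1, 1, 1, 3) by direct count.
toy_db <- function() {
  demo <- tibble::tibble(
    report_id = sprintf("T%02d", 1:6),
    case_id = sprintf("K%02d", 1:6),
    receipt_date = as.Date("2020-01-01") + 0:5,
    age_years = c(40, 55, 60, 35, 70, 28),
    sex = c("F", "M", "F", "M", "F", "U"),
    country = "US"
  )
  drug <- tibble::tibble(
    report_id = c("T01", "T02", "T03", "T04", "T05", "T06"),
    verbatim_name = c("lithium", "LITHIUM CARBONATE", "OZEMPIC",
                      "ibuprofen", "metformin", "sertraline"),
    role = c("PS", "PS", "PS", "PS", "PS", "PS")
  )
  reac <- tibble::tibble(
    report_id = c("T01", "T02", "T03", "T04", "T05", "T06"),
    preferred_term = c("Acute kidney injury", "Nausea", "Headache",
                       "Acute kidney injury", "Rash", "Dizziness")
  )
  normalize_drug_names(faers_db(demo, drug, reac), default_synonym_map())
}

aki_endpoint <- function() endpoint_set("Acute kidney injury",
                                        "Acute kidney injury")

# single-effect configuration used by the recovery checks: theta planted on
# one drug-endpoint pair, no contamination
recovery_config <- function(n_reports, theta, seed) {
  default_sim_config(
    n_reports = n_reports, seed = seed,
    effects = data.frame(drug = "lithium", term = "Acute kidney injury",
                         theta = theta)
  )
}

# slow but transparent recount of the four cells, record by record
naive_contingency <- function(db, query, endpoint) {
  out <- c(a = 0, b = 0, c = 0, d = 0)
  for (id in db$demo$report_id) {
    dg <- db$drug[db$drug$report_id == id, ]
    rc <- db$reac[db$reac$report_id == id, ]
    q <- switch(query$mode,
      primary_suspect = any(dg$role == "PS" & dg$normalized_name %in% query$drugs),
      any_role = if (query$combination) {
        all(query$drugs %in% dg$normalized_name)
      } else {
        any(dg$normalized_name %in% query$drugs)
      }
    )
    e <- any(tolower(trimws(rc$preferred_term)) %in% endpoint$terms)
    cell <- if (q && e) "a" else if (q) "b" else if (e) "c" else "d"
    out[cell] <- out[cell] + 1
  }
  out
}
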