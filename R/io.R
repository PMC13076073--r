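#' Write a report database to the three-table CSV layout
#'
#' Emits `demo.csv`, `drug.csv` and `reac.csv` (UTF-8, header row, RFC-4180
#' quoting) into `path`, the on-disk exchange format the curation reader
#' consumes. Dates are written as ISO 8601.
#'
#' @param db A [faers_db()] (or plain list with `demo`, `drug`, `reac`).
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_report_tables <- function(db, path) {
  stopifnot(all(c("demo", "drug", "reac") %in% names(db)))
  if (nrow(db$demo) == 0) stop("refusing to write an empty database", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(db$demo, file.path(path, "demo.csv"), na = "")
  readr::write_csv(db$drug, file.path(path, "drug.csv"), na = "")
  readr::write_csv(db$reac, file.path(path, "reac.csv"), na = "")
  invisible(path)
}

#' Read a report database from the three-table CSV layout
#'
#' Reads `demo.csv`, `drug.csv` and `reac.csv` from `path` and bundles them
#' as a [faers_db()], sorted by `report_id`. Reports present in `demo` but
#' absent from the drug or reaction tables simply have no rows there; they
#' are flagged later by [validate_records()]. A `report_id` duplicated in
#' `demo.csv` is a parse error.
#'
#' @param path Directory containing the three CSVs.
#' @return A `faers_db`.
#' @export
read_report_tables <- function(path) {
  need <- file.path(path, c("demo.csv", "drug.csv", "reac.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing input table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  demo <- readr::read_csv(
    need[1],
    col_types = readr::cols(
      report_id = readr::col_character(), case_id = readr::col_character(),
      receipt_date = readr::col_date(), age_years = readr::col_double(),
      sex = readr::col_character(), country = readr::col_character()
    )
  )
  drug <- readr::read_csv(
    need[2],
    col_types = readr::cols(report_id = readr::col_character(),
                            verbatim_name = readr::col_character(),
                            role = readr::col_character())
  )
  reac <- readr::read_csv(
    need[3],
    col_types = readr::cols(report_id = readr::col_character(),
                            preferred_term = readr::col_character())
  )
  for (tb in list(demo, drug, reac)) {
    pr <- readr::problems(tb)
    if (nrow(pr)) {
      stop("malformed row(s): ", paste(utils::capture.output(print(pr)),
                                       collapse = "\n"), call. = FALSE)
    }
  }
  if (anyDuplicated(demo$report_id)) {
    dup <- demo$report_id[duplicated(demo$report_id)][1]
    stop("duplicate report_id in demo.csv: ", dup, call. = FALSE)
  }
  bad_role <- setdiff(unique(drug$role), c("PS", "SS", "C", "I"))
  if (length(bad_role)) {
    stop("drug.csv contains unknown role code(s): ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  faers_db(
    demo[order(demo$report_id), ],
    drug[order(drug$report_id), ],
    reac[order(reac$report_id), ]
  )
}

#' Read a drug-synonym map
#'
#' Two-column CSV `verbatim,normalized` mapping case-folded verbatim strings
#' (brand names, abbreviations, salt forms) to canonical names. Keys are
#' case-folded and trimmed on read; canonical names are added as identity
#' entries if absent, so the map always maps canonical names to themselves.
#'
#' @param path CSV file path.
#' @return A tibble with columns `verbatim`, `normalized`.
#' @export
read_synonym_map <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(
    verbatim = readr::col_character(), normalized = readr::col_character()
  ))
  synonym_map(map)
}

#' @rdname read_synonym_map
#' @param map A data frame with columns `verbatim`, `normalized`.
#' @export
synonym_map <- function(map) {
  stopifnot(all(c("verbatim", "normalized") %in% names(map)))
  map <- tibble::tibble(
    verbatim = casefold_trim(map$verbatim),
    normalized = casefold_trim(map$normalized)
  )
  canon <- unique(map$normalized)
  map <- dplyr::bind_rows(
    map, tibble::tibble(verbatim = canon, normalized = canon)
  )
  map <- dplyr::distinct(map)
  if (anyDuplicated(map$verbatim)) {
    stop("synonym map is not functional: one verbatim maps to two names",
         call. = FALSE)
  }
  map
}

#' Read endpoint definitions
#'
#' Endpoint definitions are JSON: either one object `{"name": ..., "terms":
#' [...]}` or an array of such objects. Each endpoint names an outcome and
#' the MedDRA preferred terms that count toward it.
#'
#' @param path JSON file path.
#' @return A list of [endpoint_set()] objects.
#' @export
read_endpoints <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) {
      endpoint_set(x$name[i], unlist(x$terms[i]))
    })
  } else {
    list(endpoint_set(x$name, unlist(x$terms)))
  }
}

casefold_trim <- function(x) tolower(trimws(x))
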