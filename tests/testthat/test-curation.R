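test_that("drug-name normalization maps brands and flags unknowns", {
  map <- synonym_map(data.frame(
    verbatim = c("ozempic", "semaglutide"),
    normalized = c("semaglutide", "semaglutide")
  ))
  db <- faers_db(
    tibble::tibble(report_id = "R1", case_id = "C1",
                   receipt_date = as.Date("2020-01-01"),
                   age_years = 40, sex = "F", country = "US"),
    tibble::tibble(report_id = rep("R1", 3),
                   verbatim_name = c("OZEMPIC", "semaglutide", "xyzzy-999"),
                   role = c("PS", "SS", "C")),
    tibble::tibble(report_id = "R1", preferred_term = "Nausea")
  )
  norm <- normalize_drug_names(db, map)
  expect_equal(norm$drug$normalized_name,
               c("semaglutide", "semaglutide", "xyzzy-999"))
  expect_equal(norm$drug$unresolved, c(FALSE, FALSE, TRUE))
  # idempotent
  expect_identical(normalize_drug_names(norm, map)$drug, norm$drug)
})

test_that("a synonym map with conflicting entries is rejected", {
  expect_error(
    synonym_map(data.frame(verbatim = c("x", "X "),
                           normalized = c("drug1", "drug2"))),
    "functional"
  )
})

test_that("validation excludes by the fixed reason precedence", {
  mk_demo <- function(id, date, age = 40) {
    tibble::tibble(report_id = id, case_id = paste0("c", id),
                   receipt_date = as.Date(date), age_years = age,
                   sex = "F", country = "US")
  }
  demo <- dplyr::bind_rows(
    mk_demo("R1", "2020-05-01"),              # valid
    mk_demo("R2", "2002-05-01"),              # before window
    mk_demo("R3", NA),                        # missing date
    mk_demo("R4", "2020-05-01"),              # no drugs
    mk_demo("R5", "2020-05-01"),              # no reactions
    mk_demo("R6", "2020-05-01", age = -3),    # negative age
    mk_demo("R7", "2002-05-01", age = -3)     # date wins over demographics
  )
  drug <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R5", "R6", "R7"),
    verbatim_name = "lithium", role = "PS", normalized_name = "lithium",
    unresolved = FALSE
  )
  reac <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R4", "R6", "R7"),
    preferred_term = "Nausea"
  )
  val <- validate_records(faers_db(demo, drug, reac),
                          window = c("2003-12-01", "2024-12-31"))
  expect_equal(val$db$demo$report_id, "R1")
  rep <- val$report
  expect_equal(rep$n_input, 7)
  expect_equal(rep$n_output, 1)
  expect_equal(rep$n_excluded_invalid, 6)
  tally <- setNames(rep$reasons$n, rep$reasons$reason)
  expect_equal(tally[["outside window"]], 3) # R2, R3, R7
  expect_equal(tally[["no drugs"]], 1)
  expect_equal(tally[["no reactions"]], 1)
  expect_equal(tally[["invalid demographics"]], 1)
})

test_that("deduplication keeps the latest report, ids breaking ties", {
  demo <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R4"),
    case_id = c("c1", "c2", "c3", "c4"),
    receipt_date = as.Date(c("2020-01-01", "2020-01-15",
                             "2021-06-01", "2021-06-01")),
    age_years = c(40, 40, 60, 60), sex = c("F", "F", "M", "M"),
    country = "US"
  )
  drug <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R4"),
    verbatim_name = "lithium", role = "PS",
    normalized_name = "lithium", unresolved = FALSE
  )
  reac <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R4"),
    preferred_term = "Nausea"
  )
  ded <- deduplicate(faers_db(demo, drug, reac))
  # R1/R2 same tuple: latest (R2) kept; R3/R4 tie on date: smallest id kept
  expect_setequal(ded$db$demo$report_id, c("R2", "R3"))
  expect_equal(ded$report$n_removed_duplicates, 2)
  expect_equal(ded$removed$kept_report_id[ded$removed$report_id == "R1"], "R2")
  expect_equal(ded$removed$kept_report_id[ded$removed$report_id == "R4"], "R3")
})

test_that("records differing in one reaction under distinct cases both survive", {
  demo <- tibble::tibble(
    report_id = c("R1", "R2"), case_id = c("c1", "c2"),
    receipt_date = as.Date("2020-01-01"), age_years = 40, sex = "F",
    country = "US"
  )
  drug <- tibble::tibble(report_id = c("R1", "R2"), verbatim_name = "lithium",
                         role = "PS", normalized_name = "lithium",
                         unresolved = FALSE)
  reac <- tibble::tibble(report_id = c("R1", "R1", "R2"),
                         preferred_term = c("Nausea", "Rash", "Nausea"))
  ded <- deduplicate(faers_db(demo, drug, reac))
  expect_equal(nrow(ded$db$demo), 2)
})

test_that("a shared case_id groups versions of one case", {
  demo <- tibble::tibble(
    report_id = c("R1", "R2"), case_id = c("cX", "cX"),
    receipt_date = as.Date(c("2020-01-01", "2020-03-01")),
    age_years = c(40, 41), sex = c("F", "F"), country = c("US", "CA")
  )
  drug <- tibble::tibble(report_id = c("R1", "R2"), verbatim_name = "lithium",
                         role = "PS", normalized_name = "lithium",
                         unresolved = FALSE)
  reac <- tibble::tibble(report_id = c("R1", "R2"),
                         preferred_term = c("Nausea", "Rash"))
  ded <- deduplicate(faers_db(demo, drug, reac))
  expect_equal(ded$db$demo$report_id, "R2") # latest version wins
  expect_equal(ded$removed$key_type, "case_id")
})

test_that("curation conserves records and is idempotent and order-invariant", {
  sim <- simulate_faers(default_sim_config(3000, seed = 31,
                                           duplicate_rate = 0.05,
                                           invalid_rate = 0.02))
  map <- default_synonym_map()
  cur <- curate(sim$db, map)
  rep <- cur$report
  expect_equal(rep$n_input,
               rep$n_output + rep$n_excluded_invalid + rep$n_removed_duplicates)
  # idempotence: curating the curated database removes nothing further
  cur2 <- curate(cur$db, map)
  expect_equal(cur2$report$n_output, rep$n_output)
  expect_identical(sort(cur2$db$demo$report_id), sort(cur$db$demo$report_id))
  # order invariance: shuffling input rows leaves the retained set unchanged
  set.seed(1)
  shuf <- faers_db(
    sim$db$demo[sample(nrow(sim$db$demo)), ],
    sim$db$drug[sample(nrow(sim$db$drug)), ],
    sim$db$reac[sample(nrow(sim$db$reac)), ]
  )
  cur3 <- curate(shuf, map)
  expect_identical(sort(cur3$db$demo$report_id), sort(cur$db$demo$report_id))
})

test_that("every injected clone is caught; extra removals are true collisions", {
  sim <- simulate_faers(default_sim_config(2000, seed = 41,
                                           duplicate_rate = 0.05))
  cur <- curate(sim$db, default_synonym_map())
  tr <- sim$truth$reports
  clones <- tr$report_id[!is.na(tr$is_duplicate_of)]
  gone <- cur$removed$report_id
  # recall: each clone pair lost exactly one member to dedup
  pair_hit <- vapply(clones, function(cl) {
    src <- tr$is_duplicate_of[tr$report_id == cl]
    cl %in% gone || src %in% gone
  }, logical(1))
  expect_true(all(pair_hit))
  expect_equal(sum(pair_hit), round(0.05 * 2000))
  # precision: any removed report not explained by an injected clone must be
  # a genuine key collision - same demographics, drugs and reactions as the
  # record kept in its place
  flagged <- union(clones, tr$is_duplicate_of[!is.na(tr$is_duplicate_of)])
  unexplained <- cur$removed[!cur$removed$report_id %in% flagged, ]
  db <- normalize_drug_names(sim$db, default_synonym_map())
  for (i in seq_len(nrow(unexplained))) {
    lost <- unexplained$report_id[i]
    kept <- unexplained$kept_report_id[i]
    d1 <- db$demo[db$demo$report_id == lost, ]
    d2 <- db$demo[db$demo$report_id == kept, ]
    expect_identical(d1[c("sex", "country")], d2[c("sex", "country")],
                     ignore_attr = TRUE)
    key <- function(tb, id, col) sort(unique(tb[[col]][tb$report_id == id]))
    expect_identical(key(db$drug, lost, "normalized_name"),
                     key(db$drug, kept, "normalized_name"))
    expect_identical(key(db$reac, lost, "preferred_term"),
                     key(db$reac, kept, "preferred_term"))
  }
})

test_that("reading rejects a demo table with duplicated report ids", {
  dir <- withr::local_tempdir()
  sim <- simulate_faers(default_sim_config(20, seed = 2))
  db <- sim$db
  db$demo <- dplyr::bind_rows(db$demo, db$demo[1, ])
  readr::write_csv(db$demo, file.path(dir, "demo.csv"))
  readr::write_csv(db$drug, file.path(dir, "drug.csv"))
  readr::write_csv(db$reac, file.path(dir, "reac.csv"))
  expect_error(read_report_tables(dir), "duplicate report_id")
  expect_error(read_report_tables(withr::local_tempdir()), "missing input")
})
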