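test_that("contamination disabled yields exactly n clean reports", {
  cfg <- default_sim_config(100, seed = 7)
  sim <- simulate_faers(cfg)
  expect_equal(nrow(sim$db$demo), 100)
  expect_true(all(is.na(sim$truth$reports$is_duplicate_of)))
  expect_false(any(sim$truth$reports$is_invalid))
  # every primary report is structurally valid
  expect_true(all(sim$db$demo$report_id %in% sim$db$drug$report_id))
  expect_true(all(sim$db$demo$report_id %in% sim$db$reac$report_id))
})

test_that("the same seed reproduces the database byte for byte", {
  cfg <- default_sim_config(500, seed = 13, duplicate_rate = 0.04,
                            invalid_rate = 0.02)
  s1 <- simulate_faers(cfg)
  s2 <- simulate_faers(cfg)
  expect_identical(s1$db$demo, s2$db$demo)
  expect_identical(s1$db$drug, s2$db$drug)
  expect_identical(s1$db$reac, s2$db$reac)
  expect_identical(s1$truth$reports, s2$truth$reports)
  # and a different seed does not
  s3 <- simulate_faers(default_sim_config(500, seed = 14,
                                          duplicate_rate = 0.04,
                                          invalid_rate = 0.02))
  expect_false(identical(s1$db$demo, s3$db$demo))
})

test_that("contamination counts equal the rounded configured fractions", {
  cfg <- default_sim_config(1000, seed = 3, duplicate_rate = 0.053,
                            invalid_rate = 0.021)
  sim <- simulate_faers(cfg)
  tr <- sim$truth$reports
  expect_equal(sum(!is.na(tr$is_duplicate_of)), round(0.053 * 1000))
  expect_equal(sum(tr$is_invalid), round(0.021 * 1000))
  expect_equal(nrow(sim$db$demo), 1000 + 53 + 21)
  # duplicate pointers reference existing originals
  expect_true(all(stats::na.omit(tr$is_duplicate_of) %in% tr$report_id))
  # clones match their source on demographics, drugs and reactions
  dup <- tr[!is.na(tr$is_duplicate_of), ]
  demo <- sim$db$demo
  for (i in seq_len(nrow(dup))) {
    clone <- demo[demo$report_id == dup$report_id[i], ]
    src <- demo[demo$report_id == dup$is_duplicate_of[i], ]
    expect_identical(clone[c("age_years", "sex", "country")],
                     src[c("age_years", "sex", "country")])
    shift <- as.integer(clone$receipt_date - src$receipt_date)
    expect_true(shift >= 0 && shift <= 30)
    key <- function(tb, id, col) sort(tb[[col]][tb$report_id == id])
    expect_identical(key(sim$db$drug, clone$report_id, "verbatim_name"),
                     key(sim$db$drug, src$report_id, "verbatim_name"))
    expect_identical(key(sim$db$reac, clone$report_id, "preferred_term"),
                     key(sim$db$reac, src$report_id, "preferred_term"))
  }
  # invalid copies are genuinely corrupted
  inv_ids <- tr$report_id[tr$is_invalid]
  corrupted <- vapply(inv_ids, function(id) {
    !id %in% sim$db$drug$report_id ||
      !id %in% sim$db$reac$report_id ||
      (!is.na(demo$age_years[demo$report_id == id]) &&
         demo$age_years[demo$report_id == id] < 0)
  }, logical(1))
  expect_true(all(corrupted))
})

test_that("each report carries exactly one primary-suspect drug", {
  sim <- simulate_faers(default_sim_config(2000, seed = 5))
  ps_per_report <- table(sim$db$drug$report_id[sim$db$drug$role == "PS"])
  expect_true(all(ps_per_report == 1))
  expect_equal(length(ps_per_report), 2000)
  expect_true(all(sim$db$drug$role %in% c("PS", "SS", "C", "I")))
})

test_that("catalog event frequencies are Bernoulli-calibrated under the null", {
  n <- 50000
  sim <- simulate_faers(default_sim_config(n, seed = 21, effects = NULL))
  events <- default_event_catalog()
  hits <- table(factor(sim$db$reac$preferred_term, levels = events$term))
  freq <- as.numeric(hits) / n
  se <- sqrt(events$baseline_prob * (1 - events$baseline_prob) / n)
  expect_true(all(abs(freq - events$baseline_prob) <= 3 * se))
})

test_that("raising a planted odds multiplier raises the mean ROR estimate", {
  mean_ror <- function(theta, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_faers(recovery_config(10000, theta, seed = s))
      db <- normalize_drug_names(sim$db, default_synonym_map())
      ct <- build_contingency(db, drug_query("lithium", mode = "any_role"),
                              aki_endpoint())
      # pool across seeds on the log scale; skip inestimable draws
      log(ror_with_ci(ct$a, ct$b, ct$c, ct$d)$ror)
    }, numeric(1)), na.rm = TRUE)
  }
  seeds <- 1:50
  m <- vapply(c(1, 3, 8), mean_ror, numeric(1), seeds = seeds)
  expect_true(all(diff(m) > 0))
})

test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(default_sim_config(0), "n_reports")
  expect_error(default_sim_config(10, duplicate_rate = 0.6, invalid_rate = 0.5),
               "sum below 1")
  expect_error(
    sim_config(10, drug_catalog = default_drug_catalog(),
               event_catalog = default_event_catalog(),
               effects = data.frame(drug = "nope", term = "Nausea", theta = 2)),
    "absent from drug_catalog"
  )
  expect_error(
    sim_config(10, drug_catalog = default_drug_catalog(),
               event_catalog = default_event_catalog(),
               effects = data.frame(drug = "lithium", term = "Nausea",
                                    theta = 0)),
    "theta"
  )
  expect_error(
    sim_config(10, date_start = "2024-01-01", date_end = "2023-01-01",
               drug_catalog = default_drug_catalog(),
               event_catalog = default_event_catalog()),
    "date_start"
  )
})

test_that("the three-table layout round-trips through disk losslessly", {
  dir <- withr::local_tempdir()
  sim <- simulate_faers(default_sim_config(200, seed = 9,
                                           duplicate_rate = 0.05,
                                           invalid_rate = 0.05))
  write_report_tables(sim$db, dir)
  expect_true(all(file.exists(file.path(dir, c("demo.csv", "drug.csv",
                                               "reac.csv")))))
  back <- read_report_tables(dir)
  expect_equal(back$demo, sim$db$demo[order(sim$db$demo$report_id), ],
               ignore_attr = TRUE)
  expect_equal(
    dplyr::arrange(back$drug, report_id, verbatim_name, role),
    dplyr::arrange(sim$db$drug[c("report_id", "verbatim_name", "role")],
                   report_id, verbatim_name, role),
    ignore_attr = TRUE
  )
  expect_equal(
    dplyr::arrange(back$reac, report_id, preferred_term),
    dplyr::arrange(sim$db$reac, report_id, preferred_term),
    ignore_attr = TRUE
  )
  # a report with an emptied drug list simply has no drug rows
  inv <- sim$truth$reports$report_id[sim$truth$reports$is_invalid]
  dropped <- setdiff(inv, back$drug$report_id)
  expect_true(all(!dropped %in% back$drug$report_id))
})
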