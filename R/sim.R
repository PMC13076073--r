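#' Configure a synthetic spontaneous-report database
#'
#' Builds and validates the generative configuration for
#' [simulate_faers()]. The generator emulates the structure of a
#' FAERS-style spontaneous reporting system: each report carries
#' demographics, a receipt date, a set of drug mentions with role codes
#' (one primary suspect per report), and a set of MedDRA preferred-term
#' reactions. Drug-event association strength is planted directly on the
#' reporting-odds scale, so downstream disproportionality estimates have a
#' known ground truth.
#'
#' The event model is per-term independent Bernoulli with log-odds additive
#' drug effects: a report containing drugs \eqn{D} includes preferred term
#' \eqn{j} with probability
#' \eqn{\mathrm{logit}^{-1}(\mathrm{logit}(p_j) + \sum_{k \in D} \ln\theta_{kj})}.
#' Under this model a planted multiplier \eqn{\theta} is exactly the true
#' reporting odds ratio the pipeline estimates, which makes parameter
#' recovery well-defined.
#'
#' @param n_reports Number of primary (pre-contamination) reports.
#' @param date_start,date_end Receipt-date window (coerced with `as.Date()`);
#'   dates are drawn uniformly over the closed window.
#' @param drug_catalog Data frame with columns `name` (normalized drug name),
#'   `aliases` (list-column of character vectors of verbatim spellings;
#'   brand names, salt forms, the canonical name itself) and
#'   `marketing_prob` (per-report inclusion probability).
#' @param event_catalog Data frame with columns `term` (MedDRA preferred
#'   term) and `baseline_prob` (per-report inclusion probability when no
#'   effect applies).
#' @param effects Data frame with columns `drug`, `term`, `theta`
#'   (odds multiplier > 0); every row must reference a catalog drug and term.
#' @param role_distribution Named probabilities over the non-primary-suspect
#'   role codes `SS`, `C`, `I`. Exactly one mention per report is assigned
#'   role `PS`; the remaining mentions draw from this distribution.
#' @param duplicate_rate Fraction in `[0, 1)` of reports cloned as
#'   near-duplicates (same demographics, drugs and reactions; new report and
#'   case ids; receipt date shifted by at most 30 days).
#' @param invalid_rate Fraction in `[0, 1)` of reports appended as corrupted
#'   copies (drug list emptied, reaction list emptied, or age set negative).
#' @param seed Integer random seed; the full generation is deterministic
#'   given the configuration.
#' @return A validated `sim_config` list.
#' @seealso [default_sim_config()] for the study-shaped default catalog.
#' @export
sim_config <- function(n_reports,
                       date_start = "2003-12-01", date_end = "2024-12-31",
                       drug_catalog, event_catalog,
                       effects = NULL,
                       role_distribution = c(SS = 0.3, C = 0.6, I = 0.1),
                       duplicate_rate = 0, invalid_rate = 0,
                       seed = 1L) {
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1 ||
      n_reports != floor(n_reports)) {
    fail("n_reports must be a positive integer")
  }
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_start > date_end) {
    fail("date_start must not be after date_end")
  }
  drug_catalog <- tibble::as_tibble(drug_catalog)
  event_catalog <- tibble::as_tibble(event_catalog)
  if (!all(c("name", "aliases", "marketing_prob") %in% names(drug_catalog))) {
    fail("drug_catalog needs columns name, aliases, marketing_prob")
  }
  if (!all(c("term", "baseline_prob") %in% names(event_catalog))) {
    fail("event_catalog needs columns term, baseline_prob")
  }
  if (anyDuplicated(drug_catalog$name)) fail("duplicate drug names in catalog")
  if (anyDuplicated(event_catalog$term)) fail("duplicate terms in catalog")
  if (any(drug_catalog$marketing_prob < 0 | drug_catalog$marketing_prob > 1)) {
    fail("marketing_prob outside [0, 1]")
  }
  if (any(event_catalog$baseline_prob < 0 | event_catalog$baseline_prob > 1)) {
    fail("baseline_prob outside [0, 1]")
  }
  if (is.null(effects)) {
    effects <- tibble::tibble(drug = character(), term = character(),
                              theta = double())
  }
  effects <- tibble::as_tibble(effects)
  if (!all(c("drug", "term", "theta") %in% names(effects))) {
    fail("effects needs columns drug, term, theta")
  }
  if (any(effects$theta <= 0)) fail("effect theta must be > 0")
  if (!all(effects$drug %in% drug_catalog$name)) {
    fail("effect references a drug absent from drug_catalog")
  }
  if (!all(effects$term %in% event_catalog$term)) {
    fail("effect references a term absent from event_catalog")
  }
  if (!setequal(names(role_distribution), c("SS", "C", "I")) ||
      any(role_distribution < 0) || sum(role_distribution) <= 0) {
    fail("role_distribution must be non-negative probabilities over SS, C, I")
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1 ||
      invalid_rate < 0 || invalid_rate >= 1 ||
      duplicate_rate + invalid_rate >= 1) {
    fail("duplicate_rate and invalid_rate must lie in [0, 1) and sum below 1")
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      date_start = date_start, date_end = date_end,
      drug_catalog = drug_catalog, event_catalog = event_catalog,
      effects = effects,
      role_distribution = role_distribution / sum(role_distribution),
      duplicate_rate = duplicate_rate, invalid_rate = invalid_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Fillers keep every primary report structurally valid (>= 1 drug with a PS
# role, >= 1 reaction) without perturbing the catalog marginals: names are
# drawn from pools of common drugs/PTs disjoint from the configured
# catalogs, so minimal reports still vary as real ones do.
FILLER_DRUGS <- c(
  "acetaminophen", "aspirin", "naproxen", "loratadine", "cetirizine",
  "ranitidine", "simvastatin", "lisinopril", "losartan", "hydrochlorothiazide",
  "levothyroxine", "gabapentin", "tramadol", "prednisone", "albuterol",
  "fluoxetine", "citalopram", "alprazolam", "warfarin", "clopidogrel"
)
FILLER_TERMS <- c(
  "drug ineffective", "off label use", "product dose omission",
  "malaise", "asthenia", "pruritus", "insomnia", "anxiety", "dyspnoea",
  "arthralgia", "myalgia", "back pain", "abdominal pain", "constipation",
  "dyspepsia", "weight decreased", "weight increased", "somnolence",
  "tremor", "palpitations", "hyperhidrosis", "alopecia", "urticaria",
  "chest pain", "oedema peripheral", "pyrexia", "cough", "hypertension",
  "blood glucose increased", "fall"
)

#' Generate a synthetic spontaneous-report database
#'
#' Draws a FAERS-like report database from a [sim_config()], then appends
#' the configured contamination: `round(duplicate_rate * n_reports)`
#' near-duplicate clones (identical demographics, drugs and reactions; fresh
#' report/case ids; receipt date shifted forward by 0-30 days, clamped to
#' the window) and `round(invalid_rate * n_reports)` corrupted copies (drug
#' list emptied, reaction list emptied, or age set negative, cycling over
#' the three modes). Ground truth flags every appended record.
#'
#' Randomness is consumed in a fixed documented order (receipt dates, ages,
#' age missingness, sex, country, drug inclusion matrix, verbatim alias
#' picks per drug, primary-suspect pick per report, non-PS roles, filler
#' drug picks, reaction inclusion matrix, filler reaction picks, duplicate
#' sources and date shifts, invalid sources and corruption modes), so a
#' seed pins the output byte-for-byte.
#'
#' Reports whose catalog draws yield no drug receive one filler mention
#' (as primary suspect, being the only mention) drawn uniformly from a
#' pool of common drug names disjoint from the catalog; reports with no
#' catalog reaction receive one filler preferred term drawn from a pool of
#' common non-catalog PTs. Because no filler name appears in the catalogs,
#' catalog drug and event frequencies remain exactly Bernoulli at their
#' configured probabilities, while minimal reports stay varied enough that
#' the deduplication key does not collapse them wholesale.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \item{db}{a `faers_db`: list of tibbles `demo`, `drug`, `reac`
#'     (the three-table layout written by [write_report_tables()])}
#'   \item{truth}{ground truth: `reports` (tibble with `report_id`,
#'     `is_duplicate_of`, `is_invalid`) and `effects` (the planted
#'     odds multipliers)}
#' @examples
#' cfg <- default_sim_config(n_reports = 500, seed = 42)
#' sim <- simulate_faers(cfg)
#' sim$db$demo
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- config$drug_catalog
  events <- config$event_catalog
  k <- nrow(drugs); j <- nrow(events)

  # -- demographics ---------------------------------------------------------
  n_days <- as.integer(config$date_end - config$date_start) + 1L
  receipt <- config$date_start + (sample.int(n_days, n, replace = TRUE) - 1L)
  age <- pmin(pmax(round(stats::rnorm(n, 52, 18)), 0), 99)
  age[stats::runif(n) < 0.08] <- NA_real_
  sex <- sample(c("F", "M", "U"), n, replace = TRUE, prob = c(0.54, 0.42, 0.04))
  country <- sample(c("US", "CA", "GB", "DE", "FR", "JP", "AU", "BR"), n,
                    replace = TRUE,
                    prob = c(0.55, 0.06, 0.08, 0.07, 0.06, 0.08, 0.05, 0.05))

  # -- drug mentions --------------------------------------------------------
  inc <- stats::runif(n * k) < rep(drugs$marketing_prob, each = n)
  dim(inc) <- c(n, k)
  drug_rows <- lapply(seq_len(k), function(kk) {
    idx <- which(inc[, kk])
    al <- drugs$aliases[[kk]]
    verb <- al[sample.int(length(al), length(idx), replace = TRUE)]
    list(report = idx, name = rep(drugs$name[kk], length(idx)), verbatim = verb)
  })
  drug_long <- tibble::tibble(
    report = unlist(lapply(drug_rows, `[[`, "report")),
    name = unlist(lapply(drug_rows, `[[`, "name")),
    verbatim = unlist(lapply(drug_rows, `[[`, "verbatim"))
  )
  drug_long <- drug_long[order(drug_long$report), ]
  # exactly one PS per report: uniform pick among its catalog mentions
  cnt <- tabulate(drug_long$report, nbins = n)
  with_drug <- which(cnt > 0L)
  first_row <- cumsum(c(1L, cnt))[with_drug]  # row index of first mention
  ps_row <- first_row +
    floor(stats::runif(length(with_drug)) * cnt[with_drug])
  role <- sample(names(config$role_distribution), nrow(drug_long),
                 replace = TRUE, prob = config$role_distribution)
  role[ps_row] <- "PS"
  drug_long$role <- role
  no_drug <- which(cnt == 0L)
  if (length(no_drug)) {
    pool <- setdiff(FILLER_DRUGS, drugs$name)
    pick <- pool[sample.int(length(pool), length(no_drug), replace = TRUE)]
    drug_long <- dplyr::bind_rows(drug_long, tibble::tibble(
      report = no_drug, name = pick, verbatim = pick, role = "PS"
    ))
  }

  # -- reactions: logit-additive planted effects ----------------------------
  log_theta <- matrix(0, k, j, dimnames = list(drugs$name, events$term))
  if (nrow(config$effects)) {
    idx <- cbind(match(config$effects$drug, drugs$name),
                 match(config$effects$term, events$term))
    log_theta[idx] <- log(config$effects$theta)
  }
  prob <- rep(events$baseline_prob, each = n)
  dim(prob) <- c(n, j)
  eff_cols <- which(colSums(log_theta != 0) > 0)
  if (length(eff_cols)) {
    eff_drugs <- which(rowSums(log_theta != 0) > 0)
    delta <- (inc[, eff_drugs, drop = FALSE] * 1) %*%
      log_theta[eff_drugs, eff_cols, drop = FALSE]
    base <- rep(stats::qlogis(events$baseline_prob[eff_cols]),
                each = n)
    prob[, eff_cols] <- stats::plogis(base + delta)
  }
  hit <- stats::runif(n * j) < prob
  dim(hit) <- c(n, j)
  reac_long <- tibble::tibble(
    report = rep(seq_len(n), j)[as.vector(hit)],
    term = rep(events$term, each = n)[as.vector(hit)]
  )
  no_reac <- setdiff(seq_len(n), unique(reac_long$report))
  if (length(no_reac)) {
    pool <- setdiff(FILLER_TERMS, casefold_trim(events$term))
    pick <- pool[sample.int(length(pool), length(no_reac), replace = TRUE)]
    reac_long <- dplyr::bind_rows(
      reac_long, tibble::tibble(report = no_reac, term = pick)
    )
  }
  reac_long <- reac_long[order(reac_long$report), ]

  # -- contamination --------------------------------------------------------
  n_dup <- round(config$duplicate_rate * n)
  n_inv <- round(config$invalid_rate * n)
  dup_src <- if (n_dup) sample.int(n, n_dup) else integer()
  dup_shift <- if (n_dup) sample(0:30, n_dup, replace = TRUE) else integer()
  inv_src <- if (n_inv) sample.int(n, n_inv) else integer()
  inv_mode <- if (n_inv) {
    sample(c("no_drugs", "no_reactions", "negative_age"), n_inv, replace = TRUE)
  } else character()

  rid <- function(i) sprintf("R%08d", i)
  cid <- function(i) sprintf("C%08d", i)

  demo <- tibble::tibble(
    report_id = rid(seq_len(n)), case_id = cid(seq_len(n)),
    receipt_date = receipt, age_years = age, sex = sex, country = country
  )
  drug_tbl <- tibble::tibble(
    report_id = rid(drug_long$report),
    verbatim_name = drug_long$verbatim, role = drug_long$role
  )
  reac_tbl <- tibble::tibble(
    report_id = rid(reac_long$report), preferred_term = reac_long$term
  )

  append_copies <- function(src, new_ids) {
    demo_c <- demo[src, ]
    demo_c$report_id <- rid(new_ids)
    demo_c$case_id <- cid(new_ids)
    id_map <- stats::setNames(rid(new_ids), rid(src))
    drug_c <- drug_tbl[drug_tbl$report_id %in% rid(src), ]
    drug_c$report_id <- unname(id_map[drug_c$report_id])
    reac_c <- reac_tbl[reac_tbl$report_id %in% rid(src), ]
    reac_c$report_id <- unname(id_map[reac_c$report_id])
    list(demo = demo_c, drug = drug_c, reac = reac_c)
  }

  if (n_dup) {
    ids <- n + seq_len(n_dup)
    cp <- append_copies(dup_src, ids)
    cp$demo$receipt_date <- pmin(cp$demo$receipt_date + dup_shift,
                                 config$date_end)
    demo <- dplyr::bind_rows(demo, cp$demo)
    drug_tbl <- dplyr::bind_rows(drug_tbl, cp$drug)
    reac_tbl <- dplyr::bind_rows(reac_tbl, cp$reac)
  }
  if (n_inv) {
    ids <- n + n_dup + seq_len(n_inv)
    cp <- append_copies(inv_src, ids)
    drop_drug <- rid(ids)[inv_mode == "no_drugs"]
    drop_reac <- rid(ids)[inv_mode == "no_reactions"]
    cp$drug <- cp$drug[!cp$drug$report_id %in% drop_drug, ]
    cp$reac <- cp$reac[!cp$reac$report_id %in% drop_reac, ]
    cp$demo$age_years[inv_mode == "negative_age"] <- -1
    demo <- dplyr::bind_rows(demo, cp$demo)
    drug_tbl <- dplyr::bind_rows(drug_tbl, cp$drug)
    reac_tbl <- dplyr::bind_rows(reac_tbl, cp$reac)
  }

  truth_reports <- tibble::tibble(
    report_id = demo$report_id,
    is_duplicate_of = c(rep(NA_character_, n), rid(dup_src),
                        rep(NA_character_, n_inv)),
    is_invalid = c(rep(FALSE, n + n_dup), rep(TRUE, n_inv))
  )

  list(
    db = faers_db(demo, drug_tbl, reac_tbl),
    truth = list(reports = truth_reports, effects = config$effects)
  )
}

#' Bundle the three-table report layout
#'
#' A spontaneous-report database is carried as three tidy tables sharing
#' `report_id`: `demo` (one row per report: `report_id`, `case_id`,
#' `receipt_date`, `age_years`, `sex`, `country`), `drug` (one row per drug
#' mention: `verbatim_name`, `role` in PS/SS/C/I, plus `normalized_name`
#' and `unresolved` once normalized) and `reac` (one row per reaction
#' preferred term).
#'
#' @param demo,drug,reac The three tables.
#' @return A list of the three tibbles with class `faers_db`.
#' @export
faers_db <- function(demo, drug, reac) {
  stopifnot(is.data.frame(demo), is.data.frame(drug), is.data.frame(reac))
  if (anyDuplicated(demo$report_id)) {
    stop("duplicate report_id in demo table", call. = FALSE)
  }
  structure(
    list(demo = tibble::as_tibble(demo), drug = tibble::as_tibble(drug),
         reac = tibble::as_tibble(reac)),
    class = "faers_db"
  )
}

#' @export
print.faers_db <- function(x, ...) {
  cat("<faers_db> ", nrow(x$demo), " reports, ",
      nrow(x$drug), " drug mentions, ",
      nrow(x$reac), " reactions\n", sep = "")
  invisible(x)
}
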