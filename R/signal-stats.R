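#' Disproportionality statistics for 2x2 contingency tables
#'
#' These functions compute the standard pharmacovigilance disproportionality
#' metrics from the cells of a report-level 2x2 contingency table:
#'
#' \describe{
#'   \item{a}{reports with the drug of interest AND the event of interest}
#'   \item{b}{reports with the drug, without the event}
#'   \item{c}{reports without the drug, with the event}
#'   \item{d}{reports with neither}
#' }
#'
#' All functions are vectorised over the four cells. Quantities that are not
#' estimable for a given table (for example the reporting odds ratio when a
#' cell is zero) are returned as `NA` rather than raising an error:
#' inestimability is a result, not a failure, because spontaneous-report
#' analyses routinely produce zero-count drug-event combinations.
#'
#' @param a,b,c,d Non-negative integer cell counts (recycled to a common
#'   length).
#' @param conf_level Confidence level for the odds-ratio interval
#'   (default 0.95, the conventional Woolf interval).
#' @param continuity If `TRUE`, add 0.5 to every cell of tables containing a
#'   zero before computing the ROR and its interval (Haldane-Anscombe
#'   correction). Off by default: zero-cell tables are reported as not
#'   estimable, matching how such combinations are usually published.
#' @return `ror_with_ci()` returns a tibble with columns `ror`, `ror_ci_low`,
#'   `ror_ci_high`; `prr()`, `rrr()`, `chi2_yates()` and `fisher_exact_p()`
#'   return numeric vectors; `ic_with_ic025()` returns a tibble with columns
#'   `ic` and `ic025`.
#' @name disproportionality
NULL

check_cells <- function(a, b, c, d) {
  n <- vapply(list(a, b, c, d), length, 1L)
  if (length(unique(n[n != 1L])) > 1L) {
    stop("cell vectors a, b, c, d must have equal (or unit) lengths", call. = FALSE)
  }
  bad <- function(x) any(!is.na(x) & (x < 0 | x != floor(x)))
  if (bad(a) || bad(b) || bad(c) || bad(d)) {
    stop("cells a, b, c, d must be non-negative integers", call. = FALSE)
  }
  invisible(NULL)
}

# cell products overflow 32-bit integers well inside FAERS-scale counts
as_dbl_cells <- function(a, b, c, d) {
  list(a = as.double(a), b = as.double(b), c = as.double(c), d = as.double(d))
}

#' @rdname disproportionality
#' @details The reporting odds ratio is ROR = (a*d)/(b*c), the odds of the
#'   event among drug reports divided by the odds among all other reports.
#'   The interval is the Woolf log-normal interval
#'   exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' @export
ror_with_ci <- function(a, b, c, d, conf_level = 0.95, continuity = FALSE) {
  check_cells(a, b, c, d)
  x <- as_dbl_cells(a, b, c, d); a <- x$a; b <- x$b; c <- x$c; d <- x$d
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (continuity) {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
  }
  estimable <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(estimable, (a * d) / (b * c), NA_real_)
  se <- ifelse(estimable, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(
    ror = ror,
    ror_ci_low = exp(log(ror) - z * se),
    ror_ci_high = exp(log(ror) + z * se)
  )
}

#' @rdname disproportionality
#' @details The proportional reporting ratio is
#'   PRR = (a/(a+b)) / (c/(c+d)): the proportion of drug reports mentioning
#'   the event over the same proportion among all other reports. Not
#'   estimable when a+b = 0 or c = 0.
#' @export
prr <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  x <- as_dbl_cells(a, b, c, d); a <- x$a; b <- x$b; c <- x$c; d <- x$d
  estimable <- (a + b) > 0 & c > 0
  ifelse(estimable, (a / (a + b)) / (c / (c + d)), NA_real_)
}

#' @rdname disproportionality
#' @details The relative reporting ratio is the observed-over-expected count,
#'   RRR = a*N / ((a+b)*(a+c)) with N = a+b+c+d. Not estimable when either
#'   margin a+b or a+c is zero.
#' @export
rrr <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  x <- as_dbl_cells(a, b, c, d); a <- x$a; b <- x$b; c <- x$c; d <- x$d
  n <- a + b + c + d
  estimable <- (a + b) > 0 & (a + c) > 0
  ifelse(estimable, a * n / ((a + b) * (a + c)), NA_real_)
}

#' @rdname disproportionality
#' @details `chi2_yates()` is the continuity-corrected (Yates) chi-square
#'   statistic N*(|ad-bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d)), floored at zero
#'   when |ad-bc| <= N/2, and `NA` when any margin is zero.
#' @export
chi2_yates <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  x <- as_dbl_cells(a, b, c, d); a <- x$a; b <- x$b; c <- x$c; d <- x$d
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- abs(a * d - b * c) - n / 2
  ifelse(denom > 0, ifelse(dev > 0, n * dev^2 / denom, 0), NA_real_)
}

#' @rdname disproportionality
#' @details `fisher_exact_p()` is the two-sided Fisher exact p-value obtained
#'   by full hypergeometric enumeration: with margins fixed, probabilities of
#'   all achievable tables are summed over tables no more probable than the
#'   observed one (with a relative tolerance of 1e-7 on the comparison, the
#'   minimum-likelihood two-sided convention). Deterministic; defined for any
#'   non-degenerate table, and 1 when a margin is zero.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    fisher_p_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

fisher_p_one <- function(a, b, c, d) {
  if (anyNA(c(a, b, c, d))) return(NA_real_)
  m <- a + c           # total event reports
  k <- a + b           # total drug reports
  n_tot <- a + b + c + d
  if (m == 0 || k == 0 || m == n_tot || k == n_tot) return(1)
  support <- max(0L, k + m - n_tot):min(k, m)
  dens <- stats::dhyper(support, m, n_tot - m, k)
  obs <- stats::dhyper(a, m, n_tot - m, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' @rdname disproportionality
#' @param mode How to compute the IC025 lower credibility bound. `"gamma"`
#'   (default) takes the exact 0.025 quantile of the shrunk posterior:
#'   log2(G / (E + 0.5)) with G ~ Gamma(shape = a + 0.5, rate = 1).
#'   `"approx"` uses the widely used closed form
#'   IC - 3.3*(a+0.5)^(-1/2) - 2*(a+0.5)^(-3/2).
#' @details The information component is the shrunk log2
#'   observed-to-expected ratio IC = log2((a + 0.5)/(E + 0.5)) with
#'   E = (a+b)(a+c)/N. The additive 0.5 implements Bayesian shrinkage toward
#'   the database-wide reporting mean, which damps small-count noise (and the
#'   notoriety/Weber reporting artifacts it amplifies). IC is finite even at
#'   a = 0. IC025 > 0 is the Bayesian half of the signal rule.
#' @export
ic_with_ic025 <- function(a, b, c, d, mode = c("gamma", "approx")) {
  check_cells(a, b, c, d)
  mode <- match.arg(mode)
  x <- as_dbl_cells(a, b, c, d); a <- x$a; b <- x$b; c <- x$c; d <- x$d
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- if (mode == "gamma") {
    log2(stats::qgamma(0.025, shape = a + 0.5, rate = 1) / (e + 0.5))
  } else {
    ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  }
  tibble::tibble(ic = ic, ic025 = ic025)
}

#' Evans screening criteria
#'
#' The classical three-part screen for a drug-event pair: more than two
#' co-occurrence reports, a continuity-corrected chi-square above 4, and a
#' disproportionality ratio above 2. The ratio screened is the reporting odds
#' ratio by default; `metric = "prr"` substitutes the proportional reporting
#' ratio as in Evans' original formulation. A pair with a missing
#' (not estimable) ratio or chi-square fails the screen.
#'
#' @inheritParams disproportionality
#' @param chi2 Continuity-corrected chi-square values, as from [chi2_yates()].
#' @param ratio The disproportionality ratio being screened (ROR or PRR).
#' @return Logical vector.
#' @export
evans_criteria <- function(a, chi2, ratio) {
  out <- a > 2 & !is.na(chi2) & chi2 > 4 & !is.na(ratio) & ratio > 2
  out & !is.na(out)
}

#' Classify a drug-event pair against the signal rule
#'
#' A pair is a `"SIGNAL"` when the association p-value is below 0.05 and the
#' IC025 lower credibility bound is above 0 (both strict); it is
#' `"NOT_ESTIMABLE"` when no case was observed (a = 0) and the reporting odds
#' ratio is not estimable; otherwise `"NO_SIGNAL"`.
#'
#' @param p_value Two-sided association p-values.
#' @param ic025 IC 95% credibility lower bounds.
#' @param a Case counts (cell a).
#' @param ror_estimable Logical; whether the ROR was estimable for each pair.
#' @return Character vector over `c("SIGNAL", "NO_SIGNAL", "NOT_ESTIMABLE")`.
#' @export
classify_signal <- function(p_value, ic025, a, ror_estimable) {
  dplyr::case_when(
    !ror_estimable & a == 0 ~ "NOT_ESTIMABLE",
    p_value < 0.05 & ic025 > 0 ~ "SIGNAL",
    .default = "NO_SIGNAL"
  )
}

#' Compute the full disproportionality panel for a table of 2x2 counts
#'
#' The workhorse statistical step: takes a data frame with cell-count columns
#' `a`, `b`, `c`, `d` (one row per drug-event pair; any other columns, such
#' as query and endpoint labels, are carried through) and appends every
#' metric of the signal framework - ROR with Woolf 95% CI, Fisher exact
#' p-value, PRR, RRR, Yates chi-square, expected count, shrunk information
#' component with IC025, case count, the Evans screen, and the signal
#' classification.
#'
#' @param data A data frame with integer columns `a`, `b`, `c`, `d`.
#' @param ic_mode `"gamma"` (exact posterior quantile, default) or
#'   `"approx"` (closed-form) IC025; see [ic_with_ic025()].
#' @param continuity Forwarded to [ror_with_ci()].
#' @param evans_metric `"ror"` (default) or `"prr"`: which ratio the Evans
#'   screen tests.
#' @return A tibble: the input columns followed by `n_cases`, `ror`,
#'   `ror_ci_low`, `ror_ci_high`, `p_value`, `prr`, `rrr`, `chi2`,
#'   `expected`, `ic`, `ic025`, `evans_met`, `classification`.
#' @examples
#' signal_stats(data.frame(a = 20, b = 80, c = 10, d = 890))
#' @export
signal_stats <- function(data, ic_mode = c("gamma", "approx"),
                         continuity = FALSE,
                         evans_metric = c("ror", "prr")) {
  stopifnot(is.data.frame(data), all(c("a", "b", "c", "d") %in% names(data)))
  ic_mode <- match.arg(ic_mode)
  evans_metric <- match.arg(evans_metric)
  a <- data$a; b <- data$b; c <- data$c; d <- data$d
  check_cells(a, b, c, d)
  x <- as_dbl_cells(a, b, c, d); a <- x$a; b <- x$b; c <- x$c; d <- x$d

  or <- ror_with_ci(a, b, c, d, continuity = continuity)
  ic <- ic_with_ic025(a, b, c, d, mode = ic_mode)
  n <- a + b + c + d
  out <- dplyr::bind_cols(
    tibble::as_tibble(data),
    tibble::tibble(n_cases = data$a),
    or,
    tibble::tibble(
      p_value = fisher_exact_p(a, b, c, d),
      prr = prr(a, b, c, d),
      rrr = rrr(a, b, c, d),
      chi2 = chi2_yates(a, b, c, d),
      expected = (a + b) * (a + c) / n
    ),
    ic
  )
  ratio <- if (evans_metric == "ror") out$ror else out$prr
  out$evans_met <- evans_criteria(a, out$chi2, ratio)
  out$classification <- classify_signal(out$p_value, out$ic025, a, !is.na(out$ror))
  out
}
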