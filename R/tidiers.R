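#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run
#'
#' `tidy()` returns the per-pair results table; `glance()` a one-row run
#' summary.
#'
#' @param x A `pv_run` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per (query, endpoint) pair.
#'   `glance()`: a one-row tibble with the curation counts and the tally of
#'   classifications.
#' @export
tidy.pv_run <- function(x, ...) {
  x$results
}

#' @rdname tidy.pv_run
#' @export
glance.pv_run <- function(x, ...) {
  tibble::tibble(
    n_input = x$curation$n_input,
    n_excluded_invalid = x$curation$n_excluded_invalid,
    n_removed_duplicates = x$curation$n_removed_duplicates,
    n_curated = x$curation$n_output,
    n_pairs = nrow(x$results),
    n_signal = sum(x$results$classification == "SIGNAL"),
    n_no_signal = sum(x$results$classification == "NO_SIGNAL"),
    n_not_estimable = sum(x$results$classification == "NOT_ESTIMABLE")
  )
}
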