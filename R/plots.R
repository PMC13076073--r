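#' Forest plot of reporting odds ratios
#'
#' One panel per query, endpoints on the y axis, ROR point estimates with
#' their 95% intervals on a log-scaled x axis and a dashed reference line at
#' ROR = 1. Not-estimable pairs appear as an `NE` annotation with no
#' interval.
#'
#' @param results Results tibble with `label`, `endpoint`, `ror`,
#'   `ror_ci_low`, `ror_ci_high` columns (e.g. `tidy(run)`).
#' @return A ggplot object.
#' @export
plot_forest <- function(results) {
  stopifnot(all(c("label", "endpoint", "ror", "ror_ci_low", "ror_ci_high")
                %in% names(results)))
  results <- dplyr::mutate(
    results,
    endpoint = factor(.data$endpoint, levels = rev(unique(.data$endpoint))),
    ne = is.na(.data$ror)
  )
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$ror, y = .data$endpoint)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      data = ~dplyr::filter(.x, !.data$ne),
      ggplot2::aes(xmin = .data$ror_ci_low, xmax = .data$ror_ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, !.data$ne), size = 2) +
    ggplot2::geom_text(
      data = ~dplyr::filter(.x, .data$ne),
      ggplot2::aes(x = 1), label = "NE", size = 3, colour = "grey40"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI, log scale)",
                  y = NULL) +
    ggplot2::theme_bw()
}

#' @rdname plot_forest
#' @param object A `pv_run` from [run_pipeline()].
#' @param ... Unused.
#' @export
autoplot.pv_run <- function(object, ...) {
  plot_forest(object$results)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
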