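#' Waterfall plot of BestAvgResponse
#'
#' The standard efficacy display of a PDX trial: one bar per model,
#' sorted by ascending BestAvgResponse within arm and colored by mRECIST
#' call, faceted by arm.
#'
#' @param responses Response tibble from [pdx_response()].
#' @return A ggplot object.
#' @export
plot_waterfall <- function(responses) {
  wf <- waterfall_table(responses)
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$rank, y = .data$best_avg_response,
                                   fill = .data$mrecist)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(CR = "#1b7837", PR = "#7fbf7b",
                                          SD = "#fdb863", PD = "#b2182b"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "BestAvgResponse (%)", fill = "mRECIST") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Kaplan-Meier step plot
#'
#' @param object A `km_fit` object.
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  # prepend the (0, 1) anchor for each group so the step starts at S=1
  anchors <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(anchors,
                         dplyr::select(object, "group", "time", "survival"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Doubling-free survival",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Prior-exposure versus response scatter plot
#'
#' @param responses Response tibble.
#' @param annotations Annotations with `model_id`, `prior_drug_count`.
#' @return A ggplot object.
#' @export
plot_exposure_response <- function(responses, annotations) {
  per_model <- responses |>
    dplyr::filter(.data$arm != "untreated") |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(mean_bar = mean(.data$best_avg_response),
                     .groups = "drop") |>
    dplyr::inner_join(
      dplyr::distinct(annotations, .data$model_id, .data$prior_drug_count),
      by = "model_id")
  ggplot2::ggplot(per_model, ggplot2::aes(.data$prior_drug_count,
                                          .data$mean_bar)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey40") +
    ggplot2::labs(x = "Prior drugs (patient)",
                  y = "Mean BestAvgResponse (%)") +
    ggplot2::theme_minimal()
}
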