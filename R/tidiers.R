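#' Broom-style tidiers
#'
#' `tidy()` returns the per-component table of a fitted object;
#' `glance()` returns its one-row summary.
#'
#' @param x A `km_fit` or `logrank_test` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.km_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @export
glance.km_fit <- function(x, ...) {
  x |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = max(.data$n_risk),
      events = sum(.data$n_event),
      median_survival = {
        below <- .data$time[.data$survival <= 0.5]
        if (length(below)) min(below) else NA_real_
      },
      .groups = "drop")
}

#' @rdname tidiers
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(group = names(x$observed),
                 observed = unname(x$observed),
                 expected = unname(x$expected))
}

#' @rdname tidiers
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chisq, df = x$df, p.value = x$p)
}
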