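#' Objective response rate
#'
#' The fraction of mRECIST calls that are objective responses (CR or PR),
#' in percent — the per-agent summary shown above waterfall plots.
#'
#' @param calls Character or factor vector of mRECIST categories.
#' @return Percent of calls that are CR or PR.
#' @export
objective_response_rate <- function(calls) {
  calls <- as.character(calls)
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop_pdx("no response calls", "undefined_rate")
  100 * sum(calls %in% c("CR", "PR")) / length(calls)
}

#' Chemosensitivity classification per model
#'
#' A PDX evaluated with multiple single agents is called broadly
#' chemosensitive when at least two of its arms achieved an objective
#' response (CR/PR), and chemoresistant when at most one did. Models
#' tested with fewer than `min_tested` agents cannot be classified and
#' get `NA`.
#'
#' @param responses A response tibble from [pdx_response()] (or any table
#'   with `model_id`, `arm`, `mrecist`); untreated arms are excluded.
#' @param min_tested Minimum number of tested agents (default 2).
#' @return A tibble with `model_id`, `n_objective_responses`, `n_tested`,
#'   `chemo_class` in `{"chemosensitive", "chemoresistant", NA}`.
#' @export
classify_chemosensitivity <- function(responses, min_tested = 2) {
  responses |>
    dplyr::filter(.data$arm != "untreated") |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      n_objective_responses = sum(as.character(.data$mrecist) %in% c("CR", "PR")),
      n_tested = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(chemo_class = dplyr::if_else(
      .data$n_tested < min_tested, NA_character_,
      dplyr::if_else(.data$n_objective_responses >= 2,
                     "chemosensitive", "chemoresistant")))
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator of the survivor function from
#' right-censored times: at each distinct event time t with d events among
#' n at risk, survival is multiplied by (1 - d/n). Censored observations
#' leave the risk set without contributing an event. With no censoring
#' the estimate equals the empirical survivor function.
#'
#' @param time Numeric vector of follow-up times (days), >= 0.
#' @param event Integer vector (1 = event, 0 = censored) aligned with
#'   `time`.
#' @param group Optional grouping vector; the estimate is computed within
#'   each group.
#' @return An object of class `km_fit`: a tibble of the step function
#'   with columns `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1))
#' @export
km_fit <- function(time, event, group = NULL) {
  if (length(time) == 0) stop_pdx("empty survival sample", "empty_sample")
  if (length(time) != length(event)) {
    stop_pdx("time and event must be aligned", "length_mismatch")
  }
  if (any(time < 0)) stop_pdx("times must be >= 0", "invalid_sample")
  if (is.null(group)) group <- rep("all", length(time))
  df <- tibble::tibble(group = as.character(group), time = time,
                       event = as.integer(event))
  out <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      tt <- sort(unique(d$time))
      n_total <- nrow(d)
      surv <- 1
      purrr::map(tt, function(t0) {
        n_risk <- sum(d$time >= t0)
        n_event <- sum(d$time == t0 & d$event == 1)
        n_censor <- sum(d$time == t0 & d$event == 0)
        surv <<- surv * (1 - n_event / n_risk)
        tibble::tibble(time = t0, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv)
      }) |> purrr::list_rbind()
    }) |>
    dplyr::ungroup()
  structure(out, class = c("km_fit", class(out)))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' The standard two-sample log-rank statistic: at each distinct event
#' time the observed events in group A are compared to the expectation
#' under the hypergeometric null given the pooled risk sets, and
#' `(O - E)^2 / V` is referred to a chi-square distribution on one
#' degree of freedom.
#'
#' @param time_a,event_a Times and event flags for group A.
#' @param time_b,event_b Times and event flags for group B.
#' @return An object of class `logrank_test`: list with `chisq`, `p`,
#'   `observed`, `expected` (both per group), `df`.
#' @examples
#' logrank_test(c(1, 2, 3), c(1, 1, 1), c(10, 11, 12), c(1, 1, 1))
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop_pdx("both groups must be non-empty", "empty_sample")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    stop_pdx("no events in either group; statistic undefined", "no_events")
  }
  pooled <- tibble::tibble(
    time = c(time_a, time_b),
    event = as.integer(c(event_a, event_b)),
    grp = rep(c("a", "b"), c(length(time_a), length(time_b))))
  event_times <- sort(unique(pooled$time[pooled$event == 1]))
  o_a <- e_a <- v <- 0
  for (t0 in event_times) {
    at_risk <- pooled$time >= t0
    n <- sum(at_risk)
    n_a <- sum(at_risk & pooled$grp == "a")
    d <- sum(pooled$time == t0 & pooled$event == 1)
    d_a <- sum(pooled$time == t0 & pooled$event == 1 & pooled$grp == "a")
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  total_events <- sum(pooled$event)
  chisq <- if (v > 0) (o_a - e_a)^2 / v else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(chisq = chisq, p = p,
                 observed = c(a = o_a, b = total_events - o_a),
                 expected = c(a = e_a, b = total_events - e_a),
                 df = 1L), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank (Mantel-Cox) test\n")
  cat(sprintf("  chisq = %.4f on %d df, p = %.4g\n", x$chisq, x$df, x$p))
  cat(sprintf("  observed a/b: %g/%g, expected a/b: %.2f/%.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' Replicate reproducibility of BestAvgResponse
#'
#' Pearson correlation (with its two-sided p-value) between
#' BestAvgResponse values of replicated model x drug experiments — the
#' reproducibility check for the one-animal-per-arm design.
#'
#' @param rep1,rep2 Numeric vectors of paired BestAvgResponse values.
#' @return A tibble with `r`, `p`, `n`.
#' @export
replicate_reproducibility <- function(rep1, rep2) {
  keep <- stats::complete.cases(rep1, rep2)
  rep1 <- rep1[keep]; rep2 <- rep2[keep]
  if (length(rep1) < 3) stop_pdx("need >= 3 replicate pairs", "too_few_pairs")
  if (stats::sd(rep1) == 0 || stats::sd(rep2) == 0) {
    stop_pdx("zero variance; correlation undefined", "undefined_correlation")
  }
  ct <- stats::cor.test(rep1, rep2)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(rep1))
}

#' Patient-PDX response concordance
#'
#' For every model x drug with a patient response annotation other than
#' `untested`, the PDX is labelled sensitive when its mRECIST call is CR
#' or PR (resistant for SD/PD), the patient call is collapsed to the same
#' sensitive/resistant vocabulary (CR/PR -> sensitive, SD/PD ->
#' resistant), and the pair is concordant when the two labels match.
#'
#' @param responses Response tibble with `model_id`, `arm`, `mrecist`.
#' @param patient_responses Tibble with `model_id`, `drug`,
#'   `patient_response` in `{CR, PR, SD, PD, sensitive, resistant,
#'   untested}`.
#' @return A list with `combinations` (per-pair tibble: `model_id`,
#'   `drug`, `patient_sensitive`, `pdx_sensitive`, `concordant`) and
#'   `percent_concordant`. With no comparable pairs, `combinations` is
#'   empty and `percent_concordant` is `NA`.
#' @export
patient_pdx_concordance <- function(responses, patient_responses) {
  collapse <- function(x) {
    dplyr::case_when(
      x %in% c("CR", "PR", "sensitive") ~ "sensitive",
      x %in% c("SD", "PD", "resistant") ~ "resistant",
      TRUE ~ NA_character_)
  }
  tab <- patient_responses |>
    dplyr::filter(.data$patient_response != "untested") |>
    dplyr::inner_join(
      dplyr::select(responses, "model_id", drug = "arm", "mrecist"),
      by = c("model_id", "drug")) |>
    dplyr::mutate(
      patient_sensitive = collapse(.data$patient_response) == "sensitive",
      pdx_sensitive = as.character(.data$mrecist) %in% c("CR", "PR"),
      concordant = .data$patient_sensitive == .data$pdx_sensitive) |>
    dplyr::select("model_id", "drug", "patient_sensitive",
                  "pdx_sensitive", "concordant")
  pct <- if (nrow(tab) == 0) NA_real_ else 100 * mean(tab$concordant)
  list(combinations = tab, percent_concordant = pct)
}

#' Prior drug exposure versus mean PDX response
#'
#' Pearson correlation between the number of drugs the donor patient
#' received before engraftment and the per-model mean BestAvgResponse
#' across tested arms (untreated excluded, untested arms never imputed).
#' A positive correlation means heavier pretreatment tracks with poorer
#' PDX responses.
#'
#' @param responses Response tibble with `model_id`, `arm`,
#'   `best_avg_response`.
#' @param annotations Tibble with `model_id`, `prior_drug_count`.
#' @return A tibble with `r`, `p`, `n`.
#' @export
exposure_response_correlation <- function(responses, annotations) {
  per_model <- responses |>
    dplyr::filter(.data$arm != "untreated") |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(mean_bar = mean(.data$best_avg_response),
                     .groups = "drop") |>
    dplyr::inner_join(
      dplyr::distinct(annotations, .data$model_id, .data$prior_drug_count),
      by = "model_id")
  if (nrow(per_model) < 3) stop_pdx("need >= 3 models", "too_few_models")
  if (stats::sd(per_model$prior_drug_count) == 0 ||
      stats::sd(per_model$mean_bar) == 0) {
    stop_pdx("zero variance; correlation undefined", "undefined_correlation")
  }
  ct <- stats::cor.test(per_model$prior_drug_count, per_model$mean_bar)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = nrow(per_model))
}

#' Waterfall-ordered response table
#'
#' Sorts a response table by ascending BestAvgResponse within arm, the
#' order used for waterfall plots.
#'
#' @param responses Response tibble from [pdx_response()].
#' @return The same tibble sorted, with a per-arm `rank` column.
#' @export
waterfall_table <- function(responses) {
  responses |>
    dplyr::group_by(.data$arm) |>
    dplyr::arrange(.data$best_avg_response, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
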