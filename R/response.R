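#' Tumor volume from caliper measurements
#'
#' Computes tumor volume with the standard hemi-ellipsoid approximation
#' `V = (length x width^2) / 2`, the formula used throughout PDX efficacy
#' studies. Length is the larger caliper dimension; if a width exceeds its
#' length the two are swapped with a warning rather than rejected, since
#' transposed caliper readings are a common transcription slip.
#'
#' @param length_mm Numeric vector of tumor lengths (mm).
#' @param width_mm Numeric vector of tumor widths (mm), recycled against
#'   `length_mm`.
#' @return Numeric vector of volumes in cubic millimetres.
#' @examples
#' caliper_volume(10, 10) # 500
#' caliper_volume(6, 4)   # 48
#' @export
caliper_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0, na.rm = TRUE) || any(width_mm < 0, na.rm = TRUE)) {
    stop_pdx("caliper measurements must be non-negative", "invalid_measurement")
  }
  swapped <- !is.na(length_mm) & !is.na(width_mm) & width_mm > length_mm
  if (any(swapped)) {
    warning(sum(swapped), " measurement(s) had width > length; swapped")
    tmp <- length_mm[swapped]
    length_mm[swapped] <- width_mm[swapped]
    width_mm[swapped] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Percent volume change from baseline
#'
#' For a volume trajectory, the percent change at day t is
#' `dV_t = 100 * (V_t - V_0) / V_0`, where `V_0` is the day-0 (baseline)
#' volume. By construction `dV` is exactly 0 at day 0 and bounded below by
#' -100 (complete regression).
#'
#' @param volumes Numeric vector of volumes (mm^3), first element at day 0.
#' @return Numeric vector of percent changes, same length as `volumes`.
#' @export
percent_change <- function(volumes) {
  if (length(volumes) == 0) stop_pdx("empty volume series", "empty_series")
  v0 <- volumes[[1]]
  if (is.na(v0) || v0 <= 0) {
    stop_pdx("baseline volume must be positive", "zero_baseline")
  }
  out <- (volumes - v0) / v0 * 100
  out[[1]] <- 0
  out
}

#' BestAvgResponse of a percent-change series
#'
#' For each eligible day t at or beyond `window_start`, the running mean of
#' all percent-change values from day 0 through day t (inclusive, so the
#' day-0 zero is in every mean) is computed; BestAvgResponse is the minimum
#' of those running means. It rewards responses that are both deep and
#' sustained: a transient dip before the window opens cannot dominate.
#'
#' @param days Numeric vector of measurement days, strictly increasing,
#'   starting at 0.
#' @param delta Numeric vector of percent changes aligned with `days`.
#' @param window_start First eligible day (default 14).
#' @return The BestAvgResponse in percent (a single number).
#' @export
best_avg_response <- function(days, delta, window_start = 14) {
  check_series(days, delta)
  eligible <- which(days >= window_start)
  if (length(eligible) == 0) {
    stop_pdx("no measurement at or beyond the BestAvgResponse window",
             "insufficient_observation")
  }
  running_means <- cumsum(delta) / seq_along(delta)
  min(running_means[eligible])
}

#' BestResponse of a percent-change series
#'
#' The minimum percent change over all days at or beyond `window_start`
#' (default 10). Together with BestAvgResponse it drives the mRECIST call:
#' BestResponse captures the deepest regression, BestAvgResponse its
#' durability.
#'
#' @inheritParams best_avg_response
#' @param window_start First eligible day (default 10).
#' @return The BestResponse in percent.
#' @export
best_response <- function(days, delta, window_start = 10) {
  check_series(days, delta)
  eligible <- which(days >= window_start)
  if (length(eligible) == 0) {
    stop_pdx("no measurement at or beyond the BestResponse window",
             "insufficient_observation")
  }
  min(delta[eligible])
}

check_series <- function(days, delta) {
  if (length(days) != length(delta)) {
    stop_pdx("days and delta must have equal length", "length_mismatch")
  }
  if (length(days) == 0 || days[[1]] != 0) {
    stop_pdx("series must start at day 0", "invalid_series")
  }
  if (any(diff(days) <= 0)) {
    stop_pdx("days must be strictly increasing", "invalid_series")
  }
  invisible(TRUE)
}

#' mRECIST classification thresholds
#'
#' The default thresholds of the modified-RECIST convention for PDX trials.
#' Rules are applied in order CR, PR, SD and both arms of a rule must hold
#' (strict inequalities); anything that fails all three is PD.
#'
#' @param cr,pr,sd Length-2 numeric vectors giving the
#'   `(BestResponse, BestAvgResponse)` upper bounds for each category.
#' @return A named list usable as the `criteria` argument of
#'   [classify_mrecist()].
#' @export
mrecist_criteria <- function(cr = c(-95, -40), pr = c(-50, -20),
                             sd = c(35, 30)) {
  stopifnot(length(cr) == 2, length(pr) == 2, length(sd) == 2)
  list(CR = cr, PR = pr, SD = sd)
}

#' Assign an mRECIST category from response metrics
#'
#' Applies the modified-RECIST rules for PDX studies: CR if
#' BestResponse < -95 and BestAvgResponse < -40; PR if BestResponse < -50
#' and BestAvgResponse < -20; SD if BestResponse < 35 and
#' BestAvgResponse < 30; otherwise PD. All inequalities are strict, so a
#' model sitting exactly on a boundary falls into the less favourable
#' category.
#'
#' @param best_response,best_avg_response Numeric vectors (percent),
#'   recycled to common length.
#' @param criteria Threshold set from [mrecist_criteria()].
#' @return A factor with levels `CR < PR < SD < PD` (ordered).
#' @export
classify_mrecist <- function(best_response, best_avg_response,
                             criteria = mrecist_criteria()) {
  n <- max(length(best_response), length(best_avg_response))
  br <- rep_len(best_response, n)
  bar <- rep_len(best_avg_response, n)
  out <- rep("PD", n)
  out[br < criteria$SD[1] & bar < criteria$SD[2]] <- "SD"
  out[br < criteria$PR[1] & bar < criteria$PR[2]] <- "PR"
  out[br < criteria$CR[1] & bar < criteria$CR[2]] <- "CR"
  out[is.na(br) | is.na(bar)] <- NA
  factor(out, levels = c("CR", "PR", "SD", "PD"), ordered = TRUE)
}

#' Tumor-volume doubling event
#'
#' Scans a volume trajectory for the first measurement day on which the
#' volume reaches at least twice baseline (inclusive). If the tumor never
#' doubles within the observed series the animal is censored at its last
#' measurement day. Feeds doubling-free survival analysis.
#'
#' @param days Numeric vector of measurement days starting at 0.
#' @param volumes Numeric vector of volumes aligned with `days`.
#' @return A list with elements `time` (days) and `event` (1 = doubled,
#'   0 = censored).
#' @export
doubling_event <- function(days, volumes) {
  if (length(days) != length(volumes) || length(days) == 0) {
    stop_pdx("days and volumes must be non-empty and aligned",
             "invalid_series")
  }
  v0 <- volumes[[1]]
  if (is.na(v0) || v0 <= 0) stop_pdx("baseline must be positive", "zero_baseline")
  hit <- which(volumes >= 2 * v0)
  hit <- hit[hit > 1] # day 0 cannot be a doubling event
  if (length(hit) > 0) {
    list(time = days[[min(hit)]], event = 1L)
  } else {
    list(time = days[[length(days)]], event = 0L)
  }
}

#' Response metrics and mRECIST calls for a measurement table
#'
#' The per-arm analysis of a PDX trial in one call: caliper pairs are
#' converted to volumes, days beyond the study horizon are truncated,
#' percent change from baseline is computed, and BestResponse,
#' BestAvgResponse, the mRECIST category and the doubling event are
#' derived for every `model_id` x `arm` (x `animal_id`) series.
#'
#' Arms whose observation span never reaches the BestAvgResponse window
#' (e.g. an animal sacrificed before day 14) cannot be classified; they
#' are dropped with a warning.
#'
#' @param measurements A data frame with columns `model_id`, `arm`,
#'   `animal_id`, `day`, `length_mm`, `width_mm` (the measurements CSV
#'   schema written by [write_cohort()]).
#' @param horizon Truncate each series at this day before computing
#'   metrics (default 28, the usual study length).
#' @param bar_window First eligible day for BestAvgResponse (default 14).
#' @param br_window First eligible day for BestResponse (default 10).
#' @param criteria mRECIST thresholds from [mrecist_criteria()].
#' @return A tibble with one row per model x arm x animal:
#'   `model_id`, `arm`, `animal_id`, `best_response`, `best_avg_response`,
#'   `mrecist`, `doubling_time`, `doubling_event`, `n_days_observed`.
#' @examples
#' cohort <- simulate_pdx_cohort(sim_config(n_models = 3, seed = 1))
#' pdx_response(cohort$measurements)
#' @export
pdx_response <- function(measurements, horizon = 28, bar_window = 14,
                         br_window = 10, criteria = mrecist_criteria()) {
  required <- c("model_id", "arm", "animal_id", "day", "length_mm", "width_mm")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop_pdx(paste("measurements table lacks columns:",
                   paste(missing_cols, collapse = ", ")), "bad_schema")
  }
  meas <- measurements |>
    dplyr::mutate(volume = caliper_volume(.data$length_mm, .data$width_mm)) |>
    dplyr::filter(.data$day <= horizon) |>
    dplyr::arrange(.data$model_id, .data$arm, .data$animal_id, .data$day)

  res <- meas |>
    dplyr::group_by(.data$model_id, .data$arm, .data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      keep <- !is.na(df$volume)
      days <- df$day[keep]
      vols <- df$volume[keep]
      if (length(days) == 0 || days[[1]] != 0 || max(days) < bar_window) {
        return(tibble::tibble(
          best_response = NA_real_, best_avg_response = NA_real_,
          doubling_time = NA_real_, doubling_event = NA_integer_,
          n_days_observed = if (length(days)) max(days) else NA_real_
        ))
      }
      delta <- percent_change(vols)
      dbl <- doubling_event(days, vols)
      tibble::tibble(
        best_response = best_response(days, delta, br_window),
        best_avg_response = best_avg_response(days, delta, bar_window),
        doubling_time = dbl$time,
        doubling_event = dbl$event,
        n_days_observed = max(days)
      )
    }) |>
    dplyr::ungroup()

  unclass_n <- sum(is.na(res$best_avg_response))
  if (unclass_n > 0) {
    warning(unclass_n, " series observed for <", bar_window,
            " days (or lacking day 0) were dropped from classification")
    res <- dplyr::filter(res, !is.na(.data$best_avg_response))
  }
  res |>
    dplyr::mutate(mrecist = classify_mrecist(.data$best_response,
                                             .data$best_avg_response,
                                             criteria)) |>
    dplyr::select("model_id", "arm", "animal_id", "best_response",
                  "best_avg_response", "mrecist", "doubling_time",
                  "doubling_event", "n_days_observed")
}
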