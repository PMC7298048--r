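#' Configuration for a synthetic PDX cohort
#'
#' Bundles and validates the parameters of the cohort simulator. The
#' defaults emulate a mid-size single-agent PDX trial: ~30 models, four
#' treatment arms plus an untreated control, twice-weekly calipering over
#' a 28-day study, 100 mm^3 enrolment volume and ~10% caliper noise.
#'
#' The latent growth model for each model x arm is biphasic: a resistant
#' compartment (fraction `f_r` of baseline) grows exponentially at rate
#' `g` while the sensitive remainder regresses at rate `k` under drug, so
#' `V(t) = V0 * (f_r * exp(g t) + (1 - f_r) * exp(-k t))`. Untreated arms
#' have `k = 0`, `f_r = 1`. The resistant fraction increases linearly
#' with the number of drug lines the donor patient received before
#' engraftment (`prior_drug_effect` per drug, clipped to `[0, 1]`),
#' encoding acquired cross-resistance.
#'
#' @param n_models Number of PDX models.
#' @param arms Character vector of arm names; must include `"untreated"`.
#' @param measurement_days Ascending day offsets including 0.
#' @param baseline_volume Enrolment volume in mm^3.
#' @param growth_rate_range Per-day exponential growth-rate interval for
#'   the resistant/untreated compartment.
#' @param kill_rate_range Per-day regression-rate interval for the
#'   sensitive compartment under drug.
#' @param resistant_fraction_range Interval in `[0, 1]` for the baseline
#'   resistant fraction before the prior-treatment shift.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise on volume.
#' @param prior_drug_effect Additive shift of the resistant fraction per
#'   prior drug line.
#' @param mean_prior_drugs Mean of the Poisson draw for per-model prior
#'   drug counts.
#' @param n_features,n_rppa_features Feature counts of the simulated RNA
#'   and RPPA matrices.
#' @param n_spikes_per_sample Expression outliers planted per sample.
#' @param spike_magnitude Spike position in IQR units above Q3 of the
#'   feature's pre-spike distribution.
#' @param seed Integer root seed; per-model child seeds are derived from
#'   it (see [simulate_pdx_cohort()]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_models = 30,
                       arms = c("untreated", "doxorubicin", "gemcitabine",
                                "cisplatin", "paclitaxel"),
                       measurement_days = seq(0, 28, by = 4),
                       baseline_volume = 100,
                       growth_rate_range = c(0.03, 0.09),
                       kill_rate_range = c(0.05, 0.35),
                       resistant_fraction_range = c(0, 0.6),
                       noise_cv = 0.1,
                       prior_drug_effect = 0.08,
                       mean_prior_drugs = 3,
                       n_features = 500,
                       n_rppa_features = 100,
                       n_spikes_per_sample = 2,
                       spike_magnitude = 3,
                       seed = 1L) {
  cfg <- list(
    n_models = as.integer(n_models), arms = arms,
    measurement_days = measurement_days,
    baseline_volume = baseline_volume,
    growth_rate_range = growth_rate_range,
    kill_rate_range = kill_rate_range,
    resistant_fraction_range = resistant_fraction_range,
    noise_cv = noise_cv, prior_drug_effect = prior_drug_effect,
    mean_prior_drugs = mean_prior_drugs,
    n_features = as.integer(n_features),
    n_rppa_features = as.integer(n_rppa_features),
    n_spikes_per_sample = as.integer(n_spikes_per_sample),
    spike_magnitude = spike_magnitude,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok_range <- function(r) length(r) == 2 && !any(is.na(r)) && r[1] <= r[2]
  if (cfg$n_models < 1) stop_pdx("n_models must be >= 1", "invalid_config")
  if (!"untreated" %in% cfg$arms) {
    stop_pdx("arms must include an 'untreated' control arm", "invalid_config")
  }
  d <- cfg$measurement_days
  if (length(d) < 2 || d[1] != 0 || any(diff(d) <= 0) || any(d < 0)) {
    stop_pdx("measurement_days must be ascending, non-negative, include 0",
             "invalid_config")
  }
  if (!ok_range(cfg$growth_rate_range) || !ok_range(cfg$kill_rate_range) ||
      !ok_range(cfg$resistant_fraction_range)) {
    stop_pdx("rate ranges must be length-2 with lower <= upper",
             "invalid_config")
  }
  if (any(cfg$resistant_fraction_range < 0) ||
      any(cfg$resistant_fraction_range > 1)) {
    stop_pdx("resistant_fraction_range must lie in [0, 1]", "invalid_config")
  }
  if (cfg$noise_cv < 0) stop_pdx("noise_cv must be >= 0", "invalid_config")
  if (cfg$baseline_volume <= 0) {
    stop_pdx("baseline_volume must be positive", "invalid_config")
  }
  invisible(cfg)
}

#' Simulate one tumor-volume trajectory
#'
#' Evaluates the biphasic latent model
#' `V(t) = V0 * (f_r * exp(g t) + (1 - f_r) * exp(-k t))` at the given
#' days, multiplies each value by lognormal noise with coefficient of
#' variation `noise_cv` (mean 1, so noise is unbiased on the volume
#' scale), and back-converts each noisy volume to a caliper pair
#' consistent with `V = L W^2 / 2` at the fixed aspect ratio
#' `L = aspect * W`.
#'
#' @param v0 Baseline volume (mm^3), > 0.
#' @param growth_rate Per-day growth rate `g` of the resistant
#'   compartment (>= 0).
#' @param kill_rate Per-day regression rate `k` of the sensitive
#'   compartment (>= 0).
#' @param resistant_fraction Fraction `f_r` in `[0, 1]`.
#' @param days Ascending day offsets including 0.
#' @param noise_cv Lognormal noise CV (>= 0).
#' @param aspect Length-to-width ratio used to split volumes into
#'   calipers (default 1).
#' @param seed Optional integer seed applied locally.
#' @return A tibble with columns `day`, `volume_true`, `volume`,
#'   `length_mm`, `width_mm`.
#' @export
simulate_growth <- function(v0, growth_rate, kill_rate, resistant_fraction,
                            days, noise_cv = 0, aspect = 1, seed = NULL) {
  if (v0 <= 0) stop_pdx("baseline volume must be positive", "invalid_parameter")
  if (growth_rate < 0 || kill_rate < 0) {
    stop_pdx("rates must be non-negative", "invalid_parameter")
  }
  if (resistant_fraction < 0 || resistant_fraction > 1) {
    stop_pdx("resistant_fraction must lie in [0, 1]", "invalid_parameter")
  }
  if (noise_cv < 0) stop_pdx("noise_cv must be >= 0", "invalid_parameter")
  if (length(days) == 0 || days[1] != 0 || any(diff(days) <= 0)) {
    stop_pdx("days must be ascending and include 0", "invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  latent <- v0 * (resistant_fraction * exp(growth_rate * days) +
                    (1 - resistant_fraction) * exp(-kill_rate * days))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(days), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise <- rep(1, length(days))
  }
  v <- latent * noise
  width <- (2 * v / aspect)^(1 / 3)
  tibble::tibble(
    day = days, volume_true = latent, volume = v,
    length_mm = aspect * width, width_mm = width
  )
}

# child seed for unit i of kind `offset`: stable under adding models
# because each model's stream depends only on (root seed, i)
child_seed <- function(root, i, offset = 0L) {
  (as.integer(root) %% 100000L) * 20011L + offset * 1009L + i
}

#' Simulate a synthetic PDX cohort
#'
#' Generates a full cohort under the one-animal-per-arm design: latent
#' growth parameters per model x arm, caliper measurement tables,
#' subtype-structured RNA and RPPA expression matrices with planted
#' outlier spikes, a mutation/CNA call table, clinical annotations with
#' prior-drug counts and patient response calls, and a truth table of the
#' latent parameters and the mRECIST category implied by each noiseless
#' trajectory.
#'
#' Randomness uses a single root seed with per-model child seeds derived
#' by a fixed counter scheme, so a cohort is reproducible and models
#' already simulated do not change when `n_models` grows.
#'
#' Patient response calls per drug are the intended (noiseless) PDX call
#' flipped with probability `1 - concordance` and thinned to `untested`
#' at random, emulating incomplete pre-engraftment treatment histories.
#'
#' @param config A [sim_config()] object.
#' @param concordance Probability a patient call agrees with the intended
#'   PDX sensitivity call (default 0.65).
#' @return A list of class `pdx_cohort` with elements `measurements`,
#'   `annotations`, `rna`, `rppa`, `mutations`, `truth`, `spikes` and
#'   `config`.
#' @examples
#' cohort <- simulate_pdx_cohort(sim_config(n_models = 4, seed = 7))
#' names(cohort)
#' @export
simulate_pdx_cohort <- function(config = sim_config(), concordance = 0.65) {
  validate_sim_config(config)
  cfg <- config
  treated_arms <- setdiff(cfg$arms, "untreated")
  model_ids <- sprintf("SIM%03d", seq_len(cfg$n_models))

  per_model <- purrr::map(seq_len(cfg$n_models), function(i) {
    set.seed(child_seed(cfg$seed, i, 0L))
    prior_drugs <- stats::rpois(1, cfg$mean_prior_drugs)
    g <- stats::runif(1, cfg$growth_rate_range[1], cfg$growth_rate_range[2])
    f_base <- stats::runif(1, cfg$resistant_fraction_range[1],
                           cfg$resistant_fraction_range[2])
    arm_rows <- purrr::map(cfg$arms, function(arm) {
      if (arm == "untreated") {
        k <- 0; f_r <- 1
      } else {
        k <- stats::runif(1, cfg$kill_rate_range[1], cfg$kill_rate_range[2])
        f_r <- min(1, max(0, f_base + cfg$prior_drug_effect * prior_drugs +
                            stats::runif(1, -0.05, 0.05)))
      }
      tibble::tibble(arm = arm, growth_rate = g, kill_rate = k,
                     resistant_fraction = f_r)
    }) |> purrr::list_rbind()
    arm_rows$model_id <- model_ids[i]
    arm_rows$prior_drug_count <- prior_drugs
    arm_rows
  }) |> purrr::list_rbind()

  # intended category from the noiseless trajectory
  truth <- per_model |>
    dplyr::rowwise() |>
    dplyr::mutate(intended = {
      tr <- simulate_growth(cfg$baseline_volume, .data$growth_rate,
                            .data$kill_rate, .data$resistant_fraction,
                            cfg$measurement_days, noise_cv = 0)
      delta <- percent_change(tr$volume_true)
      as.character(classify_mrecist(
        best_response(cfg$measurement_days, delta),
        best_avg_response(cfg$measurement_days, delta)))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("model_id", "arm", "growth_rate", "kill_rate",
                  "resistant_fraction", "prior_drug_count", "intended")

  measurements <- purrr::map(seq_len(cfg$n_models), function(i) {
    rows <- truth[truth$model_id == model_ids[i], ]
    purrr::map(seq_len(nrow(rows)), function(j) {
      tr <- simulate_growth(
        cfg$baseline_volume, rows$growth_rate[j], rows$kill_rate[j],
        rows$resistant_fraction[j], cfg$measurement_days,
        noise_cv = cfg$noise_cv,
        seed = child_seed(cfg$seed, i, 1L) + j * 131L)
      tibble::tibble(model_id = rows$model_id[j], arm = rows$arm[j],
                     animal_id = paste0(rows$model_id[j], "_", rows$arm[j], "_a1"),
                     day = tr$day, length_mm = tr$length_mm,
                     width_mm = tr$width_mm)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  # annotations: subtype mix emulating a TN/HER2-skewed breast PDX library
  set.seed(child_seed(cfg$seed, 0L, 2L))
  subtypes <- sample(c("Basal", "HER2E", "LumB"), cfg$n_models,
                     replace = TRUE, prob = c(0.70, 0.27, 0.03))
  er <- ifelse(subtypes == "LumB", "+", ifelse(stats::runif(cfg$n_models) < 0.15, "+", "-"))
  her2 <- ifelse(subtypes == "HER2E", ifelse(stats::runif(cfg$n_models) < 0.7, "+", "-"), "-")
  brca <- sample(c("", "BRCA1", "BRCA2"), cfg$n_models, replace = TRUE,
                 prob = c(0.8, 0.15, 0.05))
  prior_by_model <- truth |>
    dplyr::distinct(.data$model_id, .data$prior_drug_count)

  intended_wide <- truth |>
    dplyr::filter(.data$arm != "untreated") |>
    dplyr::select("model_id", "arm", "intended")
  patient_calls <- intended_wide |>
    dplyr::mutate(
      pdx_sensitive = .data$intended %in% c("CR", "PR"),
      flip = stats::runif(dplyr::n()) > concordance,
      untested = stats::runif(dplyr::n()) < 0.25,
      patient_response = dplyr::case_when(
        .data$untested ~ "untested",
        xor(.data$pdx_sensitive, .data$flip) ~ "sensitive",
        TRUE ~ "resistant"
      )
    ) |>
    dplyr::select("model_id", drug = "arm", "patient_response")

  annotations <- tibble::tibble(
    model_id = model_ids, pdx_subtype = subtypes, pdx_er = er,
    pdx_her2 = her2, germline_brca = brca
  ) |>
    dplyr::left_join(prior_by_model, by = "model_id")

  # expression: subtype block structure + spiked outliers
  rna <- simulate_expression(model_ids, subtypes, cfg$n_features,
                             cfg$n_spikes_per_sample, cfg$spike_magnitude,
                             child_seed(cfg$seed, 0L, 3L), prefix = "GENE")
  rppa <- simulate_expression(model_ids, subtypes, cfg$n_rppa_features,
                              max(1L, cfg$n_spikes_per_sample %/% 2L),
                              cfg$spike_magnitude,
                              child_seed(cfg$seed, 0L, 4L), prefix = "PROT")

  mutations <- simulate_mutations(model_ids, child_seed(cfg$seed, 0L, 5L))

  structure(list(
    measurements = measurements, annotations = annotations,
    rna = rna$matrix, rppa = rppa$matrix, mutations = mutations,
    truth = truth, patient_responses = patient_calls,
    spikes = dplyr::bind_rows(
      dplyr::mutate(rna$spikes, platform = "RNA"),
      dplyr::mutate(rppa$spikes, platform = "RPPA")),
    config = cfg
  ), class = "pdx_cohort")
}

# block-structured lognormal-ish expression with planted outlier spikes;
# spikes are placed at Q3 + magnitude*IQR of the feature's pre-spike values
simulate_expression <- function(sample_ids, subtypes, n_features, n_spikes,
                                magnitude, seed, prefix = "GENE") {
  set.seed(seed)
  n <- length(sample_ids)
  features <- sprintf("%s%04d", prefix, seq_len(n_features))
  # first 20% of features carry subtype-specific mean shifts
  n_block <- max(1L, n_features %/% 5L)
  shift <- matrix(0, n_features, n)
  for (st in unique(subtypes)) {
    idx <- which(subtypes == st)
    block_means <- stats::rnorm(n_block, mean = 0, sd = 1.5)
    shift[seq_len(n_block), idx] <- block_means
  }
  values <- matrix(stats::rnorm(n_features * n, mean = 8, sd = 1),
                   n_features, n) + shift
  dimnames(values) <- list(features, sample_ids)
  spikes <- purrr::map(seq_len(n), function(j) {
    feats <- sample(seq_len(n_features), n_spikes)
    tibble::tibble(feature = features[feats], sample = sample_ids[j],
                   row = feats, col = j)
  }) |> purrr::list_rbind()
  for (r in seq_len(nrow(spikes))) {
    i <- spikes$row[r]; j <- spikes$col[r]
    q <- stats::quantile(values[i, ], c(0.25, 0.75), names = FALSE)
    values[i, j] <- q[2] + magnitude * (q[2] - q[1])
  }
  list(matrix = values, spikes = dplyr::select(spikes, "feature", "sample"))
}

simulate_mutations <- function(model_ids, seed) {
  set.seed(seed)
  panel <- tibble::tibble(
    gene = c("PIK3CA", "PIK3CA", "ERBB2", "TP53", "ATM", "ARID1A",
             "CDH1", "PIK3R1", "FGFR1", "MYC", "MDM2", "PTEN", "INPP4B"),
    alteration = c("H1047R", "E545K", "L755S", "R175H", "truncating",
                   "truncating", "truncating", "truncating", "amp", "amp",
                   "amp", "del", "del"),
    class = c("hotspot-mutation", "hotspot-mutation", "hotspot-mutation",
              "hotspot-mutation", "truncating", "truncating", "truncating",
              "truncating", "amplification", "amplification",
              "amplification", "deletion", "deletion")
  )
  purrr::map(model_ids, function(m) {
    k <- stats::rpois(1, 2)
    if (k == 0) return(NULL)
    rows <- panel[sample(nrow(panel), min(k, nrow(panel))), ]
    dplyr::mutate(rows, model_id = m, .before = 1)
  }) |> purrr::list_rbind()
}

#' @export
print.pdx_cohort <- function(x, ...) {
  cat("<pdx_cohort> ", x$config$n_models, " models x ",
      length(x$config$arms), " arms; ",
      nrow(x$measurements), " caliper measurements\n", sep = "")
  cat("  RNA ", nrow(x$rna), " x ", ncol(x$rna), "; RPPA ", nrow(x$rppa),
      " x ", ncol(x$rppa), "; ", nrow(x$mutations %||% data.frame()),
      " mutation calls\n", sep = "")
  invisible(x)
}
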