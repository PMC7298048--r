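test_that("objective response rate counts CR and PR", {
  expect_equal(objective_response_rate(c("CR", "PR", "SD", "PD")), 50)
  expect_equal(objective_response_rate(c("PD", "PD", "PD")), 0)
  expect_equal(objective_response_rate(c(rep("CR", 2), rep("PR", 3),
                                         rep("SD", 10), rep("PD", 10))), 20)
  expect_error(objective_response_rate(character()),
               class = "pdxtrial_undefined_rate")
})

test_that("chemosensitivity needs >= 2 objective responses of >= 2 agents", {
  resp <- tibble::tibble(
    model_id = c(rep("A", 4), rep("B", 4), rep("C", 2), rep("D", 1),
                 rep("E", 2)),
    arm = c(paste0("d", 1:4), paste0("d", 1:4), paste0("d", 1:2), "d1",
            c("d1", "untreated")),
    mrecist = c("CR", "CR", "PD", "PD",
                "PR", "SD", "SD", "PD",
                "PR", "PR", "CR", "CR", "PD"))
  cls <- classify_chemosensitivity(resp)
  get <- function(m) cls$chemo_class[cls$model_id == m]
  expect_equal(get("A"), "chemosensitive")
  expect_equal(get("B"), "chemoresistant")
  expect_equal(get("C"), "chemosensitive") # two agents is the minimum
  expect_true(is.na(get("D"))) # single agent: not classifiable
  expect_true(is.na(get("E"))) # untreated arm does not count as tested
})

test_that("product-limit estimate matches hand computation and empirical S", {
  # no ties, all events
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # tied events: risk set 4 at t=2 with 2 events -> factor (1 - 2/4)
  km2 <- km_fit(c(2, 2, 3, 5), c(1, 1, 1, 0))
  expect_equal(km2$survival[km2$time == 2], 1 - 2 / 4)
  # all censored -> survival stays 1
  km3 <- km_fit(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  # uncensored: equals the empirical survivor function
  set.seed(1)
  tt <- sample(1:20, 30, replace = TRUE)
  km4 <- km_fit(tt, rep(1, 30))
  emp <- sapply(km4$time, function(t0) mean(tt > t0))
  expect_equal(km4$survival, emp, tolerance = 1e-12)
})

test_that("product-limit estimate agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(5)
  tt <- rexp(40, 0.1)
  ev <- rbinom(40, 1, 0.7)
  km <- km_fit(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km$survival[km$n_event > 0],
               sf$surv[sf$n.event > 0], tolerance = 1e-9)
})

test_that("log-rank test matches a hand O-E computation and survdiff", {
  # identical groups -> chi2 = 0, p = 1
  same <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # 6-subject worked example, O-E accumulated by hand:
  # t=1: E_a += 3/6, V += .25; t=2: E_a += 2/5, V += .24;
  # t=3: E_a += 1/4, V += .1875; group b events occur with n_a = 0
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(10, 11, 12), c(1, 1, 1))
  expect_equal(unname(lr$expected["a"]), 0.5 + 0.4 + 0.25, tolerance = 1e-12)
  expect_equal(lr$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)
  expect_lt(lr$p, 0.05)

  skip_if_not_installed("survival")
  set.seed(8)
  ta <- rexp(25, 0.1); ea <- rbinom(25, 1, 0.8)
  tb <- rexp(25, 0.2); eb <- rbinom(25, 1, 0.8)
  lr2 <- logrank_test(ta, ea, tb, eb)
  sd2 <- survival::survdiff(
    survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, each = 25))
  expect_equal(lr2$chisq, sd2$chisq, tolerance = 1e-9)
})

test_that("log-rank is symmetric in its arguments", {
  set.seed(3)
  ta <- rexp(15, 0.1); ea <- rbinom(15, 1, 0.7)
  tb <- rexp(20, 0.3); eb <- rbinom(20, 1, 0.7)
  ab <- logrank_test(ta, ea, tb, eb)
  ba <- logrank_test(tb, eb, ta, ea)
  expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("log-rank degenerate inputs error cleanly", {
  expect_error(logrank_test(numeric(), integer(), 1, 1),
               class = "pdxtrial_empty_sample")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
               class = "pdxtrial_no_events")
})

test_that("replicate reproducibility returns Pearson r with p", {
  expect_equal(replicate_reproducibility(c(1, 2, 3, 4), c(1, 2, 3, 4))$r, 1)
  expect_equal(replicate_reproducibility(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, -1)
  expect_error(replicate_reproducibility(c(1, 1, 1), c(1, 2, 3)),
               class = "pdxtrial_undefined_correlation")
  expect_error(replicate_reproducibility(c(1, 2), c(1, 2)),
               class = "pdxtrial_too_few_pairs")
})

test_that("simulated replicates at low noise are highly correlated", {
  cfg <- sim_config(n_models = 13, noise_cv = 0.05, seed = 31)
  r1 <- suppressWarnings(pdx_response(
    simulate_pdx_cohort(cfg)$measurements))
  # replicate: same latent parameters, fresh measurement noise
  co <- simulate_pdx_cohort(cfg)
  set.seed(99)
  meas2 <- co$measurements
  meas2$length_mm <- meas2$length_mm * exp(rnorm(nrow(meas2), 0, 0.02))
  meas2$width_mm <- meas2$width_mm * exp(rnorm(nrow(meas2), 0, 0.02))
  r2 <- suppressWarnings(pdx_response(meas2))
  pairs <- dplyr::inner_join(r1, r2, by = c("model_id", "arm"),
                             suffix = c("_1", "_2"))
  rr <- replicate_reproducibility(pairs$best_avg_response_1,
                                  pairs$best_avg_response_2)
  expect_gt(rr$r, 0.9)
})

test_that("patient-PDX concordance collapses calls and counts matches", {
  resp <- tibble::tibble(
    model_id = c("A", "A", "B", "B"),
    arm = c("dox", "cis", "dox", "cis"),
    mrecist = c("CR", "SD", "PD", "PR"))
  pt <- tibble::tibble(
    model_id = c("A", "A", "B", "B", "B"),
    drug = c("dox", "cis", "dox", "cis", "gem"),
    patient_response = c("sensitive", "resistant", "sensitive", "SD",
                         "untested"))
  out <- patient_pdx_concordance(resp, pt)
  # A/dox: sens-CR conc; A/cis: res-SD conc; B/dox: sens-PD disc;
  # B/cis: SD(resistant)-PR disc; B/gem untested -> excluded
  expect_equal(nrow(out$combinations), 4)
  expect_equal(out$percent_concordant, 50)
  # invariant to row order and to adding untested combinations
  out2 <- patient_pdx_concordance(resp[sample(4), ],
                                  dplyr::bind_rows(pt[sample(5), ],
                                                   tibble::tibble(
                                                     model_id = "A",
                                                     drug = "gem",
                                                     patient_response = "untested")))
  expect_equal(out2$percent_concordant, out$percent_concordant)
  # 3 of 4 matching -> 75
  resp3 <- dplyr::mutate(resp,
                         mrecist = c("CR", "SD", "PR", "PR"))
  expect_equal(patient_pdx_concordance(resp3, pt)$percent_concordant, 75)
})

test_that("exposure-response correlation rejects degenerate exposure", {
  resp <- tibble::tibble(model_id = c("A", "B", "C"),
                         arm = "dox",
                         best_avg_response = c(-50, 0, 50))
  ann <- tibble::tibble(model_id = c("A", "B", "C"), prior_drug_count = 2)
  expect_error(exposure_response_correlation(resp, ann),
               class = "pdxtrial_undefined_correlation")
})

test_that("separated kill rates make chemosensitive models respond deeper", {
  co <- simulate_pdx_cohort(sim_config(
    n_models = 40, kill_rate_range = c(0.02, 0.5),
    resistant_fraction_range = c(0, 0.9), noise_cv = 0.05, seed = 77))
  resp <- suppressWarnings(pdx_response(co$measurements))
  cls <- classify_chemosensitivity(resp)
  merged <- resp |>
    dplyr::filter(arm != "untreated") |>
    dplyr::group_by(model_id) |>
    dplyr::summarise(mean_bar = mean(best_avg_response)) |>
    dplyr::inner_join(cls, by = "model_id") |>
    dplyr::filter(!is.na(chemo_class))
  means <- tapply(merged$mean_bar, merged$chemo_class, mean)
  expect_lt(means["chemosensitive"], means["chemoresistant"])
})

test_that("waterfall table sorts ascending within arm", {
  resp <- tibble::tibble(model_id = c("A", "B", "C", "A", "B"),
                         arm = c("d1", "d1", "d1", "d2", "d2"),
                         best_avg_response = c(10, -40, 3, 5, -2),
                         mrecist = factor("SD", levels = c("CR", "PR", "SD", "PD")))
  wf <- waterfall_table(resp)
  expect_equal(wf$model_id[wf$arm == "d1"], c("B", "C", "A"))
  expect_equal(wf$rank[wf$arm == "d2"], 1:2)
})
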