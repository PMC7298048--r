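test_that("median centering gives zero-median features and is idempotent", {
  m <- rbind(A = c(1, 2, 4), B = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  cm <- median_center_log2(m, scale = "linear")
  expect_equal(cm["A", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(cm["B", ], c(s1 = 0, s2 = 0, s3 = 0))
  # already-centered log2 input is a fixed point
  expect_equal(median_center_log2(cm), cm)
  expect_error(median_center_log2(rbind(c(-1, 2, 3)), scale = "linear"),
               class = "pdxtrial_nonpositive")
})

test_that("outlier score is (x - Q3)/IQR with a strict 1.5 call threshold", {
  # values engineered so Q3 = 6, IQR = 4 under type-7 quantiles
  v <- c(2, 2, 6, 6)
  expect_equal(quantile(v, 0.75, names = FALSE), 6)
  expect_equal(outlier_score(v, 6), 0)
  expect_equal(outlier_score(v, 12), 1.5)
  expect_gt(outlier_score(v, 12.1), 1.5)
  # score exactly 1.5 is NOT an outlier anywhere in the pipeline
  m <- rbind(F1 = c(2, 2, 6, 6, 12))
  colnames(m) <- paste0("s", 1:5)
  calls <- call_outliers(m)
  # leave-value-in: 12 contributes to its own quartiles
  q <- quantile(c(2, 2, 6, 6, 12), c(0.25, 0.75), names = FALSE)
  expect_equal(calls$score[calls$sample == "s5"],
               (12 - q[2]) / (q[2] - q[1]))
  expect_error(outlier_score(c(1, 2, 3), 2),
               class = "pdxtrial_too_few_values")
})

test_that("outlier score is translation-equivariant", {
  set.seed(11)
  v <- rnorm(20)
  for (shift in c(-3, 0.5, 10)) {
    expect_equal(outlier_score(v + shift, 1 + shift),
                 outlier_score(v, 1), tolerance = 1e-12)
  }
})

test_that("call_outliers flags exactly the spiked cells", {
  set.seed(2)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("F", 1:50), paste0("s", 1:20)))
  q <- quantile(m[7, ], c(0.25, 0.75), names = FALSE)
  m[7, 3] <- q[2] + 10 * (q[2] - q[1])
  calls <- call_outliers(m)
  flagged <- calls[calls$outlier, ]
  expect_true(any(flagged$feature == "F7" & flagged$sample == "s3"))
  # constant features produce no calls at all
  m2 <- matrix(5, 10, 10, dimnames = list(paste0("F", 1:10), paste0("s", 1:10)))
  expect_equal(nrow(call_outliers(m2)), 0)
})

test_that("spiked cohort outliers are recovered against the truth table", {
  co <- simulate_pdx_cohort(sim_config(n_models = 30, seed = 19))
  for (platform in c("RNA", "RPPA")) {
    mat <- if (platform == "RNA") co$rna else co$rppa
    sp <- co$spikes[co$spikes$platform == platform, ]
    calls <- call_outliers(mat)
    hits <- dplyr::inner_join(sp, calls[calls$outlier, ],
                              by = c("feature", "sample"))
    expect_gte(nrow(hits) / nrow(sp), 0.95)
  }
})

test_that("signature scores sum positives minus negatives after centering", {
  m <- rbind(A = c(1, 1, 1), B = c(2, 2, 2), C = c(0.5, 0.5, 0.5))
  colnames(m) <- paste0("s", 1:3)
  # already-centered semantics: center = FALSE
  sc <- signature_score(m, positive = c("A", "B"), negative = "C",
                        center = FALSE)
  expect_equal(unname(sc), rep(2.5, 3))
  # flipping a feature from positive to negative negates its contribution
  sc_flip <- signature_score(m, positive = "A", negative = c("B", "C"),
                             center = FALSE)
  expect_equal(unname(sc - sc_flip), rep(2 * 2, 3))
  # single positive component equals the centered value itself
  one <- signature_score(m, positive = "A", center = TRUE)
  cm <- median_center_log2(m)
  expect_equal(one, cm["A", ])
  # missing components are dropped with a message; all missing errors
  expect_message(signature_score(m, positive = c("A", "ZZZ"), center = FALSE),
                 "dropped")
  expect_error(signature_score(m, positive = "ZZZ", center = FALSE),
               class = "pdxtrial_missing_components")
  expect_error(signature_score(m, positive = "A", negative = "A"),
               class = "pdxtrial_overlapping_signature")
})

test_that("signature score is linear in the matrix values", {
  set.seed(23)
  m1 <- matrix(rnorm(30), 5, 6,
               dimnames = list(LETTERS[1:5], paste0("s", 1:6)))
  m2 <- matrix(rnorm(30), 5, 6, dimnames = dimnames(m1))
  pos <- c("A", "C"); neg <- "E"
  s_sum <- signature_score(m1 + m2, pos, neg, center = FALSE)
  expect_equal(s_sum,
               signature_score(m1, pos, neg, center = FALSE) +
                 signature_score(m2, pos, neg, center = FALSE),
               tolerance = 1e-12)
})

test_that("ssGSEA matches the cumulative-sum oracle on small universes", {
  set.seed(29)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    v <- rnorm(n)
    names(v) <- paste0("g", seq_len(n))
    k <- sample(1:(n - 1), 1)
    set <- sample(names(v), k)
    for (alpha in c(0, 0.25, 1)) {
      expect_equal(ssgsea_score(v, set, alpha),
                   brute_ssgsea(v, set, alpha), tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA signs and symmetries behave as expected", {
  v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_gt(ssgsea_score(v, "g1", alpha = 0), 0)
  expect_lt(ssgsea_score(v, "g4", alpha = 0), 0)
  # complement sets have opposite signs at alpha = 0
  s <- ssgsea_score(v, c("g1", "g2"), alpha = 0)
  expect_equal(ssgsea_score(v, c("g3", "g4"), alpha = 0), -s,
               tolerance = 1e-12)
  # identical rankings give identical scores regardless of scale
  expect_equal(ssgsea_score(v * 10 + 2, c("g1", "g3"), 0.25),
               ssgsea_score(v, c("g1", "g3"), 0.25))
  expect_error(ssgsea_score(v, names(v)), class = "pdxtrial_set_is_universe")
  expect_error(ssgsea_score(v, "absent"), class = "pdxtrial_empty_set")
})

test_that("BH adjustment matches the brute-force step-up everywhere", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(37)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
    # BH never decreases a p-value
    expect_true(all(p.adjust(p, "BH") >= p))
    # rejection set invariant under permutation
    perm <- sample(length(p))
    expect_equal(p.adjust(p, "BH")[perm], p.adjust(p[perm], "BH"))
  }
})

test_that("RNA-protein correlation recovers planted relationships", {
  set.seed(41)
  n <- 20
  samples <- paste0("s", 1:n)
  rna <- matrix(rnorm(30 * n), 30, n,
                dimnames = list(paste0("T", 1:30), samples))
  rppa <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("P", 1:10), samples))
  # P1 exactly tracks T1
  rppa["P1", ] <- rna["T1", ]
  pm <- tibble::tibble(probe = paste0("P", 1:10),
                       transcript = paste0("T", 1:10))
  out <- rna_protein_correlation(rna, rppa, pm)
  row1 <- out$table[out$table$probe == "P1", ]
  expect_equal(row1$r, 1, tolerance = 1e-9)
  expect_lt(row1$p_adjusted, 1e-6)
  # independent noise probes mostly non-significant
  expect_lt(out$percent_significant, 30)
  expect_error(rna_protein_correlation(rna[, 1:2], rppa[, 1:2], pm),
               class = "pdxtrial_too_few_samples")
})

test_that("expression and GMT files round-trip", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, tmp)
  expect_equal(read_expression(tmp), m, tolerance = 1e-12)
  sets <- list(SET1 = c("A", "B"), PI3K_POS = c("B", "C"), PI3K_NEG = "A")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_equal(read_gmt(gmt), sets)
  sigs <- read_signatures(gmt)
  expect_equal(sigs$PI3K$positive, c("B", "C"))
  expect_equal(sigs$PI3K$negative, "A")
})
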