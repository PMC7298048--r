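#' Median-center an expression matrix on the log2 scale
#'
#' Log2-transforms a linear-scale matrix (values must be positive) and
#' subtracts each feature's median across samples, so every feature has
#' median 0. Matrices already on the log2 scale are centered without
#' transformation; centering is idempotent.
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param scale Either `"log2"` (default; values already log-scale) or
#'   `"linear"` (log2 applied first).
#' @return A centered matrix with the same dimnames.
#' @export
median_center_log2 <- function(mat, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (scale == "linear") {
    if (any(mat <= 0, na.rm = TRUE)) {
      stop_pdx("linear-scale values must be strictly positive", "nonpositive")
    }
    mat <- log2(mat)
  }
  meds <- apply(mat, 1, stats::median, na.rm = TRUE)
  sweep(mat, 1, meds, "-")
}

#' IQR outlier score
#'
#' The outlier score of an observation x against a feature's per-sample
#' distribution is `(x - Q3) / IQR`, with quartiles under the linear
#' order-statistic interpolation convention (position `h = (n-1)p + 1`,
#' R's default type 7). An observation is called an outlier when its
#' score strictly exceeds 1.5. When the IQR is 0 the score is undefined
#' (`NA`) and never an outlier.
#'
#' @param values Numeric vector: the feature's values across samples
#'   (the reference distribution, which includes x itself under the
#'   leave-value-in convention).
#' @param x Numeric vector of observations to score against `values`.
#' @return Numeric vector of scores (NA where IQR is 0).
#' @export
outlier_score <- function(values, x) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    stop_pdx("need >= 4 values to define quartiles", "too_few_values")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(rep(NA_real_, length(x)))
  (x - q[2]) / iqr
}

#' Call expression outliers across a matrix
#'
#' Applies [outlier_score()] feature by feature, scoring each sample's
#' value against its feature's full per-sample distribution
#' (leave-value-in), and flags pairs with score > 1.5. Constant features
#' (IQR 0) never yield calls.
#'
#' @param mat Numeric matrix, features x samples.
#' @param threshold Outlier call threshold on the score (default 1.5,
#'   strict inequality).
#' @return A tibble of (feature, sample, value, score, outlier) for all
#'   finite scores.
#' @export
call_outliers <- function(mat, threshold = 1.5) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat))
  scores <- t(apply(mat, 1, function(v) {
    vv <- v[!is.na(v)]
    if (length(vv) < 4) return(rep(NA_real_, length(v)))
    q <- stats::quantile(vv, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    if (iqr == 0) return(rep(NA_real_, length(v)))
    (v - q[2]) / iqr
  }))
  tibble::tibble(
    feature = rep(rownames(mat), times = ncol(mat)),
    sample = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat),
    score = as.vector(scores)
  ) |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::mutate(outlier = .data$score > threshold)
}

#' RPPA pathway signature score
#'
#' Scores a pathway signature per sample by summing its positive
#' regulatory components and subtracting its negative regulatory
#' components on median-centered log2 values. Components absent from the
#' matrix are dropped with a message; a signature with no matching
#' components is an error.
#'
#' @param mat Numeric matrix, features x samples (centered internally
#'   unless `center = FALSE`).
#' @param positive,negative Character vectors of feature ids.
#' @param center Median-center the matrix first (default TRUE; set FALSE
#'   when the input is already centered).
#' @param scale Passed to [median_center_log2()] when centering.
#' @return A named numeric vector of per-sample scores.
#' @export
signature_score <- function(mat, positive, negative = character(),
                            center = TRUE, scale = "log2") {
  if (length(positive) == 0) {
    stop_pdx("signature needs at least one positive component", "empty_signature")
  }
  if (length(intersect(positive, negative)) > 0) {
    stop_pdx("positive and negative components must be disjoint",
             "overlapping_signature")
  }
  if (center) mat <- median_center_log2(mat, scale = scale)
  pos <- intersect(positive, rownames(mat))
  neg <- intersect(negative, rownames(mat))
  dropped <- length(positive) + length(negative) - length(pos) - length(neg)
  if (dropped > 0) {
    message(dropped, " signature component(s) absent from matrix; dropped")
  }
  if (length(pos) == 0 && length(neg) == 0) {
    stop_pdx("no signature components present in matrix", "missing_components")
  }
  pos_sum <- if (length(pos)) colSums(mat[pos, , drop = FALSE]) else 0
  neg_sum <- if (length(neg)) colSums(mat[neg, , drop = FALSE]) else 0
  pos_sum - neg_sum
}

#' Single-sample gene-set enrichment score
#'
#' A per-sample enrichment score for one gene set: features are ranked by
#' decreasing expression (ties broken by stable feature order), in-set
#' features accumulate weight `rank^alpha` (rank-normalized value) while
#' out-of-set features accumulate uniformly, and the score is the sum
#' over the ranked list of the difference between the weighted in-set
#' and unweighted out-of-set cumulative distributions. With `alpha = 0`
#' the in-set weights are uniform. Scores are unnormalized and intended
#' for comparisons within one analysis.
#'
#' @param values Named numeric vector: one sample's expression, names are
#'   feature ids.
#' @param set Character vector of member feature ids.
#' @param alpha Rank weight exponent (default 0.25).
#' @return A single enrichment score.
#' @export
ssgsea_score <- function(values, set, alpha = 0.25) {
  if (is.null(names(values))) stop_pdx("values must be named", "unnamed_values")
  set <- unique(set)
  set <- set[set %in% names(values)]
  n <- length(values)
  if (length(set) == 0) stop_pdx("gene set is empty in this universe", "empty_set")
  if (length(set) == n) {
    stop_pdx("gene set equals the feature universe; out-of-set ECDF undefined",
             "set_is_universe")
  }
  # stable order: decreasing value, ties by original position
  ord <- order(-values, seq_along(values))
  in_set <- names(values)[ord] %in% set
  # rank-normalized value = N..1 down the sorted list
  rnk <- n - seq_len(n) + 1
  w <- abs(rnk)^alpha
  w_in <- ifelse(in_set, w, 0)
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_set) / (n - length(set))
  sum(p_in - p_out)
}

#' ssGSEA scores across a matrix of samples
#'
#' Convenience wrapper applying [ssgsea_score()] to every sample
#' (column) and gene set.
#'
#' @param mat Numeric matrix, features x samples.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha Rank weight exponent.
#' @return A tibble (set, sample, score).
#' @export
ssgsea <- function(mat, sets, alpha = 0.25) {
  purrr::imap(sets, function(members, set_name) {
    tibble::tibble(
      set = set_name,
      sample = colnames(mat),
      score = purrr::map_dbl(seq_len(ncol(mat)), function(j) {
        v <- mat[, j]
        names(v) <- rownames(mat)
        ssgsea_score(v, members, alpha)
      }))
  }) |> purrr::list_rbind()
}

#' RNA-protein correlation across shared samples
#'
#' For each probe in a probe-to-transcript map, computes the Pearson
#' correlation between the RPPA probe and its transcript over samples
#' shared by the two matrices (pairwise-complete), adjusts p-values by
#' Benjamini-Hochberg across probes, and reports the fraction of probes
#' significant at the given adjusted-p cutoff.
#'
#' @param rna,rppa Numeric matrices, features x samples.
#' @param probe_map Data frame with columns `probe` (RPPA feature id) and
#'   `transcript` (RNA feature id).
#' @param sig_level Adjusted-p cutoff for the significant fraction
#'   (default 0.05).
#' @return A list with `table` (probe, transcript, r, p, p_adjusted, n)
#'   and `percent_significant`.
#' @export
rna_protein_correlation <- function(rna, rppa, probe_map, sig_level = 0.05) {
  shared <- intersect(colnames(rna), colnames(rppa))
  if (length(shared) < 3) {
    stop_pdx("need >= 3 shared samples", "too_few_samples")
  }
  tab <- probe_map |>
    dplyr::filter(.data$probe %in% rownames(rppa),
                  .data$transcript %in% rownames(rna)) |>
    dplyr::mutate(purrr::map2_dfr(.data$probe, .data$transcript, function(p, t) {
      x <- rppa[p, shared]; y <- rna[t, shared]
      keep <- stats::complete.cases(x, y)
      if (sum(keep) < 3 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                              n = sum(keep)))
      }
      ct <- stats::cor.test(x[keep], y[keep])
      tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                     n = sum(keep))
    }))
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  pct <- 100 * mean(tab$p_adjusted < sig_level, na.rm = TRUE)
  list(table = tibble::as_tibble(tab), percent_significant = pct)
}
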