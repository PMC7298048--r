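# independent brute-force oracles used across tests; deliberately naive
# implementations kept separate from the package's code paths

# BestAvgResponse by explicit enumeration of every running mean
brute_best_avg <- function(days, delta, window_start = 14) {
  means <- c()
  for (i in seq_along(days)) {
    if (days[i] >= window_start) {
      means <- c(means, mean(delta[1:i]))
    }
  }
  min(means)
}

# Benjamini-Hochberg step-up by its textbook definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[ord[i]])
    adj[ord[i]] <- prev
  }
  adj
}

# ssGSEA score by explicit cumulative sums over the sorted list
brute_ssgsea <- function(values, set, alpha) {
  ord <- order(-values, seq_along(values))
  nm <- names(values)[ord]
  n <- length(values)
  in_set <- nm %in% set
  w <- (n - seq_len(n) + 1)^alpha
  num <- den <- 0
  den_w <- sum(w[in_set])
  n_out <- n - sum(in_set)
  score <- 0
  cum_in <- cum_out <- 0
  for (j in seq_len(n)) {
    if (in_set[j]) cum_in <- cum_in + w[j] else cum_out <- cum_out + 1
    score <- score + cum_in / den_w - cum_out / n_out
  }
  score
}

# product-limit estimate at each distinct time, by hand
brute_km <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  out <- data.frame(time = tt, survival = NA_real_)
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# small deterministic measurement table: one model, one arm
toy_measurements <- function(volumes,
                             days = c(0, 4, 7, 11, 14, 18, 21, 25, 28),
                             model = "M1", arm = "drugA") {
  w <- (2 * volumes)^(1 / 3)
  tibble::tibble(model_id = model, arm = arm, animal_id = paste0(model, "_a1"),
                 day = days, length_mm = w, width_mm = w)
}
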