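# internal helpers

# round-half-up to `digits` decimals; base round() is round-half-even and
# would print 72.95 -> 72.9 where clinical tables print 73.0
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pdx <- function(msg, class) {
  rlang::abort(msg, class = paste0("pdxtrial_", class))
}
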