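# Internal numerical helpers shared across fitters.

# Row-wise log-sum-exp; `m` is a numeric matrix of log terms.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# log(1 + exp(t)) without overflow.
softplus <- function(t) {
  out <- t
  small <- t < 30
  out[small] <- log1p(exp(t[small]))
  out
}

# Deterministic child seed for replication (ns, r) under a master seed.
# Pure integer arithmetic in doubles (< 2^53), reduced below 2^31 so it is a
# valid argument to set.seed() regardless of platform.
child_seed <- function(master_seed, ns, r) {
  h <- (as.numeric(master_seed) %% 2147483647) * 2654435 +
    as.numeric(ns) * 97561 + as.numeric(r) * 7919 + 1
  as.integer(h %% 2147483629)
}

# Draw from a tiny deterministic linear congruential generator, used for
# multi-start initialisation without touching the global RNG stream.
lcg_runif <- function(n, seed) {
  state <- as.numeric(seed %% 2147483647)
  if (state <= 0) state <- 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be strictly positive and finite", what), call. = FALSE)
  }
  invisible(x)
}
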