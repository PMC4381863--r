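# Independent oracles used across tests.

# Brute-force unrolling of the online kernel-size recursion.
oracle_kernel_size <- function(states, h1 = 1) {
  h <- h1
  for (n in seq_along(states)[-1]) {
    d2 <- vapply(states[seq_len(n - 1L)],
                 function(s) sum((s - states[[n]])^2), 0)
    h_temp <- sum(d2) / (2 * (n - 1L))
    h <- c(h, (sum(h) + h_temp) / n)
  }
  h
}

# Kernel LMS update toward fixed targets d, applied to a frozen function:
# one pass over (x_k, d_k), each center getting eta * (d_k - f0(x_k)).
oracle_klms <- function(f0, X, d, eta) {
  resid <- d - predict(f0, X)
  f <- f0
  for (k in seq_len(nrow(X))) {
    f$centers <- rbind(f$centers, X[k, ])
    f$coef <- c(f$coef, eta * resid[k])
  }
  f
}

# Returns-to-go of a trajectory at gamma = 1.
oracle_returns <- function(rewards) rev(cumsum(rev(rewards)))

# A chain whose every episode is the single deterministic transition
# 1 -> terminal with reward r1 (start mass moved to state 1).
single_transition_chain <- function(r1 = -2) {
  ch <- build_chain("linear")
  ch$rewards[1L] <- r1
  ch$start <- c(1, rep(0, 11))
  ch
}
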