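# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized internals.

# Fault assessment by direct rule application, player by player.
brute_fault <- function(state, kind, nu = NULL, theta = NULL) {
  N <- length(state)
  at_fault <- logical(N)
  for (i in seq_len(N)) {
    if (state[i]) next # cooperators are never at fault
    at_fault[i] <- switch(
      kind,
      uniform = TRUE,
      single_file = i == 1L || state[i - 1L],
      groups = {
        m <- (i - 1L) %/% nu + 1L
        if (m == 1L) TRUE else {
          prev <- which((seq_len(N) - 1L) %/% nu + 1L == m - 1L)
          sum(state[prev]) >= theta * length(prev)
        }
      })
  }
  at_fault
}

# Per-player cooperation probability by direct application of the payoff
# definitions, using one-flip re-evaluation for every cooperator.
brute_probs <- function(state, h, kind, beta, pi_cap, pool = "cooperators",
                        a = 1, nu = NULL, theta = NULL) {
  N <- length(state)
  n_c <- sum(state)
  n_p <- switch(pool, cooperators = n_c, all = N, fraction = a * n_c)
  fault_now <- brute_fault(state, kind, nu, theta)
  n_f <- sum(fault_now)
  P <- numeric(N)
  for (i in seq_len(N)) {
    if (!state[i]) {
      p <- if (fault_now[i]) pi_cap * n_p / n_f else 0
    } else {
      flipped <- state
      flipped[i] <- FALSE
      cf <- brute_fault(flipped, kind, nu, theta)
      if (cf[i]) {
        np_cf <- switch(pool, cooperators = n_c - 1, all = N,
                        fraction = a * (n_c - 1))
        p <- pi_cap * np_cf / sum(cf)
      } else {
        p <- 0
      }
    }
    H <- p + h[i]
    P[i] <- if (is.infinite(beta)) {
      if (H > 0) 1 else if (H == 0) 0.5 else 0
    } else {
      0.5 * (tanh(beta * H) + 1)
    }
  }
  P
}

# All 2^N logical configurations as rows.
all_states <- function(N) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  dimnames(m) <- NULL
  m
}

random_state <- function(N, p = 0.5) stats::runif(N) < p
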