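# Exact finite-chain validation: the full 2^N Markov chain over
# configurations, its stationary distribution and the stationary expected
# cooperator density. Dense construction only; intended for N <= 12.

#' Build the exact Markov chain over all configurations
#'
#' Enumerates all `2^N` cooperation configurations and assembles the
#' row-stochastic transition matrix of the synchronous dynamics:
#' `T[s, s'] = prod_i P_i(s)^[s'_i = C] * (1 - P_i(s))^[s'_i = D]`, with
#' the per-player probabilities from [cooperation_probs()]. For finite
#' `beta` every entry is strictly positive, so the chain is ergodic with a
#' unique stationary distribution. The deterministic limit `beta = Inf` is
#' rejected (the chain may be reducible); use direct simulation for
#' cascade checks instead.
#'
#' @inheritParams cooperation_probs
#' @param max_n Size guard (default 12, i.e. at most 4096 states).
#' @return A list of class `exact_chain` with `states` (a `2^N x N`
#'   logical matrix), `transition` (dense `2^N x 2^N`), `density`
#'   (`n_c/N` per state) and the inputs.
#' @export
build_chain <- function(profile, rule, params, max_n = 12L) {
  assert_profile(profile)
  N <- profile$N
  if (N > max_n) {
    stop(sprintf("exact chain needs 2^N states; N = %d exceeds the guard ",
                 N), sprintf("max_n = %d", max_n), call. = FALSE)
  }
  if (is.infinite(params$beta)) {
    stop("beta = Inf is not supported by the exact chain (it may be ",
         "reducible); use simulation for deterministic-limit checks",
         call. = FALSE)
  }
  n_states <- 2L^N
  # state index s (0-based) has player i cooperating iff bit i-1 is set
  states <- matrix(FALSE, n_states, N)
  for (i in seq_len(N)) {
    states[, i] <- bitwAnd(seq_len(n_states) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  partition <- resolve_partition(rule, N)
  log_p <- matrix(0, n_states, N)
  log_q <- matrix(0, n_states, N)
  for (s in seq_len(n_states)) {
    P <- cooperation_probs(states[s, ], profile, rule, params, partition)
    log_p[s, ] <- log(P)
    log_q[s, ] <- log1p(-P)
  }
  # T = exp(log_p %*% t(S) + log_q %*% t(1 - S)), assembled by state
  S <- t(states) * 1
  transition <- exp(log_p %*% S + log_q %*% (1 - S))
  structure(list(states = states, transition = transition,
                 density = rowSums(states) / N,
                 profile = profile, rule = rule, params = params),
            class = "exact_chain")
}

#' Stationary distribution of an exact chain
#'
#' Power iteration from the uniform distribution until the L1 change per
#' sweep drops below `tol`.
#'
#' @param chain An [build_chain()] result.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @param start Optional starting distribution (defaults to uniform); the
#'   ergodic limit does not depend on it.
#' @return Numeric stationary probability vector over the `2^N` states.
#' @export
stationary_distribution <- function(chain, tol = 1e-12, max_iter = 1e6,
                                    start = NULL) {
  if (!inherits(chain, "exact_chain")) {
    stop("`chain` must come from build_chain()", call. = FALSE)
  }
  n <- nrow(chain$transition)
  x <- if (is.null(start)) rep(1 / n, n) else start / sum(start)
  if (length(x) != n) stop("`start` has the wrong length", call. = FALSE)
  for (iter in seq_len(max_iter)) {
    x_new <- as.vector(x %*% chain$transition)
    x_new <- x_new / sum(x_new)
    if (sum(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  stop("power iteration did not converge within `max_iter` sweeps",
       call. = FALSE)
}

#' Stationary expected cooperator density of an exact chain
#'
#' @inheritParams stationary_distribution
#' @param dist Optional precomputed stationary distribution.
#' @return The exact long-run expectation of `n_c / N`.
#' @export
expected_density <- function(chain, dist = NULL, tol = 1e-12) {
  if (is.null(dist)) dist <- stationary_distribution(chain, tol = tol)
  sum(dist * chain$density)
}
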