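# Stochastic dynamics: sigmoidal cooperation probabilities with a
# punishment term, synchronous Monte-Carlo updates, stationary-density
# estimation and first-passage times to full cooperation.

#' Dynamics parameters
#'
#' @param beta Rationality (inverse-temperature-like) parameter, `>= 0`.
#'   `beta = 0` gives fully random behaviour, `beta = Inf` the
#'   deterministic (threshold) limit.
#' @param pi Punishment capacity per punisher, `>= 0`. The total capacity
#'   `pi * n_p` is divided equally among the `n_f` players at fault.
#' @param pool Who punishes: `"cooperators"` (the default; `n_p = n_c`),
#'   `"all"` (`n_p = N`, defectors punish too), or `"fraction"`
#'   (`n_p = a * n_c`, equivalent to rescaling `pi` by `a`).
#' @param a Punishing fraction in `(0, 1]`, used when `pool = "fraction"`.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(beta, pi,
                            pool = c("cooperators", "all", "fraction"),
                            a = 1) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("`beta` must be a single nonnegative number (Inf allowed)",
         call. = FALSE)
  }
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi < 0 ||
      !is.finite(pi)) {
    stop("`pi` must be a single finite nonnegative number", call. = FALSE)
  }
  pool <- match.arg(pool)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a > 1) {
    stop("`a` must be a single number in (0, 1]", call. = FALSE)
  }
  structure(list(beta = beta, pi = pi, pool = pool, a = a),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf("<dynamics_params> beta = %g, pi = %g, pool = %s%s\n",
              x$beta, x$pi, x$pool,
              if (x$pool == "fraction") sprintf(" (a = %g)", x$a) else ""))
  invisible(x)
}

#' Simulation configuration
#'
#' @param t_max Maximum number of synchronous time steps.
#' @param burn_in Steps discarded before averaging.
#' @param window Steps averaged after the burn-in
#'   (`burn_in + window <= t_max`).
#' @param realizations Number of independent realizations `R`.
#' @param init Initial condition: `"all_C"`, `"all_D"`, a density in
#'   `[0, 1]` (each player independently cooperates with that
#'   probability), or an explicit logical vector.
#' @param seed Master seed. Every realization runs on an independent
#'   substream derived deterministically from it, so all results are
#'   bit-reproducible for a fixed `(config, seed)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_max = 2000, burn_in = 500, window = 500,
                       realizations = 100, init = "all_D", seed = 1) {
  t_max <- assert_count(t_max, "t_max")
  burn_in <- assert_count(burn_in, "burn_in", zero_ok = TRUE)
  window <- assert_count(window, "window", zero_ok = TRUE)
  realizations <- assert_count(realizations, "realizations")
  seed <- assert_count(seed, "seed", zero_ok = TRUE)
  if (burn_in + window > t_max) {
    stop("`burn_in + window` must not exceed `t_max`", call. = FALSE)
  }
  if (is.character(init)) {
    init <- match.arg(init, c("all_C", "all_D"))
  } else if (is.numeric(init)) {
    if (length(init) != 1L || is.na(init) || init < 0 || init > 1) {
      stop("numeric `init` must be a density in [0, 1]", call. = FALSE)
    }
  } else if (!is.logical(init)) {
    stop("`init` must be \"all_C\", \"all_D\", a density, or a logical ",
         "vector", call. = FALSE)
  }
  structure(list(t_max = t_max, burn_in = burn_in, window = window,
                 realizations = realizations, init = init, seed = seed),
            class = "sim_config")
}

# Draw/construct the initial state for a population of size N. Consumes
# RNG only for density initial conditions.
init_state <- function(init, N) {
  if (is.logical(init)) {
    assert_state(init, N)
    return(init)
  }
  if (is.numeric(init)) return(stats::runif(N) < init)
  switch(init,
         all_C = rep(TRUE, N),
         all_D = rep(FALSE, N),
         stop("unknown init ", init, call. = FALSE))
}

#' Effective number of punishers
#'
#' @param state Logical cooperation vector.
#' @param pool,a See [dynamics_params()].
#' @return The (possibly fractional) punisher count `n_p`.
#' @export
effective_punishers <- function(state,
                                pool = c("cooperators", "all", "fraction"),
                                a = 1) {
  assert_state(state)
  pool <- match.arg(pool)
  n_c <- sum(state)
  switch(pool,
         cooperators = n_c,
         all = length(state),
         fraction = a * n_c)
}

# The sigmoidal choice probability P = (tanh(beta * H) + 1) / 2, with the
# beta = Inf limit as a threshold rule (P = 1/2 exactly at H = 0).
sigmoid_prob <- function(H, beta) {
  if (is.infinite(beta)) {
    (H > 0) + 0.5 * (H == 0)
  } else {
    0.5 * (tanh(beta * H) + 1)
  }
}

# Vectorized per-player punishment machinery. Returns, for the time-t
# configuration, the punishment term p_i of every player in O(N):
#  - a defector at fault feels      p = pi * n_p / n_f
#  - a defector not at fault feels  p = 0
#  - a cooperator who would be at fault were she alone to defect feels the
#    counterfactual deterrent       p = pi * np_cf / nf_cf
#    where np_cf excludes herself from the punisher pool and nf_cf is the
#    fault count of the one-flip configuration
#  - a cooperator who would not be at fault feels p = 0.
# Counterfactual fault counts are computed in closed form per rule rather
# than by N one-flip re-evaluations; tests cross-check this against the
# direct flip-and-recount route.
punishment_terms <- function(state, rule, params, partition = NULL) {
  N <- length(state)
  coop <- state
  n_c <- sum(coop)
  n_p <- switch(params$pool,
                cooperators = n_c, all = N, fraction = params$a * n_c)
  np_cf <- switch(params$pool,
                  cooperators = n_c - 1L, all = N,
                  fraction = params$a * (n_c - 1))

  if (rule$kind == "uniform") {
    at_fault <- !coop
    n_f <- N - n_c
    would_fault <- rep(TRUE, N)        # any cooperator would be at fault
    nf_cf <- rep(n_f + 1, N)
  } else if (rule$kind == "single_file") {
    pred_coop <- c(TRUE, coop[-N])     # player 1: bootstrap
    at_fault <- !coop & pred_coop
    n_f <- sum(at_fault)
    # If cooperator i defects: she is at fault iff her predecessor
    # cooperates; her successor (if a currently at-fault defector) loses
    # fault status because its predecessor now defects.
    succ_loses <- c(!coop[-1L], FALSE) # at_fault[i+1] given coop[i] TRUE
    would_fault <- pred_coop
    nf_cf <- n_f + as.integer(pred_coop) - as.integer(succ_loses)
  } else { # groups
    if (is.null(partition)) partition <- assign_groups(N, rule$nu)
    g <- partition$group
    n_groups <- partition$n_groups
    sizes <- partition$sizes
    coop_g <- tabulate(g[coop], nbins = n_groups)
    def_g <- sizes - coop_g
    pass <- c(TRUE, coop_g[-n_groups] >= rule$theta * sizes[-n_groups])
    at_fault <- !coop & pass[g]
    n_f <- sum(at_fault)
    # If a cooperator in group m defects: she joins the fault set iff
    # group m passes (unchanged: it depends on group m-1); group m + 1 may
    # stop passing because group m loses one cooperator.
    pass_next_cf <- (coop_g - 1) >= rule$theta * sizes  # for group m+1
    delta_next <- numeric(n_groups)
    if (n_groups > 1L) {
      m <- seq_len(n_groups - 1L)
      delta_next[m] <- (as.integer(pass_next_cf[m]) -
                          as.integer(pass[m + 1L])) * def_g[m + 1L]
    }
    would_fault <- pass[g]
    nf_cf <- n_f + as.integer(pass[g]) + delta_next[g]
  }

  p <- numeric(N)
  idx_def <- !coop & at_fault
  if (n_f > 0 && any(idx_def)) p[idx_def] <- params$pi * n_p / n_f
  idx_coop <- coop & would_fault
  if (any(idx_coop)) {
    p[idx_coop] <- params$pi * np_cf / nf_cf[idx_coop]
  }
  list(p = p, at_fault = at_fault, would_fault = would_fault, n_f = n_f,
       n_p = n_p, np_cf = np_cf, nf_cf = nf_cf)
}

#' Cooperation probabilities of every player
#'
#' Computes, for the current configuration, each player's payoff balance
#' `H_i = p_i + h_i` and cooperation probability
#' `P_i = (tanh(beta * H_i) + 1) / 2`; `p_i` is the punishment (or, for
#' cooperators, counterfactual deterrent) term described in
#' [punishment terms][influence].
#'
#' @param state Logical cooperation vector.
#' @param profile A [predisposition_profile][build_linear_profile].
#' @param rule A [strategy_rule()].
#' @param params A [dynamics_params()].
#' @param partition Optional precomputed group partition.
#' @return Numeric vector of probabilities, one per player.
#' @export
cooperation_probs <- function(state, profile, rule, params,
                              partition = NULL) {
  assert_profile(profile)
  assert_state(state, profile$N)
  pt <- punishment_terms(state, rule, params, partition)
  sigmoid_prob(pt$p + profile$values, params$beta)
}

#' Influence breakdown for one player
#'
#' Decomposes the update probability of player `i` in the current
#' configuration into its punishment term `p`, predisposition `h`, payoff
#' balance `H = p + h` and cooperation probability `P`. For a defector the
#' reported `n_f` is the current fault count; for a cooperator, `n_p` and
#' `n_f` are the counterfactual values (the punisher pool excluding
#' herself, and the fault count were she alone to defect).
#'
#' @inheritParams cooperation_probs
#' @param i Player index.
#' @return A list of class `influence_breakdown` with elements `p`, `h`,
#'   `H`, `P`, `at_fault`, `n_p`, `n_f`.
#' @examples
#' prof <- build_linear_profile(4)
#' influence(2, c(TRUE, FALSE, FALSE, FALSE), prof,
#'           strategy_rule("uniform"), dynamics_params(beta = 1, pi = 1))
#' @export
influence <- function(i, state, profile, rule, params, partition = NULL) {
  assert_profile(profile)
  assert_state(state, profile$N)
  i <- assert_count(i, "i")
  if (i > profile$N) stop("`i` out of range", call. = FALSE)
  pt <- punishment_terms(state, rule, params, partition)
  h <- profile$values[i]
  p <- pt$p[i]
  if (state[i]) {
    at_fault <- pt$would_fault[i]
    n_p <- pt$np_cf
    n_f <- if (at_fault) pt$nf_cf[i] else NA_real_
  } else {
    at_fault <- pt$at_fault[i]
    n_p <- pt$n_p
    n_f <- pt$n_f
  }
  structure(list(p = p, h = h, H = p + h,
                 P = sigmoid_prob(p + h, params$beta),
                 at_fault = at_fault, n_p = n_p, n_f = n_f),
            class = "influence_breakdown")
}

#' One synchronous update of the whole population
#'
#' Every player's next state is an independent Bernoulli draw with success
#' probability `P_i`, all probabilities computed from the time-`t`
#' configuration. Uses (and advances) the current RNG stream; seed it with
#' `set.seed()` for reproducibility.
#'
#' @inheritParams cooperation_probs
#' @return The next logical state vector.
#' @export
step_state <- function(state, profile, rule, params, partition = NULL) {
  P <- cooperation_probs(state, profile, rule, params, partition)
  stats::runif(length(state)) < P
}

# Unchecked inner loop shared by the trajectory/stationary/speed drivers.
# Runs `t_max` synchronous steps (or stops early at full cooperation when
# `stop_at_full`), returning the density series rho_0..rho_T and, when
# requested, the first-passage time tau.
run_chain <- function(state, profile, rule, params, partition, t_max,
                      stop_at_full = FALSE, full_threshold = 1) {
  N <- profile$N
  h <- profile$values
  beta <- params$beta
  rho <- numeric(t_max + 1L)
  rho[1L] <- sum(state) / N
  tau <- NA_integer_
  n_full <- ceiling(full_threshold * N)
  for (t in seq_len(t_max)) {
    pt <- punishment_terms(state, rule, params, partition)
    P <- sigmoid_prob(pt$p + h, beta)
    state <- stats::runif(N) < P
    rho[t + 1L] <- sum(state) / N
    if (stop_at_full && sum(state) >= n_full) {
      tau <- t
      rho <- rho[seq_len(t + 1L)]
      break
    }
  }
  list(state = state, rho = rho, tau = tau)
}

#' Simulate one trajectory of the cooperator density
#'
#' @inheritParams cooperation_probs
#' @param config A [sim_config()]; `realizations` is ignored (one run).
#' @param keep_states If `TRUE`, also return the full `(t_max + 1) x N`
#'   logical state history.
#' @return A list of class `trajectory` with `rho` (length `t_max + 1`,
#'   including the initial condition), `t` (0-based times) and optionally
#'   `states`.
#' @export
run_trajectory <- function(profile, rule, params, config = sim_config(),
                           keep_states = FALSE) {
  assert_profile(profile)
  partition <- resolve_partition(rule, profile$N)
  out <- with_seed(config$seed, {
    state <- init_state(config$init, profile$N)
    if (!keep_states) {
      run_chain(state, profile, rule, params, partition, config$t_max)
    } else {
      states <- matrix(NA, config$t_max + 1L, profile$N)
      states[1L, ] <- state
      rho <- numeric(config$t_max + 1L)
      rho[1L] <- sum(state) / profile$N
      for (t in seq_len(config$t_max)) {
        state <- step_state(state, profile, rule, params, partition)
        states[t + 1L, ] <- state
        rho[t + 1L] <- sum(state) / profile$N
      }
      list(state = state, rho = rho, states = states)
    }
  })
  structure(list(rho = out$rho, t = seq_along(out$rho) - 1L,
                 states = out$states),
            class = "trajectory")
}

#' Estimate the stationary cooperator density
#'
#' Runs `realizations` independent realizations; each is simulated for
#' `burn_in + window` steps and the density averaged over the
#' post-burn-in window. The estimate is the mean of the per-realization
#' means, with their standard error.
#'
#' @inheritParams run_trajectory
#' @return A list of class `stationary_estimate` with `rho_bar`, `se`,
#'   `per_realization` and `config`.
#' @export
estimate_stationary <- function(profile, rule, params,
                                config = sim_config()) {
  assert_profile(profile)
  if (config$window == 0L) {
    stop("`window` must be positive to estimate a stationary density",
         call. = FALSE)
  }
  partition <- resolve_partition(rule, profile$N)
  R <- config$realizations
  seeds <- derive_seeds(config$seed, R)
  steps <- config$burn_in + config$window
  keep <- config$burn_in + 1L + seq_len(config$window)  # indices into rho
  per <- vapply(seq_len(R), function(r) {
    with_seed(seeds[r], {
      state <- init_state(config$init, profile$N)
      out <- run_chain(state, profile, rule, params, partition, steps)
      mean(out$rho[keep])
    })
  }, numeric(1))
  se <- if (R > 1L) stats::sd(per) / sqrt(R) else NA_real_
  structure(list(rho_bar = mean(per), se = se, per_realization = per,
                 config = config),
            class = "stationary_estimate")
}

#' @export
print.stationary_estimate <- function(x, ...) {
  cat(sprintf("<stationary_estimate> rho_bar = %.4f (SE %.4f, R = %d)\n",
              x$rho_bar, x$se, length(x$per_realization)))
  invisible(x)
}

#' Time to reach full cooperation
#'
#' First-passage time `tau` to global cooperation (`n_c = N`, or
#' `rho >= full_threshold` for noisy regimes) from the configured initial
#' condition, per realization, with the speed `v = N / tau`. Runs that do
#' not reach full cooperation within `t_max` steps are censored. An
#' already-cooperative start has `tau = 0` and no defined speed.
#'
#' @inheritParams run_trajectory
#' @param full_threshold Density counted as "full cooperation"
#'   (default 1, i.e. every player cooperates).
#' @return A list of class `speed_result` with `tau` (integer, `NA` when
#'   censored), `censored` (logical), `v` (`N/tau`, `NA` for censored or
#'   `tau = 0` runs), `mean_v` (over uncensored runs with `tau >= 1`) and
#'   `censored_fraction`.
#' @export
time_to_cooperation <- function(profile, rule, params,
                                config = sim_config(),
                                full_threshold = 1) {
  assert_profile(profile)
  partition <- resolve_partition(rule, profile$N)
  R <- config$realizations
  seeds <- derive_seeds(config$seed, R)
  N <- profile$N
  n_full <- ceiling(full_threshold * N)
  tau <- integer(R)
  for (r in seq_len(R)) {
    tau[r] <- with_seed(seeds[r], {
      state <- init_state(config$init, N)
      if (sum(state) >= n_full) 0L
      else run_chain(state, profile, rule, params, partition,
                     config$t_max, stop_at_full = TRUE,
                     full_threshold = full_threshold)$tau
    })
  }
  censored <- is.na(tau)
  v <- ifelse(censored | tau == 0L, NA_real_, N / tau)
  ok <- !is.na(v)
  structure(list(tau = tau, censored = censored, v = v,
                 mean_v = if (any(ok)) mean(v[ok]) else NA_real_,
                 censored_fraction = mean(censored), N = N),
            class = "speed_result")
}

#' @export
print.speed_result <- function(x, ...) {
  cat(sprintf(
    "<speed_result> N = %d, R = %d: mean v = %s, censored %.0f%%\n",
    x$N, length(x$tau),
    if (is.na(x$mean_v)) "n/a" else sprintf("%.3f", x$mean_v),
    100 * x$censored_fraction))
  invisible(x)
}

#' Export a trajectory or stationary estimate as delimited text
#'
#' Trajectories are written as `(t, rho)`; stationary estimates as
#' `(realization, rho_mean)`. A YAML metadata sidecar `<path>.meta.yaml`
#' records the run configuration when supplied.
#'
#' @param x A `trajectory` or `stationary_estimate`.
#' @param path Output file.
#' @param meta Optional named list written to the sidecar.
#' @return Invisibly, `path`.
#' @export
write_run <- function(x, path, meta = NULL) {
  if (inherits(x, "trajectory")) {
    df <- data.frame(t = x$t, rho = x$rho)
  } else if (inherits(x, "stationary_estimate")) {
    df <- data.frame(realization = seq_along(x$per_realization),
                     rho_mean = x$per_realization)
  } else {
    stop("`x` must be a trajectory or stationary_estimate", call. = FALSE)
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) write_meta(meta, path)
  invisible(path)
}
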