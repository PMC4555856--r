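C <- TRUE
D <- FALSE

test_that("effective punisher counts follow the pool policy", {
  state <- c(C, C, D, D, D)
  expect_identical(effective_punishers(rep(D, 5), "cooperators"), 0L)
  expect_identical(effective_punishers(state, "cooperators"), 2L)
  expect_identical(effective_punishers(state, "all"), 5L)
  expect_equal(effective_punishers(state, "fraction", a = 0.5), 1)
  expect_equal(
    effective_punishers(c(rep(C, 10), rep(D, 5)), "fraction", a = 0.5), 5)
})

test_that("influence decomposes payoffs as punishment plus predisposition", {
  prof <- build_linear_profile(4)
  uni <- strategy_rule("uniform")
  # (C,D,D,D), pi=1, cooperators punish: each defector gets p = 1 * 1 / 3
  par <- dynamics_params(beta = 1, pi = 1)
  for (i in 2:4) {
    br <- influence(i, c(C, D, D, D), prof, uni, par)
    expect_equal(br$p, 1 / 3)
    expect_equal(br$h, prof$values[i])
    expect_equal(br$H, br$p + br$h)
    expect_equal(br$P, 0.5 * (tanh(br$H) + 1))
    expect_identical(br$n_f, 3L)
    expect_identical(br$n_p, 1L)
  }
  # beta = 0: choices are coin flips whatever the balance
  par0 <- dynamics_params(beta = 0, pi = 1)
  for (i in 1:4) {
    expect_equal(influence(i, c(C, D, D, D), prof, uni, par0)$P, 0.5)
  }
  # a defector not at fault feels no punishment
  sf <- strategy_rule("single_file")
  br <- influence(3, c(C, D, D, D), prof, sf, par)
  expect_equal(br$p, 0)
  expect_equal(br$H, prof$values[3])
  expect_false(br$at_fault)
  # a cooperator uses the one-flip counterfactual excluding herself
  br <- influence(1, c(C, C, D, D), prof, uni, par)
  expect_identical(br$n_p, 1L)   # the other cooperator
  expect_equal(br$n_f, 3)        # both defectors plus herself
  expect_equal(br$p, 1 / 3)
})

test_that("vectorized probabilities match one-flip brute force everywhere", {
  set.seed(202)
  cases <- list(
    list(kind = "uniform", rule = strategy_rule("uniform")),
    list(kind = "single_file", rule = strategy_rule("single_file")),
    list(kind = "groups", nu = 3, theta = 0.8,
         rule = strategy_rule("groups", nu = 3, theta = 0.8)),
    list(kind = "groups", nu = 5, theta = 0.4,
         rule = strategy_rule("groups", nu = 5, theta = 0.4)))
  pools <- list(list(pool = "cooperators", a = 1),
                list(pool = "all", a = 1),
                list(pool = "fraction", a = 0.3))
  for (rep in 1:20) {
    N <- sample(5:40, 1)
    state <- random_state(N, stats::runif(1))
    beta <- stats::runif(1, 0, 4)
    pi_cap <- stats::runif(1, 0, 1.5)
    prof <- build_linear_profile(N)
    for (cs in cases) {
      if (!is.null(cs$nu) && cs$nu > N) next
      for (pl in pools) {
        par <- dynamics_params(beta, pi_cap, pl$pool, pl$a)
        expect_equal(
          cooperation_probs(state, prof, cs$rule, par),
          brute_probs(state, prof$values, cs$kind, beta, pi_cap,
                      pl$pool, pl$a, cs$nu, cs$theta),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("the sigmoid is symmetric, increasing, and 1/2 at balance zero", {
  prof <- build_linear_profile(10)
  uni <- strategy_rule("uniform")
  # h_2 = 0 and player 2 unpunished when pi = 0: P = 1/2 exactly
  par <- dynamics_params(beta = 3, pi = 0)
  expect_equal(influence(2, rep(D, 10), prof, uni, par)$P, 0.5)
  # P(-H) = 1 - P(H) and monotone in H through the pi lever
  state <- rep(D, 10)
  P_lo <- cooperation_probs(state, prof, uni, dynamics_params(2, 0.1))
  P_hi <- cooperation_probs(state, prof, uni, dynamics_params(2, 0.9))
  expect_true(all(P_hi >= P_lo))
  H <- seq(-2, 2, by = 0.25)
  P <- 0.5 * (tanh(1.7 * H) + 1)
  expect_equal(P + rev(P), rep(1, length(H)))
})

test_that("synchronous steps are bit-reproducible and respect beta = Inf", {
  prof <- build_linear_profile(20)
  uni <- strategy_rule("uniform")
  par <- dynamics_params(2, 0.5)
  state <- random_state(20)
  set.seed(9); s1 <- step_state(state, prof, uni, par)
  set.seed(9); s2 <- step_state(state, prof, uni, par)
  expect_identical(s1, s2)
  # deterministic limit: all balances positive => everyone cooperates
  par_inf <- dynamics_params(Inf, 2)
  set.seed(1)
  expect_true(all(step_state(rep(C, 20), prof, uni, par_inf)))
  # pi(N-1) > 1 makes the all-cooperate state absorbing under beta = Inf
  traj <- run_trajectory(prof, uni, par_inf,
                         sim_config(t_max = 50, burn_in = 0, window = 1,
                                    realizations = 1, init = "all_C",
                                    seed = 4))
  expect_identical(traj$rho, rep(1, 51))
})

test_that("trajectories start at the configured initial condition", {
  prof <- build_linear_profile(30)
  uni <- strategy_rule("uniform")
  par <- dynamics_params(1, 0.3)
  cfg <- function(init) sim_config(t_max = 20, burn_in = 0, window = 1,
                                   realizations = 1, init = init, seed = 2)
  expect_equal(run_trajectory(prof, uni, par, cfg("all_C"))$rho[1], 1)
  expect_equal(run_trajectory(prof, uni, par, cfg("all_D"))$rho[1], 0)
  tr <- run_trajectory(prof, uni, par, cfg(0.5), keep_states = TRUE)
  expect_equal(dim(tr$states), c(21, 30))
  expect_equal(tr$rho, rowMeans(tr$states))
  # identical seeds give identical trajectories
  expect_identical(run_trajectory(prof, uni, par, cfg("all_D"))$rho,
                   run_trajectory(prof, uni, par, cfg("all_D"))$rho)
})

test_that("pi = 0 decouples players into independent sigmoid coin flips", {
  # with no punishment the stationary density has the closed form
  # (1/N) sum_i (tanh(beta h_i) + 1) / 2, whatever the rule
  N <- 100
  prof <- build_linear_profile(N)
  beta <- 1.5
  closed <- mean(0.5 * (tanh(beta * prof$values) + 1))
  for (rule in list(strategy_rule("uniform"),
                    strategy_rule("groups", nu = 10, theta = 0.8))) {
    est <- estimate_stationary(
      prof, rule, dynamics_params(beta, 0),
      sim_config(t_max = 600, burn_in = 100, window = 500,
                 realizations = 10, init = "all_D", seed = 33))
    expect_lt(abs(est$rho_bar - closed), 3 * est$se)
  }
})

test_that("stationary estimates average the post-burn-in window", {
  prof <- build_linear_profile(50)
  uni <- strategy_rule("uniform")
  par <- dynamics_params(0, 0)   # beta = 0: iid Bernoulli(1/2)
  est <- estimate_stationary(prof, uni, par,
                             sim_config(t_max = 300, burn_in = 100,
                                        window = 200, realizations = 8,
                                        init = "all_D", seed = 12))
  expect_length(est$per_realization, 8)
  expect_equal(est$rho_bar, mean(est$per_realization))
  expect_equal(est$se, stats::sd(est$per_realization) / sqrt(8))
  expect_lt(abs(est$rho_bar - 0.5), 3 * est$se)
  expect_error(
    estimate_stationary(prof, uni, par,
                        sim_config(t_max = 10, burn_in = 5, window = 0,
                                   realizations = 2)),
    "window")
})

test_that("the single-file cascade marches one player per step", {
  # beta = Inf, cooperators punish: player 1 flips on her own
  # predisposition, player 2 is a fair coin only while player 1 defects,
  # and thereafter the lone at-fault frontier player flips each step, so
  # tau = N - 1 (coin success) or N (coin failure)
  sf <- strategy_rule("single_file")
  for (N in c(10, 50)) {
    prof <- build_linear_profile(N)
    par <- dynamics_params(Inf, 0.5)
    sp <- time_to_cooperation(prof, sf, par,
                              sim_config(t_max = 5 * N, burn_in = 0,
                                         window = 1, realizations = 20,
                                         init = "all_D", seed = 21))
    expect_false(any(sp$censored))
    expect_true(all(sp$tau %in% c(N - 1L, N)))
    expect_equal(sp$v[!is.na(sp$v)], N / sp$tau[!is.na(sp$v)])
  }
})

test_that("first-passage bookkeeping handles trivial and censored runs", {
  prof <- build_linear_profile(20)
  sf <- strategy_rule("single_file")
  # already cooperative: tau = 0, speed undefined
  sp <- time_to_cooperation(prof, sf, dynamics_params(Inf, 0.5),
                            sim_config(t_max = 10, burn_in = 0,
                                       window = 1, realizations = 3,
                                       init = "all_C", seed = 1))
  expect_identical(sp$tau, rep(0L, 3))
  expect_true(all(is.na(sp$v)))
  # pi = 0, beta = Inf from all defect: players i >= 3 never cooperate
  sp <- time_to_cooperation(prof, sf, dynamics_params(Inf, 0),
                            sim_config(t_max = 200, burn_in = 0,
                                       window = 1, realizations = 3,
                                       init = "all_D", seed = 2))
  expect_true(all(sp$censored))
  expect_equal(sp$censored_fraction, 1)
})

test_that("run exports write the documented delimited columns", {
  prof <- build_linear_profile(10)
  uni <- strategy_rule("uniform")
  par <- dynamics_params(1, 0.2)
  tr <- run_trajectory(prof, uni, par,
                       sim_config(t_max = 5, burn_in = 0, window = 1,
                                  realizations = 1, init = "all_D",
                                  seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_run(tr, path, meta = list(note = "smoke"))
  df <- read.csv(path)
  expect_identical(names(df), c("t", "rho"))
  expect_equal(df$rho, tr$rho)
  expect_true(file.exists(paste0(path, ".meta.yaml")))
})
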