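# Phase-diagram machinery: (beta, pi) sweeps of the stationary density,
# speed maps, sweep comparisons, region summaries, and config/table I/O.

new_sweep_grid <- function(beta, pi, value, se, kind, meta,
                           censored_fraction = NULL) {
  structure(list(beta = beta, pi = pi, value = value, se = se,
                 kind = kind, censored_fraction = censored_fraction,
                 meta = meta),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf(
    "<sweep_grid> %s over %d beta x %d pi cells (rule %s, init %s, N %d)\n",
    x$kind, length(x$beta), length(x$pi), x$meta$rule_kind, x$meta$init,
    x$meta$N))
  invisible(x)
}

#' Monte-Carlo sweep of the stationary density over (beta, pi)
#'
#' Runs [estimate_stationary()] on every cell of a rectangular parameter
#' grid. Each cell uses an independent seed derived deterministically from
#' `config$seed`, so the whole sweep is bit-reproducible.
#'
#' @param profile A predisposition profile.
#' @param rule A [strategy_rule()].
#' @param beta,pi Increasing grids of rationality and punishment values.
#' @param config A [sim_config()] applied to every cell.
#' @param pool,a Punisher pool policy, see [dynamics_params()].
#' @return A `sweep_grid` whose `value` is the `length(beta) x length(pi)`
#'   matrix of stationary densities, with matching `se`.
#' @export
run_sweep <- function(profile, rule, beta, pi, config = sim_config(),
                      pool = "cooperators", a = 1) {
  assert_profile(profile)
  check_grid_axes(beta, pi)
  nb <- length(beta); np <- length(pi)
  cell_seeds <- matrix(derive_seeds(config$seed, nb * np), nb, np)
  value <- se <- matrix(NA_real_, nb, np)
  for (ib in seq_len(nb)) {
    for (ip in seq_len(np)) {
      params <- dynamics_params(beta[ib], pi[ip], pool = pool, a = a)
      cfg <- config
      cfg$seed <- cell_seeds[ib, ip]
      est <- estimate_stationary(profile, rule, params, cfg)
      value[ib, ip] <- est$rho_bar
      se[ib, ip] <- est$se
    }
  }
  new_sweep_grid(beta, pi, value, se, kind = "rho",
                 meta = sweep_meta(profile, rule, config, pool, a))
}

#' Monte-Carlo sweep of the speed to full cooperation
#'
#' As [run_sweep()], but each cell reports the mean speed `v = N / tau`
#' over uncensored realizations of [time_to_cooperation()] from the
#' all-defect initial condition. Cells where no realization reaches full
#' cooperation within `t_max` steps report `v = 0` and a censored
#' fraction of 1.
#'
#' @inheritParams run_sweep
#' @param full_threshold Density counted as full cooperation (default 1).
#' @return A `sweep_grid` with `kind = "speed"` and a
#'   `censored_fraction` matrix.
#' @export
speed_map <- function(profile, rule, beta, pi, config = sim_config(),
                      pool = "cooperators", a = 1, full_threshold = 1) {
  assert_profile(profile)
  check_grid_axes(beta, pi)
  if (!identical(config$init, "all_D")) {
    stop("speed maps measure escape from universal defection; ",
         "`config$init` must be \"all_D\"", call. = FALSE)
  }
  nb <- length(beta); np <- length(pi)
  cell_seeds <- matrix(derive_seeds(config$seed, nb * np), nb, np)
  value <- se <- cens <- matrix(NA_real_, nb, np)
  for (ib in seq_len(nb)) {
    for (ip in seq_len(np)) {
      params <- dynamics_params(beta[ib], pi[ip], pool = pool, a = a)
      cfg <- config
      cfg$seed <- cell_seeds[ib, ip]
      sp <- time_to_cooperation(profile, rule, params, cfg,
                                full_threshold = full_threshold)
      ok <- !is.na(sp$v)
      value[ib, ip] <- if (any(ok)) mean(sp$v[ok]) else 0
      se[ib, ip] <- if (sum(ok) > 1L) {
        stats::sd(sp$v[ok]) / sqrt(sum(ok))
      } else NA_real_
      cens[ib, ip] <- sp$censored_fraction
    }
  }
  new_sweep_grid(beta, pi, value, se, kind = "speed",
                 meta = sweep_meta(profile, rule, config, pool, a),
                 censored_fraction = cens)
}

check_grid_axes <- function(beta, pi) {
  if (length(beta) < 1L || is.unsorted(beta, strictly = TRUE) ||
      any(beta < 0)) {
    stop("`beta` must be a strictly increasing nonnegative grid",
         call. = FALSE)
  }
  if (length(pi) < 1L || is.unsorted(pi, strictly = TRUE) || any(pi < 0)) {
    stop("`pi` must be a strictly increasing nonnegative grid",
         call. = FALSE)
  }
  invisible(TRUE)
}

sweep_meta <- function(profile, rule, config, pool, a) {
  list(N = profile$N, provenance = profile$provenance,
       rule_kind = rule$kind, nu = rule$nu, theta = rule$theta,
       pool = pool, a = a,
       init = if (is.character(config$init)) config$init else "explicit",
       t_max = config$t_max, burn_in = config$burn_in,
       window = config$window, realizations = config$realizations,
       master_seed = config$seed)
}

#' Cellwise difference between two sweeps
#'
#' `reference - test` on identical axes: the canonical use is the gap
#' between the density maintainable from an all-cooperate start and the
#' density achievable from an all-defect start under a targeted strategy.
#'
#' @param reference,test `sweep_grid` objects on identical `beta` and `pi`
#'   axes.
#' @return An object of class `sweep_comparison` with the `delta` matrix.
#' @export
compare_sweeps <- function(reference, test) {
  if (!inherits(reference, "sweep_grid") || !inherits(test, "sweep_grid")) {
    stop("both arguments must be sweep_grid objects", call. = FALSE)
  }
  if (!isTRUE(all.equal(reference$beta, test$beta)) ||
      !isTRUE(all.equal(reference$pi, test$pi))) {
    stop("sweeps are on different (beta, pi) axes", call. = FALSE)
  }
  structure(list(beta = reference$beta, pi = reference$pi,
                 delta = reference$value - test$value,
                 reference_meta = reference$meta, test_meta = test$meta),
            class = "sweep_comparison")
}

#' Fraction of the swept parameter space reaching a density
#'
#' @param grid A `sweep_grid` of stationary densities.
#' @param threshold Density in `(0, 1]` above which a cell counts as
#'   (globally) cooperative; default 0.9, robust to finite-beta
#'   fluctuation around full cooperation.
#' @return Fraction of cells with `rho_bar >= threshold`.
#' @export
achievable_fraction <- function(grid, threshold = 0.9) {
  if (!inherits(grid, "sweep_grid") || grid$kind != "rho") {
    stop("`grid` must be a sweep_grid of stationary densities",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  mean(grid$value >= threshold)
}

#' Write a sweep (or comparison) as long-format delimited text
#'
#' One row per cell with header `beta, pi, value, se, n_realizations`
#' (plus `censored_fraction` for speed maps; comparisons have columns
#' `beta, pi, delta`). A YAML sidecar `<path>.meta.yaml` records the full
#' run metadata including the master seed.
#'
#' @param grid A `sweep_grid` or `sweep_comparison`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path) {
  if (inherits(grid, "sweep_comparison")) {
    df <- expand.grid(beta = grid$beta, pi = grid$pi,
                      KEEP.OUT.ATTRS = FALSE)
    df$delta <- as.vector(grid$delta)
    meta <- list(kind = "comparison", reference = grid$reference_meta,
                 test = grid$test_meta)
  } else if (inherits(grid, "sweep_grid")) {
    df <- expand.grid(beta = grid$beta, pi = grid$pi,
                      KEEP.OUT.ATTRS = FALSE)
    df$value <- as.vector(grid$value)
    df$se <- as.vector(grid$se)
    df$n_realizations <- grid$meta$realizations
    if (!is.null(grid$censored_fraction)) {
      df$censored_fraction <- as.vector(grid$censored_fraction)
    }
    meta <- c(list(kind = grid$kind), grid$meta)
  } else {
    stop("`grid` must be a sweep_grid or sweep_comparison", call. = FALSE)
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  write_meta(meta, path)
  invisible(path)
}

#' Read back a sweep written by [write_grid()]
#'
#' @param path Path given to [write_grid()].
#' @return A `sweep_grid` (comparisons are returned as plain data frames).
#' @export
read_grid <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  if ("delta" %in% names(df)) return(df)
  beta <- sort(unique(df$beta))
  pi <- sort(unique(df$pi))
  ord <- order(match(df$pi, pi), match(df$beta, beta))
  df <- df[ord, , drop = FALSE]
  nb <- length(beta); np <- length(pi)
  kind <- if (!is.null(meta$kind)) meta$kind else "rho"
  meta$kind <- NULL
  new_sweep_grid(
    beta, pi,
    value = matrix(df$value, nb, np), se = matrix(df$se, nb, np),
    kind = kind, meta = meta,
    censored_fraction = if ("censored_fraction" %in% names(df)) {
      matrix(df$censored_fraction, nb, np)
    } else NULL)
}

write_meta <- function(meta, path) {
  meta$punisim_version <-
    as.character(utils::packageVersion("punisim"))
  yaml::write_yaml(drop_null(meta), paste0(path, ".meta.yaml"))
  invisible(path)
}

drop_null <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, logical(1))]
    lapply(x, drop_null)
  } else x
}

# ---- run configuration files -------------------------------------------

run_config_defaults <- function() {
  list(n_players = 200L, beta = 2.5, pi = 0.4, rule = "uniform", nu = NULL,
       theta = NULL, pool = "cooperators", a = 1, init = "all_D",
       t_max = 2000L, burn_in = 500L, window = 500L, realizations = 100L,
       seed = 1L, noise_sd = 0, swap_fraction = 0, het_scale = 1)
}

#' Read and validate a run configuration file
#'
#' Run configurations are YAML files whose keys mirror the function
#' arguments (`n`, `beta`, `pi`, `rule`, `nu`, `theta`, `pool`, `a`,
#' `init`, `t_max`, `burn_in`, `window`, `realizations`, `seed`,
#' `noise_sd`, `swap_fraction`, `het_scale`). Omitted keys take the
#' defaults (uniform rule, cooperators pool, all-defect start, burn-in
#' 500, window 500, 100 realizations); unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A validated named list of class `run_config` with defaults
#'   filled in.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a YAML mapping",
                          call. = FALSE)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain named list of the same keys).
#' @export
write_run_config <- function(config, path) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  yaml::write_yaml(drop_null(unclass(config)), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  cfg$n_players <- assert_count(cfg$n_players, "n_players")
  if (cfg$n_players < 3L) stop("config key `n_players` must be at least 3", call. = FALSE)
  for (key in c("beta", "pi", "noise_sd", "swap_fraction", "het_scale")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("config key `%s` must be a nonnegative number", key),
           call. = FALSE)
    }
  }
  if (cfg$swap_fraction > 1) {
    stop("config key `swap_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!cfg$rule %in% c("uniform", "single_file", "groups")) {
    stop("config key `rule` must be uniform, single_file or groups",
         call. = FALSE)
  }
  if (cfg$rule == "groups") {
    rule <- strategy_rule("groups", nu = cfg$nu, theta = cfg$theta)
    cfg$nu <- rule$nu
  }
  if (!cfg$pool %in% c("cooperators", "all", "fraction")) {
    stop("config key `pool` must be cooperators, all or fraction",
         call. = FALSE)
  }
  params <- dynamics_params(cfg$beta, cfg$pi, cfg$pool, cfg$a)
  sim <- sim_config(cfg$t_max, cfg$burn_in, cfg$window, cfg$realizations,
                    init = if (is.numeric(cfg$init)) cfg$init else
                      match.arg(cfg$init, c("all_C", "all_D")),
                    seed = cfg$seed)
  cfg$init <- sim$init
  structure(cfg, class = "run_config")
}

#' Assemble model objects from a run configuration
#'
#' Expands a `run_config` into the profile (with the configured
#' perturbations applied in the order heterogeneity scale, Gaussian
#' noise, position swaps), strategy rule, dynamics parameters and
#' simulation config.
#'
#' @param cfg A `run_config` from [read_run_config()].
#' @return A list with elements `profile`, `rule`, `params`, `config`.
#' @export
build_run <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  profile <- build_linear_profile(cfg$n_players)
  if (cfg$het_scale != 1) {
    profile <- scale_heterogeneity(profile, cfg$het_scale)
  }
  if (cfg$noise_sd > 0) {
    profile <- apply_gaussian_noise(profile, cfg$noise_sd,
                                    seed = cfg$seed + 1L)
  }
  if (cfg$swap_fraction > 0) {
    profile <- swap_positions(profile, cfg$swap_fraction,
                              seed = cfg$seed + 2L)
  }
  rule <- if (cfg$rule == "groups") {
    strategy_rule("groups", nu = cfg$nu, theta = cfg$theta)
  } else {
    strategy_rule(cfg$rule)
  }
  list(profile = profile, rule = rule,
       params = dynamics_params(cfg$beta, cfg$pi, cfg$pool, cfg$a),
       config = sim_config(cfg$t_max, cfg$burn_in, cfg$window,
                           cfg$realizations, cfg$init, cfg$seed))
}
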