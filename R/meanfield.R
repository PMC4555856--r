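# Mean-field analysis of the uniform strategy with cooperators as
# punishers: the deterministic one-step map G(rho), its fixed points,
# their stability and bifurcation scans.

# Guard for the pi*rho/(1-rho) singularity at rho = 1.
MF_EPS <- 1e-9

#' Mean-field map of the cooperator density
#'
#' The expected cooperator density one synchronous step after the
#' population sits at density `rho`, for the uniform strategy with
#' cooperators as punishers (where the punishment term felt by every
#' at-fault player is `pi * rho / (1 - rho)`):
#' `G(rho) = (1/N) * sum_i (tanh(beta * (pi * rho / (1 - rho)
#'           - (i - 2) / (N - 2))) + 1) / 2`.
#' At `rho = 1` the punishment term diverges and `G` is taken as its
#' continuity limit 1 (when `beta > 0` and `pi > 0`; for `pi = 0` the map
#' is constant in `rho` and that constant is returned).
#'
#' `G_continuum` is the closed-form continuum approximation obtained by
#' replacing the player average with an integral over predispositions
#' uniform on `[-1, 1/(N-2)]`; it differs from `G_discrete` by at most
#' O(1/N) and serves as an independent analytic check.
#'
#' @param rho Cooperator density in `[0, 1]` (vectorized).
#' @param beta Rationality parameter, `>= 0`.
#' @param pi Punishment capacity per punisher, `>= 0`.
#' @param N Population size (>= 3).
#' @return Expected next-step density, same length as `rho`.
#' @export
G_discrete <- function(rho, beta, pi, N) {
  N <- assert_count(N, "N")
  if (N < 3L) stop("`N` must be at least 3", call. = FALSE)
  if (any(is.na(rho)) || any(rho < 0) || any(rho > 1)) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  h <- -(seq_len(N) - 2) / (N - 2)
  vapply(rho, function(r) {
    if (r >= 1 - MF_EPS) {
      if (pi > 0 && beta > 0) return(1)
      r <- 0 # pi = 0: map constant in rho; beta = 0 handled by sigmoid
    }
    c_term <- pi * r / (1 - r)
    mean(sigmoid_prob(c_term + h, beta))
  }, numeric(1))
}

#' @rdname G_discrete
#' @export
G_continuum <- function(rho, beta, pi, N) {
  N <- assert_count(N, "N")
  if (N < 3L) stop("`N` must be at least 3", call. = FALSE)
  if (any(is.na(rho)) || any(rho < 0) || any(rho > 1)) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (beta == 0) return(rep(0.5, length(rho)))
  a <- -1
  b <- 1 / (N - 2)
  vapply(rho, function(r) {
    if (r >= 1 - MF_EPS) {
      if (pi > 0) return(1)
      r <- 0
    }
    c_term <- pi * r / (1 - r)
    if (is.infinite(beta)) {
      # fraction of h in [a, b] with c + h > 0
      return(min(1, max(0, (b + c_term) / (b - a))))
    }
    0.5 + (log_cosh(beta * (c_term + b)) - log_cosh(beta * (c_term + a))) /
      (2 * beta * (b - a))
  }, numeric(1))
}

#' Expected direction of evolution of the cooperator density
#'
#' The sign of `G(rho) - rho`: `+1` when cooperation is expected to grow,
#' `-1` when it is expected to decline, `0` (within `tol`) at a fixed
#' point.
#'
#' @inheritParams G_discrete
#' @param tol Band around zero reported as `0`.
#' @return Integer sign in `{-1, 0, 1}`, vectorized over `rho`.
#' @export
flow_direction <- function(rho, beta, pi, N, tol = 1e-8) {
  d <- G_discrete(rho, beta, pi, N) - rho
  ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
}

#' Fixed points of the mean-field map and their stability
#'
#' Scans `G(rho) - rho` for sign changes on a grid over `[0, 1 - eps]`,
#' refines each root by bisection, and classifies stability by the map
#' criterion `|G'(rho*)| < 1` (central finite difference). The boundary
#' point `rho = 1` — a fixed point in the continuity limit whenever
#' `beta > 0` and `pi > 0` — is appended with `boundary = TRUE`; it is
#' attracting since `G(rho) > rho` just below it. `rho = 0` is never a
#' literal root for finite `beta` (`G(0) > 0` strictly) and is therefore
#' not listed; use [flow_direction()] near the boundaries instead.
#'
#' @inheritParams G_discrete
#' @param grid_size Number of scan points (>= 100).
#' @param tol Bisection tolerance on `|G(rho*) - rho*|`.
#' @param deriv_step Central-difference step for `G'`.
#' @return A `data.frame` of class `fixed_points` with columns
#'   `rho_star`, `derivative`, `stable`, `boundary`, ordered by
#'   `rho_star`.
#' @examples
#' find_fixed_points(beta = 0, pi = 0.4, N = 200)  # single point at 0.5
#' @export
find_fixed_points <- function(beta, pi, N, grid_size = 2001, tol = 1e-10,
                              deriv_step = 1e-6) {
  grid_size <- assert_count(grid_size, "grid_size")
  if (grid_size < 100L) stop("`grid_size` must be >= 100", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  g_fun <- function(r) G_discrete(r, beta, pi, N) - r
  grid <- seq(0, 1 - MF_EPS, length.out = grid_size)
  gv <- g_fun(grid)
  roots <- grid[gv == 0]
  flips <- which(gv[-grid_size] * gv[-1L] < 0)
  for (k in flips) {
    lo <- grid[k]; hi <- grid[k + 1L]
    while (hi - lo > tol / 4) {
      mid <- (lo + hi) / 2
      if (g_fun(lo) * g_fun(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(roots))
  deriv <- vapply(roots, function(r) {
    lo <- max(0, r - deriv_step); hi <- min(1 - MF_EPS, r + deriv_step)
    (G_discrete(hi, beta, pi, N) - G_discrete(lo, beta, pi, N)) / (hi - lo)
  }, numeric(1))
  out <- data.frame(rho_star = roots, derivative = deriv,
                    stable = abs(deriv) < 1,
                    boundary = rep(FALSE, length(roots)))
  if (pi > 0 && beta > 0) {
    out <- rbind(out, data.frame(rho_star = 1, derivative = NA_real_,
                                 stable = TRUE, boundary = TRUE))
  }
  class(out) <- c("fixed_points", "data.frame")
  attr(out, "beta") <- beta
  attr(out, "pi") <- pi
  attr(out, "N") <- N
  out
}

#' Scan fixed points along beta or pi
#'
#' Recomputes [find_fixed_points()] along an increasing grid of one
#' parameter with the other held fixed, producing the data behind a
#' bifurcation diagram (stable and unstable branches of `rho*`).
#'
#' @param axis `"beta"` or `"pi"`: the swept parameter.
#' @param values Strictly increasing grid of parameter values.
#' @param beta,pi The fixed value of the non-swept parameter (supply the
#'   one that `axis` does not name).
#' @param N Population size.
#' @param ... Passed on to [find_fixed_points()].
#' @return A `data.frame` of class `bifurcation_scan` with columns
#'   `axis_value`, `rho_star`, `derivative`, `stable`, `boundary`.
#' @export
bifurcation_scan <- function(axis = c("beta", "pi"), values,
                             beta = NULL, pi = NULL, N, ...) {
  axis <- match.arg(axis)
  if (length(values) < 1L || is.unsorted(values, strictly = TRUE)) {
    stop("`values` must be strictly increasing", call. = FALSE)
  }
  fixed <- if (axis == "beta") pi else beta
  if (is.null(fixed)) {
    stop(sprintf("supply the fixed `%s` value",
                 if (axis == "beta") "pi" else "beta"), call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    fp <- if (axis == "beta") {
      find_fixed_points(beta = v, pi = fixed, N = N, ...)
    } else {
      find_fixed_points(beta = fixed, pi = v, N = N, ...)
    }
    cbind(axis_value = v, as.data.frame(fp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bifurcation_scan", "data.frame")
  attr(out, "axis") <- axis
  attr(out, "fixed") <- fixed
  attr(out, "N") <- N
  out
}
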