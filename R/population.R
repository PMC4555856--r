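# Predisposition profiles: the ordered intrinsic cooperation tendencies
# h_1 .. h_N that encode player heterogeneity.

#' Create a predisposition profile
#'
#' Low-level constructor. Most users should call [build_linear_profile()]
#' and then perturb the result with [scale_heterogeneity()],
#' [apply_gaussian_noise()] or [swap_positions()].
#'
#' @param values Numeric vector of predispositions `h_1 .. h_N`
#'   (dimensionless payoff units), ordered by player index.
#' @param provenance Either `"baseline"` (the unperturbed linear profile) or
#'   `"perturbed"`.
#' @return An object of class `predisposition_profile`: a list with elements
#'   `N`, `values` and `provenance`.
#' @export
predisposition_profile <- function(values, provenance = "perturbed") {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  provenance <- match.arg(provenance, c("baseline", "perturbed"))
  structure(
    list(N = length(values), values = values, provenance = provenance),
    class = "predisposition_profile"
  )
}

#' @export
print.predisposition_profile <- function(x, ...) {
  cat(sprintf("<predisposition_profile> N = %d (%s)\n", x$N, x$provenance))
  cat(sprintf("  h_1 = %.4g, h_2 = %.4g, ..., h_N = %.4g; mean = %.4g\n",
              x$values[1L], x$values[2L], x$values[x$N], mean(x$values)))
  invisible(x)
}

#' Build the linear predisposition profile
#'
#' Players are ranked from most to least intrinsically cooperative and the
#' predisposition of player `i` is `h_i = -(i - 2) / (N - 2)`. Player 1 is
#' the only one with a slight tendency to cooperate (`h_1 = 1/(N-2)`),
#' player 2 is indifferent (`h_2 = 0`), and predispositions decrease
#' linearly down to `h_N = -1`.
#'
#' @param N Number of players, at least 3 (the formula is degenerate below
#'   that).
#' @return A `predisposition_profile` with provenance `"baseline"`.
#' @examples
#' prof <- build_linear_profile(200)
#' prof$values[c(1, 2, 200)]  # 1/198, 0, -1
#' @export
build_linear_profile <- function(N) {
  N <- assert_count(N, "N")
  if (N < 3L) {
    stop("`N` must be at least 3: the linear profile -(i-2)/(N-2) is ",
         "degenerate for smaller populations", call. = FALSE)
  }
  i <- seq_len(N)
  predisposition_profile(-(i - 2) / (N - 2), provenance = "baseline")
}

#' Rescale heterogeneity about the mean predisposition
#'
#' Stretches (`lambda > 1`) or shrinks (`lambda < 1`) the spread of the
#' predispositions while keeping the mean exactly constant:
#' `h'_i = m + lambda * (h_i - m)` with `m = mean(h)`. `lambda = 0` gives a
#' homogeneous population; `lambda = 1` is the identity.
#'
#' @param profile A `predisposition_profile`.
#' @param lambda Nonnegative heterogeneity scale.
#' @return A new `predisposition_profile` (provenance `"perturbed"` unless
#'   `lambda == 1`).
#' @export
scale_heterogeneity <- function(profile, lambda) {
  assert_profile(profile)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  }
  if (lambda == 1) return(profile)
  m <- mean(profile$values)
  predisposition_profile(m + lambda * (profile$values - m), "perturbed")
}

#' Add Gaussian noise to the predispositions
#'
#' Adds independent zero-mean normal deviates of standard deviation `sd` to
#' each `h_i`. The perturbed profile keeps the original player ordering:
#' fault-assignment strategies keep using the published ranking even though
#' the noisy predispositions may no longer be monotone.
#'
#' @inheritParams scale_heterogeneity
#' @param sd Noise standard deviation (>= 0).
#' @param seed Integer seed; the same `(profile, sd, seed)` always yields
#'   the same output.
#' @return A new `predisposition_profile`.
#' @export
apply_gaussian_noise <- function(profile, sd, seed) {
  assert_profile(profile)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("`sd` must be a single nonnegative number", call. = FALSE)
  }
  seed <- assert_count(seed, "seed", zero_ok = TRUE)
  if (sd == 0) return(profile)
  values <- with_seed(seed, profile$values + stats::rnorm(profile$N, 0, sd))
  predisposition_profile(values, "perturbed")
}

#' Randomly swap the positions of a fraction of players
#'
#' Selects `round(fraction * N)` distinct players uniformly without
#' replacement; each selected player, in selection order, exchanges
#' predisposition values with a counterpart drawn uniformly from all `N`
#' positions (a self-draw is a no-op). The multiset of values is preserved
#' exactly; only the assignment of values to ranks changes, which degrades
#' the information the targeted strategies rely on.
#'
#' @inheritParams apply_gaussian_noise
#' @param fraction Fraction of players whose position is switched, in
#'   `[0, 1]`.
#' @return A new `predisposition_profile`.
#' @export
swap_positions <- function(profile, fraction, seed) {
  assert_profile(profile)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("`fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  seed <- assert_count(seed, "seed", zero_ok = TRUE)
  n_swap <- round(fraction * profile$N)
  if (n_swap == 0L) return(profile)
  values <- with_seed(seed, {
    v <- profile$values
    chosen <- sample.int(profile$N, n_swap)
    partners <- sample.int(profile$N, n_swap, replace = TRUE)
    for (k in seq_len(n_swap)) {
      i <- chosen[k]; j <- partners[k]
      tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
    }
    v
  })
  predisposition_profile(values, "perturbed")
}

#' Write / read a predisposition profile
#'
#' Profiles are stored as two-column delimited text with a header row,
#' columns `player_index` (1-based) and `h`.
#'
#' @param profile A `predisposition_profile`.
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return `write_profile` invisibly returns `path`; `read_profile` returns
#'   a `predisposition_profile` with provenance `"perturbed"` unless the
#'   values match the baseline formula exactly.
#' @export
write_profile <- function(profile, path, sep = ",") {
  assert_profile(profile)
  df <- data.frame(player_index = seq_len(profile$N), h = profile$values)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE)
  if (!all(c("player_index", "h") %in% names(df))) {
    stop("profile file must have columns `player_index` and `h`",
         call. = FALSE)
  }
  df <- df[order(df$player_index), , drop = FALSE]
  if (!identical(as.integer(df$player_index), seq_len(nrow(df)))) {
    stop("`player_index` must be exactly 1..N", call. = FALSE)
  }
  N <- nrow(df)
  i <- seq_len(N)
  baseline <- N >= 3 && isTRUE(all.equal(df$h, -(i - 2) / (N - 2),
                                         tolerance = 1e-12))
  predisposition_profile(df$h, if (baseline) "baseline" else "perturbed")
}
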