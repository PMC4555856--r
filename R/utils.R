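# Internal validation and RNG helpers.

assert_count <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (zero_ok) 0 else 1) {
    stop(sprintf("`%s` must be a single %s integer", name,
                 if (zero_ok) "nonnegative" else "positive"), call. = FALSE)
  }
  as.integer(x)
}

assert_profile <- function(profile) {
  if (!inherits(profile, "predisposition_profile")) {
    stop("`profile` must be a `predisposition_profile` ",
         "(see build_linear_profile())", call. = FALSE)
  }
  invisible(profile)
}

assert_state <- function(state, N = NULL) {
  if (!is.logical(state) || anyNA(state)) {
    stop("`state` must be a logical vector (TRUE = cooperate) without NAs",
         call. = FALSE)
  }
  if (!is.null(N) && length(state) != N) {
    stop(sprintf("`state` has length %d but N = %d", length(state), N),
         call. = FALSE)
  }
  invisible(state)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive `n` independent substream seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Numerically stable log(cosh(x)).
log_cosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}
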