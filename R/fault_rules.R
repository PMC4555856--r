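# Fault-assignment strategies: which defectors are "at fault" (punishable)
# in a given configuration, and the one-flip counterfactual used to
# compute a cooperator's deterrent.

#' Define a fault-assignment strategy
#'
#' Three strategies decide which defectors are punishable:
#' * `"uniform"` — every defector is at fault; the community's punishing
#'   capacity is divided among all of them.
#' * `"single_file"` — defector `i` is at fault only if player `i - 1`
#'   (the next-most-cooperative player) currently cooperates; player 1 is
#'   always at fault when defecting (the bootstrap rule).
#' * `"groups"` — players are partitioned into contiguous blocks of size
#'   `nu` in rank order; a defector in group `m` is at fault iff at least a
#'   proportion `theta` of the players in group `m - 1` cooperate; group 1
#'   is always at fault when defecting.
#'
#' `single_file` is exactly `groups` with `nu = 1` and any
#' `theta` in `(0, 1]`.
#'
#' @param kind One of `"uniform"`, `"single_file"`, `"groups"`.
#' @param nu Group size (groups strategy only), a positive integer.
#' @param theta Cooperation threshold in `(0, 1]` (groups strategy only),
#'   applied to the actual size of the preceding group.
#' @return An object of class `strategy_rule`.
#' @examples
#' strategy_rule("groups", nu = 10, theta = 0.8)
#' @export
strategy_rule <- function(kind = c("uniform", "single_file", "groups"),
                          nu = NULL, theta = NULL) {
  kind <- match.arg(kind)
  if (kind == "groups") {
    nu <- assert_count(nu, "nu")
    if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
        theta <= 0 || theta > 1) {
      stop("`theta` must be a single number in (0, 1]", call. = FALSE)
    }
  } else {
    if (!is.null(nu) || !is.null(theta)) {
      stop("`nu` and `theta` apply only to the groups strategy",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, nu = nu, theta = theta),
            class = "strategy_rule")
}

#' @export
print.strategy_rule <- function(x, ...) {
  if (x$kind == "groups") {
    cat(sprintf("<strategy_rule> groups (nu = %d, theta = %g)\n",
                x$nu, x$theta))
  } else {
    cat(sprintf("<strategy_rule> %s\n", x$kind))
  }
  invisible(x)
}

#' Partition players into contiguous rank-ordered groups
#'
#' Players `1..nu` form group 1, `nu+1..2*nu` group 2, and so on; the last
#' group is smaller when `nu` does not divide `N`.
#'
#' @param N Number of players.
#' @param nu Group size, `1 <= nu <= N`.
#' @return An object of class `group_partition`: list with `group`
#'   (group index per player), `sizes` (players per group) and `n_groups`.
#' @examples
#' assign_groups(7, 3)$sizes  # 3 3 1
#' @export
assign_groups <- function(N, nu) {
  N <- assert_count(N, "N")
  nu <- assert_count(nu, "nu")
  if (nu > N) stop("`nu` must not exceed `N`", call. = FALSE)
  group <- (seq_len(N) - 1L) %/% nu + 1L
  sizes <- tabulate(group)
  structure(list(group = group, sizes = sizes, n_groups = length(sizes)),
            class = "group_partition")
}

# Resolve the partition a rule needs (NULL for non-group rules).
resolve_partition <- function(rule, N, partition = NULL) {
  if (rule$kind != "groups") return(NULL)
  if (is.null(partition)) return(assign_groups(N, rule$nu))
  if (!inherits(partition, "group_partition") ||
      length(partition$group) != N) {
    stop("`partition` must be a group_partition over N players",
         call. = FALSE)
  }
  partition
}

#' Which players are at fault in a configuration?
#'
#' Applies a fault-assignment strategy to a full configuration of
#' cooperation states. Only defectors can be at fault; the strategy decides
#' which of them are.
#'
#' @param state Logical vector of length `N`, `TRUE` = cooperate.
#' @param rule A [strategy_rule()].
#' @param partition Optional precomputed [assign_groups()] partition
#'   (groups strategy only); computed from `rule$nu` when omitted.
#' @return An object of class `fault_assessment`: list with `at_fault`
#'   (logical per player) and `n_f` (number of players at fault).
#' @examples
#' rule <- strategy_rule("single_file")
#' fault_mask(c(TRUE, TRUE, FALSE, FALSE, FALSE), rule)$at_fault
#' @export
fault_mask <- function(state, rule, partition = NULL) {
  assert_state(state)
  if (!inherits(rule, "strategy_rule")) {
    stop("`rule` must be a `strategy_rule`", call. = FALSE)
  }
  N <- length(state)
  partition <- resolve_partition(rule, N, partition)
  at_fault <- switch(
    rule$kind,
    uniform = !state,
    single_file = !state & c(TRUE, state[-N]),
    groups = {
      coop_per_group <- tabulate(partition$group[state],
                                 nbins = partition$n_groups)
      pass <- c(TRUE, coop_per_group[-partition$n_groups] >=
                  rule$theta * partition$sizes[-partition$n_groups])
      !state & pass[partition$group]
    }
  )
  structure(list(at_fault = at_fault, n_f = sum(at_fault)),
            class = "fault_assessment")
}

#' Counterfactual fault assessment for a cooperator
#'
#' Evaluates [fault_mask()] on the configuration identical to `state`
#' except that cooperating player `i` is flipped to defect, all other
#' players held fixed. This is the assessment a cooperator uses to gauge
#' the punishment she would attract by defecting; the returned `n_f` is the
#' counterfactual fault count (which includes player `i` herself whenever
#' `self_at_fault` is `TRUE`).
#'
#' @inheritParams fault_mask
#' @param i Index of a player who cooperates in `state`.
#' @return A `fault_assessment` with an extra element `self_at_fault`.
#' @export
counterfactual_fault <- function(state, rule, partition = NULL, i) {
  assert_state(state)
  i <- assert_count(i, "i")
  if (i > length(state)) stop("`i` out of range", call. = FALSE)
  if (!state[i]) {
    stop(sprintf("player %d already defects; the counterfactual is only ",
                 i), "defined for cooperators", call. = FALSE)
  }
  flipped <- state
  flipped[i] <- FALSE
  fa <- fault_mask(flipped, rule, partition)
  fa$self_at_fault <- fa$at_fault[i]
  fa
}
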