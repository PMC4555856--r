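---
title: "Targeted punishment in heterogeneous social dilemmas: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted punishment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punisim)
```

## The model

`punisim` simulates a binary-state social dilemma among $N$ heterogeneous
players. At every synchronous time step each player independently chooses
to cooperate with probability

$$P_i = \tfrac12\left[\tanh(\beta H_i) + 1\right],
\qquad H_i = p_i + h_i,$$

the transition rule familiar from Ising spins and Hopfield neurons.
$H_i$ is the perceived net payoff difference in favour of cooperating.
Its two parts:

* **Predisposition** $h_i = -(i-2)/(N-2)$: players are ranked from most
  to least intrinsically cooperative. Player 1 slightly favours
  cooperation ($h_1 = 1/(N-2)$), player 2 is exactly indifferent, player
  $N$ has $h_N = -1$. The profile is in dimensionless payoff units; its
  slope fixes the payoff scale against which $\pi$ is measured.
* **Punishment** $p_i$: $n_p$ punishers each wield capacity $\pi$,
  divided equally over the $n_f$ players currently *at fault*, so an
  at-fault defector feels $p_i = \pi n_p / n_f$ and a defector not at
  fault feels $p_i = 0$. A *cooperator* is deterred by the counterfactual:
  if she would be at fault were she alone to defect, she feels
  $p_i = \pi \tilde n_p / \tilde n_f$, where the tilded counts are taken
  in the one-flip configuration and the punisher pool excludes herself
  (with cooperators as punishers, $\tilde n_p = n_c - 1$). We include the
  factor $\pi$ in the counterfactual term for dimensional consistency
  with the at-fault balance; omitting it would make the deterrent
  incommensurable with $h_i$.

Three punisher-pool policies are supported: `cooperators`
($n_p = n_c$, the default), `all` ($n_p = N$; defectors punish too), and
`fraction` ($n_p = a\,n_c$, exactly equivalent to rescaling
$\pi \to a\pi$, which is why it is implemented as a real-valued count).

### Fault-assignment strategies

* **uniform** — all defectors are at fault ($n_f = N - n_c$);
* **single file** — defector $i$ is at fault iff player $i-1$ cooperates;
* **groups** — contiguous rank-ordered blocks of size $\nu$ (the last
  block may be short); a defector in block $m$ is at fault iff at least
  a proportion $\theta$ of block $m-1$ cooperates.

Single file is exactly groups with $\nu = 1$ (any $\theta \in (0,1]$);
the test suite checks this over all $2^N$ configurations for small $N$.
Three conventions required a decision:

* *Bootstrap*: group 1 — and player 1 under single file — is
  unconditionally at fault when defecting. Without it nothing can start
  a cascade from universal defection; extending the rule from the groups
  strategy to single file keeps the $\nu = 1$ equivalence exact.
* *Inclusive threshold*: "at least a proportion $\theta$" is the
  comparison $\#\text{cooperators} \ge \theta \cdot |{\rm block}\ m-1|$
  on the preceding block's actual size.
* *Time-$t$ evaluation*: fault (and every counterfactual) is evaluated on
  the time-$t$ configuration; a counterfactual flips exactly one player
  and holds everyone else fixed.

### Update scheme

Updates are synchronous: all $N$ players redraw their states
simultaneously from the time-$t$ probabilities. This matches the
mean-field construction, which treats $G(\rho_t)$ as the expected
density after one whole-population update. (The sigmoid rule would admit
an asynchronous one-player-per-tick variant; we did not implement one,
as all analyses in the package are phrased in whole-population steps.)

The per-step kernel is $O(N)$: for each rule the counterfactual fault
counts of all cooperators are obtained in closed form (e.g. under single
file, flipping cooperator $i$ adds herself to the fault set iff her
predecessor cooperates and removes her successor iff that successor is
an at-fault defector) rather than by $N$ one-flip re-evaluations. A
deliberately naive flip-and-recount implementation lives in the test
helpers and cross-checks the kernel on randomized configurations for
every rule and pool.

$\beta = \infty$ is implemented as the continuity limit of the sigmoid:
$P = 1$ for $H > 0$, $P = \tfrac12$ at $H = 0$, $P = 0$ for $H < 0$.

## Tunable parameters

| Parameter | Meaning | Units / range | Default |
|---|---|---|---|
| $N$ | players | $\ge 3$ | 200 |
| $\beta$ | rationality | $[0, \infty]$ | — |
| $\pi$ | punishment capacity per punisher | payoff units, $\ge 0$ | — |
| pool, $a$ | who punishes | see above | `cooperators` |
| $\nu, \theta$ | group size, threshold | $\nu \ge 1$, $\theta \in (0,1]$ | — |
| `t_max`, `burn_in`, `window` | steps | counts | 2000 / 500 / 500 |
| `realizations` | independent runs | count | 100 |

$N = 200$ mirrors the number of countries in the world, the motivating
application. Defaults for the groups strategy follow the reference
setting $\nu = 10$, $\theta = 0.8$ at $N = 200$ (20 groups).

Stationarity is operationalized as a fixed burn-in followed by a fixed
averaging window, both configurable, rather than adaptive detection —
adaptivity would make runs irreproducible across seeds. The estimator is
the mean over realizations of per-realization window means; its standard
error is taken across realizations, which is robust to within-run
autocorrelation. In bistable regimes the "stationary" density is
metastable and depends on the initial condition by design — that
dependence is the object of study, so burn-in must not be long enough to
tunnel between basins (at $N = 200$ tunnelling is astronomically rare).

## Mean-field analysis

For the uniform rule with cooperators as punishers (and only there — the
targeted strategies break the permutation symmetry the derivation needs),
every at-fault player feels $\pi n_c/(N - n_c) = \pi\rho/(1-\rho)$ and
the expected next-step density is

$$G(\rho) = \frac1N \sum_{i=1}^N \frac{\tanh\!\big(\beta(\pi\rho/(1-\rho)
  - \tfrac{i-2}{N-2})\big) + 1}{2}.$$

Fixed points solve $G(\rho^*) = \rho^*$; a fixed point is stable when
$|G'(\rho^*)| < 1$. Numerical choices:

* the singularity at $\rho = 1$ is guarded by $\varepsilon = 10^{-9}$;
  $\rho = 1$ is reported as a *boundary* fixed point (the continuity
  limit $G \to 1$ for $\beta, \pi > 0$), attracting since $G > \rho$
  just below it;
* $\rho = 0$ is **not** listed as a fixed point: $G(0) > 0$ strictly for
  finite $\beta$, so universal defection always drifts upward a little;
  boundary behaviour is reported through `flow_direction`
  ($\mathrm{sign}(G - \rho)$) instead;
* roots are located by sign changes on a 2001-point grid and refined by
  bisection to $10^{-10}$; derivatives use central differences with step
  $10^{-6}$. Stability by $|G'| < 1$ and the inward/outward flow pattern
  can disagree only for $G' < -1$ oscillatory cases, which are reported
  as unstable; both diagnostics are exposed.

`G_continuum` replaces the player average with an integral over $h$
uniform on $[-1, 1/(N-2)]$, giving the closed form
$\tfrac12 + \frac{\ln\cosh\beta(c+b) - \ln\cosh\beta(c+a)}{2\beta(b-a)}$
with $c = \pi\rho/(1-\rho)$ (evaluated with a stable
$\ln\cosh$). It is an independent analytic check of `G_discrete`; they
agree to $O(1/N)$ and the tests assert $2/N$.

The resulting structure: at moderate $\pi$ (e.g. 0.4) an interval of
$\beta$ carries a stable low-$\rho$ fixed point and an unstable
threshold above it — universal defection is trapped even though
universal cooperation is maintainable. At higher $\pi$ (e.g. 0.6) an
interval of $\beta$ opens with no stable interior point: an
uninterrupted path from $\rho = 0$ to $\rho = 1$. At fixed
$\beta = 2.5$ the trap disappears above a critical $\pi \approx 0.6$.

## Exact oracle

For $N \le 12$ the synchronous chain over all $2^N$ configurations is
built densely, with transition elements
$\prod_i P_i(s)^{[s'_i = C]}(1-P_i(s))^{[s'_i = D]}$. For finite $\beta$
all entries are positive, so the chain is ergodic; the stationary law is
found by power iteration (L1 tolerance $10^{-12}$, cap $10^6$ sweeps) and
is start-independent, which the tests verify. $\beta = \infty$ is
rejected — the deterministic chain can be reducible — and
deterministic-limit claims are checked by direct cascade simulation
instead. The oracle's stationary expected density anchors the
Monte-Carlo estimator across rules and pools at small $N$, and
reproduces the $\pi = 0$ product-form closed form
$\frac1N\sum_i \tfrac12[\tanh(\beta h_i)+1]$ to $10^{-10}$.

## The deterministic single-file cascade

With $\beta = \infty$, cooperators punishing and all players defecting,
player 1 cooperates on her own predisposition at the first step; the
indifferent player 2 ($h_2 = 0$, unpunished while player 1 defects) is a
fair coin at that step only; thereafter exactly one player — the at-fault
frontier defector — converts per step. Since at most players 1 and 2 can
flip in the first step and one player per step after, $n_c(t) \le t+1$
and therefore $\tau \ge N-1$: the first-passage time is exactly $N-1$
(coin succeeds) or $N$ (coin fails), each with probability $\tfrac12$,
giving speed $v = N/\tau \approx 1$.

Sustaining the cascade needs more than flipping the frontier. The
frontier player at position $k$ feels $\pi(k-1)$ against at worst
$-1$, so any $\pi > 1/(N-1)$ suffices there; but the already-converted
cooperator at position $k-2$ shares her counterfactual punishment with
the frontier ($\tilde n_f = 2$) and feels $\pi(k-2)/2$ against
$-(k-4)/(N-2)$, so the cascade survives for all frontier positions only
when $\pi > 2(N-4)/(N-2)^2 \approx 2/N$ — about twice the frontier-only
bound. The packaged tests exercise the cascade at $\pi = 0.5$, far
inside the safe regime; at, say, $N = 10$ and $\pi = 0.13$ (above the
frontier bound, below the maintenance bound) the column collapses behind
the frontier and full cooperation is never reached.

## Synthetic-data generator and its scope

All "data" in this package is generated by the simulator itself; the
generator's defaults are the study conditions: $N = 200$ players on the
linear profile, 100 realizations per estimate, all-cooperate versus
all-defect initial conditions, sweep ranges $\beta \in [0,5]$,
$\pi \in [0,1.5]$ (the figure axis ranges are not fixed by the source
material; these brackets contain every reported qualitative transition —
the $\pi = 0.4$ bistable regime, the $\pi = 0.6$ corridor, the
$\beta = 2.5$ critical-$\pi$ scan). Robustness perturbations mirror the
described variations: Gaussian noise on $h_i$ (its standard deviation
is a free parameter, as no value is fixed by the source), random
re-positioning of 25% of players (implemented as sequential
transpositions with uniformly chosen counterparts, self-swap a no-op —
the simplest reading of "switching with randomly chosen counterparts"),
heterogeneity rescaling at constant mean, and the all-players punisher
pool.

What the generator does *not* emulate: real decision-makers are not
exchangeable sigmoid units — there is no network structure, no memory,
no strategic anticipation, no evolutionary (imitation) update, and the
payoff scale is stylized. Passing tests therefore certify the internal
consistency of model, mean-field theory and simulator — not predictions
about empirical populations.

## Problem sizes used in the packaged checks

The packaged test-and-reproduction runs scale the study conditions down
to keep them comfortably reproducible on a laptop while leaving every
statistical margin intact: stationary estimates use 10–50 realizations
with burn-in/window 500/500 (200/2800 for the small-$N$ oracle
comparisons, where mixing at $\beta = 1$ is fast), and the strategy
comparison runs a $10 \times 10$ grid at $N = 50$ with $R = 10$ and
burn-in/window 300/200. At those sizes the full suite runs in about two
minutes; all comparisons are made at $3\times$ the measured standard
error, so the scaled-down sizes do not loosen any check.

## Known limitations

* The mean-field machinery covers only the uniform rule with
  cooperators as punishers; targeted strategies are analysed by
  simulation (no analytic treatment exists to compare against).
* The exact oracle is dense and capped at $N = 12$ by memory
  ($2^{12} \times 2^{12}$ transition matrix).
* `pool = "fraction"` uses the exact $\pi \to a\pi$ equivalence (a
  real-valued punisher count) rather than sampling a discrete subset of
  punishers; fluctuations in *who* punishes are therefore not modelled.
* Censored cells in speed maps report $v = 0$ with a censored-fraction
  flag; the mean speed over uncensored runs is upward-biased in cells
  where only fast runs finish within `t_max`.
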