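---
title: "Markovian kinetics of Cdc20 inhibition and APC/C activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markovian kinetics of Cdc20 inhibition and APC/C activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacr)
```

## The system and its two phases

The spindle assembly checkpoint (SAC) must do two contradictory things
well. While any kinetochore is unattached it must make accidental APC/C
activation by free Cdc20 very unlikely, for as long as chromosome
congression takes (tens of minutes). The moment the last kinetochore
attaches, it must let Cdc20 activate *all* APC/C targets quickly, so that
anaphase is not delayed. `sacr` models both phases as continuous-time
Markov chains on small copy numbers, because the free Cdc20 pool under
checkpoint inhibition is tiny (on the order of one molecule or less) and
deterministic rate equations are not meaningful at that scale.

**Checkpoint (inhibition) phase.** The state is the number `k` of free
Cdc20 molecules. Three channels act:

* production `k -> k+1` at rate `lambda * (S - k)` — Cdc20 is released
  from a finite pool of `S` sequestering complexes, which caps `k` at `S`
  exactly (the truncation of the state space is not an approximation);
* inhibition `k -> k-1` at rate `k_minus1 * k` — capture of free Cdc20 by
  the mitotic checkpoint complex (MCC), assumed homogeneously distributed
  and constant in time;
* activation at rate `mu * N * k` — any free molecule reaching any of the
  `N` unattached-kinetochore APC/C targets. This is absorbing: one
  activation event ends the checkpoint's protection, so the phase-1
  observable is the survival probability `P(t)` that it has not happened
  by time `t`.

`P(t)` has a closed form: the generating function of the chain propagates
along characteristics of a Riccati equation, whose linearisation has two
real roots `r1 >= r2` of `X^2 - (-lambda + mu*N + k_minus1) X -
k_minus1*lambda`, and

`P(t) = [((lambda+r1) e^{-(lambda+r2)t} - (lambda+r2) e^{-(lambda+r1)t}) / (r1 - r2)]^S.`

The package takes this formula as the artifact and *proves it
numerically* rather than re-deriving it symbolically: `cme_survival()`
integrates the full master equation with an independent stiff solver, and
the test suite requires agreement to 1e-6 absolute at the worked point
and on randomized parameter sets (see "Validation scales" below).

**Anaphase-onset (activation) phase.** Once all kinetochores attach, MCC
production stops and its clearance is taken as fast relative to the
activation dynamics, so inhibition is switched off exactly
(`k_minus1 = 0` in this phase; `k_minus1` enters only through the initial
condition). The state is `(k, m)`: `k` Cdc20 molecules in total, `m` of
them bound to (and having activated) distinct APC/C targets. Channels:

* production `(k,m) -> (k+1,m)` at `lambda * (S - k)`;
* activation `(k,m) -> (k,m+1)` at `mu * (N - m) * (k - m)` — the `k - m`
  free molecules each see the `N - m` remaining targets.

Both coordinates are non-decreasing, so the chain is acyclic. Anaphase is
triggered at absorption into `m = N`; the observable is the mean
absorption time `tau`.

## Equilibrium as the hand-over between phases

Conditioned on the checkpoint surviving, the activation channel drops out
of the phase-1 dynamics and `k` follows a plain birth-death chain with
birth `lambda*(S-k)` and death `k_minus1*k`. Its stationary law is
binomial with `S` trials and success probability
`lambda/(lambda + k_minus1)` — at the PTK2 defaults a mean of only
`S*lambda/(lambda + k_minus1) ~ 0.0125` molecules. This law is the default
initial condition of the activation phase. Two diagnostics are exported:
`stationarity_residual()` verifies that the closed form annihilates the
generator (detailed balance holds link by link), and
`equilibrium_relaxation_time()` returns the slowest relaxation scale
`1/(lambda + k_minus1)`. The hand-over assumes the checkpoint lasted long
compared to that scale (about 1/24 s at the defaults, so comfortably
satisfied); no hard threshold is imposed — users of unusual parameter
regimes should compare the checkpoint duration to the diagnostic
themselves.

## Solving for the mean activation time

Integrating the forward equations of the activation chain over all time
converts them into a linear system for the expected occupation times
`a(k,m)` of the transient states (`m < N`):

`[lambda*(S-k) + mu*(N-m)*(k-m)] a(k,m) = init(k) 1(m=0) + lambda*(S-k+1) a(k-1,m) + mu*(N-m+1)*(k-m+1) a(k,m-1)`

with `tau = sum a(k,m)`. These balance equations are derived directly from
the transition rates above — each inflow coefficient is exactly the exit
rate of the feeding state, which is what conservation of probability flux
demands. Because the chain is acyclic, `occupation_times()` solves the
system in one topological-order sweep (increasing `m`, then increasing
`k`), never iterating to convergence; the cost is linear in the roughly
`N*(S+1)` states (about 39 000 at the defaults, milliseconds in
practice). Two independent routes guard the sweep: a sparse
fundamental-matrix solve of the same chain (`method = "matrix"`) and
time-integration of the transient master equations
(`transient_distribution()`) followed by quadrature.

Degenerate inputs are refused rather than patched: `lambda = 0` with
initial mass below `k = N` means absorption is unreachable
(`tau = Inf`, a classed error that the constraint evaluator maps to a
failed timing constraint), and a reachable state with zero exit rate is
reported as a model degeneracy instead of dividing by zero.

## Parameters, units and defaults

| quantity | meaning | default | unit |
|---|---|---|---|
| `lambda` | per-complex Cdc20 production rate | `1e-4` (`lambda*S = 0.3`) | s⁻¹ |
| `k_minus1` | per-molecule inhibition rate | 24 | s⁻¹ |
| `mu` | per-molecule, per-target arrival rate | `2e-4` | s⁻¹ |
| `N` | chromosomes / APC/C targets | 13 | — |
| `S` | Cdc20-sequestering complex pool | 3000 | — |
| `tau1_s` | checkpoint duration for C1 | 1200 | s |
| `p_threshold` | survival floor for C1 | 0.95 | — |
| `tau_prime_s` | activation-time ceiling for C2 | 600 | s |

The defaults describe PTK2 (rat-kangaroo kidney) cells: 13 chromosomes,
a flat ~100 µm³ cell, and a 50 nM pool of sequestering complexes
(`nanomolar_to_copies(50, 100)` = 3011, used as the round number 3000).

Two constructors derive rates from physical geometry.
`k_minus1_smoluchowski()` computes the diffusion-limited capture rate
`2*pi*b*D*[MCC]`; at `b` = 2 nm, `D` = 20 µm²/s and 10⁴ MCC copies in
100 µm³ it gives `8*pi = 25.13` s⁻¹, and the package default of 24 s⁻¹
should be read as that figure rounded. `mu_from_geometry()` computes
`4aD/V`, which at the tabulated geometry (`a` = 0.01 µm) gives
8e-3 s⁻¹ — a factor 40 above the default `mu = 2e-4` s⁻¹. The two values
cannot be reconciled from the geometry alone; the package deliberately
keeps the tabulated effective `mu` as the default (it is the value the
worked-point analysis is built on, and plausibly absorbs target-search
effects the bare small-target formula ignores) while leaving the
geometric constructor available and documented as inconsistent with it.
Users deriving `mu` from their own geometry should treat the default and
the constructor as two distinct modelling choices, not interchangeable.

## The constraint domain

`evaluate_constraints()` checks C1 (`P(tau1) >= p_threshold`) and C2
(`tau <= tau_prime_s`) at one parameter point; `scan_domain()` maps them
over a `(lambda*S, k_minus1)` grid. The scan is parameterised by the
aggregate production rate `lambda*S` rather than `lambda` because that is
the scale on which the two constraints act (the survival exponent and the
early production flux are both proportional to it); `lambda = lambdaS/S`
internally. Default axes are 41 log-spaced points over
`lambda*S` in `[0.01, 2]` and `k_minus1` in `[0.1, 100]` s⁻¹ — log
spacing because both constraints respond multiplicatively, and this range
brackets the admissible band on all sides. Since `P` falls and `tau`
falls as production grows, each fixed-`k_minus1` row of the admissible
set Ω is an interval: C2 sets its left edge, C1 its right edge.
`boundary_lambdaS()` locates either edge by plain bisection (chosen over
superlinear root finders so that the bracket width contracts exactly by
half per step, making the `tol` argument an honest guarantee); a
divergent `tau` is kept as an explicit `Inf` and excluded from brackets.
At the worked point the package computes `P(1200 s) = 0.96`,
`tau = 345 s` and `rho = k_minus1/(lambda*S) = 80`, inside Ω. The
`rho` and `lambda*S` extents of Ω that `glance()` reports are
descriptive outputs of whatever grid was scanned, not calibrated
constants.

## The synthetic trajectory generator

`simulate_inhibition()` and `simulate_activation()` are exact
stochastic simulations (Gillespie direct method) of the two reaction
networks — the same processes the analytic layers describe, with no
approximation beyond floating point. With only two or three channels the
direct method (one uniform pair per event: exponential waiting time at
the total propensity, then a propensity-proportional channel choice) is
the simplest auditable choice; no tau-leaping or hybrid acceleration is
used or needed at these rates. Determinism contract: a trajectory is a
pure function of `(params, seed)`; ensembles derive per-run seeds from a
root seed by a counter-based map, so results do not depend on execution
order. The ensemble runner skips per-event recording and keeps only
outcomes (absorption time, final state), which is what the summaries
need.

What the generator emulates is exactly the model: exponential waiting
times, constant MCC, a well-stirred cell with scalar effective rates.
What it does *not* emulate — and what passing Monte-Carlo checks
therefore cannot certify about real cells — includes spatial diffusion
and local depletion around kinetochores (space enters only through the
effective rates `mu` and `k_minus1`), time-varying MCC levels during
checkpoint establishment or silencing, gradual decay of inhibition at
the phase hand-over, per-kinetochore attachment dynamics (`N` is fixed
within each phase), and the downstream securin/separase cascade between
APC/C activation and physical chromatid separation.

## Numerical choices

* **Survival in log space.** `P(t)` is a number near 1 raised to
  `S ~ 3000`; `survival_probability()` computes
  `S * log B(t)` with `log B = -(lambda+r2) t + log1p((lambda+r2) *
  (1 - e^{-(r1-r2)t})/(r1-r2))`, which is exact at `t = 0` and immune to
  the harmless underflow of `e^{-(lambda+r1)t}`.
* **Stable roots.** `r2` is computed from the product relation
  `r1*r2 = -k_minus1*lambda` and `lambda + r2` from
  `(lambda+r1)(lambda+r2) = lambda*mu*N`, never by subtracting nearly
  equal square roots; at the defaults the naive subtraction would lose
  six significant digits exactly where the survival exponent needs them.
* **Degenerate double root.** `r1 = r2` occurs only on the measure-zero
  set `k_minus1*lambda = 0` with `mu*N + k_minus1 = lambda`; the analytic
  limit `B = e^{-lambda t}(1 + lambda t)` is used there, not a tolerance
  fallback.
* **Clamping policy.** Probabilities are clamped into `[0, 1]` only when
  the excursion is at rounding level; a closed-form value exceeding 1 by
  more than 1e-12 (or an absorbed mass exceeding 1 by more than 1e-8 in
  the ODE layer) raises an error, so genuine bugs cannot hide behind the
  clamp.
* **Stiff master-equation integration.** The inhibition-phase system is
  stiff when `k_minus1 >> lambda` (ratio ~ 1e5 at the defaults);
  `cme_survival()` uses `lsoda` with a tridiagonal banded Jacobian, so a
  factorisation costs O(S) and the full worked point (3001 states,
  1200 s) integrates in well under a second.
* **Conservation diagnostic.** The absorbed probability is recovered by
  quadrature of the absorption flux on a grid refined around the fast
  initial relaxation, using a Hermite-corrected trapezoidal rule (the
  flux derivative is available exactly through the generator), and
  `max |sum_k p_k + p_absorbed - 1|` is reported with the result.
* **Binomial pmf via log-gamma.** Equilibrium probabilities go through
  `dbinom()`; naive factorials overflow near `S = 3000`.

## Validation scales

The automated checks run the full worked point wherever it is cheap
(closed form vs. master equation on `[0, 1200]` s with 3001 states; the
occupation-time sweep vs. the sparse matrix solve on all ~39 000 states)
and scale down only where a dense oracle is the point: matrix-exponential
and fundamental-matrix cross-checks use pools of `S <= 20` (at most 200
chain states), and transient-quadrature checks use `S = 6, N = 2` with a
step small enough for 1e-4 agreement. Monte-Carlo consistency uses 10⁴
trajectories per phase (acceptance suite; smaller ensembles in unit
tests), with agreement required within three standard errors — per time
point for survival, for the mean activation time, and per pooled bin
(expected count ≥ 5) for the equilibrium histogram.

## Known limitations

Beyond the generator's scope listed above: the constraint domain is
unbounded above in `k_minus1` (a ceiling would need an independent bound
on MCC concentration, e.g. through the Smoluchowski helper, which the
package reports but does not impose); the conditioned equilibrium is used
as the exact phase hand-over law rather than the true conditional
distribution of the absorbing chain (the difference is negligible
whenever survival stays near 1, which is the only regime where the
checkpoint is doing its job); and the mean activation time is sensitive
to that initial law — `tau` falls steeply as the initial free-Cdc20 level
rises — so conclusions about anaphase timing inherit any uncertainty in
the equilibrium Cdc20 level.
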