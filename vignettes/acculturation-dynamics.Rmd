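---
title: "Acculturation dynamics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acculturation dynamics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accultdyn)
```

## The model

A population of `N` individuals carries one of two cultural traits: R,
the trait initially carried by all residents, and I, the trait carried
by every arriving immigrant. Each trait is linked to an acculturation
orientation with two dimensions: cultural conservatism `c` — the
inclination to retain the own trait when interacting across the cultural
divide — and interaction tendencies `x_same` / `x_other`. A pair
actually interacts with the product of the two partners' tendencies, so
the mixed-pair interaction probability is `X_ir = x_ir * x_ri`.

Dynamics are event based. Per event, a uniformly drawn focal individual
is either replaced by a type-I immigrant (probability `m`) or paired
with one of the other `N - 1` individuals. A realised mixed interaction
makes the focal switch trait with changing probability
`S = (1 - c) * bias(dW)`, where `bias(dW) = 2 / (1 + exp(-dW))` is a
logistic success bias in the payoff advantage `dW` of the partner's
trait over the own. The factor 2 makes `S = 1 - c` exactly when payoffs
are equal. When an individual switches trait it also adopts the other
type's orientation: trait and orientation are inextricably linked, so
the population state is fully described by the type frequency.

Payoff regimes (`payoff_spec()`):

* **baseline** — no payoff consequences, `S = 1 - c`;
* **resident_advantage / immigrant_advantage** — the superior trait
  earns a constant `W0 > 0`, the other 0;
* **coordination / complementation** — a trait earns `W0` times its
  perceived frequency (coordination: the common trait wins) or `W0`
  times the perceived frequency of the other trait (complementation:
  the rare trait wins).

Perception is filtered through the interaction structure: an individual
estimates a trait's frequency by the rate at which it encounters it,
the conditional probability
`p_{x|y} = p_x X_xy / (p_x X_xy + (1 - p_x) X_yy)`. A rare type that
seldom meets the majority (low `X_ir`) therefore perceives its own
trait as common — the enclave effect.

The mean-field limit of the event process is

$$\frac{dp_i}{dt} = \frac{1}{N}\left[m(1 - p_i) +
  (1-m)(1-p_i)\,p_i\,X_{ir}\,\Delta S(p_i)\right],$$

with `dS = S_r - S_i` the net flow from R to I per realised mixed
interaction. `p_i = 1` is always an equilibrium (immigration cannot
restore trait R once it is gone), and `p_i = 0` never is
(`drift(0) = m/N > 0`): under sustained immigration the immigrant trait
cannot go extinct. Internal equilibria solve `M = Psi(p_i)` with
`M = m/(1-m)` (the odds of a migration versus an interaction event) and
`Psi(p_i) = -p_i X_ir dS(p_i)`.

## Parameters that matter

| Parameter | Meaning | Domain | Default use |
|---|---|---|---|
| `N` | population size | integer ≥ 2 | 1000 in the study protocol |
| `m` | migration-event probability per event | (0, 1) | swept 0.001–0.096 |
| `c_r`, `c_i` | conservatism of each type | [0, 1] | swept 0.001–0.951 |
| `X_ir` | mixed-pair interaction probability | [0, 1] | 0.1 / 0.5 |
| `W0` | superior payoff magnitude | > 0 | 1 |

All are probabilities (dimensionless); `m` is *relative* to interaction
events, not a per-time rate, so one time unit of the mean-field model
corresponds to about `N` events of the stochastic engine (the `1/N`
prefactor is kept in `drift()` for that reason).

The qualitative message is monotone in the baseline regime: the
coexistence frequency of the immigrant trait rises with `m` and falls
with both `delta_c = c_r - c_i` and `X_ir`, and coexistence exists at
all only when `m/(1-m) < delta_c * X_ir` — i.e. when residents are the
more conservative type *and* the groups actually interact.

## Design choices

Several points are genuinely open at the level of the verbal model; the
package resolves them as follows.

**Same-type perception.** Applying the cross-type conditional
probability formula literally with observer = observed collapses to the
true frequency, discarding the encounter-rate weighting that motivates
perceived frequencies in the first place. The package therefore
computes same-type perceptions as complements,
`p_{r|r} = 1 - p_{i|r}`, which is the conditional distribution over
partner types that the interaction process actually generates. The
literal reading remains available via `model_params(literal_perception =
TRUE)` so both interpretations can be compared.

**Changing probabilities above 1.** The success bias ranges up to 2, so
the raw `S = (1 - c) * bias` can exceed 1 (e.g. `c = 0`, `dW = 1` gives
1.462). The deterministic engine uses the raw value — that is what
makes the printed closed forms exact. The stochastic engine clamps each
per-event switch probability to `min(S, 1)` and counts clamping events
in the trajectory's `clamp_count`; agreement between the two engines is
only asserted in clamp-free parameter regions.

**Partner sampling.** The focal cannot be paired with itself, so the
partner is uniform over the remaining `N - 1` individuals. This puts a
factor `N/(N-1)` into the exact one-event expectation
(`expected_step_change()`), which vanishes in the mean-field limit.

**Perception in the simulator.** Perceived frequencies are recomputed
from the current global counts before every realised interaction, not
accumulated from an individual's interaction history, keeping the two
engines comparable state by state.

**Replicate seeding.** `run_replicates()` seeds the generator with the
master seed and draws one `sample.int()` seed per replicate, so an
entire sweep is reproducible from a single integer.

## Numerical choices

* `find_equilibria()` scans `Psi - M` on a uniform grid of 2001 points
  and refines each bracketed sign change by bisection to `tol = 1e-10`.
  `Psi` is smooth with at most a handful of crossings in every scenario
  covered, so this is ample; roots closer than the grid spacing would
  merge (documented limitation, not observed in practice).
* Stability is classified from the drift sign at `p* ± max(10 tol,
  spacing/10)` rather than from derivatives — robust for the
  tangency-free crossings that occur here, and identical in spirit to
  reading flow arrows off the phase line. Fixation is classified by the
  drift sign just below 1.
* A root found at `p = 1` itself is reported as the fixation
  equilibrium, never duplicated as an internal one; `p = 0` is never
  reported (drift there is strictly positive).
* `integrate_drift()` is a fixed-step classical Runge–Kutta scheme with
  states clipped to `[0, 1]` against round-off; the dynamics are
  one-dimensional, smooth and slow (rates of order `1/N`), so step-size
  control would add nothing.
* Degenerate perception (an observer whose total encounter rate is
  exactly zero) raises an error rather than returning a number;
  boundary frequencies with positive interaction probabilities are
  fine.

## The stochastic engine as a study in its own right

The event loop is implemented in C++ (via Rcpp) using R's own RNG, so
`set.seed()` makes runs bit-for-bit reproducible, including the clamp
counter. The replication protocol used in tests and in
`scripts/acceptance.R` — a population of 1000, 10 replicates of 10^6
events, migration and conservatism grids of `baseline_sweep_grid()` —
is the full study design; the `reduced = TRUE` grids (4 values per
swept parameter, 3 replicates of 2×10^5 events) are strict subsets for
desk-scale runs. At the reference point (`m = 0.01`, `delta_c = 0.5`,
`X_ir = 0.5`) the replicate mean lands within three standard errors of
the analytic coexistence value 0.0404; the same bound holds for the
reduced protocol.

What the stochastic engine emulates is exactly the model above — and
nothing more. Real acculturation data feature spatial and network
structure, within-group heterogeneity of orientations, time-varying
migration pressure, population growth and multi-trait cultural
repertoires; none of these are modelled, so agreement between the two
engines validates the implementation, not the model's realism.

## Known limitations

* Exactly two cultural traits, orientations homogeneous within a type
  and frozen to the trait; no evolving or mismatched orientations.
* Well-mixed interactions only; no spatial or network structure.
* Constant `N` and constant immigration of a single type; no bursts,
  no demographic change.
* The equilibrium scan is a grid-plus-bisection procedure, not a
  continuation method: it locates crossings, not tangencies, and does
  not track equilibria across parameter space.
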