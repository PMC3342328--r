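---
title: "A stochastic model of DNA-repair decline in homeostatic tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic model of DNA-repair decline in homeostatic tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueratchet)
```

## The model

`tissueratchet` simulates a population of `N` fast-turnover cells held at
constant size by homeostasis. In every elementary step one cell, chosen
uniformly at random, suffers a DNA damage and resolves it in one of three
ways:

1. **Repair**, with the cell's own repair probability `R`. Nothing changes.
2. **Apoptosis**, with probability `a` given failed repair. The dead cell is
   immediately replaced by the division of a peer — any survivor in the
   well-mixed system, a lattice neighbour in the spatial variants — and the
   daughter inherits the parent's repair rate.
3. **Mutation** otherwise: the damage is fixed permanently and the cell's
   repair probability drops by the fragility increment `delta`.

All cells start at the common rate `r0`, so a cell carrying `i` mutations
repairs with probability `r0 - i*delta`, clamped into `[0, 1]`. Mutations
are irreversible and heritable; undamaged cells can therefore never be
recreated once lost. Time is reported in *sweeps* (`N` steps), so each cell
is damaged once per unit time on average, making trajectories comparable
across system sizes. Division counts are tracked (they equal apoptosis
counts one-for-one), which is the model's implicit accounting of
replicative (Hayflick-type) exhaustion; no division cutoff is enforced, and
stem-cell influx, senescence, cell-cycle structure and replication-induced
damage are deliberately outside the model's scope.

The scientific point of the model is a competition: selection (damaged
cells fail repair more often, die more often, and are replaced by
better-repairing peers) opposes mutation pressure, producing a long-lived
*temporary steady state* in which the population mean repair rate stays
high before collapsing — a Muller's-ratchet-like loss of the least-damaged
class ends the metastable phase.

## Mean-field theory

Writing `n_i` for the number of cells with `i` mutations, the expected
dynamics per step are

```
dn_0/dt = (n_0/N) [ a (1 - Rbar) - (1 - R_0) ]
dn_i/dt = (n_{i-1}/N) (1-a) (1 - R_{i-1}) + (n_i/N) [ a (1 - Rbar) - (1 - R_i) ]
```

with `R_i = r0 - i*delta` and `Rbar` the population mean rate: each class
loses members whenever one of its cells fails to repair (death or
promotion), gains a member whenever any death occurs and the dividing cell
belongs to it (total death rate `a(1 - Rbar)`), and damaged classes also
gain by mutation from below. Stationarity of the undamaged class forces

```
Rbar* = 1 - (1 - r0)/a,
```

which exists as a positive steady state only for `a > 1 - r0`
(`steady_state_mean_repair()` flags the regime). Substituting into the
stationarity condition for class `i` gives the recurrence
`n_i * i*delta = n_{i-1} * (1-a) * (1 - r0 + (i-1)*delta)`
(`occupancy_recurrence()`), whose solution is

```
n_i* = n_0* (1-a)^i C(beta + i - 1, i),    beta = (1 - r0)/delta,
n_0* = N a^beta,
```

a negative-binomial profile over mutation levels; the normalisation
`sum n_i* = N` fixes `n_0*` (`occupancy_distribution()`). The generalised
binomial coefficient is evaluated through log-gamma, so non-integer `beta`
is fully supported. Because the death rate per damage event in the steady
state is `a (1 - Rbar*) = 1 - r0`, the mean cell lifetime is `1/(1 - r0)`
damage events (equivalently sweeps) — notably independent of `a` and
`delta`. The same identity explains the apoptosis-rate invariance: raising
`a` raises `Rbar*` by exactly the amount that keeps the death (and hence
division) rate unchanged, so tissue turnover does not accelerate.

Linearising around the fixed point while holding `Rbar` fixed, a
perturbation of class `i` relaxes at `-i*delta/N` per step
(`perturbation_decay_rate()`). The undamaged class is *marginally* stable:
its fluctuations are not restored, so `n_0` performs a random walk that
eventually hits zero. The first-passage time of that event, `T*`, measured
in sweeps, is the persistence time of the temporary steady state and the
model's proxy for the onset of tissue ageing. After the loss of class 0 the
argument repeats one level up with a smaller, less stable undamaged-proxy
class, so the collapse accelerates.

## Choices made where the design was open

* **State representation.** The well-mixed engine works on the occupancy
  vector `n_i`, not an agent list: a step costs O(occupied levels) and a
  10^7-step run takes well under a second. The law is exactly the same; an
  agent-list mode (`run_agent_lifetimes()`) exists solely for per-cell
  lifetime bookkeeping, which the count vector cannot express. Once the
  ratchet advances past the clamp point the occupied band drifts upward
  indefinitely; the engine tracks the lowest occupied level so that cost
  does not grow with elapsed time.
* **Clamping.** The repair probability is clamped at 0 once
  `r0 - i*delta < 0`; mutation counts keep incrementing past the clamp.
  The theory, by contrast, sums over all levels with unclamped rates —
  mirroring the approximation in the analytic treatment, valid because the
  stationary mass beyond the clamp point is negligible for small `delta`.
  `occupancy_distribution()` reports that mass (`clamp_tail_mass`) so the
  approximation is checkable rather than silent.
* **Replacement sampling.** The dividing cell is uniform over the `N - 1`
  survivors (the dead cell is gone and cannot self-replace). On the
  lattice the divider is uniform over the von Neumann neighbourhood (4
  neighbours in 2D, 6 in 3D, "square lattice" read as simple cubic in 3D)
  with periodic boundaries — the minimal choice that avoids edge artifacts
  in the size-scaling study. Whether 4- or 8-neighbour connectivity or open
  boundaries were intended in the original formulation is not stated
  anywhere; the qualitative linear-in-N scaling is expected to be robust to
  this choice, exact `T*` values are not.
* **Truncation closure of the mean-field vector.** `mean_field_rhs()`
  suppresses the mutation outflow of the top class it is given, so the
  derivatives sum to zero exactly for any state; with the tail truncated at
  relative mass `1e-12` the closure is numerically invisible.
* **Integration.** `integrate_mean_field()` uses classical fixed-step RK4
  (via deSolve) and validates the step size internally by halving it until
  the endpoint moves by less than `1e-6` relative — simple, deterministic,
  and stiff-free at these scales.
* **Randomness.** Every run consumes R's global RNG after `set.seed(seed)`;
  replicate `r` of a study uses `base_seed + r`. Identical configuration
  and seed reproduce trajectories and output tables byte for byte; the CLI
  records the fully resolved configuration and seed alongside every result.
* **Censoring.** Replicates that reach `max_sweeps` without extinction
  enter the `T*` median as lower bounds at the horizon, and a median that
  itself falls on a censored value is flagged as a bound, never reported as
  an estimate. Monotonicity claims across conditions use one-sided Wilcoxon
  rank tests over replicates — first-passage times are heavy-tailed, so no
  normality is assumed.
* **Invalid regime.** For `a < 1 - r0` the formal `Rbar*` is negative; the
  theory functions return the value but flag `valid_regime = FALSE` rather
  than extrapolating, since the analysis says nothing about that regime.

## Measuring the linear relaxation rate

Verifying the `-i*delta/N` relaxation against the integrated equations
requires care: perturbing a single class also perturbs `N` and `Rbar`, and
the feedback through `Rbar` is of the same order as the diagonal rate. The
package's tests therefore use the perturbation pattern
`(+1, 0, -3, +2) * eps` applied at levels `(i, i+1, i+2, i+3)`: because the
per-level rates are linear in the level, this pattern leaves both the cell
count and the mean repair rate exactly unchanged at `t = 0`, isolating the
diagonal decay. The measured log-slope of the class-`i` deviation then
falls within a few percent of `-i*delta/N` for `i = 1, 2, 3`, and the
class-0 deviation shows no comparable decay (marginality).

## Study conditions

The canonical parameter set used throughout documentation and checks is
`N = 5000, r0 = 0.9, delta = 0.05, a = 0.5`, for which
`Rbar* = 0.8`, `beta = 2`, `n_0* = 1250` and the expected lifetime is 10
events. Steady-state averages use 2000 sweeps with a 500-sweep burn-in,
which holds the time-averaged mean repair rate within 1% of `Rbar*` at this
size.

Persistence-time studies use deliberately small, fast-aging systems so that
extinction is observed rather than extrapolated: the monotonicity study
runs `N = 50, r0 = 0.5, delta = 0.25, a = 0.6` (20 replicates, horizon
20000 sweeps) against single-parameter increases of `r0`, `a` and `delta`.
The size-scaling study uses `r0 = 0.8, delta = 0.1, a = 0.49` on
`N = 64, 144, 256` — chosen once so that, at desk scale, both regimes are
visible within the horizon: the well-mixed median `T*` grows steeply
(log-log slope near 4, the "drastic" cooperative regime, 20 replicates),
while the periodic 2D lattice grows close to linearly (slope near 0.9; 400
replicates, since the median of heavy-tailed first-passage samples is
noisy and the lattice runs are three orders of magnitude cheaper than the
largest well-mixed ones). The complete-graph lattice mode reproduces
well-mixed statistics on the same per-site representation and serves as the
cross-engine equivalence check.

## What the generator does and does not emulate

All data are generated by the model itself; there is no external input. The
simulations realise exactly the three-outcome damage law above, so passing
checks demonstrate internal consistency of engine and theory and the
reproducibility of the claimed phenomenology — the plateau, its level, the
occupancy profile, the lifetime and apoptosis-rate invariances, and the
topology-dependent scaling of `T*`. They do not validate the model against
biological tissue: real tissues have stem-cell influx, senescent arrest,
replication-coupled damage, non-uniform damage rates and selection on
functions other than repair, all outside this model's scope.

## Known limitations

* No analytic prediction of `T*` is attempted; the fluctuation argument
  motivates it, but `T*` is measured by simulation only.
* The linear-stability result is the stated first-order diagonal rate; the
  full spectrum including the `Rbar` coupling is not derived.
* Exact plotted magnitudes of the original figures are not reproduced —
  the underlying parameter values are not machine-readable — so the
  experiments verify directions, invariances, scalings and
  theory-simulation agreement instead.
* At small `N` the plateau mean sits slightly below `Rbar*` (finite-size
  bias of order 1% at `N = 64`); comparisons at that scale use matched
  protocols rather than the asymptotic value.
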