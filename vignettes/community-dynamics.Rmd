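---
title: "Community dynamics of a social microbe: model, bifurcation analysis and games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community dynamics of a social microbe: model, bifurcation analysis and games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmgame)
```

## The model

Communities of social microbes — *Bacillus subtilis* biofilms,
*Dictyostelium* aggregates, myxobacterial fruiting bodies — maintain
coexisting phenotypes: a resistant reserve (spores and spore-like cells), a
producer subpopulation that pays the cost of public goods such as biofilm
matrix, and motile cells capable of chemotaxis. `biofilmgame` analyses a
deliberately minimal description of such a community with three
subpopulations R (resistant), P (producer) and M (motile):

$$
\frac{dR}{dt} = k_1 N R - k_4 R - k_2 R P, \qquad
\frac{dP}{dt} = -k_3 P + k_5 M, \qquad
\frac{dM}{dt} = k_4 R - k_5 M .
$$

Cells differentiate along R → M → P. The resistant reserve proliferates
autocatalytically on a constant nutrient supply $N$ (its restricted
metabolism is assumed never nutrient-limited inside the community), and the
bilinear coupling $k_2 R P$ expresses that resistance is costly in
proportion to how much the community invests in public goods — the model's
carrier of bet hedging.

### Parameters

All rate constants are first-order, in h$^{-1}$; defaults follow the
reference parameterization of the underlying oscillator:

| parameter | meaning | default |
|---|---|---|
| `k1` | proliferation of R per unit nutrient | 1 |
| `k2` | cost of resistance (R·P coupling) | 1 |
| `k3` | cost of public-goods production (P decay) | 1 |
| `k4` | R → M transition | 1 |
| `k5` | M → P maturation | 1 |
| `N`  | nutrient level (dimensionless) | 4 |

`k3` is the biologically interesting dial: it stands in for antibiotic
stress, which makes the producer phenotype costly. The packaged analyses
treat everything else as fixed unless the user says otherwise.

## Steady states, stability and the Hopf point

The model is simple enough that its fixed-point structure is fully
closed-form, and the package derives rather than approximates it. Besides
the origin, a positive steady state exists whenever $k_1 N > k_4$:

$$
P^* = \frac{k_1 N - k_4}{k_2}, \qquad
R^* = \frac{k_3 P^*}{k_4}, \qquad
M^* = \frac{k_4 R^*}{k_5},
$$

giving the steady resistant fraction $R^*/(R^*+P^*) = k_3/(k_3+k_4)$. The
characteristic polynomial of the Jacobian there is
$\lambda^3 + a_1 \lambda^2 + a_2 \lambda + a_3$ with

$$
a_1 = k_3 + k_5, \qquad a_2 = k_3 k_5, \qquad a_3 = k_3 k_5 (k_1 N - k_4).
$$

`characteristic_coefficients()` computes the coefficients from the Jacobian
itself (trace, principal minors, determinant); the closed forms above serve
as an independent oracle in the test-suite, which checks the identity on
100 random parameter sets. By the Routh–Hurwitz criterion the positive
state is stable iff $a_1 a_2 > a_3$; equality is the Hopf condition, and
solving it for the public-goods cost gives

$$
k_3^{c} = k_1 N - k_4 - k_5 ,
$$

which is `hopf_k3_critical()`. At the defaults $k_3^c = 2$. The condition
is independent of $k_2$: the cost of resistance moves the steady state but
not the bifurcation. A property test verifies this over random $k_2$, and
`hopf_k3_numeric()` provides the second, closed-form-free route (bisection
on the real part of the complex eigenvalue pair). One caveat worth
recording: qualitative descriptions of the damped regime sometimes key it
to $2 k_2 < k_3$, suggesting a $k_2$-dependent boundary; the linearization
yields none, and the package reports the $k_2$-free condition while
exposing the classifier thresholds so users can probe the transition region
themselves. We do not attempt to resolve that discrepancy.

```{r}
stability_report(model_parameters())
```

Eigenvalues with $|\mathrm{Re}\,\lambda| < 10^{-9}$ are classified as
`nonhyperbolic` rather than forced into a stable/unstable call; exactly at
$k_3 = k_3^c$ this is the honest label.

## Simulation and the log chart

`simulate_model()` integrates with lsoda (adaptive, automatically switching
between stiff and non-stiff methods; compiled right-hand side), reporting
on a fixed grid — by default the reference time course of 25 h in 1000
steps of 0.025 h. Tolerances default to `rtol = 1e-8`, `atol = 1e-10`,
tight because two regimes are numerically demanding: very large `k3`
(stiff) and very small `k3`.

The small-`k3` spike regime is the delicate one. Between spikes the
resistant population collapses to values of order $10^{-35}$ while obeying
$d(\log R)/dt = k_1 N - k_4 - k_2 P$, a perfectly smooth equation. In the
linear chart the integrator's step control underflows and the trajectory is
destroyed; the package therefore integrates in the chart
$(\log R,\, P,\, M)$ whenever the initial $R$ is positive, and in the
linear chart on the invariant face $R = 0$ (where the residual (P, M)
system is linear). Positivity of $R$ is then structural; tiny negative
excursions of $P$ or $M$ within the absolute tolerance are clamped to zero.
Initial conditions are not part of the model specification; the default
$(1,1,1)$ is arbitrary, and every regime claim in the tests is re-checked
from five random positive starts drawn log-uniformly from $[0.25, 4]$.

The ratio series $R/(R+P)$ is the observable of interest throughout. Where
$R + P < 10^{-12}$ the ratio is reported as `NA` (undefined), never as 0.

## Regime classification

Four qualitative regimes occur as `k3` grows: spike-like oscillations
(bet-hedging bursts of R on a producer-dominated background), near-sinusoidal
cycling, damped oscillations into the steady state, and monotonic
relaxation. `classify_regime()` reduces a trajectory to one label using the
post-transient ratio series (the first half of the horizon is discarded;
damped cases near the bifurcation decay slowly, so the window is generous):

* envelope gap ≤ `osc_tol` (default $10^{-3}$): non-oscillatory at this
  horizon; the label is `damped_to_steady` if the full series has at least
  one overshoot peak more than `osc_tol` above the final value, else
  `monotonic_relaxation`;
* otherwise oscillatory: with ≥ 2 post-transient peaks, a last-to-first
  peak-amplitude ratio below `damped_ratio` (default 0.9) means the
  envelope is still contracting (damped). Spike trains with periods of
  ~55 h can leave a single peak in the window, so with < 2 peaks the peak
  comparison is retried over the last 75 % of the horizon before falling
  back to a quarter-by-quarter contraction check;
* sustained oscillations split by duty cycle — the fraction of
  post-transient time spent above the envelope midline — with spikes below
  `duty_spike` (default 0.25). The spike/sinusoid distinction is visual in
  origin, so these thresholds are exposed in `regime_control()` rather than
  buried.

At the defaults the reference points `k3 = 0.1, 1, 10, 1000` classify as
spike, sinusoidal, damped and monotonic respectively, from the default
start and from random positive starts. Classification runs use a 200 h
horizon.

## Bifurcation scan

`bifurcation_scan()` sweeps `k3`, simulates past the transient and records
the envelope (max/min) of the ratio series — the numeric counterpart of the
analytic Hopf point. The scan default horizon is 800 h: just above the
bifurcation the envelope decays at the slow rate of the eigenvalue pair
(about $e^{-0.018 t}$ at $k_3 = 2.2$), and a shorter horizon would leave
decayed-but-not-converged envelopes that masquerade as oscillation. With
800 h the gap at $k_3 = 2.2$ is ~$3 \times 10^{-4}$ and the steady arm
matches $k_3/(k_3+1)$ to better than $10^{-3}$ on the 0.2–3 grid of step
0.1. The scan's `hopf_estimate` (first grid point whose gap falls below
`gap_tol`) approaches the analytic value from above as the horizon grows;
the property test that demands agreement within one grid step scales its
horizon to each parameter family's own decay rate for that reason.

## The game-theoretic companion

Two complementary games describe the same biology.

**Three strategies.** R resists what kills P, P outgrows M, M escapes what
starves R: cyclic dominance, i.e. a rock–paper–scissors game. `payoff_rps()`
encodes the ±1 win/loss matrix (zero-sum). `pure_nash()` confirms by
exhaustive deviation checking that no pure equilibrium exists, and
`mixed_nash()` finds the unique mixed equilibrium, uniform at 1/3 — computed
by support enumeration and cross-checked against the minimax linear
programme (`minimax_lp()`, simplex method), two genuinely independent
routes.

**Two strategies, three stress levels.** A nascent cell (row player) meets
the mature community (column player), each resistant or producer. The
moderate-stress payoffs are the base table; absence of stress adds one
point to every payoff earned while playing P, high stress subtracts one.
`payoff_two_strategy()` builds all three. The equilibrium structure tracks
stress: none in pure strategies at moderate stress (cyclic switching, the
two-strategy echo of the oscillatory regime), a *weak* (P, P) equilibrium
without stress — weak because the nascent cell's R-deviation ties, which is
exactly why occasional resistance spikes are unsurprising — and a strict
(R, R) equilibrium under high stress. Weak equilibria are therefore
reported and flagged, never dropped. The no-stress game is degenerate (the
tie produces a continuum of mixed equilibria $x = (p, 1-p)$ against mature
P for $p \in [0.4, 1]$); `mixed_nash()` flags degeneracy via the standard
criterion — an equilibrium strategy with more pure best responses than its
support size — and returns endpoint representatives.

**Replicator dynamics.** `replicator_dynamics()` integrates the standard
single-population replicator equation
$\dot x_i = x_i((Ax)_i - x^\top A x)$ for symmetric games. This is an
extension beyond the payoff-table analysis, implementing the classical ODE
treatment of the cyclic game: interior orbits of the zero-sum
rock–paper–scissors matrix are closed, and the tests verify the two
invariants that characterize them (simplex sum conserved to $10^{-8}$;
$x_1 x_2 x_3$ constant to $10^{-6}$ over 100 time units).

Support enumeration covers support pairs of all sizes (not only equal
sizes) so that degenerate continua are met rather than skipped; candidate
systems are solved by SVD least squares, candidates verified by a
no-profitable-deviation check at $10^{-7}$, and duplicates merged at
$10^{-7}$. Games are limited to four strategies per player — enumeration is
exponential, and nothing in this setting needs more.

## Synthetic fixtures: what they do and do not show

`generate_fixtures()` produces the deterministic test families: the four
regime-defining parameter sets (`k3` ∈ {0.1, 1, 10, 1000}, with jittered
variants) and random 2×2 / 3×3 bimatrices, half zero-sum, used by the
Nash-oracle property tests. These fixtures emulate the *model's* study
conditions, not data: the model has no measurement noise, no demographic
stochasticity, no spatial structure, and its rate constants are order-one
abstractions rather than organism-specific estimates. Passing tests
therefore certify the mathematics — fixed points, bifurcation, equilibria,
invariants — and say nothing about whether a particular biofilm follows
this dynamics; spike periods, for instance, are not calibrated to any
organism.

## Numerical choices, degenerate inputs, limitations

* Negative or non-finite populations are rejected, not clipped: the model
  is only meaningful on the non-negative orthant.
* A parameter set with $k_1 N \le k_4$ has only the origin; analyses that
  need the positive state fail with a clear error. $k_1 N \le k_4 + k_5$
  yields "no Hopf point" (`NA`), not an exception.
* Single-point scan grids return envelopes but no Hopf estimate.
* Trajectories shorter than twice the transient window are refused by the
  classifier.
* The classifier is horizon-relative: a damped case whose decay time
  exceeds the horizon is honestly labelled as oscillatory *at that
  horizon*. Lengthen `t_end` to resolve slow decays.
* Problem sizes used by the packaged analyses: 200 h classification runs,
  800 h scan horizons on 29-point grids, 100-parameter-set and 200-game
  property families. These are the package's reference settings; all are
  arguments, not constants.
* Out of scope by design: spatial (PDE) and agent-based descriptions,
  organism-specific parameter fitting, and any claim about absolute
  population sizes — only the composition ratio $R/(R+P)$ is interpreted.
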