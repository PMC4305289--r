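---
title: "Computation by instability: the dynamics of asymmetric winner-take-all networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computation by instability: the dynamics of asymmetric winner-take-all networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtadyn)
```

## The model

`wtadyn` simulates and analyses soft winner-take-all (sWTA) circuits of
linear threshold neurons (LTNs): rate units with activation
$f(u) = \max(u, 0)$, bounded below but unbounded above. A circuit of $N$
units obeys

$$\tau \dot{x} = f(W x + I(t)) - G x,$$

where $W$ is the (asymmetric) weight matrix with the convention
$W_{ij}$ = weight of the connection $j \to i$, $G$ is the diagonal matrix
of leak conductances, and $I(t)$ the external input (excitatory units
only). The canonical motif built by `build_wta(n_exc)` has `n_exc`
excitatory units, each with self-excitation $\alpha_1$, optional chain
excitation $\alpha_2$ to its neighbours, and a single shared inhibitory
unit: each excitatory unit drives it with $\beta_2$ and receives
$-\beta_1$ back. Because excitation and inhibition are carried by distinct
cell types, $W$ is inherently asymmetric; the asymmetry is not a nuisance
but the mechanism — it supplies the rotational component of the dynamics
that keeps the high-gain positive feedback bounded.

After the competition settles, the winner expresses an amplified copy of
its input: with unit leaks $x_w = g I_w$ with gain
$g = 1/(1 - \alpha_1 + \beta_1\beta_2)$ (`wta_gain()`); with general leaks
the fixed point is $x_w = I_w / (G_\mathrm{exc} - \alpha_1 +
\beta_1\beta_2 / G_\mathrm{inh})$ (`steady_state_winner()`), the oracle
against which the integrator is tested (relative error $< 10^{-6}$).

## Permitted and forbidden subspaces

Only units whose rectifier argument $(Wx + I)_i$ is positive contribute to
the dynamics. Writing $\Sigma$ for the diagonal 0/1 matrix of this *active
set*, the effective Jacobian is $J = \Sigma W - G$
(`effective_jacobian()`). Each activation pattern therefore defines a
linear regime — a *subspace* — and the piecewise-linear flow is analysed
per subspace:

* **permitted** — all eigenvalue real parts of $J$ negative: contracting
  in the metric given by the inverse eigenvector matrix ($\Theta =
  Q^{-1}$, `contraction_metric()`); under constant input the state never
  leaves. These are the candidate solutions.
* **forbidden** — maximal eigenvalue real part positive (expanding) while
  the trace is negative. The top eigenvector is *mixed* (has strictly
  positive and strictly negative entries, `mixed_eigenvector_check()`), so
  some unit is driven below threshold exponentially fast and the active
  set must change.
* **neither** — eigenvalues inside the tolerance band (default
  `tol = 1e-9`); surfaced explicitly, never silently binned. For weight
  matrices built by the package's builders with parameters inside the
  bounds, this class is empty except in degenerate cases (see the gain
  sweep note below).
* **off** — the empty active set; pure leak decay, trivially stable.

The trace of $J$ is the Gaussian divergence: the exponential rate at which
state-space volume contracts. Under constant input every transition
strictly decreases it, which orders the subspaces into a hierarchy the
computation descends — `enumerate_subspaces()` ranks them by divergence,
descending. Two conventions required a decision:

* *Subspace identity.* For the chain motif the pattern is taken over the
  excitatory units only ($2^k$ sets), with inhibitory co-activity derived
  (active iff a connected excitatory unit is active); `mode = "full"`
  enumerates over all units, appropriate for grid networks with many
  inhibitory units.
* *Index of the off state.* Divergence of the empty set is 0 by
  convention, which plain descending order would rank first; the package
  places it last, after the most contracting single-winner sets, so the
  enumeration runs from the all-on set down the hierarchy and ends at the
  off state.

Parameter validity is the pair of bounds $1 < \alpha_1 <
2\sqrt{\beta_1\beta_2}$ and $\tfrac14 < \beta_1\beta_2 < 1$
(`validate_params()`). The upper bound on $\alpha_1$ is a rotation-speed
condition (`rotation_stability()`): the inhibitory loop must rotate the
flow fast enough to stabilise the positive diagonal. The reference
parameter set used throughout — $\alpha_1 = 1.2$, $\beta_1 = 3$,
$\beta_2 = 0.25$, $G_\mathrm{exc} = 1.1$, $G_\mathrm{inh} = 1.5$, $\tau =
1$ — sits comfortably inside both bounds and is the package default.

## Gradient and rotation

Within a subspace the flow is $\dot x = M x + u$ with $M$ the effective
system matrix. `helmholtz_split()` separates $M = M_1 + M_2$: the diagonal
$M_1$ (self-excitation minus leak) carries all of the divergence — the
gradient component — while the zero-trace remainder $M_2$ (the
excitatory–inhibitory loops) steers. $M_2$ is not skew-symmetric as
written since $\beta_2 \neq \beta_1$, but rescaling each inhibitory
coordinate by $\sqrt{\beta_1/\beta_2}$ (the diagonal transform $\Phi$)
makes it so, with off-diagonal magnitudes $\sqrt{\beta_1\beta_2}$; being
diagonal, $\Phi$ commutes with $M_1$ and preserves every eigenvalue. The
transform exists only for uniform loop weights and no off-diagonal
excitatory–excitatory coupling; otherwise `valid = FALSE` is returned with
the residual asymmetry norm, rather than a silently wrong $\Phi$.

The role of rotation is distilled in the 2×2 example
$M = \begin{pmatrix} 1 & a \\ -a & -2 \end{pmatrix}$ (`example_2x2()`):
its divergence is $-1$ for every rotation weight $a$, yet it is linearly
stable only when $a^2 > 2$ — volume contraction alone does not imply
stability; the rotation must be fast enough. `stability_sweep_2x2()`
verifies the threshold by brute-force eigenvalue sweep.

## Simulation protocols

`simulate_network()` integrates the dynamics by the forward Euler scheme
with `dt = 0.01` and $\tau = 1$, so one time constant spans exactly 100
steps. Inputs are zero until `onset_step` (default 2000) and constant
afterwards, drawn i.i.d. $N(\mu, \sigma)$ per excitatory unit (defaults
$\mu = 6$, $\sigma = 1$; the entropy experiments use $\sigma = 0.25$).
Optional input noise $N(0, \sigma_\mathrm{noise})$ is added to the
excitatory inputs from onset onward and redrawn every $\tau$ — redrawing
every step would make the noise magnitude depend on the integration step.
State-conditional rules add an increment to a target unit's input while
the network occupies a trigger pattern, which is how computations are
steered by their own intermediate states. The integrator core is compiled
(Rcpp) because the ensemble protocols integrate $10^7$ Euler steps per
experiment; it draws from the R RNG, so every run is reproducible under
`set.seed()`.

Numerical choices worth stating:

* The active set is decided by the sign of the rectifier argument
  $(Wx + I)_i$ — the same quantity whose sign gates $\Sigma$ in the
  Jacobian — not by the state ($x_i$ decays only asymptotically to zero,
  so a state threshold would need an arbitrary cutoff and would lag the
  dynamics; `active_pattern(use_state = TRUE)` provides it for
  comparison).
* Transitions are logged at the first step the pattern differs, with no
  debouncing: under noise, brief excursions are genuine transitions and
  belong in the statistics.
* Initial states: zero for single demonstration runs, i.i.d. $U[0,1)$ per
  unit for ensembles. The onset entropy is zero either way, because the
  all-on set is entered regardless of initial conditions.
* Halving `dt` moves the converged state by less than $10^{-4}$
  relative; quiescence and the closed-form winner state are fixed points
  of the discrete map to $10^{-12}$ per step.
* *Grazing crossings.* When a unit's rectifier argument approaches zero
  tangentially, the forward Euler scheme at `dt = 0.01` can detect the
  crossing up to a time constant early and then reverse it, logging a
  spurious up/down bounce pair (about 0.5% of no-noise transitions).
  Refining `dt` to 0.002 removes these events, so the strict model
  invariants — divergence descent, irreversible deactivation, absorbing
  permitted subspaces — are tested at the refined step, while all recorded
  protocols and statistics keep `dt = 0.01`. No debouncing is applied
  anywhere: under noise, brief excursions are genuine transitions.

## Ensembles, entropy, and steering

`run_ensemble()` repeats the simulation with fresh inputs, initial states
and noise (child seeds drawn once from the master seed, so any single run
is reproducible in isolation), and pools: the occupancy distribution
$p_i(t)$ over subspaces every $\tau$, its Shannon entropy $H(t) = -\sum_i
p_i \log_2 p_i$ (with $0\log_2 0 = 0$), the transition log with source and
destination divergences, the transition graph, and each run's first entry
into a permitted subspace. With the reference network and inputs
$N(6, 0.25)$, $H$ is exactly 0 at onset (all runs in the all-on set),
rises to a peak near 3.8 bits while runs spread over the forbidden
hierarchy, then falls to the 2-bit plateau of four equiprobable winners.
Raising the gain ($\alpha_1 \in \{1.15, 1.2, 1.3\}$, `gain_sweep()`)
shifts the whole excursion earlier without changing the plateau; adding
steering connections ($\alpha_2 = 0.2$ from unit 1 to 2 plus $0.2$ from 4
to 2) biases the competition toward unit 2 and lowers both peak and
plateau. The sweep starts at 1.15 rather than 1.1 because with
$G_\mathrm{exc} = 1.1$ a self-weight of 1.1 exactly cancels the leak:
multi-active subspaces become marginally stable (maximal eigenvalue 0,
class "neither") and escape only algebraically, so there is no meaningful
asymptote to compare.

**Against-gradient transitions.** Under constant input the divergence
hierarchy is strict; only input changes can push the network to a subspace
with larger divergence. With noise $N(0, 1)$ redrawn every $\tau$,
`against_gradient_fraction()` measures the share of such transitions. Its
default window is each run's *computation*: the transitions from input
onset up to and including the first entry into a permitted subspace. The
window matters: after convergence, noise keeps producing paired up/down
excursions at a constant rate, so a fraction pooled over the whole run
grows with the simulation budget toward one half and is a property of the
run length, not of the network. The windowed fraction is
duration-independent and comes out near 28% under the reference
conditions (1000 runs); `window = "all"` exposes the whole-run pooling for
comparison (about 39% at 10 000 steps).

## Random grid assemblies

`build_random_grid()` scatters the two motifs over a square grid: each
spot holds a neuron with probability 0.4, excitatory with probability 0.8;
every excitatory unit excites itself and is wired into up to 8 reciprocal
loops with uniformly chosen inhibitory units, each candidate kept with
probability 0.4 (so a unit is isolated with probability $0.6^8 \approx
1.7\%$ when a full candidate pool exists). Two deliberate choices:

* **Loop-gain normalization.** Giving every realized loop the full
  per-loop weights would hand a unit with $k$ partners an aggregate loop
  gain $k\,\beta_1\beta_2 \approx 2.4$ on average — far outside the
  $(\tfrac14, 1)$ bound the per-neuron analysis requires — and the
  resulting over-inhibition makes *larger* grids settle *faster*,
  inverting the size scaling. The builder therefore divides the received
  inhibitory weight by the unit's number of realized loops
  (`normalize_inhibition = TRUE`), keeping every unit's aggregate loop
  gain at $\beta_1\beta_2 = 0.75$ regardless of how many partners it
  drew. The flag can be disabled to study the raw scheme.
* **Bounded population.** An isolated self-exciting unit keeps a positive
  eigenvalue in every active set containing it, so a grid containing one
  can never reach a permitted subspace. `time_to_permitted_vs_size()`
  therefore redraws grids (deterministically) until no excitatory unit is
  isolated — the population for which convergence is guaranteed — and
  uses a generous censoring budget of 120 $\tau$ so that slow large-grid
  runs are measured rather than censored (a short budget censors
  selectively at large sizes and biases their means down). Censored runs
  are counted and reported, never dropped.

With sides 4–10 at 100 runs each, the mean time from onset to the first
permitted subspace grows from roughly 1 000 to about 2 000 steps,
saturating between sides 8 and 10 at these scaled-down sizes: grid
occupancy couples the number of inhibitory units to the grid area, so
larger grids also carry denser shared inhibition, which accelerates the
competition and partly offsets the deeper forbidden hierarchy.

## What the generator does and does not emulate

The synthetic protocols reproduce the study conditions exactly as stated —
parameter values, input distributions, noise schedule, onset timing,
ensemble sizes — and all quantitative claims in this vignette are
recomputed by the test suite or the acceptance script at those sizes.
They do not emulate biological realism beyond the model class: no
transmission delays, no saturation, no plasticity, no spatially structured
connectivity, and inputs are piecewise-constant rather than naturalistic.
Passing tests therefore certify the dynamical-systems claims about the
model, not predictions for any particular biological circuit.

## Known limitations

* Subspace enumeration is exponential in the number of pattern bits and
  capped (default 20); grid networks are analysed through sampled
  trajectories and per-pattern classification instead.
* The permitted test uses the diagonalizing metric; no search over general
  contraction metrics is attempted, so a "neither" verdict does not prove
  the absence of some other certifying metric.
* For user-supplied weight matrices outside the builder families the
  permitted/forbidden dichotomy need not be exhaustive; "neither"
  outcomes are reported as such.
* The Euler scheme locates threshold crossings only to within one step;
  `dt = 0.01` makes the residual effect smaller than the tolerances used
  in the tests, but event-exact integration is out of scope.
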