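---
title: "Loop models of Mal de Debarquement Syndrome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop models of Mal de Debarquement Syndrome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddsloops)
```

This vignette documents the models behind `mddsloops`, the assumptions
they commit to, the parameters that matter, and the numerical and design
choices made where more than one construction was defensible. The
hypothesis chain it implements: passive wave motion entrains an internal
oscillator spanning the vestibular nuclei (VN) and the flocculonodular
cerebellum (Purkinje cells, PJ); that oscillator is the internal model
that cancels the disturbance aboard; synaptic long-term potentiation
(LTP), promoted by CGRP, strengthens the loop until the oscillator no
longer dies away after disembarkation, leaving a phantom sensation of
self-motion (MdDS).

## 1. The random-Jacobian ensemble

The circuit has four nodes (`PJ_A`, `VN_A`, `VN_B`, `PJ_B`; A/B are the
two brainstem sides) wired as two ipsilateral negative loops, a
commissural double-negative loop between the VN, and two extra
contralateral inhibitory edges, plus self-inhibition on every node
(`canonical_structure()`). Interaction strengths are not known
quantitatively, so the analysis is distributional: each non-zero Jacobian
entry is `sign * u * w` with `u ~ U[0, 1]` drawn independently per entry
and `w` one of three class weights (`w_self`, `w_exc`, `w_inh`, arbitrary
units). A matrix counts as *oscillatory* when some eigenvalue has real
part above and imaginary part magnitude above `1e-9` relative to the
matrix scale — the spectral condition for growing oscillations of
`dx/dt = J x`. `oscillation_probability()` estimates the ensemble
fraction with its binomial standard error; `sweep_oscillation()` grids
it over weights, with a per-point RNG stream derived from one master
seed (`derive_seed()`, a two-round Lehmer map) so any single point can
be recomputed alone.

Choices worth stating:

* **Distribution.** Only the range of the random factor is physically
  motivated; uniform on `[0, 1]` is the minimal commitment. Entries are
  independent. The diagonal is sampled like any other entry by default
  (`random_diagonal = FALSE` fixes it at `-w_self` instead); sampling it
  preserves the interpretation of `w_self` as a scale, not a value.
* **Monte-Carlo sizes.** 100,000 matrices per point (SE ≤ 0.0016)
  reproduce the reference curves; the test-suite and the acceptance
  script use 10,000 per point with a weight step of 5, which keeps every
  regime comparison above 3 combined standard errors while running in
  seconds. The compiled core (`RcppArmadillo`) classifies roughly a
  million 4×4 spectra per second, using R's RNG so `set.seed()`
  semantics hold.
* **Tolerances.** The strict inequalities use `1e-9` relative to
  `max(1, max|J|)`; on 4×4 problems this separates genuine spectra from
  rounding noise, and the measure of the ensemble within the band is
  negligible.

### The time-domain cross-check

Because the oscillation probability is the package's central statistic,
it is verified by a second, algorithmically independent route
(`classify_time_domain()`): integrate the state-transition matrix of
`dx/dt = J x` (exact 4th-order one-step propagator over short intervals)
and re-orthonormalise by a hand-written Gram–Schmidt QR after every
interval — the discrete-QR method. The running means of `log|R_ii|`
converge to the sorted real parts of all four eigenvalues, so growth is
mode-resolved; this matters because a substantial share of oscillatory
draws in this ensemble also carry a *larger* real unstable eigenvalue,
which defeats any single-trajectory test. Complex pairs are recognised
by two complementary signatures: anti-correlated oscillation of
adjacent `log|R_ii|` columns (variance cancellation over a contiguous
block with persistent zero crossings), and, for normal blocks whose
`log|R_ii|` is exactly flat, steady rotation of the Q-frame
(`|<q_i(k), q_i(k-1)>|` persistently below 1 at a non-decaying angle —
a decaying angle indicates a slow real-mode exchange and is rejected).
Decisions whose growth estimate falls within the finite-window
resolution of the stability boundary are re-run with a window four
times longer, up to three times. The classifier reports that resolution;
disagreements with the eigenvalue route are expected only for spectra
closer to the boundary than it, which is the property the tests assert
alongside ≥ 99% agreement.

## 2. The firing-rate realisation

The spectral analysis speaks about linearisations, so the package
carries a concrete nonlinear system with the right linearisation:
`dx_i/dt = -d_i x_i + sum_j W_ij tanh(s x_j) + u_i(t)`
(`rate_network()`). tanh is the standard saturating rate nonlinearity;
it makes the origin an equilibrium with Jacobian `-D + s W` (exactly the
canonical sign pattern) and bounds every state by
`(sum_j |W_ij| + max|u|)/min d_i`. `W` comes from a weight scheme either
deterministically (`sign * w`, the "midscale" option) or as one frozen
random sample. Entrainment (`entrain()`) drives the two VN nodes in
antiphase with a sinusoid — side-to-side vestibular stimulation — and
summarises the driven and released dynamics with periodogram-based
descriptors (`detect_oscillation()`: interpolated periodogram peak,
log-linear envelope fit on peak magnitudes, and a damping label with a
`1e-3`-per-cycle dead band around "sustained").

Two honest caveats. First, the time-domain results are verification
devices for the spectral claims, not independent physiological claims;
the nonlinearity was chosen for convenience, and nothing here commits to
tanh being the right saturations of real VN/PJ populations. Second,
linear classification predicts the *local* behaviour: when a strongly
unstable real mode coexists with an unstable complex pair, the saturated
attractor may be a fixed point rather than a limit cycle (and vice
versa). With the deterministic midscale realisation, agreement between
the spectral category and the saturated nonlinear behaviour is above
95% over the tested weight range; with random realisations it is a few
points lower. The tests use an adaptive simulation horizon because
weakly unstable modes (growth rates of order 0.01/s) need several
hundred seconds to saturate.

## 3. Posture and the internal model

The stance model is the minimal system consistent with the loop account:
a unit-inertia linearised inverted pendulum,
`theta'' = omega_u^2 theta + u_C + u_A + d(t)`, with

* `omega_u = sqrt(9.81)` 1/s — gravity over a 1 m effective pendulum;
* the stabilising reflex `u_C = -Kp theta - Kd theta'` (defaults
  `Kp = 20` s^-2, `Kd = 8` s^-1; any `Kp > omega_u^2`, `Kd > 0`
  stabilises the pendulum alone);
* an adaptation loop: a second-order resonant compensator
  `z'' + 2 rho omega_c z' + omega_c^2 z = k_a e`, error `e = -theta`,
  output `u_A = z'`, with centre frequency `omega_c` (rad/s), damping
  `rho >= 0` and gain `k_a = 2`. Closed-loop stability is checked at
  construction from the quartic characteristic polynomial.

With `rho = 0` and `omega_c` equal to the disturbance frequency, the
closed loop has a transmission zero at that frequency: the disturbance
is cancelled exactly (the Internal Model Principle), `u_A` converges to
`-d` (phase opposition), and the posture residual collapses relative to
the PD-only response. All of this is checked against the closed-form
transfer function `theta/d = N_c / (P_c N_c + k_a s)`
(`frequency_response()`), which also exhibits the notch at `omega_c`
whose depth diverges as `rho` goes to 0.

**The two phases.** Aboard, the full closed loop runs, forced by the
disturbance. Ashore, both the disturbance and the entraining error
drive are gone, and the compensator rings *freely* from its exit state,
feeding `u_A` one-way into the stabilising loop. This one-way reading
is a deliberate design decision, for two reasons: it identifies the
post-disembarkation regime purely with the oscillator's own damping
(`tau = 1/(rho omega_c)` exactly; `rho = 0` gives a permanent oscillator
at the entrained frequency — the MdDS state), whereas the error-coupled
closed loop is asymptotically stable for any `k_a > 0` and could never
sustain the phantom oscillation; and it matches the interpretation of
the ashore phase as an autonomous, over-learned internal model no longer
tracking anything. `phantom_motion_signal()` returns that `u_A` — the
perceived self-motion proxy. The posture response it induces has the
same magnitude as the pre-adaptation aboard response (both pass
`amplitude × |PD gain|`), so "the stabilising loop prevails" here means
bounded, aboard-scale sway, not strictly smaller sway.

**Disturbances.** `disturbance_spec()` distinguishes a pure sinusoid
(regular sea waves; default 0.25 Hz, inside the 0.2–0.3 Hz band of sea
travel, amplitude 0.05 in the pendulum's normalised acceleration units),
a sinusoid plus Gaussian noise, and dominance-free broadband noise
(AR(1)-filtered Gaussian, road travel). The generator enforces spectral
contracts — at least 99% of periodogram power within one bin of the
nominal frequency for the pure tone (measured after trimming to an
integer number of cycles, otherwise leakage makes the contract
meaningless), at most 20% for broadband. What it does *not* emulate:
multi-axis motion, amplitude modulation of real swell, or sensory noise;
passing tests show disturbance rejection for the signal class the
internal model represents, not robustness to realistic sea states.
Compensator frequency adaptation is likewise out of scope: `omega_c` is
set to the drive frequency, i.e. the entrained state is assumed
accomplished.

**Numerics.** `deSolve::lsoda` with tolerances `1e-9` (network: `1e-8`
relative / `1e-10` absolute); outputs on a fixed 0.05 s grid; envelope
fitting by log-linear regression on peak magnitudes, discarding peaks
below 1% of the maximum because the finite-window DC offset of a
decaying record pollutes `|x|` far down the decay. Ringing frequency
from mean upward-zero-crossing spacing (periodogram fallback), which
resolves the 1%-of-0.25 Hz comparisons that a 400 s periodogram bin
alone would not.

## 4. The LTP switch

`dL/dt = -delta L + g L^n/(K^n + L^n) + eta B` is the canonical
one-variable positive-feedback switch: decay, sigmoidal self-activation
(Hill exponent `n >= 2`; bistability needs the sigmoid), and additive
BDNF input. CGRP enters only as the multiplicative factor
`g = g0 (1 + c)` — it is reported as an LTP promoter, and no CGRP
dynamics are modelled. Defaults `delta = K = eta = 1`, `n = 4`,
`g0 = 1.2`, `c ∈ {0, 1.5}` were verified before freezing: for
`delta = K = 1, n = 4` the fold condition gives bistability onset at
`g = min_L (1+L^4)^2/(4L^3) ≈ 0.94` and irreversibility onset at
`g = min_L (1+L^4)/L^3 = 4·3^(-3/4) ≈ 1.755`, so `g = 1.2` sits in the
reversible-bistable window (saddle-node inputs `B_off ≈ 0.386 <
B_on ≈ 0.469`) and `g = 3.0` (high CGRP) is irreversible — the high-LTP
state survives `B = 0`.

`ltp_equilibria()` brackets roots on a dense grid and polishes with
`uniroot` (`1e-12`); stability comes from the sign of the derivative.
`bifurcation_scan()` follows branches over a `B` grid and refines the
saddle-nodes by bisection on the stable-equilibrium count; near the
bistable onset the window in `B` shrinks below any fixed grid, so the
scan warns and rescans finer when it barely resolves the window, and
threshold estimates remain resolution-limited from above.
`hysteresis_trace()` performs the quasi-static loop (default step 1% of
the range, relaxation `20/delta` per step); near a saddle-node the
passage is critically slow, which is why jump localisation to within
one step needs a generous relaxation time.

**Coupling to the network.** `ltp_to_weights()` multiplies connection
weights by the saturating gain `m(L) = 1 + lambda L/(L + K_m)`
(`lambda = 6`, `K_m = 1`), carrying the base inhibitory weight 10 to
≈ 55 at the high-LTP state. The default couples *both* the inhibitory
and the excitatory class. This was an empirical decision: the ensemble's
oscillation probability at fixed moderate excitation peaks near
inhibitory weight 20–30 and then declines slowly, so an inhibition-only
coupling is not monotone over the coupled range; along the diagonal
(both classes strengthened together) the probability is strictly
increasing — consistent with the loop analysis, where the tendency to
oscillate is highest when both inhibitory and excitatory connections
are strong. LTP confined to GABAergic fibres remains available
(`couple_excitatory = FALSE`).

## 5. The end-to-end chain

`full_chain()` composes the three modules at a low and a high CGRP
factor: classify the switch, apply a BDNF pulse (default height 1,
above `B_on` in both regimes) and relax back to `B = 0`, map the final
LTP level to weights, estimate the oscillation probability (100,000
matrices), then map the switch regime to the posture compensator's
damping — irreversible → `rho = 0`, reversible bistable → `rho = 0.02`,
monostable → `rho = 0.2` — and simulate disembarkation. The regime→rho
mapping is interpretive glue, not a measured relationship: it encodes
"irreversible plasticity ⇒ permanent oscillator" and nothing more
quantitative, and whether transient MdD versus chronic MdDS corresponds
to small-versus-zero damping or to distinct mechanisms is precisely the
open question the model leaves open. Every stage derives its RNG stream
from the master seed, so the whole report is reproducible bit for bit.

```{r chain, eval = FALSE}
full_chain(seed = 1)
```

## 6. Scope and limitations

* The loop structure is committed to the canonical four-node circuit;
  loop enumeration for arbitrary graphs, Hopf continuation and
  normal-form analysis are out of scope.
* No spiking or conductance-based neurons, delays, or stochastic
  dynamics; no VOR/velocity-storage detail; hormone biology is reduced
  to the scalar CGRP factor.
* The posture model is planar, single-segment, noise-free; the
  adaptation loop acts on the posture error (the standard internal-model
  topology) — whether the physiological loop uses an error signal or a
  sensed disturbance estimate is unknown, and no efference-copy /
  feed-forward path is modelled.
* "Semi-perfect adaptation" is operationalised as the residual at small
  positive `rho`; the package makes no claim about how small real
  compensator damping is.
* Problem sizes in the tests (10,000 matrices per sweep point, 200-case
  property samples, a 500-sample oracle comparison) were chosen to keep
  every statistical comparison at or above the 3-standard-error level;
  they are scaled-down versions of the 100,000-matrix reference
  experiments, not different designs.
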