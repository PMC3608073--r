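---
title: "Designing fluctuating voltage-clamp protocols with waveclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing fluctuating voltage-clamp protocols with waveclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveclamp)
```

## The model

`waveclamp` treats channel gating as a continuous-time Markov chain over
discrete conformational states. Each transition rate depends exponentially on
membrane potential, $\alpha(V) = \alpha(0)\,e^{qV/V_T}$, with $\alpha(0)$ the
rate at 0 mV (ms⁻¹), $q$ the gating charge (units of $e$, negative for
backward steps of activation) and $V_T = kT/e$ the thermal voltage. The
ensemble probability vector obeys the master equation
$\mathrm{d}\mathbf{P}/\mathrm{d}t = \mathbf{W}[V(t)]\,\mathbf{P}$, where the
generator $\mathbf{W}$ has multiplicity-weighted rates off the diagonal and
zero column sums. Whole-cell current follows from Ohm's law,
$i(t) = g_0\, g(V)\,(V - V_r)\,\mathbf{O}\cdot\mathbf{P}(t)$, with $g(V)$ a
degree-5 polynomial capturing the open channel's nonlinear conduction and
$g_0$ an arbitrary scale absorbing channel count and unitary conductance —
currents are therefore in arbitrary units throughout.

The assumptions are the standard ones of discrete-state gating analysis:
Markovian dynamics (no memory within a state), rates depending on the
instantaneous voltage only, an ensemble large enough that occupancies equal
probabilities, and space-clamped, series-resistance-free voltage control.

### The four Shaker schemes

Tetrameric schemes are specified abbreviated — one subunit's linear chain of
conformations plus the subunit count — and expanded by `expand_subunits()`
into composition states (multisets of subunit conformations). A transition
connects compositions differing by one subunit moving one step, with
multiplicity equal to the number of subunits able to make the move; the
expansion is verified in the test suite against an independent brute-force
enumeration of subunit configuration vectors.

* **ZHA A** — two-state subunits; the 5-state chain C1–C4, O with forward
  multiplicities 4, 3, 2, 1. Four free parameters.
* **ZHA D** — three-state subunits (15 composition states) plus a closed
  state Cf reachable only from the open state; 16 states, 12 free parameters,
  plus a cooperativity factor θ.
* **BPS** — an explicit 8-state chain using 5 independent rate pairs in the
  order α₀/β₀, α₁/β₁ (three times), α₂/β₂, α₃/β₃, α₄/β₄; 20 parameters.
* **SS** — four-state subunits (35 composition states), two concerted
  transitions through an intermediate closed state to the open state, and
  three inactivated states reachable only via the open state; 40 states.

Published parameter values ship as a JSON registry
(`inst/extdata/shaker_params.json`) read by `shaker_parameters()`.

### Interpretation choices in the published schemes

Several conventions are not fully pinned down by the published descriptions;
the package makes each one explicit and, where defensible alternatives exist,
configurable:

* **BPS backward charges.** The tabulated δ₀…δ₄ are interpreted as
  positive-magnitude backward gating charges,
  $\beta_i(V) = \beta_i(0)\,e^{-\delta_i V/V_T}$, mirroring the negative
  backward charges of the other schemes. A charge-*fraction* reading is ruled
  out by δ₂ = 2.139 > 1.
* **ZHA D θ.** θ = 8.866 multiplies the forward rate and divides the backward
  rate of the final activation step into the open composition (the original
  model-D convention). It is implemented as a voltage-independent scale on
  those edges, so the free-parameter count stays at 12; `theta_mode = "cf"`
  moves it to the Cf transitions instead.
* **ZHA D Cf direction.** Cf → O uses $k_\alpha$ and O → Cf uses $k_\beta$
  ("forward" pointing toward open); `cf_forward` swaps them.
* **SS inactivation.** "Three inactivated states reachable from the open
  state only" admits a chain or a parallel star; the default is the chain
  O–I1–I2–I3 with pairs (c,d), (c₁,d₁), (c₂,d₂). The state count, 40, is the
  same either way (`inactivation = "parallel"` selects the star). The
  40-state reading (35 composition + 2 concerted + 3 inactivated) matches the
  published 40×40 matrix dimension; a prose mention of 38 states appears to
  be inconsistent with that dimension and was not followed.

## Numerical propagation

`propagate()` iterates $\mathbf{P}(t_{i+1}) =
e^{\mathbf{W}(V_i)\,\Delta t}\,\mathbf{P}(t_i)$ with the voltage held at the
sample value across each interval. The matrix exponential is computed exactly
(scaling-and-squaring in compiled code), so the step map is a stochastic
matrix to machine precision regardless of model stiffness, and
piecewise-constant protocols are propagated exactly — halving `dt` changes a
step response only through segment-boundary alignment. Exponentials are
cached per distinct voltage quantized to `quantum` (default 0.001 mV, i.e.
indistinguishable from exact for gating charges of order 1); fluctuating
waveforms revisit values and stepped ones even more so. Simulations start
from the stationary distribution at the holding potential, obtained by
solving the generator's null space directly.

Key numeric defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| `thermal_voltage` | 24.57 mV | $kT/e$ at 12 °C, the recording temperature the shipped parameters are anchored to |
| `v_rev` | −90 mV | reversal potential; **an assumption**, not a published value — it coincides with the holding potential so resting current is exactly zero |
| `dt` | 0.01 ms | 100 kHz, inside the 50–200 kHz digitization range of typical hardware |
| `quantum` | 0.001 mV | propagator cache resolution |

## Wavelet synthesis

Pulses are parameterized by coefficients in the periodic orthonormal dyadic
wavelet basis $\psi_{m,n}(t) = 2^{-m/2}\psi(2^{-m}t - n)$ (Haar or
Daubechies-8 extremal phase, 16 taps). `dwt()` and `synthesize()` implement
the Mallat pyramid with **periodic (circular) boundary handling**, chosen
because it keeps analysis and synthesis exact mutual inverses and preserves
energy (Parseval) at every dyadic length — both properties are asserted to
1e−9 in the tests. Non-power-of-two lengths are rejected rather than silently
padded. The printed synthesis sum omits a DC term, but the multiresolution
recursion terminates in the signal mean, so the package carries an explicit
coarse/scaling term; by default the optimizer leaves it at zero and the DC
level is supplied as the synthesis `offset` (normally the holding potential).

Pulse length is `n_samples = 2^L` with `L >= n_levels`; the package default
is 1024 samples (10.24 ms at `dt` = 0.01 ms) with 8–10 levels, matching a
1–2 kHz effective band at the finest scales. Because voltage swings beyond
roughly 200 mV peak-to-peak destroy the gigaseal, `enforce_amplitude()`
rescales any candidate's fluctuation about its mean to exactly 200 mV
peak-to-peak (mean preserved, idempotent); rescaling rather than rejection
keeps the search space unconstrained (`action = "reject"` is available).

## The genetic algorithm

Each generation produces `n_daughters` candidates from the incumbent parent
by the multiplicative rule
$T \to T\,(1 + E_0 e^{-Rn}(X - \tfrac12))$, $X \sim U(0,1)$ drawn
independently per coefficient — a shared $X$ would collapse the search to one
dimension. Defaults $E_0 = 0.5$, $R = 4\times 10^{-4}$, 16 daughters follow
the published schedule for long (15 000-generation) runs; the envelope bound
$|T_\text{daughter}/T_\text{parent} - 1| \le E_0 e^{-Rn}/2$ is asserted
per generation in the tests. Design choices:

* **Elitism** is on by default (the parent competes with its daughters), so
  the best cost is monotone non-decreasing and convergence is testable;
  `elitism = FALSE` reproduces the literal daughters-only selection, under
  which the cost may fluctuate.
* **Initialization** draws coefficients from Uniform(−`init_scale`,
  `init_scale`), redrawing exact zeros, because multiplicative mutation can
  never escape an exactly-zero coefficient. `init_scale = 100` starts pulses
  at or above the amplitude bound, so the constraint — not the initial draw —
  sets the search scale from generation one.
* **Level scheduling**: `mode = "all"` perturbs every level each generation
  (default); `mode = "by-level"` cycles one level per generation.
* A single continuous perturbation schedule is used; no restarts or
  re-annealing of $E_0$.

Cost functionals: `divergence_cost()` (χ² divergence, a mean squared current
difference normalized to the number of samples, between two models' responses
to the same pulse) and `occupancy_cost()` (time-averaged probability of a
target state over a window). All randomness flows through R's seeded RNG;
a fixed seed makes `run_ga()`/`design_protocol()` bit-reproducible.

## Synthetic recordings

`make_fixture()` emulates an experimental whole-cell recording as a model
current plus i.i.d. Gaussian noise of chosen standard deviation. That
captures thermal/instrument noise amplitude but deliberately **not** the
structured artefacts of real recordings: capacitative transients (removed
experimentally by P/4- or P/2-type subtraction, which is out of scope here),
series-resistance voltage error, channel-number fluctuations (shot noise
scaling with open probability), leak, or rundown. Model-recovery results on
fixtures therefore show that the χ² ranking identifies the generating
kinetics when the noise is unstructured; they do not certify performance
against real artefact-laden data.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run design optimizations scaled to
package-check sizes: 256-sample pulses (2.56 ms at 0.01 ms), 8 levels,
16 daughters, 50–500 generations, versus the 15 000-generation production
runs the schedule is tuned for. At these sizes the optimizer demonstrably
improves on equal-norm random pulses (asserted against a 100-pulse
Monte-Carlo baseline it computes itself); production designs should use the
defaults (1024 samples or more, thousands of generations). The 2.56 ms
check-size pulses are short relative to the activation time constants of the
slower schemes, which is visible as small divergences for pairs excluding
ZHA A — expected behaviour at that pulse length, not an optimizer failure.

## Known limitations

* Whole-cell ensemble (master-equation) simulation only: no stochastic
  single-channel trajectories, no gating-current observables.
* Currents are in arbitrary units; absolute calibration is the user's
  affair via $g_0$.
* The reversal potential default (−90 mV) is an assumption to be overridden
  with the experimental value.
* Haar and Daubechies-8 families only; no wavelet packets or continuous
  transform.
* The registry ships exactly the four published Shaker schemes; the format
  is extensible but no other models are provided.
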