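---
title: "Methods: node dynamics, connectomes, and emergent functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: node dynamics, connectomes, and emergent functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`jrconnect` studies how local population dynamics and anatomical wiring
jointly shape functional connectivity (FC) in a network of Jansen–Rit
neural masses. This vignette documents the model, the numerical choices,
the tunable parameters, and the limits of what the packaged synthetic data
can demonstrate.

## The model and its assumptions

Every node is an identical Jansen–Rit cortical column: three interacting
populations (pyramidal cells, excitatory and inhibitory interneurons) whose
average postsynaptic potentials obey three second-order ODEs, written here
as six first-order equations per node. Nodes interact only through the
firing rate of afferent pyramidal populations, scaled by a coupling matrix
`w` and a global gain `ε`, entering the excitatory drive of the target node
(the `y4'` equation). The observable is the pyramidal potential
`y = y1 − y2`, the main EEG generator.

Model constants (`jr_params()`) are the standard single-column values:
`C = (135, 108, 33.75, 33.75)`, `P = 120` Hz, `a = 100/s`, `b = 50/s`,
`ν_max = 5` Hz, `v0 = 6` mV, `r = 0.56/mV`, `ε = 0.1`. The PSP amplitudes
`A ∈ [2, 14]` mV and `B ∈ [10, 30]` mV are the control parameters — they set
the excitation/inhibition balance that neuromodulation would vary in vivo.
Heterogeneity enters only through input noise; all nodes share parameters.
That assumption is what makes the linear stability analysis exact: with a
row-normalised connectome (all row sums `Γ = 1`), node-homogeneous
equilibria exist and the 6N-dimensional linearisation block-diagonalises in
the eigenbasis of `w` into N independent 6×6 problems
(`local_jacobian()`), one per connectivity eigenvalue. The package verifies
this decoupling against the explicit 6N×6N Jacobian in its tests.

## Connectome preprocessing and the surrogate generator

The empirical pipeline the package mirrors is: symmetric weighted SC →
retain the strongest fraction (default 0.23) of undirected pairs →
binarise → row-normalise. Ranking uses a deterministic tie rule (weight
descending, then smaller/larger node index) and retains
`floor(density · N(N−1)/2)` pairs; zero-weight pairs are never retained.
Row normalisation deliberately breaks symmetry (nodes have unequal
degrees); all homogeneous-equilibrium analysis relies only on the unit row
sums it guarantees.

The diffusion-MRI connectome itself is not distributable, so
`generate_modular_sc()` draws surrogates from a weighted stochastic block
model: 78 nodes (the atlas scale), four modules, within/between edge
probabilities 0.6/0.15, and lognormal(0, 1) weights on present edges —
heavy-tailed like streamline counts, which exercises the thresholding path
nontrivially. These defaults keep the raw density above the 0.23 retention
fraction. What the surrogate emulates is the modular, weighted, symmetric
character of tractography matrices; what it does not emulate is spatial
embedding, distance-dependent wiring, hubs/rich-club structure, or
subject-level variability. Consequences of that gap are flagged under
Limitations.

## Simulation

Integration uses a fixed-step Euler–Maruyama scheme at `dt = 1e-4` s (the
step halving test changes the oscillation period by < 0.5%). Noise models
the fluctuating extracortical input: per step, `P` receives an increment
`σ√dt·ξ` with `σ = 0.1` Hz (an SDE intensity; the alternative reading — an
additive value of standard deviation σ at every step regardless of `dt` —
is available as `noise_mode = "per_step"` since the convention is a genuine
ambiguity). Deterministic runs can use the classical RK4 (`method =
"rk4"`), which removes the first-order period bias of Euler and is used
wherever a simulation is compared against the phase reduction.

Durations are package choices: `t_total = 20` s with a 5 s discarded
transient by default (≥ 100 cycles of ~10 Hz activity, enough for stable
phase statistics); comparisons of averaged FC across models use shorter
6 s windows with a 0.5 s transient so that the locking transient — where
the modular structure is expressed — contributes to the average. Initial
conditions default to a uniform ±2 mV box around the equilibrium PSPs
(configurable, `ic_law`), and ensemble members derive per-realisation seeds
reproducibly from the master seed.

## Functional connectivity

Phases come from the FFT-based analytic signal of each demeaned node series
(no band-pass filtering — the raw model output is already narrowband);
5% of samples at each end are dropped to avoid wrap-around distortion.
Two synchrony metrics are provided: mean phase coherence (MPC), the modulus
of the circular mean of phase differences (the printed form of the metric
omits the modulus, which would not lie in [0, 1]; the package takes the
modulus), and mean phase agreement (MPA), the time average of
`(1 + cos Δφ)/2`. MPC saturates wherever oscillators lock at *any* lag;
MPA penalises the lag. In regimes of structured (non-synchronous) locking
the two rank node pairs consistently — the package tests this at
`(A, B) = (5, 19)` on a ring, where their binarised networks coincide — but
in near-synchronous or twisted-state regimes they measure different things
by design, and no agreement should be expected.

FC binarisation reuses the SC thresholding rule at a matched density
(default: the SC's own density), since Jaccard similarity is only
calibrated between graphs of equal edge count. Weighted Jaccard
(`Σ min / Σ max`) optionally min–max rescales both matrices first; a
numerically constant matrix is treated as constant rather than having its
rounding noise amplified.

## Stability classification and boundary tracing

`classify_point()` finds all homogeneous equilibria by scanning the scalar
consistency equation for `y` over [−20, 60] mV at 0.05 mV resolution with
bisection and Newton polishing (the generous interval covers the
physiological PSP range; roots are polished until the assembled state
annihilates the vector field to rounding error). In the saddle-node regime
a real positive eigenvalue always exists (the saddle), so the oscillatory
instability is read from the complex-pair eigenvalues only; the label is
`hopf_unstable` when a complex pair has positive real part, otherwise
`multi_equilibria` or `stable_focus_or_node`. Boundaries in the (A, B)
plane are traced by per-B bisection on this indicator (Hopf) or on the
equilibrium count (saddle-node) — simpler than numerical continuation and
sufficient because the indicator is scalar and monotone near each crossing.
The bistable band between folds of limit cycles is out of scope for
continuation; coexisting attractors are observable directly by simulating
from multiple initial conditions.

## False bifurcations

Within the oscillatory region the waveform changes qualitatively — from
sinusoidal-like (two extrema per period) to double-peaked (four) — without
any change of orbit stability. The package operationalises the transition
as the parameter value where the extrema count changes, located by
bisection (`locate_false_bifurcation()`, default tolerance 0.01 mV). Limit
cycles are extracted by RK4 simulation past the transient, period detection
from autocorrelation candidates filtered by full-state closure (which
rejects subharmonics for two-loop orbits), and sub-step refinement of the
period by minimising the spline-interpolated closure distance; cycles are
resampled at K = 1024 points. Extrema are counted on the *exact* derivative
`y' = y4 − y5` with a hysteresis threshold of 1e-3 of the derivative range,
and an inflection-plateau indicator (`(y'/s1)² + (y''/s2)²` at its minimum,
threshold 1e-3) flags the near-degenerate waveform at the transition. At
`B = 22` the package locates the transition at `A ≈ 7.7`, with the
double-peaked, slower (~6 Hz) orbits on the low-A side and sinusoidal
~11 Hz orbits on the high-A side — the ordering that matches classic
Jansen–Rit phenomenology, where spike-like waves live at lower effective
drive. Stability is verified unchanged on both sides.

## Weakly coupled oscillator reduction

For weak coupling every node stays close to the single-node limit cycle and
the network reduces to phases: `θ_i' = Ω + ε Σ_j w_ij H(θ_j − θ_i)`. The
phase interaction function is constructed from the adjoint: backward-in-time
RK4 integration of `Q' = −J(x(t))ᵀQ` along the cycle until periodic (all
non-periodic components decay backward), normalised so `Q·F = Ω` — with
that normalisation `Q` *is* the gradient of the asymptotic phase, which the
package validates by measuring phase shifts from small impulses (5%
agreement). Then `H(φ) = (1/T)∫ Q4(t) · A a f(y(t + φ/Ω)) dt`, evaluated as
a circular cross-correlation via FFT on the K-point grid; `H'` uses the
Fourier spectral derivative (cross-checked against centred differences) and
evaluation anywhere uses periodic cubic interpolation.

Key derived quantities: synchrony (which exists because row sums are
constant) is stable iff `ε H'(0) > 0`, oscillating at `Ω + εΓH(0)`; a
phase-locked state's stability comes from the Jacobian
`ε[H'(φ_j−φ_i)w_ij − δ_ij Σ_k H'(φ_k−φ_i)w_ik]`, which at synchrony reduces
to `−εH'(0)L` with `L` the graph Laplacian. The eigenmode FC predictor sums
`λ_k v_k v_kᵀ` over the Jacobian's leading modes (all N by default). Two
numerical subtleties: degenerate eigenspaces from the non-symmetric solver
are re-orthonormalised so the full-mode sum equals the spectral
reconstruction, and conjugate complex pairs are always included together so
the prediction stays real. On the synchrony-stable side (`εH'(0) > 0`) the
reconstruction weights connected pairs positively, which is the regime in
which the predictor resembles SC-driven FC.

At `(A, B) = (9, 22)`: `Ω = 68.74` rad/s (10.94 Hz), `H(0) = −0.699`
(nonzero, as required for this coupling type), `H'(0) = +0.152` (synchrony
stable). `H'(0)` changes sign across the false-bifurcation neighbourhood
(negative at `(7.5, 22)` and `(5, 19)`), reproducing the association
between waveform transitions and loss of synchronisability.

## Validation strategy

Every analytic layer is checked against an independent route: decoupled
spectra vs the explicit 6N×6N Jacobian; fixed points vs a dense scalar
scan; the adjoint vs direct impulse-response simulation; `H` vs a
long-horizon two-node full-model lock (ε = 1e−3, agreement within 0.05 rad)
and the emergent-frequency formula (relative error ~1e−6); the phase-locked
Jacobian vs finite differences; the phase model vs the full model through
matched-initial-condition FC comparisons, which recover the
weak-coupling-accuracy pattern (Jaccard ≥ 0.9 at ε = 0.01, non-increasing
through ε = 1). Simulation lengths in the tests (6–20 s, 4–8 realisations,
10–78 nodes) are chosen as the smallest at which these checks are stable.

## Limitations

* The surrogate connectome reproduces modularity and weight heavy-tails but
  not the empirical connectome's spatial and hub structure; quantities that
  depend on fine SC structure (e.g. which of two parameter-plane cells has
  the higher SC–FC Jaccard) vary across surrogate seeds at desk scale, and
  the packaged runs report them per seed rather than claiming the
  empirical-map contrast.
* Conduction delays, heterogeneous node parameters, time-resolved FC, and
  limit-cycle continuation (folds of cycles, Bogdanov–Takens points) are
  out of scope.
* The false-bifurcation detector is single-node; in networks nodes inflect
  at slightly different parameters and no network-level locus is computed.
* The phase reduction assumes a stable, strongly attracting limit cycle;
  near folds the adjoint iteration converges slowly and the reduction loses
  meaning, which `compute_adjoint()` reports as non-convergence rather than
  silently extrapolating.
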