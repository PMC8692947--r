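---
title: "Models and methods in neuroperc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in neuroperc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific content of the package: the two
models it simulates, the reconstructions and parameter choices that were
genuinely open, the numerical decisions, and what the test suite does and
does not establish.

# The neuropercolation activation process

## Graph model

The substrate is the N×N torus lattice: every vertex has exactly four
short-edge neighbors under periodic boundaries. On top of the lattice,
each unordered vertex pair at torus L1 distance d receives a long edge
independently with probability p_d = min(1, c/(N·d^α)). Choices made
where the model statement left room:

* **Metric.** "Distance on the lattice" is taken as torus L1 — the
  geodesic metric of the short-edge topology itself.
* **Minimum long-edge distance.** Pairs at distance 1 are already lattice
  neighbors; long-edge sampling starts at `d_min = 2` so no vertex pair is
  connected twice and each neighbor contributes once to the threshold
  sum. The expected long degree λ(N, c, α) = Σ_{d ≥ d_min} S(d)·p_d uses
  the same cutoff, so the analytic expectation and the sampler describe
  the same ensemble (`expected_long_degree` is tested against exhaustive
  pair enumeration). S(d) is computed by exact offset enumeration; note
  that for α = 1 the large-N limit of λ/c is 4·ln 2 ≈ 2.77, not 2: wrapped
  offsets beyond N/2 per axis contribute, which the popular 4d
  approximation misses.
* **Clamping.** p_d is clamped at 1 (the raw expression exceeds 1 for
  small N·d^α and large c).
* **Sampling.** Long edges are drawn grouped by translation-offset class
  (binomial count per class, then uniform placement), which considers
  every unordered pair exactly once and makes rebuilding with the same
  `(N, c, alpha, seed)` bit-reproducible.

## Dynamics

The update is synchronous and literal: χ_v(t+1) = 1 iff at least k
*neighbors* of v are active; v's own state is excluded. The rule is
monotone in the state but **not** monotone in time — active vertices with
fewer than k active neighbors die. Consequences embraced by the
implementation:

* All-inactive is absorbing for every k ≥ 1; all-active is absorbing for
  k ≤ minimum degree (k ≤ 4 suffices on any of these graphs).
* Synchronous threshold dynamics admits period-2 oscillations and frozen
  partial fixed points (e.g. an empty 2×2 block whose border is active is
  stable under k = 3). Trajectories therefore stop on exact state
  repetition with period 1 or 2 (`outcome = "cycle"` unless the repeated
  state is one of the absorbing extremes), a step cap (`timeout`), or the
  extremes.
* The optional noise ε is an independent post-update flip per vertex
  (default 0); ε = 0 recovers the deterministic rule exactly, and the
  equality-based termination checks are disabled when ε > 0.

States are dense 0/1 vectors in row-major vertex order; one synchronous
step is a sparse adjacency mat-vec (Matrix package) thresholded at k.

## Mean field and the critical density

The cited equations behind the phase-transition statement are not printed
in the source text; the package implements the standard annealed
reconstruction: each vertex sees 4 short neighbors plus a
Poisson(λ)-distributed number of long neighbors, each independently
active with the current density, giving

F(ρ) = Σ_j Pois(j; λ)·P(Bin(4 + j, ρ) ≥ k),

with the Poisson truncated at tail mass 10⁻¹² and renormalized. F maps
[0,1] into itself, F(0) = 0, and F is non-decreasing in ρ and in λ
(stochastic ordering); these are asserted as grid properties in the
tests. Fixed points are located by a 4001-point sign-change scan plus
`uniroot` bisection (default tolerance 10⁻⁸); stability is a central
finite-difference slope test (|F′| < 1). The critical density p_c is the
smallest interior unstable fixed point — the basin boundary between
extinction and full activation — with sentinels 0 (map above the
diagonal, e.g. k = 1) and 1 (map below, e.g. k = 4 at λ = 0). At λ = 0 and
k = 3 the interior point is the closed-form root of 4ρ² − 3ρ³ = 1,
ρ ≈ 0.76759, which the tests verify to 10⁻⁶ against an independent
dense-grid scan.

## Finite-lattice Monte Carlo, and where mean field fails

`monte_carlo_critical` bisects on p₀: each probe runs `reps` independent
trajectories and scores success as final ρ ≥ 0.99 (the 1% headroom
tolerates small frozen voids); the estimate is the crossing of the
success fraction through 1/2. The `reps` graphs are sampled once per call
and reused across probes (common random graphs sharpen the bisection);
initial states are fresh per probe. The confidence interval propagates
the binomial probe error through a linear fit of the informative probes,
floored at the bisection bracket — a logistic fit is ill-posed here
because the success curve is nearly a step function.

The acceptance machinery compares these finite-lattice estimates (N = 64,
k ∈ {2,3}, λ ∈ {0.5, 1, 2}, 20 runs per probe) with the mean-field p_c.
**They disagree beyond ±0.05 over most of that grid, and the
corresponding acceptance check fails by design rather than being
loosened.** The cause is visible in single trajectories: the
deterministic, non-monotone threshold dynamics freezes into correlated
mosaics (stable blocks, stripes, period-2 patches) at intermediate
density, so the final density varies smoothly with p₀ instead of
exhibiting the bimodal extinction/activation dichotomy the annealed map
predicts. For k = 2 the lattice activates more easily than mean field
(bootstrap-like corner growth from rare nuclei); for k = 3 erosion
dominates and the lattice needs far higher p₀. Agreement to ±0.05 emerges
only once long edges dominate (λ ≈ 2). The package reports both numbers
and their gap (`mc_vs_meanfield_max_abs_diff` in the acceptance report)
instead of hiding the discrepancy.

# The CAN model

## Equations and reconstructions

The spiking subsystem is the canonical Izhikevich (2003) form with
regular-spiking constants a = 0.02, b = 0.2, c = −65, d = 8, peak 30. The
metabolic attenuation functions are not printed in the source text;
the package uses the simplest forms satisfying their stated roles:
Ψ₁ = k_g·g·(1 − m/m_max) (glycogen→ATP conversion that shuts off at ATP
saturation) and Ψ₂ = k_m·m (linear consumption). The feedback path is
b⁺ = ω·b + β·m with ω ∈ [0.75, 1.25] and β ∈ [0, 0.5] enforced at
construction. With β = 0 the spiking trajectory is bitwise independent of
every metabolic parameter (the tests assert identity of spike times, and
against an independently coded Euler loop).

## The activity drive

The integral term feeding glycogen is interpreted as the cumulative
effect of spiking (glutamate release). Three window functionals are
available (`drive_mode`): `raw` (∫v dt over the trailing window τ),
`rectified` (∫(v − v_ref)₊ dt, the default) and `spike_count`. Two
deliberate choices:

* **Rectification reference.** The simulators rectify above the
  *spike-threshold* potential (the unstable nullcline root, −50 for
  b = 0.2), not the resting potential. With the rest reference, ordinary
  subthreshold jitter integrates into a slow metabolic fuse: the
  "silent" state accumulates glycogen for a few hundred milliseconds and
  then self-ignites, which contradicts the drive's interpretation as
  spike-driven release and destroys the model's bistability. With the
  threshold reference, quiescence produces exactly zero drive.
* **Start-up.** Histories shorter than τ/dt contribute only their
  available samples (zero drive padding) — padding raw membrane values
  with 0 mV would inject a spurious 70 mV excursion.

Within each step the order is fixed: drive from the history buffer →
metabolic update → b⁺ from the new m → Izhikevich update; the pre-reset
membrane value (capped at v_peak) enters the history, so each spike's
upstroke is seen by the drive once.

## Default scales

The model is dimensionless with time nominally in ms. Defaults were fixed
once, during model construction, to place the defaults inside the
regime the model is meant to exhibit — a quiescent state and a
metabolically self-sustained firing state coexisting at zero baseline
current:

| parameter | default | rationale |
|---|---|---|
| τ | 20 | drive window spanning ≳1 interspike interval at 30–60 Hz |
| κ | 5·10⁻⁴ | ATP saturates (m* → m_max) under sustained firing, since the measured window drive during firing is ~15–30 |
| k_g | 0.05 | glycogen→ATP conversion fast relative to consumption |
| k_m | 0.01 | ATP lifetime 100 ms, the slow variable of the loop |
| g_max, m_max | 5, 1 | m is a normalized saturation level |
| I_dc | 0 | below the b = 0.2 rheobase (I = 4): quiescence is a true state |
| w | 5 | all-to-all weight w/n; enough to synchronize tonic units |
| syn_tau | 5 | fast current-based exponential synapse |
| σ_noise | 0.2 | white-noise current σ√dt·ξ on v; small enough that the quiescent state is metastable on the simulated horizons |

The loop closes quantitatively: at steady state κ·drive ≈ k_m·m, so
sustained firing pins m near capacity, raising b⁺ from ω·b = 0.2 to
≈ 0.2 + β; for β ≳ 0.07 the rheobase then drops below zero and firing is
self-sustained at I = 0, while the depleted unit (m = 0) needs I > 4.
That separation is the hysteresis mechanism: sweeping I_dc up ignites the
population near I ≈ 4, and the ignited branch survives back down to
I = 0.

## Populations

Neurons couple through current-based exponential traces with weight w/n
(self-connections excluded; Erdős–Rényi wiring optional). By default one
glycogen pool serves the population (astrocytes service many synapses)
with per-neuron ATP; per-neuron pools are a flag. b⁺ uses each neuron's
own m. A population of one reduces exactly — bitwise — to the unit
simulator.

# Synchrony analysis

* **Order parameter.** Spike trains are binned and convolved with a
  unit-mass Gaussian (SD 5 ms by default); per-neuron instantaneous
  phases come from the FFT-based analytic signal of the mean-subtracted
  trace (no installed package provides the Hilbert construction, so it is
  implemented in-package and checked against the closed-form analytic
  signal of a cosine), and R(t) is the modulus of the mean unit phasor.
  Zero-variance traces carry no phase and are excluded; windows with
  fewer than two informative traces report R = 0 with a degenerate flag —
  silence is classified as absence of synchrony, not as coherence.
  Windowed measurements (sweeps, scans) extract phases within the
  measurement window only; computing phases on full traces lets the flat
  tails of neurons that fired earlier align spuriously.
* **State labeling.** Two-threshold Schmitt trigger (defaults θ_hi = 0.6,
  θ_lo = 0.3) to suppress chatter in the deadband; dwell statistics come
  from run lengths, with end-truncated runs flagged censored and excluded
  from the means (verified unbiased on telegraph processes with known
  geometric dwells).
* **Hysteresis sweeps** walk a parameter up then down the same grid,
  carrying the dynamical state across segments (synaptic traces and the
  drive window restart per segment; dwell ≫ τ makes this negligible).
  Bistability is branch separation > Δ_min = 0.2 in R — well above the
  1/√n noise floor for n = 50. The sweep machinery is validated against
  an injected relay surrogate with a known bistable interval.
* **Cusp scan.** Each (κ, β) cell is run from a depleted IC and from an
  ATP-primed IC (m = 0.9·m_max, g = 0 — glycogen is deliberately not
  primed, so a κ = 0 cell cannot coast on a reservoir through the
  measurement window). The κ = 0 row and β = 0 column are monostable;
  the bistable wedge requires both gains.
* **Phase cones.** φ(x) ≈ φ₀ + γ·|x − apex| is fitted by grid search over
  apexes with, per apex, a circular-linear regression: for fixed γ the
  optimal intercept is the circular mean of φ − γd, so the profile
  objective |Σ e^{i(φ−γd)}| is maximized over γ alone (coarse grid ±1
  rad/unit, then local refinement). Fit quality is the fraction of
  circular variance explained; constant fields are flagged degenerate.
  Recovery is calibrated on synthetic cones (generator = oracle): with
  0.3 rad phase noise on 16×16 grids, well over 90% of apexes are
  recovered within one lattice unit.

# What the synthetic data does and does not show

All inputs are generated: lattice states, rasters, telegraph label
series, phase-cone fields, and the relay surrogate. These validate the
machinery — exact oracle agreement for the automaton, parameter recovery
for the fitters, calibration anchors for R — under known ground truth.
They do not establish anything about recorded cortical data: the mapping
from model output to an EEG-like "phase field" is an interpretive bridge,
dwell-time statistics here are descriptive analogues of the ~100 ms
frame / ~10 ms shutter picture rather than reproductions of it, and no
fitting to experimental recordings is attempted.

# Problem sizes and numerics

Default problem sizes are chosen to make every result reproducible on a
laptop core in minutes: N = 64 lattices (4096 vertices) for critical-
density estimates with 20 runs per bisection probe; populations of
n = 50 at dt = 0.2 ms for sweeps (dt = 0.1 ms for single units); 1.2 s of
simulated time per cusp cell; 100 cones per recovery batch. Explicit
Euler is used throughout the CAN model (halving dt changes regular-
spiking counts by < 5%, asserted in the tests); the spike cutoff at
v_peak bounds the quadratic blow-up. All randomness flows from explicit
seeds; every simulator is bit-reproducible given its configuration.

# Known limitations

* The mean-field map is an annealed approximation; its p_c is not the
  finite-lattice critical density for small λ (measured and reported, see
  above), and the exact transcendental characterization from the external
  literature is not reproduced here.
* Excitatory units only; no inhibition, delays, multi-layer or reentrant
  structure.
* Current-based synapses and a two-pool metabolic abstraction; no
  conductances, compartments or hemodynamics.
* Phase-cone fitting assumes a single radial source per field; multi-cone
  interference is out of scope.
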