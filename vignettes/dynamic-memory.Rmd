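---
title: "Memory in fluctuating synapses: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory in fluctuating synapses: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dynmem)
```

## The model

`dynmem` simulates a recurrent firing-rate network of `N` units whose state
vector `x` (synaptic input) evolves as

    dx/dt = -x + W phi(x) + b(t)

with `phi` a pointwise nonlinearity (tanh by default) and `b(t)` an external
input. Time is measured in units of the neural time constant. The
connectivity `W` is itself dynamic:

    dW/dt = eta * (Delta_L + Delta_F)

where `eta` is the plasticity rate relative to the neural dynamics,
`Delta_L` is an activity-dependent learning operator derived from STDP, and
`Delta_F` is a fluctuation operator: activity-independent synaptic white
noise `xi_ij ~ N(0, 1/N)` plus one of three homeostatic rules,

* dissipation, `-beta W`;
* rate control, `[(phi0 - phi(x)) phi(x)'] o W` (Hadamard product), scaling
  each synapse by its post-synaptic rate error times its pre-synaptic rate;
* decorrelation, `I - tanh(x - xbar) tanh(x)'`, an anti-Hebbian push towards
  decorrelated rates with no rate set-point (`xbar` is a low-passed state,
  timescale 20).

The scientific object of interest is the *spectrum* of `W`. A memory stored
as a symmetric rank-1 perturbation `a uu'` appears as a real outlier
eigenvalue and implements a fixed-point attractor; a memory stored as an
anti-symmetric rank-2 perturbation `rho (uv' - vu')` appears as an imaginary
conjugate pair and implements a limit-cycle attractor on the plane spanned
by `u` and `v`. Because stability constraints act on the real part of the
spectrum, homeostatic control erodes real-coded memories while
imaginary-coded memories can persist — the central claim the package's
experiments quantify.

The rate-based STDP operator is obtained by averaging an exponential
spike-timing kernel over Poisson spiking at slowly varying rates:
`[Delta_L]_ij = a_P phi_i yP_j + a_D phi_j yD_i`, with `yP`, `yD`
first-order low-passed rates (timescales `tau_P`, `tau_D`) and `a_P > 0`,
`a_D < 0` the potentiation and depression amplitudes. For the symmetric
kernel (`tau_P = tau_D`, `a_D = -a_P`) this is purely anti-symmetric,
`a_P (phi y' - y phi')`, and modifies only the anti-symmetric component of
`W` — it writes into exactly the spectral subspace that homeostasis spares.
(The depression term enters with its negative amplitude; writing it with an
explicit minus sign would make the symmetric-kernel operator symmetric and
destroy this property, which is how we pin the sign convention.)

## Reference parameters and units

| parameter | default | meaning |
|---|---|---|
| `N` | 128 (64 in routine experiment runs) | network size |
| `dt` | 0.1 | Euler step, units of the neural time constant |
| `eta` | 0.01 | plasticity rate |
| `tau_P = tau_D` | 50 | STDP filter timescale |
| `tau_x` | 20 | decorrelation's state filter |
| `beta` | 0.1 | dissipation rate |
| `phi0` | U[-1, 1] per unit | rate-control targets |
| `xi_ij` | N(0, 1/N), fresh per step | synaptic noise |
| OU stimulus timescale | 0.01 | planar drive, effectively white per step |
| retrieval pulse | `c_u = 10` for 2 time units | associative cue |
| `g` | 1 | initial bulk scale, `W_ij ~ N(0, g^2/N)` |

Noise discretization: under the default `per_step` convention the fresh
`N(0, 1/N)` draw is included in `Delta_F` and scaled by `dt * eta` like
every other term; the `sqrt_dt` option rescales it by `1/sqrt(dt)` so that
accumulated weight variance is invariant under step refinement. The
`per_step` convention reproduces the reference numerics; the alternative is
for step-size studies.

All randomness flows from one master seed through named independent streams
(`init_W`, `init_x`, `noise`, `patterns`, `stimulus`, `trials`), so paired
experiments can vary one ingredient while replaying another exactly; the
erosion experiment's two branches consume an identical noise realization.

## Numerical choices

* Explicit Euler at `dt = 0.1` for both equations, matching the reference
  discretization; `dt` is configurable and a convergence-order test is part
  of the suite. Non-finite states abort with a typed blowup condition
  carrying the time.
* Eigendecompositions are computed only at snapshot times (default every 10
  time units): the `O(N^3)` eigen cost would otherwise dominate.
* Eigenvalue identities are matched across snapshots by exact minimum-cost
  assignment (shortest augmenting path) with cost
  `|d lambda| / s + (1 - |<v, v'>|)`, `s` the median nearest-neighbour
  spacing of the current spectrum. Value-only matching swaps conjugate
  trajectories where they cross; the eigenvector term disambiguates them
  (verified on a constructed crossing family).
* Plane overlaps orthonormalize each spanning pair, then combine the
  projections of one basis onto the other plane; the raw value is sqrt(2)
  for identical planes and `normalized` divides by sqrt(2) so that 1 means
  identical. We report the normalized value everywhere.
* The initial state is `x0 ~ N(0, 1/N)` (small, symmetry-breaking,
  unbiased); the reference text does not state it, and no noise enters the
  neural equation itself.

## The experiments and their design choices

**Erosion** (`erosion_experiment`): after a burn-in under the chosen rule, a
memory is embedded either as `a uu'` or `a (uv' - vu')` with
`a = embed_scale *` (bulk spectral radius); the memory amplitude — the real
part of the u-aligned outlier, or |Im| of the pair whose eigenplane best
overlaps the memory plane — is tracked and a half-life is measured as the
first crossing of the midpoint between the initial amplitude and the bulk
edge, linearly interpolated ("not decayed" = `Inf` when the horizon is
reached; the `ratio` field conservatively censors such values at the
observed window).

Two defaults here deviate from the obvious choices, for mechanistic
reasons found during validation:

* *Initial bulk* `g = 0.8` and a short burn-in (200), so the pre-embedding
  network is quiescent (subcritical). The multiplicative rate-control rule
  has no restoring force once rates freeze at saturation — entries with the
  wrong sign of `(phi0_i - phi_i) phi_j W_ij` then grow exponentially — so
  erosion must be probed in the regime where activity is ignited by the
  embedded memory alone, which is also the regime in which the erosion
  phenomenon is displayed (bulk edge near 1).
* *Embedding amplitude* `embed_scale = 1.5` (not 3): a barely supercritical
  real outlier ignites weak, non-frozen activity that homeostasis can
  suppress; at three times the bulk radius the frozen saturated state sets
  in and the rate-control rule amplifies the aligned outlier instead of
  eroding it.

With these conditions the decorrelation rule erodes a real-coded memory in
a few tens of time units while the matched imaginary-coded memory survives
hundreds (half-life ratios 60-100 at N = 64), and under rate control the
real memory decays within the 5000-unit horizon while the imaginary
amplitude shows no measurable decay at all.

**Learning** (`learning_experiment`): a planar Ornstein-Uhlenbeck stimulus
`b = c_u u + c_v v` drives the network while the anti-symmetric STDP term is
active. The OU coefficient RMS defaults to 10, the same scale as the
standard retrieval pulse. Two mechanisms found during calibration shape the
remaining defaults:

* What is stored is the plane of the *rates* `phi(x)`, not of the input:
  strongly saturated rates store a nonlinearly distorted image of the
  stimulated plane, and with a strong random bulk the response to a planar
  drive is the bulk-filtered plane. Either effect caps the learned
  eigenplane's overlap with `(u, v)` (near 0.8 at drive RMS above 1 or
  `g = 1`). Learning runs therefore default to sub-saturating drive and a
  weak initial bulk (`g = 0.05`), where the stored plane matches the
  stimulus plane to overlap 0.95-0.99.
* The kernel amplitude defaults to `a_P = 20` (with `a_D = -a_P`): the
  learning rate of the plane's rotation strength scales like
  `eta a_P <phi_plane^2> / tau`, and at `N = 64`, `eta = 0.01`, `tau = 50`
  an order-one kernel stores almost nothing within a 100-time-unit
  stimulus. The amplitude is a free parameter of the kernel (not fixed by
  the reference model) and is chosen once so that a 100-unit stimulus
  stores a pair far outside the bulk.
* The default homeostatic rule during learning is rate control: in a
  subcritical network it is inactive at rest, so the stored plane is not
  perturbed. Under the decorrelation rule the anti-Hebbian term
  `-tanh(x - xbar) tanh(x)'` contains an anti-symmetric component of the
  same form as the STDP operator with opposite sign (`xbar` playing the
  role of the filtered rate), and partially unlearns the memory; the
  qualitative results are preserved but weaker.

Memory strength (|Im| of the stored pair) grows monotonically with
stimulation duration, and a second plane is stored later without erasing
the first.

**Retrieval** (`retrieval_experiment`): with plasticity frozen,
`W = rho (uv' - vu') + gamma (uu' + vv')` and `gamma = 1.5 > 1` supports a
limit cycle; trajectories from inside and outside converge to the same
orbit (amplitudes agree to a fraction of a percent). With several embedded
planes, cueing one plane elevates its radial overlap well above the others
during a transient window, but the separation is not persistent: on the
winner's orbit the radial balance pins `gamma * gain = 1`, and for
Gaussian patterns with an odd nonlinearity Stein's identity makes the
small-signal gain of every other plane exactly equal to it — distractor
overlaps are marginal, grow from their nonlinear-harmonic seeds, and the
network settles into a graded multi-plane coexistence state. The report
therefore exposes both a transient-window selectivity (default window 5-20
time units after the cue) and the late-time value. In continuous time with
`gamma = 0`
the origin is globally stable and the orbit disappears — reproduced as the
collapse flag of `reduced_vs_full` — whereas the discrete-time map
`x' = sign(W x)` sustains the orbit at radius `sqrt(2/pi)` (an exact
Gaussian-projection identity: `E[v_i sign(p_u u_i + p_v v_i)]
= sqrt(2/pi) p_v / r` for `u_i, v_i ~ N(0, 1/N)`).

**Reduced model** (`reduced_step`): the steep-nonlinearity dynamics
projected on the memory plane,
`dp_u/dt = -p_u + rho q_v`, `dp_v/dt = -p_v - rho q_u`, with
`q_v = arctan(p_v / |p_u|)` and the symmetric completion
`q_u = arctan(p_u / |p_v|)` (only `q_v` is stated in the reference; the
rotational structure forces the anti-symmetric pairing). Two findings
matter for its use as an oracle:

* The arctan closure has zero net radial drive over a cycle (its radial
  component integrates to zero by the system's four-fold symmetry), so in
  the `dt -> 0` limit the reduced ODE spirals into the origin — consistent
  with the gamma = 0 collapse of the full model. Its limit cycle at the
  reference step `dt = 0.1` is discreteness-stabilized, like the
  discrete-time full model, with mean radius `0.2887 rho`.
* `reduced_vs_full` therefore compares the reduced cycle (at `dt = 0.1`)
  against the configuration of the full model that actually possesses a
  persistent orbit: the gamma-augmented (`gamma = 1.5`) steep-nonlinearity
  network, integrated at a fine step to resolve its fast rotation. At
  `rho = 4` the amplitudes agree within about 5 percent (the continuous
  full-model radius is `gamma sqrt(2/pi) = 1.197`; the reduced radius is
  1.155). With the gamma = 0 discrete map instead, whose radius
  `sqrt(2/pi)` is independent of `rho`, no quantitative agreement is
  possible — the comparison would conflate two different attractors.

**Capacity** (`capacity_experiment`): the discrete-time `gamma = 0` model
with M planes (`W = U D U'`) against a classic symmetric Hopfield baseline,
under one protocol: cue pattern 1 with 10 percent corruption, run 100
synchronous sign updates, success when the time-averaged relative target
overlap exceeds 0.9 over the last 50 steps; the critical load is the
interpolated 50-percent success point, reported as 2M/N for planar
memories (each occupies two dimensions) and M/N for Hopfield. The Hopfield
baseline reproduces the classic synchronous capacity (about 0.15). The
planar model does *not* reach it: a plus/minus-1 state has order
`sqrt(2/N)` overlap with every stored plane, and each plane is a marginally
stable rotation channel of the sign map, so cue-induced crosstalk is never
damped — it grows to an equilibrium sharing in which the target keeps the
largest but not a dominant overlap. Persistent selective retrieval
(available to fixed-point memories, whose crosstalk overlaps are damped)
does not exist in the discrete planar model; only the first one or two
steps are selective. This is reported as measured; see Limitations.

**Life cycle** (`lifecycle_experiment`): sequential learning of two planes,
a retention interval, cued retrieval of each plane and of a novel plane,
with projection traces, example synaptic weight traces, eigenvalue
snapshots, and contribution accounting — the temporal averages of
`mean(|Delta_ij|)` for the learning, homeostatic and noise terms. The noise
term's average is the half-normal value `sqrt(2/(pi N))` by construction
(about 0.10 at N = 64). Under the default rate-control rule the
activity-dependent and spontaneous contributions are of similar magnitude
(ratio about 0.6 at the defaults). Under the decorrelation rule they are
not (see Limitations). In the quiescent regime the cue pulse itself
produces a comparable transient overlap on any plane, learned or novel;
what distinguishes a learned plane is the oscillation at its stored
frequency (about `rho / 2 pi`) during retrieval, which the report exposes
via `retrieval_frequency`.

**Sparsity** (`sparsity_sweep`): a binary structural mask applied to `W`,
the noise and every update; the realized embedded amplitude shrinks
with density (masking a rank-2 operator dilutes it by the density) and the
half-life ordering of imaginary over real memories persists at all tested
densities.

## What the synthetic conditions do and do not show

All inputs are generated internally: Gaussian memory patterns with entries
`N(0, 1/N)`, Gaussian random bulks, planar OU stimuli, and rectangular
retrieval pulses. These match the reference model class, but they idealize
real data in known ways: patterns are dense and uncorrelated (no sparse or
structured representations), all units share one nonlinearity and one time
constant, there is no separation of excitation and inhibition, and the
synaptic noise is white and homogeneous. Passing tests show the spectral
mechanism — differential erosion, anti-symmetric learning, limit-cycle
retrieval — is real in this model class; they do not certify magnitudes in
biological networks.

## Known limitations

* The multiplicative rate-control rule is only conditionally stable: once
  rates freeze at saturation, part of the weight matrix grows
  exponentially. Quiescent study conditions avoid this; long runs at
  `g = 1` do not. The rule's rate set-point is likewise only weakly
  attained (the time-averaged rates approach the targets only while the
  suppression of the igniting mode lasts).
* The decorrelation rule as specified has no stationary state: the
  identity drift exceeds what `tanh(x - xbar) tanh(x)'` can balance, so
  the bulk's real spectrum grows linearly (at rate `eta`) and the network
  is eventually driven into strong chaotic activity. Differential erosion
  survives this (the rule's modification is mostly symmetric), but the
  activity-dependent contribution then exceeds the spontaneous one several
  fold, so the similar-magnitude contribution claim holds here only for
  the rate-control variant of the life cycle.
* Associative selectivity among same-strength planar memories is
  transient, in both the continuous gamma-augmented network (exact
  marginality of distractor planes on the winner's orbit, see Retrieval)
  and the discrete-time model (undamped rotating crosstalk, see Capacity);
  its capacity under a persistent-retrieval criterion is far below the
  Hopfield baseline.
* Problem sizes in the routine experiments (N = 64-512, horizons up to
  5000 time units, 16 trials per capacity point) were chosen so the whole
  suite runs comfortably on one CPU; all phenomena shown are stable under
  doubling of these sizes where we tested them.
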