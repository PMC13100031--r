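---
title: "Methods: reflex-based speed modulation in a planar neuromusculoskeletal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reflex-based speed modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reflexgait)
```

This vignette is the package's own account of its model, its numerical
choices, and the design decisions taken where the problem left them open.

## The plant

The plant is a planar (sagittal) rigid-body tree: a torso segment carrying
a floating base at the hip, and per leg a femur, tibia and foot connected
by revolute hip, knee and ankle joints — seven segments, nine degrees of
freedom. Segment masses, lengths, centers of mass and radii of gyration
come from standard anthropometric proportion tables scaled to a 74.5 kg,
1.80 m adult; they are stated equivalents of published human-model
constants, not replicas of any specific deposited model, and every value
can be overridden through `plant_config()`. The convention is x forward, y
up, joint angles zero in quiet standing and flexion positive (ankle:
dorsiflexion positive); internally all angles are radians, and degrees
appear only at I/O boundaries.

Dynamics are advanced by recursive Newton–Euler inverse dynamics: the
joint-space mass matrix is assembled column by column from
unit-acceleration calls, the bias forces from a zero-acceleration call, and
the resulting linear system is solved each step. The integrator is fixed-step
semi-implicit (symplectic) Euler at `dt = 0.5 ms`. A fixed step keeps the
stiff muscle–contact dynamics stable without the run-to-run nondeterminism
of adaptive stepping; the symplectic update bounds energy error rather than
accumulating it (a passive pendulum reduction drifts below 0.1% over 10 s
at the default step, which the test suite asserts).

Ground contact acts at the heel and toe of each foot: a smooth viscoelastic
normal force `k·dᵉ·(1 + c·ḋ)` (Hunt–Crossley-style, `k = 8·10⁴`,
`e = 1.5`, `c = 1 s/m`) clamped at zero, and regularized Coulomb friction
`−μ·F_n·clamp(v/v_reg, −1, 1)` with `μ = 0.9` and `v_reg = 0.05 m/s`. The
clamp (rather than tanh) makes the force reach the Coulomb cone exactly
once sliding exceeds `v_reg`, which keeps the saturation property testable.

## Muscles

Each of the 18 musculotendon units is a Hill model: Gaussian force–length
(width 0.56 in units of optimal CE length), hyperbolic force–velocity
(shortening curvature 0.25, eccentric plateau 1.5, slope-continuous at the
isometric point), a quadratic-then-linear series-elastic tendon
(reference strain 0.04 at maximum isometric force), a quadratic parallel
elastic element beyond optimal length, and first-order activation dynamics
with `τ_act = 10 ms` and `τ_deact = 40 ms`. The CE state is advanced by
inverting the force–velocity relation under tendon-force equilibrium; the
inversion input is clamped to the invertible force range and the CE length
to `[0.3, 1.8]·l_opt`, which keeps inactive muscles from collapsing
numerically. Muscle paths use constant moment arms per spanned joint — the
simplest faithful planar choice — with magnitudes in the 2–7 cm range
typical of the human lower limb; RF, HAM and GAS span two joints, all
others one.

## The reflex controller

Muscle stimulation is

`u_i(t) = clip( c_i + Σ_{j∈R_i} [κᴸ_ij·L̃_j(t−Δt_j) + κᶠ_ij·F̃_j(t−Δt_j)], 0, 1 )`

with L̃ the CE length normalized by optimal length and F̃ the tendon force
normalized by maximum isometric force. Clipping to [0, 1] reflects the
physical bounds of stimulation; gains may be positive (excitatory) or
negative (inhibitory). Delays are assigned by neural path length — 5 ms
for hip-level muscles (GLU, ILI), 10 ms for thigh muscles (RF, HAM, BF,
VAS), 20 ms for shank muscles (GAS, TA, SOL) — and are configurable. The
controller runs at the integrator rate; delayed signals are read from ring
buffers by nearest-sample lookup, and lookups before the history fills
return the initial sample. Both legs read the same parameter vector.

The connection set contains one homonymous connection per muscle and two
directed connections per antagonist pair. The antagonist map is derived
from joint actions: at the hip the flexors ILI and RF oppose the extensors
GLU and HAM; at the knee the extensors VAS and RF oppose the flexors HAM,
BF and GAS; at the ankle TA opposes SOL and GAS; the pair RF–HAM, which
shares two joints, is counted once. That yields 11 unique pairs, so
9 + 22 = 31 connections and 71 free parameters (31 κᴸ, 31 κᶠ, 9 c). The
canonical parameter order — all κᴸ in connection order, then all κᶠ, then
the offsets in muscle order GLU, ILI, RF, HAM, BF, VAS, GAS, TA, SOL — is
used everywhere: flat vectors, CSV columns, PCA loadings. The map is
config-overridable and the 31-count invariant is enforced at construction.

## Episodes and gait metrics

An episode integrates the closed loop until `t_max` (default 50 s) or
until the model CoM drops below the fall threshold (default 0.9 m, checked
every step). *Stable* means exactly `t_sim = t_max`. The completed
distance `d_sim` is the horizontal displacement of the CoM of the segment
that ends nearest the origin when maximizing speed (farthest when
minimizing) — a conservative reading that cannot be inflated by a single
flung segment. The actual velocity `v_act` of a stable episode is the mean
horizontal CoM velocity over `[transient, t_max]` with a 10 s default
transient; the averaging window is a package choice, since only full-length
episodes carry a `v_act`. Gait classification is kinematic: `run` if and
only if periodic flight phases occur, `walk` if at least one foot is always
grounded with alternating single and double support, `none` otherwise
(including fewer than four complete strides). Stride events threshold the
vertical ground reaction at 20 N with hysteretic release at 10 N, standard
gait-event practice.

## Speed optimization and harvesting

The cost is `J = 100·J_vel + 100·J_fall` with `J_vel = ±d_sim/t_max`
(positive sign when minimizing speed) and `J_fall = 1 − t_sim/t_max`. The
optimizer is a standard (μ/μ_w, λ) CMA-ES with rank-one and rank-μ
covariance updates and cumulative step-size adaptation, written in R (no
CMA-ES implementation ships with the environment's R stack) and validated
against closed-form optima. Defaults follow the study conditions: initial
step size σ₀ = 0.01, 20 seeds per initial point, termination when the
average relative improvement of the best cost per iteration over the last
500 iterations falls below 10⁻⁵, plus a 3000-generation safety cap.

"Intermediate optimization results" are taken to be each generation's best
candidate: this matches CMA-ES bookkeeping and keeps the harvested
parameter path continuous, since consecutive generation bests are gradual
adjustments. Harvesting re-simulates each candidate once (deterministically,
so reuse versus re-evaluation changes nothing except bookkeeping clarity)
and keeps the stable ones with their `v_act`. Per direction, the seed whose
harvest spans the widest speed range is selected; the two harvests are
concatenated, sorted by speed, and deduplicated.

## Key parameters and the speed-modulation function

PCA runs on the per-column z-scored dataset. Standardization is a design
choice: gains and offsets live on heterogeneous scales, and without it the
largest-scaled parameters would dominate the loadings regardless of their
speed relevance. Zero-variance columns are centered but not scaled. Each
component's sign is fixed so its largest-magnitude loading is positive,
making selections reproducible. The `n_key` parameters with the largest
absolute PC1 loadings (ties broken by canonical index) are the key
parameters; the study grid is `n_key ∈ {5, 10, 15, 20, 25, 30}` with
`n_key = 30`, degree 3 as the default pipeline setting.

The restricted optimization freezes all non-key entries bit-exactly at
their initial values and searches only the key subspace. The
speed-modulation function fits, per key parameter, an ordinary
least-squares polynomial of degree `d_reg ∈ {1,2,3}` of parameter value
against `v_act` (the regressor is the *achieved* speed, since dataset
records are (p, v_act) pairs), recomputed per degree with higher
coefficients exactly zero. Assembly evaluates the polynomials at the
target speed and passes all other entries through from the frozen initial
vector; extrapolation beyond the fitted range is permitted but flagged.
The offline sweep evaluates one deterministic episode per grid point
(default 0.5–3.5 m/s in 0.025 steps, 121 points) and records the stable
target range into the model. The monotonicity report treats adjacent
decreases below 10⁻⁹ m/s as ties: that tolerance is far below any
physically meaningful speed difference and exists only to keep
floating-point jitter between physically identical outcomes from counting
as inversions.

## Online modulation and transitions

Schedules start at the mid-range speed `v_start = v_min + (v_max−v_min)/2`
and hold it for a 20 s settle phase. Steps jump to
`v_start ± j·0.025 m/s`, `j ∈ 1..25`, at the settle time. Ramps follow the
triangle wave `v_min + v_a·|((τ − T/4) mod T) − T/2|` with
`T = 2(v_max−v_min)/v_a` and `v_a = 0.05 m/s` per second. The wave's time
argument is taken as `τ = t − 20 s`: with that shift the ramp starts
exactly at `v_start` and first rises toward `v_max`, which is the intended
behaviour; with raw `t` it generally would not. The target is
sampled-and-held on a 1 s lattice, so the ramp is realized as 0.05 m/s
increments once per second. At each change the full 71-entry vector is
replaced instantly while the plant state, muscle states and sensor
histories carry over — nothing is reset. Online runs, plain episodes and
transition runs all share one piecewise-constant-parameter simulation core,
so an online run with a constant schedule is bit-identical to the
corresponding offline episode (asserted in the tests). When scanning step
sizes, the largest surviving `j` is reported; the slowest and fastest
stable targets are excluded when choosing `v_min`/`v_max` to avoid
operating at the edge of stability.

Transition plans switch the complete parameter vector abruptly at fixed
10 s intervals, deliberately not aligned to gait events. Their
re-optimization stacks all sets into one CMA-ES search (2×71 or 4×71
dimensions) and minimizes `J = 100·J_fall` only — the goal of a transition
is to survive the switches, not to chase a speed — and stops immediately
if the initial plan already survives.

## The toy hopper

The desk-scale testbed is a point-mass body on one telescoping,
backward-leaning leg with two MTUs (extensor, flexor) and the reflex
network restricted to 2 homonymous + 2 antagonistic connections + 2
offsets (10 parameters). A hopper was chosen over a reduced biped because
stable hopping is reachable with a tiny optimization budget while
exercising the identical muscle, contact, controller, episode and
optimizer code paths. The committed baseline uses positive force feedback
on the extensor to rebuild the push during stance, and inhibitory length
feedback from the flexor — whose short optimal CE length turns its
normalized length into a sharp leg-extension sensor — to cut the extensor
near full extension. The resulting limit cycle hops forward at about
0.1 m/s, and the speed responds monotonically to the extensor's
homonymous force gain over [0.9, 1.7].

The hopper validates machinery, not human gait: it has no swing leg, no
balance problem (the body cannot pitch), and speeds an order of magnitude
below walking. Passing the pipeline on the hopper therefore demonstrates
that optimization, harvesting, key selection, regression and online
switching interact correctly — it does not demonstrate that the biped
reproduces published human speed ranges, which requires optimization
budgets (20 CMA-ES seeds × 2 directions × 50 s episodes on the full
model) far beyond a test suite.

Synthetic parameter-over-speed datasets provide exact ground truth for the
statistical stages: a chosen key subset follows polynomial trends in speed
(drawn with a dominant linear term, reflecting the predominantly smooth,
monotone trends of harvested datasets) plus Gaussian noise at a fixed
fraction of the signal's standard deviation; all other columns are
constant plus noise at the mean key-noise level. With the default 10%
noise, selecting 5 keys from 100 seeded replicates recovers the true set
in well over 95% of cases; with zero noise, polynomial regression recovers
the generating coefficients to machine precision — both are asserted in
the tests.

## Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on desk-scale
problems chosen as the package's own verification sizes: hopper episodes
of 10–20 s, reduced CMA-ES budgets (2 seeds per direction, populations of
8, 40 generations), 100 synthetic replicates of 40 records each, and a
0.5 s mirrored-biped comparison. The full-scale study settings (50 s
episodes, σ₀ = 0.01, 20 seeds, the 121-point sweep grid) remain the
package defaults and are pinned by tests, but no shipped test executes a
full biped optimization.

## Known limitations

* The plant is planar, armless and vestibular-free; metabolic cost is not
  modeled. These bound the attainable speed range of the biped.
* Plant constants are documented anthropometric equivalents; users with
  access to calibrated musculoskeletal parameter sets should load them via
  the configuration layer before comparing against published trajectories.
* Gait classification is operational (flight-phase based); unusual gaits
  (skipping, grounded running) map onto the nearest of walk/run/none.
* The left–right symmetry of the dynamics is exact at the level of a
  single step (mirror equivariance to machine precision), but the stiff
  muscle–contact dynamics amplify last-bit rounding differences
  exponentially, so mirrored trajectories agree tightly only over short
  horizons. This is a property of chaotic rigid-body contact dynamics, not
  an asymmetry of the model.
* The monosynaptic structure is fixed; no gain scheduling within the gait
  cycle, CPG components or supraspinal loops are modeled — by design, to
  isolate what constant-gain reflex modulation alone can do.
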