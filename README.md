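# reflexgait

Reflex-modulated speed control in simulated bipedal locomotion.

Human locomotion emerges from the interplay of the musculoskeletal system,
spinal circuits and supraspinal control. This package isolates one of those
components — spinal reflexes — and asks how far it can carry speed control
on its own. It simulates a planar neuromusculoskeletal model whose only
controller is a network of delayed, constant-gain proprioceptive reflexes,
and provides the full analysis pipeline for *modulating* those reflex gains
to set and track locomotion speed, offline and at run time, including
abrupt-switch walk–run transition experiments. It is aimed at motor-control
and biomechanics researchers studying reflex contributions to gait, and at
developers of bioinspired locomotion controllers.

## The model and controller

The plant is a planar seven-segment rigid body (torso, and femur/tibia/foot
per leg; 74.5 kg, 1.80 m by default) actuated by 18 Hill-type
musculotendon units (MTUs), nine per leg: GLU, ILI, RF, HAM, BF, VAS, GAS,
TA, SOL. Each MTU has a contractile element with Gaussian force–length and
hyperbolic force–velocity properties, a series-elastic tendon, and
first-order activation dynamics; it acts on the hip, knee and/or ankle
through constant moment arms. Ground contact is a smooth viscoelastic
normal force with regularized Coulomb friction at the heel and toe.

The stimulation of muscle *i* is a sum of delayed, gain-scaled normalized
length and force signals from the muscles *R_i* connected to it, plus a
constant offset:

    u_i(t) = c_i + Σ_{j ∈ R_i} [ κᴸ_ij · L̃_j(t − Δt) + κᶠ_ij · F̃_j(t − Δt) ]

where L̃ is contractile-element length over optimal length and F̃ is tendon
force over maximum isometric force. Connections are *homonymous* (a muscle
excited by its own feedback) or *antagonistic* (feedback from an antagonist
across a shared joint); with nine muscles this gives 31 connections, hence
**71 free parameters** (31 κᴸ, 31 κᶠ, 9 c), shared by both legs.

The pipeline on top of the simulator:

1. **Speed optimization** (`optimize_speed()`): CMA-ES minimizes
   `J = 100·J_vel + 100·J_fall`, with `J_vel = ±d_sim/t_max` (sign by
   direction) and `J_fall = 1 − t_sim/t_max`; episodes end at `t_max = 50 s`
   or when the CoM drops below 0.9 m.
2. **Harvesting** (`harvest()`, `build_omega()`): every stable intermediate
   solution along the optimization becomes a record (p, v_act) in a
   parameter-over-speed dataset Ω.
3. **Key parameters** (`fit_pca()`, `select_keys()`): PCA on the
   standardized Ω; the parameters with the largest absolute loadings on the
   first principal component are the key reflexes.
4. **Speed-modulation function** (`fit_smf()`, `assemble_params()`): a
   polynomial `SMF_k(v) = β₀ + β₁v + β₂v² + β₃v³` per key parameter maps a
   target speed to a full 71-entry parameter set (non-key entries frozen).
5. **Offline and online modulation** (`offline_sweep()`, `run_online()`):
   sweep the target-speed grid (0.5–3.5 m/s in 0.025 steps) for stability
   and speed tracking, or swap the assembled parameter set at run time to
   follow step and triangle-ramp speed schedules.
6. **Gait transitions** (`run_transition()`, `optimize_transition()`):
   switch all 71 parameters abruptly between walking and running sets every
   10 s and re-optimize the stacked 2×71 or 4×71 parameters to survive the
   switches.

A reduced testbed — a muscle-driven forward hopper with the identical
controller machinery and 10 parameters (`make_toy_plant()`) — lets the
entire pipeline run in under a minute (`pipeline_smoke()`).

## Worked example

```r
library(reflexgait)

# the desk-scale hopper with its committed baseline reflex parameters
toy <- make_toy_plant()
ep <- run_episode(toy$plant, toy$p_baseline,
                  episode_config(toy$plant, t_max = 20))
print(ep)
#> Episode: t_sim = 20.000 s / t_max = 20 s (stable), gait = run
#>   mean velocity 0.097 m/s, v_act 0.101 m/s

# maximize speed with CMA-ES, harvest stable intermediates into a dataset
h <- optimize_speed(toy$plant, encode_params(toy$p_baseline), "maximize_v",
                    cma = cma_config(sigma0 = 0.05, lambda = 8,
                                     max_gen = 40, seed = 1),
                    cfg = episode_config(toy$plant, t_max = 20),
                    check_init = FALSE)
omega <- harvest(h, toy$plant, episode_config(toy$plant, t_max = 20))
print(omega)
#> Speed dataset: 40 stable parameter sets, v_act in [0.081, 0.101] m/s

# key reflexes from the first principal component
keys <- select_keys(fit_pca(omega), 4)
print(keys)
#> Key parameters (n = 4): kL_EXT_EXT, kL_EXT_FLX, kL_FLX_EXT, kF_FLX_FLX
```

The episode print shows the termination time against the episode budget
(an episode is *stable* when it survives the whole budget), the gait label
inferred from the contact pattern (the hopper has flight phases, so it is
labelled `run`), the mean CoM velocity and the steady-state velocity
`v_act` measured after the transient. The harvested dataset is the raw
material for key-reflex selection: here four of the hopper's ten
parameters dominate the first principal component of the
parameter-over-speed variation.

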