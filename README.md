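# chemopursuit

An agent-based simulator of chemotactic pursuit: a single sensing immune
cell searches for, and eliminates, multiple chemoattractant-emitting target
cells on a two-dimensional periodic plane. The package is built for the
question *which stimulus-response strategies of chemotactic pursuit are
simultaneously efficient and versatile* when the targets span a wide
spectrum of migration behaviors — from immobile to fast and directionally
persistent. It is aimed at computational biophysicists studying cell
migration, random search, and chemotaxis, and at experimentalists who want
simulated trajectories with known ground-truth search strategies.

## Model

**Migration.** Every cell performs a discrete-time correlated random walk
with time step Δt = 1 min:

    r_n = r_{n-1} + w_n · (cos(φ_{n-1} + s_n|Δφ_n|), sin(φ_{n-1} + s_n|Δφ_n|))

where the step width w_n is Rayleigh-distributed with mean v, the turning
magnitude |Δφ_n| is drawn uniformly between persistence-dependent bounds
(ε = 1 ballistic, ε = 0 isotropic, ε = −1 reversing), and the sign
s_n ∈ {−1, +1} is the turn direction (right turn with probability q_R,
balanced at 1/2 unless steered).

**Attractant field.** Targets emit a substance that diffuses
(D = 6000 μm²/min) and decays (k = 0.6/min). In the fast-diffusion limit
each target carries a stationary radial cloud f(r) solving

    f'' + f'/r = (k/D) f,   f(r_tar) = 1,   f(r → ∞) = 0,

with diffusion length L_dif = √(D/k) = 100 μm; the clouds of all live
targets superpose linearly (minimum-image distances on the torus). The
profile is computed once by a shooting method (fourth-order Runge-Kutta on
a geometric radial grid, bisection on the initial slope) and equals
K₀(r/L_dif)/K₀(r_tar/L_dif) to better than 10⁻⁴ relative error.

**Response.** The immune cell has two migration modes — *normal*
(v_N, ε_N) and *approach* (v_A, ε_A) — and two sensors: the temporal
central-concentration difference Δρ^C and the spatial left/right sensor
difference Δρ^LR. Per step it adopts the approach mode with probability
logistic(c_A0 + c_A1·Δρ^C) and turns right with probability
logistic(c_R1·Δρ^LR). The seven parameters
π = (v_N, ε_N, v_A, ε_A, c_A0, c_A1, c_R1) define the strategy.

**Efficiency.** A run lasts T_sim = 100 min among N_tar = 10 targets in a
1000 μm box; a target is eliminated on contact (center distance ≤
r_imm + r_tar = 20 μm). The search efficiency Q is the mean number of
eliminations per run over many independently seeded runs (10⁴ for headline
numbers). Five named presets ship with the package: blind search (`bls`),
random mode switching (`rms`), temporal gradient sensing (`tgs`), spatial
gradient sensing (`sgs`), and combined sensing (`cgs`). A grid-based
cyclic-coordinate-descent optimizer with common random numbers recovers
optimal strategy parameters from the noisy Monte-Carlo objective.

## Worked example

```r
library(chemopursuit)

kernel <- solve_kernel(D = 6000, k = 0.6, r_tar = 10)
kernel
#> Stationary chemoattractant kernel
#>   D = 6000 um^2/min, k = 0.6 /min  ->  L_dif = 100 um
#>   normalized f(r_tar = 10 um) = 1, truncated at r_max = 1000 um
#>   2001 radial nodes, f(r_max) = 2.28e-09

cfg <- scenario_config(strategy = strategy_preset("sgs"))
run_simulation(cfg, seed = 1)
#> Pursuit run: Q = 2 of 10 targets eliminated (2 contact events)

estimate_Q(cfg, N_runs = 2000, master_seed = 1)
#> Search efficiency Q = 2.612 +/- 0.020 (SE), 2000 runs, mixed ensemble

estimate_Q(scenario_config(strategy = strategy_preset("bls")),
           N_runs = 2000, master_seed = 1)
#> Search efficiency Q = 0.255 +/- 0.011 (SE), 2000 runs, mixed ensemble
```

The kernel summary confirms the 100 μm diffusion length of the standard
attractant parameters. The single run shows one spatial-gradient-sensing
searcher removing 2 of 10 targets in 100 min; averaged over 2000 seeded
runs its efficiency is Q ≈ 2.6 eliminated targets per run, an order of
magnitude above the blind searcher's Q ≈ 0.26 under identical conditions.

Trajectory diagnostics (`covered_area()`, `msd()`,
`nearest_target_distances()` with the `rayleigh_nn_density()` reference)
quantify how chemotactic steering localizes the searcher near its targets.
A command-line interface (`inst/cli/chemopursuit.R`) exposes `simulate`,
`efficiency`, `heatmap`, `optimize`, `stats` and `kernel` subcommands over
YAML configuration files.

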