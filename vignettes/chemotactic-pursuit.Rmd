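---
title: "Chemotactic pursuit: model, assumptions and design choices"
author: "chemopursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemotactic pursuit: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and the places where the design was genuinely open and a decision
had to be made.

## The system

A single immune-like searcher pursues `N_tar = 10` target cells on an
`L_sys = 1000` μm square with periodic boundaries, for `T_sim = 100`
one-minute steps per run. Targets move independently of the searcher and
of each other; each emits a chemoattractant that diffuses with
`D = 6000` μm²/min and decays at `k = 0.6`/min. Both cell types have a
10 μm radius. These values are held fixed throughout; they put the system
in a biologically motivated regime (natural-killer-cell scale searchers,
attractant parameters typical of small signaling proteins in water) where
the mean nearest-neighbor target distance (≈158 μm at density 10⁻⁵ μm⁻²)
slightly exceeds the attractant's diffusion length (100 μm), so the
searcher must genuinely *search* — the nearest cloud is detectable but
weak.

## Migration model

All agents are discrete-time correlated random walkers. Per step a cell
draws a Rayleigh step width with mean `v` (so `v` is the mean speed along
the contour), a turning magnitude uniform between persistence-dependent
bounds, and a turn sign. The persistence `eps` interpolates between
ballistic (`eps = 1`, zero turning), isotropic (`eps = 0`, turns uniform
on (−π, π]) and reversing (`eps = −1`) motion. Only the *magnitude* of
the turning draw enters the heading update; the sign is applied
separately, which is what lets spatial gradient sensing steer by biasing
the sign alone while leaving the turning-angle statistics untouched.

Two conventions needed fixing that the model statement leaves open:

* **Initial headings** are drawn uniformly per agent per run. The heading
  of the "previous step" is undefined at the first step; a uniform draw
  is the least informative choice and matches random initial
  configurations.
* **Heading storage.** The heading is carried in the agent state and
  updated additively rather than recomputed as the arctangent of the last
  displacement. The two are mathematically identical, but the stored form
  has no degeneracy when a step width of zero is drawn (`v = 0` agents
  still rotate).

## The attractant field

In the fast-diffusion limit — emitter speeds (≤6 μm/min) far below the
critical velocity `L_dif/T_dif = 60` μm/min — each target carries a fully
developed stationary cloud. Outside the emitter radius the radial profile
obeys the modified Bessel equation of order zero, and the package solves
it exactly as a boundary-value problem: fourth-order Runge-Kutta
integration (via deSolve) outward from `f(r_tar) = 1` on a geometric grid
of 2000+ nodes, with bisection on the unknown initial slope between
trials that cross zero and trials that diverge, until the tail at the
truncation radius lands in `[0, 1e-8]`. The closed form
`K0(r/L_dif)/K0(r_tar/L_dif)` is *not* used in the solver — it serves as
the independent oracle in the tests, which require agreement to 1e-4
relative over the working range.

Numerical choices:

* **Truncation** at `r_max = 10·L_dif`, where the profile has decayed to
  about 10⁻⁵ of its boundary value; beyond it the kernel is defined as
  exactly zero. The neglected contribution is far below Monte-Carlo noise
  in any efficiency estimate.
* **Interpolation** of the tabulated profile is log-linear in `f`, exact
  for an exponential tail; distances inside the emitter radius clamp to
  the boundary value (the searcher's center can never be closer to an
  emission point than `r_tar`, so this is a geometric impossibility
  region, not an extrapolation).
* **Caching.** The kernel depends only on `(D, k, r_tar, r_max, n_grid)`
  and is solved once per parameter set, then reused; per-step field
  evaluations are pure interpolation.
* **Tail slope.** The profile's log-slope approaches `−1/L_dif` only
  asymptotically: the `K0` law carries an algebraic `−1/(2r)` correction,
  and the enforced zero at `r_max` bends the numerical tail down within
  the last one to two diffusion lengths. Diagnostics that check the
  exponential tail therefore fit between 4.5 and 8 diffusion lengths,
  where both distortions are small.

The clouds of all live targets add linearly, with distances measured by
the minimum-image convention on the torus.

## Sensors and response

The searcher reads the total density at its center and forms the
temporal difference against the previous step's reading (defined as zero
on the first step, so the initial mode prior is `logistic(c_A0)`). Its
two lateral sensors sit on the cell border perpendicular to the
*previous* heading — sensing happens before the current step's turn. Mode
choice (`logistic(c_A0 + c_A1·Δρ^C)`) and turn-sign choice
(`logistic(c_R1·Δρ^LR)`) are independent, memoryless draws each step.

**Sign conventions.** With positive `c_A1`, rising concentration favors
the approach mode; with positive `c_R1` and a denser field on the right,
right turns are favored, i.e. the cell steers toward the attractant. The
source narrative contains two sentences attributing attraction to
*negative* coefficients; these contradict the formulas, the stated
non-negativity constraint on the temporal sensitivity, and the reported
optima (both sensitivities optimize to +500 with attracting behavior).
The package follows the formulas.

There is no detection threshold or receptor noise: arbitrarily small
concentration differences are sensed exactly. This is a deliberate model
assumption, and it means the guided strategies are upper bounds on what a
real cell could extract from the same geometry.

## Runs, contacts and efficiency

Each step advances, in order: (1) all live targets; (2) the searcher's
sensing and mode/sign decisions against the post-target-move field;
(3) the searcher's move; (4) contact detection. Contact is touching
disks — minimum-image center distance at most `r_imm + r_tar = 20` μm —
checked at step endpoints only. The probability that a 1-minute segment
of a fast searcher crosses a contact disk and exits again without the
endpoint registering is below 2·10⁻⁴ per step at `v = 6`, beneath
Monte-Carlo noise, so no segment-sweep test is performed. A contacted
target is removed immediately, together with its cloud (its emission has
no persistence in the fast-diffusion limit).

Initial placements are uniform; any target that would start within
contact range of the searcher is re-placed, so no run opens with a
zero-effort elimination. This choice (the alternative — counting initial
overlaps — is equally defensible) lowers every efficiency estimate by
about `N_tar·π(20 μm)²/L_sys² ≈ 0.013` eliminations per run, which is
within the tolerance of every quantitative check the package makes.

The search efficiency `Q` is the mean elimination count over independent
runs. Headline numbers use 10⁴ runs (Monte-Carlo SE ≈ 0.003–0.01
depending on the strategy); every report carries its standard error so
that scaled-down estimates remain interpretable. The seed protocol draws
one child seed per run from a master seed, making the run set
reproducible, order-independent, and embarrassingly parallel; the child
derivation uses R's own generator seeded by the master rather than a
counter-based hash, which is equally deterministic and keeps the
dependency surface at base R.

Two implementations of the run loop exist: a compiled engine (Rcpp) used
for Monte-Carlo estimation and a pure-R reference engine assembled from
the exported module operations. Both consume the RNG stream in the
identical order, so they reproduce each other's trajectories bit-for-bit
from the same seed — this equality is a standing regression test of the
compiled code against the readable one.

## The target ensembles as study conditions

The *mixed* ensemble — per target, per run: speed uniform on [0, 6]
μm/min and persistence uniform on [0, 1] — is the condition under which
strategies are optimized and the headline efficiencies quoted. It
emulates a searcher that cannot anticipate its targets' behavior. The
*pure* ensemble (all targets share one `(v_tar, eps_tar)`) produces the
versatility maps `Q(v_tar, eps_tar)`; the *static* ensemble pins targets
at prescribed coordinates for deterministic unit tests. What the
generator does **not** emulate: target-target interactions, evasion of
the searcher, heterogeneity within a run's lifetime (parameters are fixed
per run), finite attractant build-up after a target first appears, and
receptor-level noise. Passing tests therefore demonstrate correctness of
the model's mathematics and the qualitative strategy ordering — not that
real immune cells achieve these efficiencies.

## Strategy presets and the optimizer

The five presets encode the optimized parameter sets of the strategy
families: homogeneous blind search (`bls`: fast, perfectly persistent),
random mode switching (`rms`: blind, but the optimizer drives it into a
single fast persistent mode, confirming that spontaneous switching buys
nothing), temporal gradient sensing (`tgs`: run-and-tumble-like —
persistent approach in rising concentration, isotropic reorientation in
falling), spatial gradient sensing (`sgs`: always-approach steering with
persistence 0.8, a compromise between covering area and being able to
turn), and combined sensing (`cgs`: spatial steering plus a
temporal-gradient escape into a less persistent mode). The `sgs` bias
`c_A0 = 500` lies outside the nominal optimization range [−5, 5]; it is
accepted by the parameter validator as an explicit always-approach
override.

The optimizer is grid-based cyclic coordinate descent: scan one free
parameter's full grid holding the others at their incumbents, update to
the scan argmax, cycle, and stop when two *subsequent* sweeps return the
same vector (a single-parameter problem therefore converges on sweep
two). Ties keep the incumbent, otherwise the lowest grid index wins —
both choices make the trace deterministic. Because the objective is a
Monte-Carlo estimate, all nodes of a scan share the same per-run seeds
(common random numbers); differences between nodes then reflect the
parameters, not the noise, and the incumbent value is non-decreasing
across sweeps. Default grids: speeds in steps of 1, persistences in steps
of 0.1, bias in steps of 1, sensitivities over {0, 5, 50, 500} (mirrored
where negative values are admissible) — every known optimum lies on these
grids. The sweep cap is 20; reaching it flags the trace rather than
erroring.

## Trajectory diagnostics

Three statistics characterize *how* a strategy searches, beyond its `Q`:

* **Covered area** `A(t)`: the plane is tiled into 10 μm patches and the
  patch containing the searcher's center is marked each step. Marking the
  center only (no disk footprint, no segment rasterization) is
  sub-dominant because the patch size equals the cell radius.
* **Mean squared displacement** over lag time, computed on unwrapped
  coordinates with all overlapping origins. No blocking correction is
  applied to its uncertainty — it is a diagnostic, not an inferential
  statistic.
* **Nearest-target distance** per step (minimum-image), against the
  closed-form Rayleigh reference `p(d) = 2πρ d exp(−πρ d²)` that holds
  for uncorrelated uniform placements.

For these diagnostics the package provides an *observation* regime
(`remove_on_contact = FALSE`) in which contacts are recorded but targets
persist and keep emitting. The distinction matters: under instant
removal, a steering searcher consumes whatever it localizes at and then
travels to the next target, and these directed between-target legs
*raise* the long-lag MSD above the blinded control — the localization
signatures (reduced MSD, nearest-target mass piling up near zero) emerge
when binding can persist, i.e. exactly when finding a target does not end
the interaction. The package therefore computes efficiency in the
elimination regime and trajectory signatures in the observation regime,
and treats the regime switch as part of the experiment definition.

## Problem sizes used in the tests

The test suite estimates the headline efficiencies at the full 10⁴ runs
per strategy; versatility maps use 7×6 grids at 2×10³ runs per node
(node SE ≈ 0.007–0.03, sufficient for trend and corner comparisons, not
for per-cell values); optimizer recovery runs the blind-search family on
coarse grids (speeds step 1, persistences step 0.25) at 2×10³ runs per
evaluation with common random numbers. Distributional checks use 10⁶
direct draws where a closed form is available and 10–30 seeded runs for
trajectory-level orderings. Full seven-parameter optimization at
headline precision is supported by the API but is not exercised by the
tests; its cost is the product of grid size, runs per evaluation, and
sweeps, and the coarse-grid default reaches the known optima.

## Known limitations

* Geometry is strictly two-dimensional; no 3D extension.
* One searcher per run (`N_imm = 1`); multi-searcher statistics are
  approximated by independent runs, which cannot capture competition for
  targets or mutual avoidance.
* The attractant is always stationary (fast-diffusion limit); wakes
  behind fast emitters and finite build-up times require the
  time-dependent reaction-diffusion problem, which is out of scope.
* Periodic boundaries make perfectly ballistic searchers traverse
  periodic orbits over long times; within the 100-minute runs used here a
  maximal-speed cell covers 60% of the linear system size, so the
  artifact is negligible, but covered-area curves over much longer
  horizons should be read with care.
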