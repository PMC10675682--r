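---
title: "Methods: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the physical model behind `slitmicelle`, the
algorithmic choices made in implementing it, and the limits of both.
The package simulates the self-assembly of short amphiphilic diblock
copolymers (A5B5) in a selective solvent with dissipative particle
dynamics (DPD), in bulk and confined in a slit between two parallel
walls of tunable affinity, and provides the analysis chain from raw
trajectories to aggregate statistics, shapes, and density profiles.

## The DPD model

All quantities are in reduced units: lengths in the interaction cutoff
`r_c`, energies in `kT`, masses in the bead mass, time in
`tau = sqrt(m r_c^2 / kT)`.  Beads interact pairwise within `r_c`
through three forces:

* **Conservative**: `F^C = a_ij (1 - r) e_ij` — soft, purely repulsive,
  finite at contact, which is what lets coarse-grained beads
  interpenetrate and makes timesteps of 0.05 tau stable.
* **Dissipative**: `F^D = -gamma (1 - r)^2 (e_ij . v_ij) e_ij` — damps
  the radial component of the relative velocity only.
* **Random**: `F^R = sigma (1 - r) theta dt^{-1/2} e_ij`, with `theta`
  drawn once per pair per step, uniform on `[-sqrt(3), sqrt(3)]` (zero
  mean, unit variance), and shared by both partners so the pair forces
  cancel exactly and momentum is conserved.

The dissipative and random forces together form the thermostat; they
produce the canonical ensemble only when `sigma^2 = 2 gamma kT`.  The
package refuses to integrate an unbalanced interaction table
(`fdt_balanced()`), and the defaults `gamma = 4.5`, `sigma = 3`,
`kT = 1` satisfy the balance exactly.

Chains are harmonic-bond chains (`U = K/2 (r - r0)^2`, `K = 4`,
`r0 = 0`) of five solvophilic A beads followed by five solvophobic B
beads.  The bead density is `rho = 3`, at which the conservative
repulsion maps linearly onto the Flory–Huggins parameter:

```
a_ij = a_ii + 3.27 chi      (a_ii = 25)
```

implemented in `chi_to_a()` / `a_to_chi()`.  The default interaction
table sets all like pairs and A–solvent to 25 (athermal), and A–B and
B–solvent to 40 (`chi ≈ 4.59`, strongly selective): B blocks collapse
into micelle cores, A blocks form the corona.  For reference,
`chi = 1/2` (a theta-state solvent) corresponds to `a = 26.64`.

## Integrator

`dpd_run()` uses the modified velocity-Verlet scheme customary in DPD,
with velocity-prediction factor `lambda = 0.65`: positions advance with
the old force, forces are evaluated once per step at predicted
velocities `v + lambda dt f`, and velocities are corrected with the
average of old and new forces.  The single force evaluation per step is
what makes the scheme cheap; `lambda = 0.65` is the standard companion
to `gamma = 4.5` and `dt = 0.05` and holds the measured temperature
within a few percent of the target.  The engine is compiled (Rcpp) with
linked-cell pair search and falls back to an all-pairs sweep when a box
is too small for three cells per periodic dimension.  The thermostat
noise comes from a self-contained xoshiro256+ generator seeded
deterministically, so a run is bit-reproducible from its seed, and R's
own RNG stream is never touched by the integrator.

## Slit geometry

A slit of width `D` is periodic in y and z only.  Walls are realized by
three cooperating ingredients at `x = ±D/2`:

1. **Hard reflection**: a bead crossing a plane is mirrored back and its
   normal velocity inverted (energy conserving).
2. **A soft repulsive wall potential**
   `U(x) = (a_wall x_c / 2)(1 - x/x_c)^2` for wall distance `x < x_c`
   (`a_wall = 25`, `x_c = 1.2`), applied identically to every mobile
   species.  Because DPD conservative forces are soft, reflection alone
   would let the near-wall density pile up unphysically; the soft
   potential restores a smooth depletion at contact.
3. **Frozen wall beads**: a slab of immobile W beads of thickness 1 r_c
   and density 3 just outside each plane.  All chemistry of the wall is
   carried by these beads: the B–W repulsion `a_BW` is the single dial
   for wall affinity, with presets 30 (repulsive), 25 (inert, i.e.
   indistinguishable from solvent), 20 (weakly attractive) and 15
   (strongly attractive).  "Attraction" in a purely repulsive model is
   relative: a B bead at the wall trades `a_BS = 40` solvent contacts
   for cheaper wall contacts.

Note that a slit system does not conserve momentum — walls absorb it —
so the momentum-conservation checks in the test suite apply to bulk
runs only.

## Aggregates and adsorption

Two chains belong to the same aggregate when at least three pairs of
their B beads are within `r_c` of each other (minimum image in periodic
directions only).  Three contacts is strict enough that two chains
merely brushing coronas are not merged, and loose enough that any
share of a common core counts.  Aggregates are the connected components
of the resulting chain graph (igraph), so membership is transitive.
The same rule, turned toward the wall, defines adsorption: a chain with
three or more B beads within 1 r_c of a reflecting plane is
wall-contacting, and an aggregate containing at least one such chain is
adsorbed.  This deliberately references the *planes*, not the randomly
placed frozen beads, so the criterion is geometric and reproducible.

## Shapes

Aggregate shape comes from the gyration tensor of the unwrapped bead
positions, eigenvalues ordered `lambda_1^2 <= lambda_2^2 <= lambda_3^2`.
Unwrapping walks the minimum-image proximity graph of the aggregate
(BFS) and accumulates image shifts; an aggregate spanning more than
half a box length is ambiguous to unwrap and is flagged with a warning
rather than silently unwrapped.  Spheres show
`lambda_i ~ A_S^{1/3}` in all three eigenvalues (`fit_size_exponent()`),
rods grow only in `lambda_3^2 = L^2/12`, and the asphericity
`lambda_3^2 - (lambda_1^2 + lambda_2^2)/2` separates the two.  Core
(B-bead) and whole-aggregate (A+B) tensors are computed side by side.

## Distributions and profiles

Association numbers pooled over frames give the number and weight
distributions `F_n` / `F_w` with averages `An` and `Aw`.  Two detectors
extract the standard summary quantities, both operating on a 3-bin
moving average (the narrowest smoothing that removes single-bin
sampling noise without displacing features):

* `unimer_fractions()`: `f_1 = F_n(1)`, and `f_low` sums `F_n` up to
  the interior minimum between the unimer peak and the main associate
  peak.  The associate peak must be a genuine local maximum — a
  decaying unimer shoulder does not qualify — and when no interior
  minimum exists the function falls back to `f_1` with a warning.
* `split_main_tail()`: the main-peak/tail boundary of `F_w` is placed
  at the maximum of the discrete second derivative beyond the mode —
  the sharpest upward curvature where the peak's shoulder hands over to
  the tail.  For a pure symmetric peak this lands near mode + sqrt(3)
  standard deviations, leaving only the outer few percent of mass as
  "tail"; a genuine tail (rods, wall pancakes) is split off at its
  onset.

Density profiles histogram bead positions in 0.25 r_c bins and
normalize by slab volume and frame count, so the profile integral is
the mean per-frame bead count.  `directional_scan()` projects positions
onto an arbitrary direction and folds them on the shortest projected
lattice vector, which exposes lamellar ordering along oblique
directions.  `layer_count()` counts prominence-gated local maxima; peak
prominence is computed directly (height above the higher of the two
key saddles) with a default gate of 10% of the profile maximum, which
ignores sampling ripple without suppressing real layers.

## Planted fixtures

Every analysis stage is validated end to end on synthetic
configurations with known ground truth: `plant_micelle()` (uniform B
core, A shell), `plant_rod()` (cylindrical core), and
`plant_pancake()` (a disk pressed within the wall-contact cutoff, so
its adsorption label is guaranteed by construction).  Each object is
re-drawn on a deterministic retry schedule until it satisfies the
three-contact criterion as a single component, and `plant_scene()`
places objects on a jittered grid with enough clearance that distinct
objects can never share a contact — the planted partition is therefore
exactly recoverable, and the test suite requires exact recovery over
100 seeds.  These fixtures are idealized: they have no velocity
distribution, no corona–corona interpenetration, and no thermal
roughness, so they validate the analysis chain, not the physics.

## Scenario scale and known limitations

The full-scale study conditions (25^3 boxes, ~4.7×10^4 beads, 10^7-plus
steps) are far beyond a desk-scale test budget.  The bundled
`scenario()` presets use a 12^3 bulk box or a D = 10 × 12^2 slit at the
same bead density (3) and copolymer concentration (25.6%), with
2 × 10^5 steps (a quarter pre-equilibration).  At this scale the
thermostat, micellization, and wall-affinity trends are all clearly
visible, but two caveats apply:

* Aggregate statistics carry large fluctuations: a 12^2 wall holds only
  a handful of micelles, so single-seed coverage numbers scatter.
* Micelle migration to walls is slow compared to the run length.  Under
  strongly attracting walls the wall layer is visibly enriched and
  prominent near-wall density maxima appear, but the global B maximum
  can still sit mid-slit, whereas a fully equilibrated system at this
  affinity would be wall-dominated.  Conclusions at desk scale should
  therefore rest on local and comparative signals (wall-layer
  enrichment, adsorbed fractions), not on global profile shape.

```{r example}
library(slitmicelle)

# a desk-scale slit run with strongly attracting walls
tr <- run_scenario("slit-strong-attract", seed = 11)

# aggregate statistics pooled over production frames
aggs <- aggregate_trajectory(tr)
dist <- aggregate_distributions(aggs)
glance(dist)

# B-bead density across the slit and coverage of the walls
autoplot(slit_profile(tr))
wall_coverage(tr)
```
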