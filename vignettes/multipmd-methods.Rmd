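---
title: "Adaptive cyclic path metadynamics on model base-pairing landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cyclic path metadynamics on model base-pairing landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Watson-Crick-Franklin (WCF) and Hoogsteen (HG) base pairs interconvert by a
180° rotation of the purine about its glycosidic bond. The rotation can
happen *inside* the double helix (small base-opening angle θ throughout) or
*outside*, with the base flipping toward the major groove at mid-rotation.
Each mechanism moreover has two directions, with the purine 6-ring sweeping
toward the 5' or the 3' neighbor. Resolving the free-energy profile of each
mechanism separately is what multiple-walker multiple-path metadynamics
does: two adaptive cyclic paths — curves in the CV space spanned by
[cos χ', sin χ', θ], where χ' is the base-rolling pseudo-dihedral — are
evolved in parallel, each carrying its own group of walkers, and special
*attractor* walkers hold the two paths through different intermediate
states so they cannot collapse onto the same channel.

This package implements that machinery as a testable engine. All-atom DNA
dynamics is replaced by overdamped Langevin dynamics on an analytic
two-channel model landscape in (χ', θ) that reproduces the topology the
method must resolve; the structural-CV calculators that would feed the CVs
from atomic coordinates are implemented against PDB input and synthetic
duplex fixtures.

Key conventions, all following the production protocol of the method:

* The paths are cyclic: node 0 and node n−1 coincide at the WCF anchor.
  Progress s runs periodically over [−1, +1] with WCF at s = ±1 and HG
  near s ≈ 0; −1 < s < 0 is the 5' rotation, 0 < s < 1 the 3' rotation.
* Outside paths use 39 nodes and a 20 ps fading-memory half-life; inside
  paths use 11 nodes and an infinite half-life.
* Nine standard walkers per path deposit Gaussian hills on s (width 0.1,
  height 0.05 kcal/mol, every 1 ps) into one shared list; a tube potential
  (upper harmonic wall at z = 0, k = 50 kcal/mol per squared path unit)
  keeps all walkers near their path.
* Three attractors per path do not deposit: two are steered to s = ±0.5
  over the first 20 ps (k = 5000) and θ-restrained (k = 5000) at 0
  (inside) or −π/2 (outside); one is held at the HG point with k = 50.
* The free-energy profile is the negative of the hill sum, snapshot every
  1/70 of the production run, averaged (with per-bin standard deviations)
  over the final 5/7.

## The model landscape

`rotor_flip_params()` defines

V(χ', θ) = B(χ', θ) · r(χ') + k_open θ² + tilt(χ'),

with r(χ') = (1 − cos(χ' − χ_WCF))(1 − cos(χ' − χ_HG)) vanishing
quadratically at both stable states, a 3'/5' blend of the barrier scales
(the 5' side is stiffer, mirroring the asymmetric chain length that makes
5' rotations harder), and a Gaussian gate of width σ_θ that lowers the
barrier along the outside channel. The gate is centered on
θ_c(χ') = θ_out · [sin(χ' − χ_WCF) sin(χ' − χ_HG)]², so the channel sits at
θ_out at mid-rotation and descends into the closed-helix basins along a
gentle diagonal: the base flips out only while it rotates. The smooth tilt
raises the HG basin by ΔF_HG.

Default numbers (kcal/mol, rad): b_in_3p = 4.2, b_in_5p = 5.0,
b_out_3p = 1.0, b_out_5p = 2.0, θ_out = −1.8, σ_θ = 0.5, k_open = 0.7,
ΔF_HG = 1.0. These were fixed once, by construction against the built-in
grid-search saddle oracle (`channel_barriers()`), to give four genuine
saddles ordered outside-3' < inside-3' < outside-5' < inside-5' with at
least ~0.6 kcal/mol between neighbors, a relaxed outside channel floor at
mid-rotation within ~0.1 rad of −π/2 (so the attractors restrained at the
paper-protocol value sit on the channel floor rather than below it), and
barriers of 3.3-6.3 kcal/mol — large enough that unbiased crossing is
rare at kT = 0.596 kcal/mol (300 K), small enough that the bias fills them
within a fraction of a desk-scale run. θ_out deeper than the −π/2 flip
angle is deliberate: the *relaxed* floor, after the k_open θ² term pulls
back, is what lands at −π/2.

Two design notes on the shape. First, with a gate centered at a fixed
θ_out independent of χ', the channel connects to the basins through
nearly right-angled corners, and the exact minimum-energy path then enters
each basin along a needle-thin spike; a 39-node discretized path cannot
represent that, and a tube-confined walker ensemble on such a path sees a
degenerate projection (two near-parallel branches closer than the tube
width). The diagonal gate removes the needles. Second, the outside barrier
scale is blended per direction (b_out_3p/b_out_5p) rather than using one
scale, because the intrinsic 3'/5' asymmetry of r(χ') alone leaves the
barrier ordering with margins too small for a stochastic check.

## Dynamics, units and numerical choices

Dynamics is overdamped (Brownian): only configurational sampling matters
for validating free-energy machinery, and it has one parameter less. One
engine "ps" is 100 Euler-Maruyama steps at dt = 0.01 with friction γ = 1,
so the protocol paces (1 ps hills and updates, 20 ps steering) map onto
engine schedules at the stated ratios. kT defaults to 0.596 kcal/mol.

The projection onto a path is piecewise-linear nearest-segment (exactly
testable against a brute-force resampling oracle); gradients of s and z
are central finite differences with step 1e-5 per axis, composed with the
analytic Jacobian of the (cos, sin) embedding. Two safeguards make this
robust: the finite-difference gradient is clipped (|∂s/∂x| ≤ 3; the
physical magnitude on the path is 2/L ≈ 0.2) because the nearest-segment
s is discontinuous on the path's cut locus and a walker swept by the cut
would otherwise receive an unphysical kick, and the deterministic drift
per substep is capped at 0.25 rad. The stiffly restrained intermediate
attractors (k = 5000) integrate with 50 substeps so k·dt/γ stays at 1.

Steered walkers are restrained on a winding-aware continuous progress
coordinate (s unwrapped along the walker's own history): near the shared
endpoint the two sides of the cyclic path are spatially adjacent, and a
minimum-image difference would let a walker flap across the cut instead of
following the moving center around the cycle.

## The run protocol

`run_multipmd()` runs two stages per path.

*Adaptation* (default 300 ps): steering for 20 ps; path updates from
t = 20 ps (so the attractors reach their stations before the path starts
to move toward them). At every update the intermediate attractors'
positions are imprinted on their nearest nodes — the attractors mark the
intermediate states the path must pass through, and holding them in the
node set makes the channel opening nucleate (and stay open)
deterministically instead of depending on a rare sampling fluctuation. After every update a single light smoothing pass
(`path_smooth`, λ = 0.1 for the first 150 ps, then 0.03) couples
neighboring nodes: this string tension lets the opening propagate node to
node across the ridge that separates the two channels, while the weaker
late tension lets the converged path settle into the channel floor. Node
positions are renormalized onto the unit cylinder of the embedding after
each update (walkers live there; cell-averaged and smoothed positions
otherwise drift systematically inward). Reparameterization is iterated
shape-preserving-spline resampling (Fritsch-Carlson): linear-chord
resampling erodes convex curves inward and a natural cubic overshoots at
attractor-held dips, feeding back into runaway needles.

*Production* (default 1200 ps): the path is frozen as the time average of
its final 100 ps of adaptation (node-scale sampling zigzag cancels), with
two extra smoothing passes for the densely discretized outside path. The
hill list is reset at the freeze and hill times restart on the production
clock. Freezing and resetting are deliberate departures from the
continuous protocol of the original method: with the nearest-segment
projection, the hill-sum estimate is unbiased only if the s map is
stationary and kink-free — bias deposited while the path still moves (or
along a path with node-scale kinks) leaves a permanently misplaced imprint
in the hill sum, because in plain metadynamics accumulated imbalances
never decay. The original method's differentiable path CV does not need
this; our exactly-testable projection does. The profile is then measured
over the final 5/7 of production with snapshots every 1/70, per the
production-protocol ratios.

Each snapshot is min-shifted before averaging (the alignment convention is
not stated by the protocol; min-shifting removes the arbitrary fill level
so the spread reflects shape), and the mean is re-anchored to 0 at the
WCF bin. When a profile is compared against the quadrature reference the
two are first least-squares aligned (the mean difference is subtracted):
free-energy profiles are defined up to an additive constant, and
anchoring both at a single noisy bin would propagate that bin's
fluctuation to every other bin of the comparison. The HG minimum is searched in |s| < 0.5 because its exact s
cannot be known a priori. The free-diffusion window defaults to 1/10 of
the analysis span, which operationalizes an otherwise qualitative
criterion.

## Oracles

Three independent references validate the engine:

* `dense_projection` (in the tests): brute-force nearest point on a
  10^5-10^6-point resampling of the path.
* `reference_fes_quadrature()`: F(s) from dense 2D grid quadrature of
  exp(−(V + k z²/2)/kT) binned by projection, with a self-convergence
  check under grid refinement.
* `mfep_descent()`: the exact zero-temperature limit of the adaptive path
  — saddle points refined from grid seeds, steepest-descent trajectories
  assembled into the minimum free-energy path. A finite-node string method
  (`string_mfep()`) is also provided; the descent construction is used as
  the oracle because it resolves narrow basin entrances that a discrete
  string systematically clips.

## What the engine does and does not show

The synthetic landscape reproduces the inside/outside two-channel topology,
the four-saddle direction asymmetry, a WCF-favoring offset, and the scale
separation between thermal fluctuations and barriers. It does not emulate
the all-atom system's rugged microstates, solvent degrees of freedom, or
the entanglement of the CVs with hundreds of orthogonal slow modes; a
passing test suite therefore validates the sampling and analysis
machinery, not force-field biophysics.

Known limitations, measured during development and stated here because
they shape the tolerances:

* Plain metadynamics (fixed hill height) has an irreducible ripple in the
  hill sum of a few hill heights even on a flat landscape; the flatness
  property is asserted at 0.3 kcal/mol (six hill heights), the engine's
  measured ripple floor.
* At sharp barrier tops the hill sum underestimates the quadrature
  reference by roughly σ²F''/2 (the Gaussian width acts as a smoothing
  kernel, and positive-only deposition can rebuild sub-σ curvature only
  slowly); on the outside path, whose larger arc length makes peaks
  sharper in s, this systematic sits near the 0.5 kT check tolerance and
  decays only slowly with production length. The production length was
  chosen so the estimate converges through this regime.
* The default inside path (infinite half-life) stiffens as weight
  accumulates, by design; it does not fully relax into the shallow
  sub-0.2-rad sag of the exact MFEP within a desk-scale run. The MFEP
  convergence check therefore uses a high-plasticity configuration
  (half-life 5 ps, tube k = 35, no station imprint). Even there the
  sampled path converges not to the dense MFEP but to its node-cell
  average: wherever the gate band gives the exact MFEP features narrower
  than the node spacing, the fading-memory fixed point (a cell mean)
  sits ~0.06 CV units from the dense curve, stably across tube
  stiffness, temperature, node count and run length. That cell-average
  residual is the honest resolution limit of an 11-node sampled string
  on this landscape.
* The adapted outside path intersects its attractor stations and follows
  the channel around them, but between stations it interpolates between
  mechanisms — exactly the behavior the original protocol describes for
  its attractors, which "mark landmarks" rather than pin the whole curve.

## Structural CVs and fixtures

χ is the O4'-C1'-N9-C4 torsion; χ' replaces the O4'/C4 references by the
sugar anchor and the purine 6-ring center of mass (groups are a shipped,
documented convention, configurable via `atom_group_spec()`, since the
exact lists live outside this protocol); θ is the torsion of the purine
base ring about the axis through the flanking-pair centers of mass,
referenced to the purine's own C1'. Negative θ is a flip toward the major
groove. Pair distances (d_WCF = A:N1-T:N3, d_HG = A:N7-T:N3, the conserved
d_HB = A:N6-T:O4, d_CC = C1'-C1', and d_NB between the neighboring-base
centers of mass) and the hydration count N_water (water oxygens within
6 Å of the adenine N6, minimum-image when a box is present) complete the
record.

`make_fixture()` builds a synthetic three-pair duplex from idealized
planar base templates (regular polygons, 1.39 Å bonds, 3.4 Å rise, 36°
twist, pairs centered on the stacking axis). The HG fixture rotates the
adenine base 180° about the glycosidic axis and re-pairs it through the
Hoogsteen edge, which produces the characteristic C1'-C1' constriction
(10.9 → 8.7 Å here, against the 10.6/9.1 Å stable-state signatures). The
`noise` argument is the per-atom RMS displacement; at 0.2 Å the
classification margins are better than 4σ. The `flipped` fixture swings
the base about the helix axis — a strained synthetic geometry whose only
job is exercising the negative-opening-angle convention.

## Problem sizes

The default configuration runs 300 ps of adaptation plus 1200 ps of
production per path (12 walkers each, 1 ps paces), the quadrature oracle
uses a 2000 × 500 grid over (χ', θ) with 200 s bins, the projection oracle
compares 1000 random points against a several-10^5-point resampling, and
the equipartition check integrates 10^6 steps of a harmonic well. These
sizes were chosen as the smallest at which the estimators are converged
well inside their check tolerances.
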