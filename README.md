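# multipmd

Multiple-walker multiple-path metadynamics on model base-pairing
landscapes.

Watson-Crick-Franklin (WCF) and Hoogsteen (HG) base pairs interconvert by
a 180° rotation of the purine about its glycosidic bond, either *inside*
the double helix or *outside*, after flipping toward the major groove —
and in either the 5' or the 3' direction. Resolving the free-energy
profile of each mechanism separately requires sampling machinery that can
hold several transition channels apart while measuring along each one.
This package implements that machinery as a self-contained, testable
engine:

* **Adaptive cyclic path collective variables** — curves in the CV space
  [cos χ', sin χ', θ] (χ' the base-rolling pseudo-dihedral, θ the base
  opening) with periodic progress s ∈ [−1, +1], WCF anchored at s = ±1 and
  HG near s ≈ 0; nearest-segment projection (s, z), fading-memory node
  updates, spline reparameterization.
* **Shared-bias metadynamics** — per path, nine standard walkers deposit
  Gaussian hills on s (width 0.1, height 0.05 kcal/mol, every 1 ps) into
  one shared list; a tube potential (k = 50) confines all walkers near
  the path; attractor walkers steered to s = ±0.5 (k = 5000, 20 ps) and
  θ-restrained at 0 (inside) or −π/2 (outside) keep the two mechanisms
  apart, and an HG attractor (k = 50) marks the rotated state.
* **Overdamped Langevin dynamics** on an analytic two-channel rotor-flip
  landscape whose four saddles order as outside-3' < inside-3' <
  outside-5' < inside-5', standing in for all-atom DNA.
* **Free-energy analysis** — F(s) as the negative hill sum, snapshot
  averaging with error bars, direction-resolved barrier and ΔF(WCF→HG)
  extraction, a free-diffusion diagnostic, and least-squares trend fits
  of barriers against structural descriptors.
* **Independent oracles** — dense 2D quadrature of the biased Boltzmann
  weight (`reference_fes_quadrature`), the exact steepest-descent minimum
  free-energy path (`mfep_descent`), a finite-node string method
  (`string_mfep`), and a grid-search saddle finder (`channel_barriers`).
* **DNA structural CVs** — χ (O4'-C1'-N9-C4), the center-of-mass
  pseudo-dihedrals χ' and θ, pairing distances (d_WCF, d_HG, d_HB, d_CC,
  d_NB), hydration counts, a WCF/HG classifier, and a synthetic
  three-pair duplex fixture generator, with PDB input/output.

## Worked example

```r
library(multipmd)

run <- run_multipmd(multipmd_config(), seed = 1)   # ~12 minutes on one CPU
run
#> multipmd_run: 2 path(s), 1200 ps, seed 1
#>   inside: 11 nodes, 10809 hills, 12 walkers
#>   outside: 39 nodes, 10809 hills, 12 walkers

cfg <- run$config
prof <- averaged_profile(run$paths$outside$hills,
                         cfg$total_ps * 2 / 7, cfg$total_ps,
                         cfg$total_ps / 70)
extract_barriers(prof)
#> barriers: 5' 5.02 (s = -0.45), 3' 3.36 (s = 0.47) kcal/mol
#> WCF -> HG: 0.965 kcal/mol at s = 0.025
```

The run adapts an inside and an outside cyclic path from the same no-flip
initial guess (the attractors pull the outside path into the flipped
channel, θ ≈ −π/2 at mid-rotation, while the inside path stays near
θ = 0), then measures metadynamics profiles along the frozen adapted
paths. The barrier summary above reads: rotating the purine through the
flipped-out channel costs ~3.4 kcal/mol in the 3' direction and
~5.0 kcal/mol in the 5' direction on the default landscape, and the HG
state sits ~1 kcal/mol above WCF — which matches the landscape's
constructed saddle heights (`channel_barriers()`) and the quadrature
reference (`reference_fes_quadrature()`) along the same path.

A thin command-line front end over the same functions ships in
`inst/cli/multipmd.R`:

```sh
Rscript inst/cli/multipmd.R run --config run.yaml --seed 1 --out out/
Rscript inst/cli/multipmd.R analyze --hills out/HILLS-outside.dat \
        --from 343 --to 1200 --every 17
```

## Documentation

The methods vignette (`vignettes/multipmd-methods.Rmd`) describes the
model landscape and its calibration, the run protocol (adaptation stage,
frozen-path production, hill reset), the numerical safeguards around the
piecewise-linear projection, the oracles, and the engine's known
limitations.
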