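# memperm

Membrane-permeation trajectory analysis and umbrella-sampling free-energy
profiles for lipid bilayer simulations, in R.

Small amphiphilic molecules — phthalate plasticizers (DMP, DBP, DEHP) are
the motivating family — partition into phospholipid membranes, change
their structure, and cross between leaflets. Quantifying that requires a
standard battery of analyses on MD output: membrane observables (area per
lipid, thickness, deuterium order parameters `Scd = ½⟨3cos²θ − 1⟩`,
tilt-angle and density profiles), solute configuration statistics (the
permeation coordinate `dz`, ring orientation θ, side-chain angle α, 2D
free-energy surfaces `F = −kBT ln(P/Pmax)`, insertion/translocation
events, aggregation), solvation and dynamics (RDFs `g(r)`, geometric
hydrogen-bond counts, lateral diffusion `D = ¼ d⟨Δr²_xy⟩/dt`), and the
potential of mean force `F(z) = −kBT ln ρ(z)` assembled from
umbrella-sampling windows by a self-consistent **WHAM** solver with a
barrier decomposition (entry barrier ΔG1, partitioning free energy ΔG2,
midplane barrier ΔG3).

`memperm` implements all of that, plus a synthetic-data module — a
coarse bilayer generator and a biased overdamped-Langevin sampler on
analytic potentials — so every estimator is validated against known
ground truth. It reads GRO/PDB structures, uses a plain-text trajectory
container, and ships a thin CLI (`inst/scripts/memperm.R`) with
`generate`, `analyze` and `wham` subcommands.

## Worked example

Sample 36 umbrella windows (centres 35 → 0 Å, 1 Å apart, the usual
water-to-midplane ladder) on a model landscape with a 2.14 kcal/mol
interfacial entry barrier and a 5.0 kcal/mol interfacial well, run WHAM,
anchor the profile to the bulk-water plateau, and decompose the barriers:

```r
library(memperm)

pot <- potential_spec(heights = c(2.14, -5.0, -4.0),
                      centers = c(20, 12, 0), widths = c(2, 2, 3))
w <- generate_langevin_windows(pot, window_centers(35, 0, 1),
                               force_constant = 2.39, temperature = 303.15,
                               dt = 0.005, n_steps = 4e5, seed = 1)
profile <- anchor_pmf(wham(w), c(30, 35))
extract_barriers(profile)
#> <barrier_report> entry dG1 = 2.197, partitioning dG2 = 4.900,
#>   midplane dG3 = 0.956 kcal/mol; minimum at z = 12.10 A
```

The recovered barriers sit within sampling error of the constructed
2.14 / 5.0 / 1.0 kcal/mol landscape, and the favourable position at
`dz ≈ 12 Å` is the headgroup–tail interface. Membrane observables come
from the generator the same way:

```r
g <- generate_bilayer_trajectory(bilayer_params(n_frames = 100, seed = 2))
mean(area_per_lipid(g$trajectory, 64)$value)   # 68.0625 (exact: 66 x 66 A box)
mean(bilayer_thickness(g$trajectory)$value)    # 37.998  (target 38 A)
```

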