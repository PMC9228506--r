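---
title: "Analysing small-molecule membrane permeation with memperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing small-molecule membrane permeation with memperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

## The scientific problem

Small amphiphilic pollutants — phthalate diesters (DMP, DBP, DEHP) are the
motivating case — partition spontaneously into phospholipid bilayers, and
both their permeation thermodynamics and their effect on the membrane are
standard questions for molecular-dynamics studies of POPC bilayers.
`memperm` implements the complete analysis layer for such studies:

* **membrane observables** — area per lipid, bilayer thickness, deuterium
  order parameters, tilt-angle distributions, component density profiles;
* **solute configuration** — the permeation coordinate `dz` (signed
  z-distance between the solute ring's centre of mass and the bilayer
  centre of mass), the ring orientation angle θ, the side-chain opening
  angle α, 2D free-energy surfaces over (dz, θ), insertion and
  midplane-translocation events, and aggregation analysis;
* **solvation and dynamics** — radial distribution functions, geometric
  hydrogen-bond counting, and lateral diffusion coefficients from
  mean-squared displacement;
* **free energies** — a from-scratch weighted histogram analysis method
  (WHAM) that turns umbrella-sampling windows into a potential of mean
  force (PMF), anchored to the bulk-water plateau, with a barrier
  decomposition ΔG1 / ΔG2 / ΔG3.

It does **not** run molecular dynamics.  A synthetic-data module generates
bilayer configurations and biased overdamped-Langevin window series with
*known ground truth*, so every estimator in the package is validated as
parameter recovery rather than against opaque reference outputs.

## Units and conventions

Coordinates and distances are Angstrom, times ns, energies kcal mol⁻¹,
temperatures K, with `kB = 0.0019872041` kcal mol⁻¹ K⁻¹ (GRO files, which
store nm, are converted on read and write).  Boxes are orthorhombic only;
triclinic input is rejected explicitly.  The bilayer normal is the z axis.
Molecules split across the periodic boundary are made whole by
minimum-image reassembly anchored at the molecule's first atom — a
deterministic, documented rule — before any centre of mass is taken.
Centres of mass are mass-weighted by default; geometric centres are
available via `mass_weighted = FALSE`, since analyses of ring positions
are sometimes reported either way.

## The data model

A `topology` is an ordered atom table (name, residue, mass, role tags)
plus contiguous molecule ranges; a `frame` holds positions, the box and a
time stamp; a `trajectory` binds a topology to time-ordered frames and an
`unwrapped` flag.  Role tags (`lipid_P`, `sn1_chain`, `ring`,
`carbonyl_O`, `water_O`, ...) come from a fixed vocabulary and decouple
every analysis from force-field atom naming: a YAML config mapping roles
to atom names (`apply_role_config()`) is all that is needed to adapt to a
new naming scheme.  Selections (`selection_spec()`) AND-combine molecule
type, atom name, role and residue filters; an empty spec is an error
rather than "select all", and a selection that matches nothing raises an
error naming the spec — silent empty analyses are impossible.

Trajectories travel on disk as a plain-text directory (`meta.json`,
`atoms.csv`, `molecules.csv`, `times.dat`, `boxes.dat`, `positions.dat`
with frame-major rows), chosen over binary formats so fixtures and results
stay inspectable and diffable; GRO/PDB single-frame I/O covers structure
exchange with MD tooling.

## The synthetic bilayer and what it does (not) emulate

The lipid model is one phosphate bead, one choline bead, one glycerol
bead and two straight 8-bead tails — the minimum that supports P–N tilt,
per-chain order parameters, thickness and lateral diffusion.  Defaults
mirror a standard fluid-phase POPC patch: 64 lipids per leaflet at
68.0625 Å² per lipid (a 66 × 66 Å box), phosphate-plane separation 38 Å,
chain order parameter 0.2, lateral diffusion 0.01 nm² ns⁻¹ (1 × 10⁻⁷
cm² s⁻¹, the fluid-phase order of magnitude), P–N tilt 72° ± 10° from the
normal, 0.5 Å positional jitter, 200 frames at 0.1 ns.

Chain orientations are drawn per frame from a Maier–Saupe distribution
`p(cosθ) ∝ exp(λ P₂(cosθ))` with λ solved numerically so that ⟨P₂⟩ equals
the requested order parameter *exactly*; each chain is straight within a
frame, so the measured central-difference order parameter recovers the
target without geometric bias.  Area per lipid is exact by construction
(lipids tile a lattice whose cell is the target APL); lateral motion is a
per-lipid 2D random walk with the requested diffusion constant, kept
unwrapped.  Solutes (6-bead ring, two side chains of 1/4/8 beads for the
three species templates) are placed by per-frame draws of (dz, θ, α),
uniformly in the plane or clustered within 6 Å of a seed solute.

What this emulates is *geometry with known statistics* — enough to
validate every estimator.  What it does not emulate: chain conformational
correlation in time, realistic water structure, electrostatics,
force-field energetics, or coupling between observables.  A passing test
therefore certifies the *estimator*, not any claim about real bilayers.

## Order parameters, tilt and densities

The deuterium order parameter is `Scd = ½⟨3cos²θ − 1⟩`, with θ the angle
between a chain vector and z.  With no hydrogens in the model, the chain
vector for carbon *i* is the heavy-atom central difference *i−1 → i+1* —
the standard united-atom surrogate; terminal carbons fall back to their
single adjacent bond and are flagged.  `Scd` is 1 for perfect alignment,
0 for isotropy (and at the magic angle `acos(1/√3) ≈ 54.74°`), −0.5 in
the membrane plane.  Thickness is the |Δz| of the two leaflet phosphate
centres of mass (a z-projection by definition); leaflets are assigned per
frame by phosphate z against the phosphate centre of mass, and a frame
with all phosphates on one side yields 0 with a warning rather than an
error, so degenerate inputs remain inspectable.  Tilt histograms default
to 1° bins on [0°, 180°]; density profiles report mass per slab volume
and conserve the selected mass exactly when the bins cover the support.

## Solute angles: two conventions for θ

"The orientation of the ring against z" has two natural readings, and
they disagree: for a ring lying flat in the membrane plane the in-plane
(para) axis makes 90° with z while the ring-plane normal makes 0°.
Because flat-lying rings are conventionally described as θ ≈ 90°,
`ring_angle_theta()` defaults to the para-axis convention (ring atom 1 →
atom 4, folded to [0°, 90°] since the axis is unsigned) and offers
`plane_normal` (SVD-fitted) as an option rather than guessing a single
intent.  α is simply the angle between the two side-chain vectors, in
[0°, 180°].

## Events: insertion, translocation, aggregation

Insertion is defined operationally — the first frame from which
`|dz| < threshold` persists for at least `persistence` frames — with
defaults of 20 Å (≈ the phosphate plane) and 10 frames; both are
configurable and recorded, since no universal criterion exists.
Midplane translocations are counted with a hysteresis band (default
±5 Å): only excursions that reach the *opposite* band count, so midplane
chatter never inflates the count.  Aggregation uses single-linkage
components of the minimum-image minimum atom–atom distance graph at a
6 Å first-contact cutoff; a solute's insertion mode is "single" or
"clustered" according to its cluster size at its insertion frame.
Analysis windows generalise "after all solutes have inserted" to frames
after the latest insertion frame, with a fixed-window override.

## RDF, hydrogen bonds, diffusion

`rdf()` histograms minimum-image pair distances and normalises by exact
spherical-shell volumes times the instantaneous partner density (boxes
may fluctuate), excluding self pairs; an ideal gas gives g = 1 at every
r, and `r_max` beyond half the smallest box edge is an error.  Hydrogen
bonds use the standard geometric criterion — H···A ≤ 2.5 Å and D–H···A
angle ≥ 150° by default, both configurable and logged — because a
distance peak alone (the ~1.8 Å first-shell signature) does not fix an
operational definition.  Lateral diffusion averages the xy mean-squared
displacement over particles and *all* time origins (computed exactly via
the FFT autocorrelation identity), fits a straight line over a lag window
defaulting to 10–50% of the maximum lag (short lags are ballistic-biased,
long lags noise-dominated), and reports `D = slope/4` in cm² s⁻¹.
Wrapped trajectories are rejected: displacement across a wrapped boundary
is meaningless.

## Umbrella sampling and WHAM

The window generator integrates the overdamped Langevin equation
`z ← z − (dt/γ) d/dz[U(z) + ½k(z−c)²] + √(2kBT dt/γ) ξ` on an analytic
sum-of-Gaussians potential, with friction γ = 1 kcal mol⁻¹ Å⁻² ns (only
kBT/γ matters).  A stability gate requires the maximum drift per step to
stay below half the per-step thermal displacement and reports the largest
admissible `dt` otherwise.  Because the potential is analytic, the exact
PMF is available by quadrature (`exact_pmf()`), giving a ground truth the
WHAM estimate must recover.

`wham()` solves the standard self-consistent equations for harmonic
biases, iterating until `max|Δf_i|` falls below 10⁻⁶ kcal mol⁻¹ (at most
10⁵ iterations), on 0.2 Å bins spanning the window centres padded by 2 Å.
Bins with fewer than 10 samples are reported as *undefined*, never
zero-filled; adjacent windows that share no occupied bin abort with an
error naming the gap, since a disconnected profile is meaningless.  An
unbiased window (k = 0) degenerates correctly to Boltzmann inversion.
Profiles are anchored so the bulk-water plateau (default dz ∈ [30, 35] Å)
has zero mean; anchoring is idempotent and gauge-invariant.  Statistical
errors are available on request via a Bayesian bootstrap (Dirichlet
weights over every window's samples, 50 resamples by default, off by
default).  Only harmonic biases are supported, there is no symmetrisation
across leaflets, and the barrier decomposition reads, from the anchored
profile: ΔG1 = the highest point in the interfacial search region
(default [15, 30] Å; floored at zero for monotone profiles), ΔG2 = depth
of the global minimum below water, ΔG3 = midplane value minus the
minimum.  The region defaults are configurable because published
profiles locate the entry barrier "at the interface" without printing
region bounds.

A note on force-constant units: umbrella force constants quoted in
kcal mol⁻¹ nm⁻² convert as 1000 kcal mol⁻¹ nm⁻² = 10 kcal mol⁻¹ Å⁻²,
which is soft for 1 Å window spacing; the conversion is honoured as
written rather than silently "corrected".

## Validation sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen so that
statistical noise sits well below each tolerance while a full run stays
in the minutes range on one CPU: 36 windows (centres 35 → 0 Å, 1 Å
apart, k = 2.39 kcal mol⁻¹ Å⁻², 303.15 K) at 4 × 10⁵ steps of
dt = 0.005 ns per window — 500 ns-equivalent sampling per window — which
puts the WHAM-vs-exact RMS at 0.05–0.16 kcal mol⁻¹ across seeds, safely
inside the 0.25 kcal mol⁻¹ acceptance bound; 128 × 2000-step random
walks for diffusion; 10⁵ orientation draws for order-parameter averages;
and an ideal-gas RDF fixture sized so the innermost shell holds several
thousand counts.  Convergence of WHAM is monotone in the tolerance, and
sampling-size improvements are verified on the seed-averaged RMS (per
individual seed, a √2 error contrast is within realisation noise).

Degenerate inputs are handled explicitly rather than silently: coplanar
phosphates (thickness 0 + warning), zero-length tilt vectors (skipped
with a warning), empty histogram bins (NA), all-empty histograms,
non-commensurate window grids, unmapped hydrogens, and wrapped input to
MSD are all either flagged or errors.

## Known limitations

The synthetic bilayer has no temporal correlation in chain orientations,
so orientation autocorrelation analyses are out of scope; there is no
electron-density or form-factor profile, no curvature spectra, no H-bond
lifetimes, no finite-size correction to D, no MBAR/2D-WHAM, and no
permeability coefficient — the pipeline stops at the PMF and its
barriers.  PMF uncertainties from the bootstrap assume samples within a
window are exchangeable, which understates error for strongly correlated
series; decorrelate (stride) first if that matters.
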