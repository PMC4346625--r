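---
title: "Models and methods behind fibremetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibremetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibremetrics)
```

`fibremetrics` quantifies water-soluble one-dimensional supramolecular
polymers — benzene-1,3,5-tricarboxamide (BTA) stacks in particular — on three
scales: molecular order inside a simulated fibre (stacking distances, amide
dihedral helicity, hydrogen-bond persistence, per-monomer self-assembly
energetics), mesoscale shape from small-angle X-ray scattering (SAXS), and
equilibrium monomer-exchange kinetics from FRET mixing assays. Because public
trajectories for such fibres are rarely deposited, the package ships a
synthetic-data module that generates every input the analyses consume, with
known ground truth, so each stage is testable end to end.

## The coarse fibre model

A monomer is represented by a C3-symmetric template: six ring carbons forming
the aromatic core, and per arm a carbonyl carbon and oxygen, an amide
nitrogen with its hydrogen, and four side-chain beads reaching the configured
extended radius (34 Å, i.e. a 6.8 nm extended diameter). The amide torsion is
defined on the ring-carbon/ring-carbon/carbonyl-carbon/carbonyl-oxygen
quadruplet; the ideal builder places every one of the 3n dihedrals at the
configured value (default −140°, a P-helical register) by internal-coordinate
construction, and stacks cores on the z axis at exactly the configured
spacing (default 3.4 Å). Fibre "length" is the periodic repeat along z,
`n × spacing` — 48 monomers at 3.4 Å give 16.3 nm. Only this periodic
convention is used anywhere; a gap-counting convention (47 gaps) would give
15.98 nm and is not offered.

The donor N–H of each arm is positioned directly beneath the arm's ideal
carbonyl oxygen so that, in the stacked register, the next monomer's oxygen
sits 3.0 Å above the donor with a near-linear N–H···O geometry. Monomers are
stacked without azimuthal twist: a twist would rotate acceptor oxygens away
from the built-in donor register, and no analysis in the package consumes
twist. All atoms carry partial charges (each arm is net neutral), 12-6
Lennard-Jones parameters chosen so the 3.4 Å stacking register sits near the
potential minimum, intrinsic Born radii, and van der Waals radii; these
travel with the topology and with its sidecar CSV on disk.

## What the trajectory generator emulates — and what it does not

`perturb_trajectory()` emulates the statistical structure of a relaxed
fibre, not its physics:

* axial spacing jitter — Gaussian with `stacking_sigma`, centred per frame
  so the gaps sum exactly to the periodic box;
* helicity mixture — each amide independently redraws its state per frame
  from the configured P/M/flipped fractions (clamped Gaussians inside
  [−180°, −90°], (−90°, 0°) and (0°, 180°]), and the carbonyl oxygen is
  repositioned by internal coordinates;
* folding — axial compression of the box to `fold_factor ×` the initial
  length, combined with a closed-loop helical lateral offset whose chord
  restores the three-dimensional intercore spacing to the configured value.
  Monomer planes tilt with the local fibre tangent, so the hydrogen-bond
  register follows the bend. `contraction()` of a generated trajectory
  therefore returns exactly `100 × (1 − fold_factor)`.

Features of real relaxation MD that are deliberately absent: no steric
relaxation (dihedral states are drawn independently, so mixed-helicity
frames can place carbonyls of adjacent monomers unphysically close), no
force field, water, or thermostat, no secondary-folding pathway (compression
plus bend stands in for it), and only a partial coupling between dihedral
state and geometric hydrogen-bond breakage — M-state carbonyls can remain
within the distance cutoff of the donor. Persistence statistics are
therefore driven by `generate_hbond_occupancy()`, which draws per-frame
Bernoulli presence at configured occupancies; passing tests show the
analyses recover constructed truth, not that the generator reproduces real
fibre dynamics.

All randomness flows from one integer seed through a per-generator stream
(a hash of seed and purpose tag), so each generator is independently and
bit-exactly reproducible.

## Structural order metrics

Intercore distances are consecutive core-centroid distances with
minimum-image wrapping along z only (the fibre is periodic only along its
axis), including the wrap-around spacing — n distances for n monomers. The
radial distribution function histograms all core–core distances up to
`r_max` (default bin 0.1 Å), normalized by spherical-shell volume and a
reference density so an uncorrelated arrangement averages to one. Because
fibre cores are not homogeneous in three dimensions, the default reference
density `n / (box_z · π · r_env²)` (with `r_env` the maximal lateral core
extent plus `r_max`) is a convention; peak-height comparisons between two
fibres are valid whenever the same convention is applied to both, and an
explicit `density` argument is available. `first_peak()` breaks ties toward
smaller r.

Helicity classification: P for dihedrals in [−180°, −90°], M for
(−90°, 0°], flipped for positive angles; the boundaries −90° and 0° are
assigned to P and M respectively. The M window is inferred from the
requirement that P, M and flipped fractions of a fibre partition to 100%;
`helicity_fractions()` checks out at exactly 100 on every trajectory. The
mean dihedral is an arithmetic mean over the equilibrated window by default
(a circular mean is available via `circular = TRUE`); which of the two an
experimental report intends is usually ambiguous, and for angle
distributions confined to one half of the circle they differ little.

Hydrogen bonds use donor–acceptor distance < 3.5 Å and D–H···A angle > 120°,
common trajectory-analysis defaults; both are arguments. A persistent bond
is one present in strictly more than 95% of equilibrated-window frames
(`persistent_hbonds()`, strict threshold: occupancy exactly 0.95 is
excluded). Analyses default to the trailing 25% of frames as the
equilibrated window, mirroring the common practice of analysing the final
quarter of a relaxation run; the fraction is an argument everywhere.

Thickness has no unique definition for a folded fibre; `fiber_dimensions()`
reports twice the 5th–95th percentile envelope of side-chain bead radial
distances, which is a stand-in, flagged as such. Stable domains are maximal
runs of at least `min_run` (default 5) consecutive monomers strictly below
the fibre-mean energy; runs do not wrap the periodic boundary unless
requested.

## The energy engine

The engine implements MM-GBSA-style bookkeeping, not dynamics:

* gas phase: pairwise Coulomb (332.0636 kcal Å mol⁻¹ e⁻²) plus 12-6
  Lennard-Jones with Lorentz–Berthelot combining, all intra-monomer pairs
  excluded, truncated at a 10 Å cutoff with no switching and no Ewald
  correction — adequate for decomposition bookkeeping, documented as such;
* polar solvation: Still's pairwise generalized Born expression including
  self terms, over Hawkins–Cramer–Truhlar pairwise-descreening effective
  radii. The descreening integral uses a single global screening scale
  (default 0.8) and caps the effective radius of deeply buried atoms at
  30 Å; without these the dense coarse geometry over-descreens. A single
  ion reduces to the Born equation to better than 1e−9 relative, for any
  charge, radius and dielectric pair. Interior/exterior dielectrics default
  to 1 and 78.5;
* nonpolar solvation: `E_NP = 0.00542 × SASA + 0.92` kcal/mol, with SASA
  from a Shrake–Rupley estimate on a deterministic Fibonacci point set
  (probe 1.4 Å, 960 points by default) — deterministic given the point
  count, per-atom values summing exactly to the total.

The self-assembly energy compares the mean per-monomer energy of the fibre
ensemble with the mean energy of a dissolved-monomer ensemble evaluated
under identical settings (the two readings of that comparison — one
monomer leaving a 48-mer, or averaging per monomer — coincide under this
averaging). Decomposition attributes gas and GB cross terms between
monomers n and m fully to the symmetric pair entry (n, m); intra-monomer GB
(with self terms) and the per-atom-attributed nonpolar term form each
monomer's own share. The nonpolar term is never split pairwise — SASA is
not a pairwise quantity. The conservation identity
`½ Σ_{n≠m} pairwise + Σ own = total` holds to 1e−6 kcal/mol on every
random toy in the test suite.

Reported bookkeeping follows the summary-table protocol: persistent bonds
per monomer is `2 × count / n` (each monomer shares bonds with two stacking
neighbours), rounded to one decimal for display; the hydrogen-bond energy
uses the unrounded value times −1.58 kcal/mol (the typical peptide hydrogen
bond in water) and is then rounded to one decimal; the
solvation-to-hydrogen-bond ratio divides by the *rounded* energy. Only this
exact protocol reproduces all printed table cells simultaneously, so it is
hard-coded and tested.

The demonstration pipeline evaluates energies on the stacked, all-P
register (fold factor 1): as noted above, sterically blind mixed-state or
strongly bent frames contain carbonyl clashes that flood the
Lennard-Jones term with repulsion an atomistic model would relax away.

## SAXS: flexible-cylinder model and fitting

The chain factor follows the Pedersen–Schurtenberger parametrization for
semi-flexible, self-avoiding chains ("method 3" with excluded-volume
corrections): below the crossover at `q·L_k = 3.1` an excluded-volume chain
function (Debye function with excluded-volume radius of gyration, blended
through a tanh crossover with a three-term power series in `(q R_g)^(−1/ν)`,
ν = 0.585, plus a local-stiffness correction term); above it the
`a₁(qb)^{−4.12} + a₂(qb)^{−4.42} + π/(q L_c)` rod asymptote, with a₁ and a₂
determined at run time by value and slope continuity at the crossover. In
the stiff regime (`L_c ≤ 4 L_k`) the chain is essentially fully extended
and the exact orientation-averaged rigid-rod (Neugebauer) form factor is
used; the fit bounds keep `L_k ≤ L_c/4` so a fit never straddles the
regime switch. The cross-section factor is the circular-cylinder
`[2 J₁(q r_cs)/(q r_cs)]²`, optionally averaged over a Gaussian dispersity
of the radius by 15-point Gauss–Legendre quadrature over ±4 standard
deviations.

`fit_wlc()` minimizes `Σ((I − model)/σ)²` by Levenberg–Marquardt. Two
numerical choices matter. First, synthetic uncertainties proportional to
the model vanish at the cross-section Bessel zeros; a handful of points
with unbounded weight can trap the optimizer in a `scale → 0` minimum, so
single-point weights are capped at 100× the median weight. Second, the
Bessel minima create genuine local optima in `r_cs`, so the fit
multi-starts over a small factor grid around the initial radius and keeps
the best deviance. Reported uncertainties are asymptotic (from the local
curvature); when the likelihood is nearly flat — as it is for the Kuhn
length of a chain whose contour length exceeds the accessible window — the
fit flags ill-conditioning rather than pretending precision, and a
parameter held or driven to a bound (typically the contour length) is
listed in `at_bound`. On self-generated noiseless data all free parameters
are recovered to 1e−6 relative; at 2% noise the median cross-section-radius
error over 20 seeds is below 0.01 nm.

`debye_profile()` provides the theoretical-curve stand-in for atomistic
scattering calculators: the orientation-averaged Debye double sum over
beads with uniform form factors, no hydration shell and no excluded-volume
solvent term — an approximation, invariant under rigid motion and bead
relabelling, not a replacement for a dedicated calculator.

## FRET exchange kinetics

The mixing assay raises the FRET ratio as dye-labelled monomers exchange
between fibres, to a plateau. The ratio is defined as
`I_acceptor / (I_donor + I_acceptor)` (bounded, scale-invariant;
acceptor/donor is available as an option) and fitted with the rising
biexponential `F(t) = F_plateau − A_fast e^{−t/τ_fast} − A_slow
e^{−t/τ_slow}`. The fit multi-starts over log-spaced timescale pairs,
optimizes log-timescales with nonnegative amplitudes, orders
`τ_fast ≤ τ_slow` canonically, and collapses to a monoexponential when the
two timescales become indistinguishable (within 5% in log) or an amplitude
degenerates, pooling the amplitude rather than reporting a spurious second
component. A constant series returns zero amplitudes with the plateau at
the mean. `plateau_time()` solves for the first time the curve reaches a
configurable fraction (default 95%) of its total rise — about 3τ for a
monoexponential — and `compare_kinetics()` reports per-component fold
changes with first-order propagated uncertainties (validated against
Monte-Carlo resampling in the tests). Replicate traces can be averaged
before fitting; a shared-timescale joint fit across replicates is not
implemented.

## Problem sizes and defaults

The package's own demonstrations and tests run on deliberately small
problems chosen to exercise every code path: fibres of 4–48 monomers, a
dozen trajectory frames, 150-point scattering grids, 200-point kinetic
traces, and 20-seed recovery experiments. Defaults encode the study
conditions of the fibre system the package models: 48 monomers, 3.4 Å
spacing, −140° dihedrals, 6.8 nm extended diameter, a 0.15–4.47 nm⁻¹
q-window, 2% scattering noise, and biexponential truth with timescales of
0.2 and 2 hours. The synthetic generators' parameter recovery says nothing
about force-field accuracy on real fibres; it certifies the analysis
chain.

## Known limitations

* The coarse monomer has no internal flexibility beyond the amide torsion;
  absolute energies are not comparable to all-atom MM-GBSA values and are
  not meant to be.
* Geometric hydrogen-bond detection on generated trajectories couples only
  partially to the drawn dihedral state (see above).
* Electrostatics are truncated at the cutoff; long-range sums are out of
  scope.
* The g(r) normalization density for a quasi-one-dimensional object is a
  stated convention, not a unique definition.
* SAXS fitting assumes a single population of flexible cylinders; no
  structure factor, bundling, or absolute-intensity calibration.
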