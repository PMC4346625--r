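# fibremetrics

Multi-scale analysis of water-soluble one-dimensional supramolecular
polymers — benzene-1,3,5-tricarboxamide (BTA) fibres in particular — for
researchers who simulate or measure such systems and need the quantitative
chain between raw trajectories/curves and the numbers that go into a
summary table.

A BTA fibre is a helical stack of C3-symmetric monomers held by threefold
amide hydrogen bonding and aromatic stacking (intercore spacing ≈ 3.4 Å),
wrapped in hydrophobic spacers and PEG tails that make it water-soluble.
The package quantifies such fibres on three scales:

* **molecular order** — intercore distances and radial distribution
  functions g(r), amide dihedral helicity (P / M / flipped classification of
  the C_AR–C_AR–C=O–O=C torsion), hydrogen-bond occupancy and persistence
  (strictly > 95% of equilibrated frames), fibre dimensions and contraction,
  solvent-accessible surface area, and detection of stable self-assembled
  domains (runs of consecutive monomers more stable than the fibre mean);
* **energetics** — an MM-GBSA-style engine: gas-phase Coulomb + 12-6
  Lennard-Jones, generalized Born polar solvation (Still's formula over
  Hawkins–Cramer–Truhlar effective radii), nonpolar solvation
  E_NP = 0.00542·SASA + 0.92 kcal/mol, the self-assembly energy
  ΔE = ⟨E per monomer in fibre⟩ − ⟨E dissolved⟩, and a per-monomer /
  pairwise decomposition whose terms re-sum exactly to the total;
* **mesoscale and kinetics** — worm-like chain (flexible cylinder) SAXS
  modelling I(q) = scale · S_chain(q; L_c, L_k) · [2J₁(q·r_cs)/(q·r_cs)]² +
  background with weighted least-squares fitting, a Debye-sum theoretical
  profile from bead coordinates, and FRET exchange kinetics: ratio
  I_A/(I_D + I_A) fitted with the rising biexponential
  F(t) = F_plateau − A_fast·e^(−t/τ_fast) − A_slow·e^(−t/τ_slow).

Because public data for these fibres are rarely deposited, a first-class
synthetic-data module generates every input with known ground truth:
ideal and perturbed stacked-fibre trajectories (multi-model PDB + parameter
sidecar CSV), Bernoulli hydrogen-bond occupancy matrices, per-monomer
energy profiles with plantable stable domains, noisy flexible-cylinder
scattering curves, and biexponential FRET traces. Identical config + seed
gives byte-identical output everywhere.

## Worked example

```r
library(fibremetrics)

# Energetic bookkeeping from persistent hydrogen-bond counts (39 / 56 / 48
# persistent bonds over 48 monomers; global solvation energies in kcal/mol)
rbind(achiral    = hbond_report_row(39, 48, -39.5),
      chiral     = hbond_report_row(56, 48, -38.9),
      discordant = hbond_report_row(48, 48, -40.3))
#>            hbs_per_bta dE_HBs sol_over_hbs
#> achiral            1.6   -2.6         15.2
#> chiral             2.3   -3.7         10.5
#> discordant         2.0   -3.2         12.6

percent_change(39, 56)        # persistent-bond gain, chiral vs achiral: +44 %
contraction(16.3, 7.1)        # achiral fibre contraction: 56 %
contraction(16.3, 9.5)        # chiral fibre contraction:  42 %

# Recover a cross-section radius from a noisy flexible-cylinder curve
truth <- wlc_params(L_c = 191.4, L_k = 19.1, r_cs = 3.1)        # nm
prof  <- generate_saxs_curve(truth, noise_fraction = 0.02, seed = 11)
fit_wlc(prof, wlc_params(191.4, 28, 2.4), fixed = c("dispersity", "L_c"))
#> WLC fit: L_c 191.4  L_k 19.14  r_cs 3.100 nm  scale 1  bkg 1.61e-10
#>   chi2/N = 0.8549; converged: TRUE; at bound: L_c

# Exchange kinetics from a synthetic FRET mixing trace (times in hours)
tr <- generate_fret_trace(list(F_plateau = 0.45, A_fast = 0.12,
                               tau_fast = 0.2, A_slow = 0.18, tau_slow = 2),
                          t_grid = seq(0.01, 20, length.out = 200),
                          noise_sd = 0.005, seed = 3)
f <- fit_biexponential(tr$time, fret_ratio(tr))
f
#> Biexponential fit: plateau 0.4507; fast A 0.1267 tau 0.1855; slow A 0.1779 tau 2.017
round(plateau_time(f), 2)     # time to 95% of the plateau: 4.96 h
```

The first block reproduces the bookkeeping chain exactly: bonds per monomer
is 2·count/48 (each monomer shares bonds with two stacking neighbours),
the hydrogen-bond energy multiplies the unrounded value by −1.58 kcal/mol
(a typical peptide hydrogen bond in water), and the final column shows the
solvation energy outweighing hydrogen bonding by an order of magnitude —
the hydrophobic effect, not hydrogen bonding, holds these fibres together.
The SAXS fit recovers the 3.1 nm cross-section radius with the contour
length pinned at its bound (the fibres are longer than the accessible
window), and the FRET fit recovers both exchange timescales within a few
percent.

A full generate → analyse → report run (structural summary, energy
decomposition, SAXS and FRET recovery, provenance manifest) is one call:

```r
res <- run_pipeline(default_pipeline_config(output_dir = "run1"))
```

`vignettes/fibremetrics-methods.Rmd` documents the models, conventions,
numerical choices and limitations.

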