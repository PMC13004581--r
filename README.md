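# anionsense

Analytics for discovering and mechanistically characterizing
**anion-sensitive fluorescent proteins**, built around the workflow that
identified cgreGFP (the GFP of the jellyfish *Clytia gregaria*) as a
turn-off anion sensor: mine a GFP-family alignment for binding-pocket
homologs, analyze molecular-dynamics trajectories for anion entry, cavity
residence, solvation shells and binding-coupled protonation shifts, and fit
the spectroscopy that quantifies sensing.

It is written for structural bioinformaticians and protein engineers who
have (or simulate) trajectory and titration data and want the paper-style
analyses as reusable, tested functions rather than one-off scripts.

## The models at the core

* **Pocket mining** — map reference pocket positions (e.g. Q69, R96, Q183,
  Y203) through an alignment, count per-member matches, filter at
  ≥ `min_matches`, and screen for hydrophobic substitutions at chosen
  positions.
* **Binding dynamics** — contact fingerprints at ≤ 4 Å, cavity occupancy
  with gap-merged residence segments, hysteresis-based entry events
  (inside < 8 Å of the chromophore centroid after visiting bulk > 15 Å),
  Kabsch-superposed RMSD/RMSF, geometric hydrogen bonds (3.5 Å / 120°),
  Shrake–Rupley SASA and chromophore planarity.
* **Solvation** — radial distribution function
  `g(r) = counts / (n_frames · N_center · ρ · V_shell)` with minimum-image
  distances, first-shell boundaries, coordination numbers.
* **Protonation** — constant-pH state analytics: fractions, state
  occupancies, transition counts, bound/unbound conditional fractions, and
  Henderson–Hasselbalch fits `f = 1/(1 + 10^(pKa − pH))`.
* **Spectroscopy** — one-site binding isotherm
  `F_obs([X]) = [X](F_max − F_min)/(K_d + [X]) + F_min` fitted by nonlinear
  least squares; 50%-signal-retention pKa estimation; fold change,
  extinction coefficients and relative quantum yield.
* **Synthetic data** — generators with planted ground truth for every input
  (alignments, trajectories, solvation boxes, constant-pH series,
  titrations), with presets encoding the measured constants (K_d 25.2 /
  15.1 / 5.3 / 10.7 mM for Cl⁻ / Br⁻ / I⁻ / NO₃⁻, non-binding gluconate,
  chromophore pKa 4.9 apo → 5.2 chloride-bound).

## Worked example

```r
library(anionsense)

# a noise-free titration from the chloride preset, fitted back
curve <- gen_titration("chloride", noise_sd = 0, seed = 1)
fit_binding_isotherm(curve)
#> <binding_fit chloride> Kd = 25.2 mM (SE 0), Fmin = 1, Fmax = 0.2

# chromophore pKa from a pH-response curve (chloride-bound preset)
ph <- gen_ph_curve(pka_presets()[["chloride_bound"]], seed = 1)
estimate_pka_50pct(ph)
#> [1] 5.215183

# entry detection on a scripted trajectory with planted truth
traj <- gen_trajectory(n_frames = 150, entry_frame = 60, seed = 21)
detect_entry_events(traj, "resname CLA", "resname CRO",
                    gate_candidates = list(c(108L, 109L), c(1L, 2L)))
#>   frame persistence gate_res1 gate_res2
#> 1    60          90       108       109
```

The fitted K_d is the preset's 25.2 mM exactly; the pKa estimate is within
0.02 pH units of the planted 5.2 (linear interpolation on a 0.25-pH grid);
the entry event lands on the planted frame 60 through the planted gate pair
108/109.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study-style analyses end to end on synthetic data, writing tables under
`results/`:

| script | what it does |
| --- | --- |
| `01_mine_pocket.R` | 806-member family screen → 71 members with ≥ 2 pocket matches, hydrophobic candidate flagged |
| `02_trajectory_binding.R` | entry event, cavity residence, RMSD/RMSF, planarity series |
| `03_solvation.R` | per-anion RDFs, first-shell boundaries, coordination counts |
| `04_protonation.R` | binding-coupled protonation shifts, Henderson–Hasselbalch pKa fit |
| `05_spectroscopy.R` | K_d fits for all anions (gluconate rejected as non-saturable), pKa estimates, photophysical constants |

Run any of them from the repository root, e.g.
`Rscript analysis/05_spectroscopy.R`.

## Package layout

```
R/                  pocket_mining, traj_io, binding_dynamics, solvation,
                    protonation, photophysics, synthetic_data
analysis/           numbered workflow drivers (write to results/)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance suites with brute-force oracles
vignettes/          methods vignette: models, parameters, design choices
```
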