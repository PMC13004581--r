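---
title: "Anion-sensing fluorescent protein analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anion-sensing fluorescent protein analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anionsense)
```

# Scope

`anionsense` re-implements, as a tested pipeline, the desk-scale analytics
behind the discovery and mechanistic characterization of an anion-sensitive
green fluorescent protein (cgreGFP from *Clytia gregaria*): mining a GFP
family alignment for binding-pocket homologs, anion-centric trajectory
analytics (entry events, cavity residence, solvation shells, protonation
coupling), and the spectroscopic fits that quantify sensing (one-site
binding isotherms, the 50%-retention chromophore pKa). Running constant-pH
molecular dynamics itself, force-field parametrization, and wet-lab work
are out of scope: the package *analyzes* such data. Because the original
500-ns trajectories and plate-reader tables are not desk-scale inputs, a
first-class synthetic-data module generates every input with planted ground
truth, and the test suite closes the loop between generators and analytics.

# Pocket mining

The screen asks: which members of a family alignment present, at the
alignment columns corresponding to a reference protein's anion-binding
pocket (Q69, R96, Q183, Y203 in an anion-sensitive YFP), either the
reference residues or informative substitutions? `map_reference_positions()`
converts the reference's 1-based *ungapped* residue numbering to alignment
columns by walking its aligned sequence; everything downstream
(`extract_pocket_table()`, `filter_members()`, `residue_distribution()`,
`rank_hydrophobic_candidates()`) works on those columns.

Design choices where the procedure was underdetermined:

* A gap at a pocket column counts as a non-match — a gapped member cannot
  present the residue. Ambiguity codes (X/B/Z) never match either.
* Comparison is case-insensitive exact equality.
* The default hydrophobic screen set is {A, V, L, I, M, F, W} (standard
  nonpolar side chains); it is an argument, not a constant, because
  "hydrophobic" has no single canonical definition.
* Reference numbering is pinned to the *supplied* reference's own ungapped
  numbering. Published pocket descriptions mix numbering schemes across
  homologs (e.g. an arginine reported as 88 in one scheme and 96 in
  another); the mapper deliberately takes whatever positions the caller
  supplies rather than adjudicating.
* Aligned FASTA and Stockholm are both accepted; `.` is normalized to `-`.

The synthetic alignment generator plants an exact match count per member.
So that planted candidate flags are exact too, non-matching pocket columns
are sampled from residues outside both the expected set and the hydrophobic
set; this makes the generator's pocket columns slightly less diverse than a
real family, which is acceptable because the generator's job is planted
truth, not evolutionary realism.

# Trajectory data model

Trajectories are frames of Angstrom coordinates over a fixed topology with
an optional orthorhombic box; the native text carrier is multi-model PDB
(`MODEL`/`ENDMDL`, `CRYST1` for the box), chosen for universality and
diffability. Frames are 0-based in all user-facing outputs (PDB `MODEL`
labels remain 1-based), residues 1-based per PDB convention. All distance
computations apply the minimum-image convention when a box is present, with
displacement components wrapped into (−L/2, L/2]. Binary formats
(DCD/XTC) and Amber's native constant-pH output are intentionally not
parsed; the titration-state carrier is a documented TSV (`frame`,
`residue_id`, `residue_name`, `state_index`, `is_protonated`, `pH`) holding
exactly what the analytics need.

The selection mini-language covers what the analyses use — `resname`,
`name`, `element`, `resid` ranges, `backbone` (N, CA, C, O), `heavy`
(element ≠ H), with `and`/`or`/`not` and parentheses — and nothing more.

# Binding dynamics

**Contacts and residence.** A residue contacts the anion in a frame when
its minimum heavy-atom distance to any anion atom is ≤ 4 Å (the cutoff the
binding cavity was defined with). A frame is *cavity-bound* when at least
`min_residues = 3` of the seven cavity residues are simultaneously in
contact; requiring three rejects grazing surface contacts, which a bare
cutoff would count. Bound runs separated by ≤ 2 unbound frames merge into
one residence segment, suppressing single-frame recrossing noise. Both
parameters are arguments.

**Entry events.** The source analyses describe barrel entry qualitatively
(a transient opening between two gate residues). Operationally, the package
flags an entry when the anion's distance to the chromophore centroid drops
below `r_inside = 8` Å and stays there for `min_persistence = 10` frames,
*after* the anion has been in bulk (> `r_bulk = 15` Å) since the previous
event. The hysteresis pair prevents boundary chatter from double-counting.
An anion that starts inside has no prior bulk frame and is not an entry.
The reported gate is the candidate residue pair with the smallest summed
minimum distance to the anion at the event frame. All three thresholds are
configurable, and the defaults reflect GFP barrel geometry (chromophore
center to barrel wall ≈ 12 Å).

**RMSD/RMSF.** Superposition uses the Kabsch algorithm with a proper
rotation enforced (determinant +1), so mirror images never masquerade as
good fits. RMSF superposes every frame onto frame 1 over the selection
before measuring fluctuations; because the centering and rotation absorb
part of any single atom's motion, a lone oscillating atom's RMSF equals its
oscillation amplitude only without superposition, which is why `rmsf()` has
a `superpose` flag.

**Hydrogen bonds.** Geometric criterion: donor-heavy-to-acceptor distance
≤ 3.5 Å and D–H···A angle ≥ 120° — a common permissive default, stated
explicitly because occupancies are not comparable across criteria. Donor
pairs whose hydrogen sits > 1.5 Å from the heavy atom are chemically
implausible and are skipped with a warning.

**SASA.** Shrake–Rupley with 960 golden-spiral points per atom and a 1.4 Å
water probe. The radius table (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Å) uses
the anions' ionic radii for the halides (Cl 1.81, Br 1.96, I 2.20 Å),
matching how the underlying study discusses anion size.

**Planarity.** Per-frame RMS distance of ring atoms from their
least-squares plane (smallest singular value of the centered coordinates,
divided by √n). Used to confirm the chromophore stays planar upon binding,
which rules out large isomerization-driven quenching.

# Solvation

`rdf()` normalizes pair counts by `n_frames × N_center × ρ × V_shell` with
exact shell volumes and the frame-averaged target density `N_target /
V_box`. The full box volume is used — no protein-excluded-volume
correction — so absolute g magnitudes from crowded systems will differ from
tools that correct for it; the convention is stated so such differences are
explainable. The bin width defaults to 0.1 Å, and `r_max` must stay within
half the smallest box length (minimum image).

First-shell detection smooths g with a 3-bin moving average, takes the
first local maximum with smoothed g > 1 (ties toward smaller r), and the
first local minimum after it. The g > 1 threshold makes the detector
reliable only where the background density is well sampled; with few frames
and sparse targets, single pair counts in small-radius bins can exceed 1
spuriously, so shell analyses in this package's own drivers use planted
shells or well-sampled boxes. For a polyatomic anion like nitrate the
center is its nitrogen; water is represented by its oxygen, matching the
convention of the underlying RDF figures.

`coordination_count()` counts targets within a cutoff of any center atom
per frame; with the cutoff set at the first-shell minimum this is the
first-shell coordination number (≥ 4 waters for chloride/bromide, ~2 for
nitrate in the planted scenarios mirroring the study).

# Protonation analytics

Constant-pH records are periodic snapshots, so missing frames are excluded
from fractions rather than forward-filled. Transitions are counted on
`state_index` changes, not just protonated/deprotonated flips, so tautomer
exchange between a carboxylate's two oxygens (the E224 behavior: equal
tautomer occupancy before binding, 100% on one oxygen after) is visible.
The module never infers chemistry: `is_protonated` is the upstream
mapping's responsibility. `binding_coupled_fractions()` conditions on the
per-frame bound flag of an occupancy series and reports a condition with no
frames as undefined (`NA`), never 0; the law of total probability (marginal
fraction = frame-weighted mix of the conditionals) holds exactly and is
tested as an identity.

`fit_titration_pka()` fits `f = 1/(1 + 10^(pKa − pH))` by nonlinear least
squares (Levenberg–Marquardt via `minpack.lm`), initialized at the pH
nearest f = 0.5.

# Spectroscopy

**Binding isotherm.** `Fobs([X]) = [X](Fmax − Fmin)/(Kd + [X]) + Fmin`,
with Fmin the emission at zero anion and Fmax the saturation asymptote —
for a turn-off sensor Fmax < Fmin. Replicates are averaged per
concentration before fitting (per-replicate pooling is a flag);
initialization is Fmin ← F(0), Fmax ← F(max), Kd ← the concentration
nearest the half-change; Kd is constrained positive and standard errors
come from the Jacobian at the optimum. A curve whose total signal change
falls below the noise floor (3× the pooled replicate SD) is rejected as
"no saturable response" — the behavior expected from the non-binding
gluconate control rather than a numerical failure.

**50%-retention pKa.** The pH-response curve is normalized to its own
min/max and scanned from high pH toward low; the first adjacent pair
bracketing 0.5 is linearly interpolated. Linear interpolation is a stated
choice (the original description does not specify one). Min/max
normalization biases the estimate when the pH grid truncates an asymptote:
on a 3.5–8 grid the bias is ≤ 0.04 pH units for pKa ≈ 4.9–5.2 (the
measured regime) but grows near the grid edges (≈ +0.26 at pKa 3.8), so
estimates within ~0.5 pH units of the grid boundary should be treated as
upper/lower bounds. Multiple crossings (noisy curves) produce a warning and
the first crossing from high pH.

**Constants.** ε280 from sequence uses 5500·nTrp + 1490·nTyr + 125·nCystine
(reduced cysteines by default); other wavelengths follow by absorbance
ratio at fixed concentration and path length. Relative quantum yield is the
slope-ratio method against a reference fluorophore with a refractive-index
correction; the reference's yield is a required input, never hard-coded.
Batch estimates combine as the mean with propagated SD `sqrt(Σ sdᵢ²)/n`.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions for all tests:

* `gen_alignment()` — 806-member family screens with a planted number of
  pocket matches per member (71 passing members in the shipped driver) and
  planted hydrophobic candidates.
* `gen_trajectory()` — a coarse pseudo-barrel (CA-only wall at 12 Å radius,
  planar 5-atom chromophore, seven single-atom cavity residues 3 Å from the
  cavity point, a two-residue gate on the entry axis), one anion scripted
  from bulk (25 Å) through the gate into the cavity at a planted entry
  frame, exactly k waters on a planted first shell (radius r0, default
  3.2 Å, k = 4 echoing the halide shells) while bound, 0.1 Å Gaussian
  jitter on everything. It is geometry sufficient to exercise contacts,
  entry, residence, shells and SASA — not physics: no forces, no water
  structure beyond the planted shell, no conformational change.
* `gen_solvation_box()` — ideal-gas and planted-shell RDF test beds.
* `gen_cphmd_states()` — Bernoulli protonation at the Henderson–Hasselbalch
  probability per frame, optionally overridden by a coupled probability on
  bound frames; real CpHMD state series are autocorrelated, so planted
  transition *counts* are not meaningful truths, only fractions are.
* `gen_titration()` / `gen_ph_curve()` — the binding isotherm and pH
  response with additive i.i.d. Gaussian noise (replicate SDs in the source
  data come without a noise model; additive Gaussian is the simplest
  consistent choice). Presets encode the measured constants: Kd 25.2 / 15.1
  / 5.3 / 10.7 mM for chloride / bromide / iodide / nitrate, gluconate
  non-binding, chromophore pKa 4.9 (apo) → 5.2 (chloride-bound), mutant
  3.6 → 4.0, ionic radii Cl 1.81, Br 1.96, I 2.20, NO₃ 2.64 Å.

Every generator takes a mandatory seed, is byte-reproducible, and leaves
the session RNG untouched. Passing tests on these generators demonstrates
that the *analytics* are correct against planted truth and exact oracles;
they do not demonstrate force-field realism, adequate sampling of real
trajectories, or instrument behavior.

`ion_counts_for_box()` reproduces the neutral-box setup at 300 mM ionic
strength (e.g. 67 monovalent anions with 75 sodium counter-ions around a
−8 e protein); since the solvated box volume is structure-dependent, the
count pair is verified through the neutrality relation rather than volume
reconstruction.

# Problem sizes and numerical choices

The shipped drivers and tests use deliberately modest sizes chosen to make
the statistical assertions sharp rather than to imitate production scale:
trajectories of 100–300 frames and ~60 atoms, 4 000-frame protonation
series (binomial SE ≈ 0.008), 1 000-point ideal-gas boxes over 20 frames,
and 100-seed sweeps for round-trip properties. Optimizer tolerances are
left at `minpack.lm` defaults except the isotherm fit (ftol/ptol 1e-12),
where the acceptance bar is 1% recovery of Kd. Ties in peak finding break
toward smaller r; superposition enforces proper rotations; half-box
displacement lands on +L/2 by convention.

# Known limitations

* The PDB writer emits fixed-format ATOM records only (no TER, no
  occupancy/B-factor semantics); element symbols are taken from columns
  77–78 with a fallback to the atom-name initial.
* RDF normalization without excluded-volume correction understates g in
  strongly crowded interiors.
* The entry-event definition is a stated operationalization, not the
  underlying study's (which gave none); alternative pathway analyses (e.g.
  iodide's) need their own gate candidates.
* The 50%-retention pKa estimator inherits the normalization bias described
  above and is an estimator, not a thermodynamic fit; `fit_titration_pka()`
  is the model-based alternative when full fractions are available.
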