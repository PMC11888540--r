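---
title: "Rebalancing protein force fields: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rebalancing protein force fields: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffbalance)
```

## The problem

Fixed-charge protein force fields historically over-stabilize compact
states: disordered chains collapse too much, and some residues (notably
Ser, Thr and Gln) carry an excess helical bias from their backbone
torsion corrections. Two families of remedies are in wide use, and both
are pure topology edits — no resimulation of parameters is involved:

* **Protein–water Lennard-Jones scaling.** For selected protein atoms,
  the pair interaction with the water oxygen is strengthened by a
  factor γ applied to the combined well depth ε. With the
  Lorentz–Berthelot rule the pair parameters are
  σ = (σᵢ + σ_OW)/2 and ε = γ·√(εᵢ ε_OW). γ = 1.10 is the
  conventional value: large enough to expand disordered ensembles,
  small enough not to unfold stable proteins.
* **ψ-torsion refinement.** The n = 1 cosine correction
  V(ψ) = k_ψ (1 + cos(ψ − δ)) on the backbone ψ angle of specific
  residues is retuned by rewriting k_ψ. The `STQ` preset takes Ser,
  Thr and Gln from 2.0 to 1.0 kJ/mol; `STQ_PRIME` keeps Ser/Thr at
  1.0 kJ/mol and sets Gln to the intermediate 1.5 kJ/mol, which
  balances the two failure modes observed in polyglutamine (too much
  helix at 2.0, too little at 1.0).

Everything in this package is organized so that each edit is (a)
expressed as a transformation of a parsed topology and (b) *proved*
correct by an independent cutoff-free energy oracle rather than by
inspection of the output file.

## Realization of selective scaling

GROMACS-dialect nonbonded overrides are per *type pair*, while the
selection rules are per *atom* (backbone vs sidechain, residue
charged or not). Selectivity is therefore realized by **atom-type
cloning**: any targeted atom whose type is shared with non-targeted
atoms is re-typed onto a clone (original name plus a configurable
suffix, default `_sc`) with identical σ, ε, mass and charge, and the
override `(clone, OW)` is emitted with ε multiplied by γ. This is the
only realization that leaves every non-targeted interaction bit-wise
untouched; per-atom charge duplication schemes touch the Coulomb
tables and were rejected. Scaling is applied only against the water
*oxygen* type because in the four-site water model used here the
hydrogens and the virtual site carry no Lennard-Jones terms.

Classification rules, and the choices behind them:

* Backbone set: N, H (incl. terminal H1–H3), CA, HA (HA2/HA3 for Gly),
  C, O, terminal carboxylate oxygens. *Backbone scaling* uses the heavy
  atoms of this set only; *sidechain scaling* includes sidechain
  hydrogens. Glycine, having no sidechain, is never selected by
  sidechain modes.
* The default charged-residue set is Asp, Glu, Lys, Arg plus doubly
  protonated His (HIP/HSP) and deprotonated Cys/Tyr variants; neutral
  His tautomers and protonated Asp/Glu (ASH/GLH) count as uncharged.
  The set is an argument of `scaling_scheme()`, not a constant.
  Charged-residue exclusion removes only the residue's *sidechain*
  atoms; charged termini follow the backbone rule.
* An unrecognized residue classifies as `OTHER` with a warning and is
  never scaled silently.

`repartition_hydrogen_masses()` reads its target literally: every
protein hydrogen's mass is *set to* the requested value (default
1.5 amu, supporting a 4 fs timestep) and the difference is subtracted
from the single bonded heavy atom, conserving each molecule's mass
exactly. Water is untouched.

## The energy oracle

`total_energy()` is a direct double sum — Lennard-Jones 12-6, Coulomb
q_iq_j/(4πε₀r), and explicit proper dihedrals — with 1-2/1-3 exclusions
and 1-4 fudge factors derived from the bond graph and the `[ defaults ]`
directive. It deliberately has **no** periodic boundary conditions,
cutoffs or mesh electrostatics: it exists to verify that a
transformation changed exactly the terms it claims to (ratios, deltas,
invariances), not to reproduce simulation energies. The tests use it to
show that γ = 1 scaling is energy-neutral to 1e-10 relative, that the
protein–water LJ component scales by exactly γ, that Coulomb terms are
bit-identical before and after, and that ψ refinement shifts the
dihedral term by (k_new − k_old)(1 + cos(nψ − δ)) exactly.

## Topology model

The parser covers the sections these workflows touch — `defaults`,
`atomtypes`, `nonbond_params`, `moleculetype`/`atoms`/`bonds`/`pairs`/
`angles`/`dihedrals`, `system`, `molecules` — and preserves everything
else (settles, exclusions, virtual sites, …) verbatim, so a parse →
transform → write cycle is a semantic fixed point on real files without
a full grammar. Indices stay 1-based as in the dialect. Combination
rules 2 (Lorentz–Berthelot) and 3 (geometric) are supported; the
C6/C12 form (rule 1) is rejected rather than mis-read. `#include` is
inlined literally when the file is present. Proper dihedrals (funct 1,
4, 9) are parsed into (phase, k, multiplicity); other functs round-trip
as opaque parameter text. A ψ quadruple of a requested residue whose
n = 1 term has no explicit in-line parameters is a hard error: a
correction living only in shared `[ dihedraltypes ]` entries cannot be
rewritten per residue, and silently cloning type-level dihedrals was
judged too surprising.

## Observables

* **Guinier analysis** fits ln I against q² and reports
  R_g = √(−3·slope). The fit window is found self-consistently: an
  initial fit on the smallest-q points gives an R_g estimate, the
  window is re-cut at q·R_g ≤ `qrg_max`, and the procedure iterates to
  a fixed point. The default `qrg_max = 1.3` is the conventional
  Guinier validity bound; the window actually used is reported in the
  result because the "right" window is a judgement call that should be
  visible, not buried.
* **Debye scattering** is the vacuum double sum
  I(q) = ΣΣ f_i f_j sinc(q r_ij) with the q → 0 limit handled
  analytically. Atomic form factors are a coarse single-Gaussian table
  (Z·exp(−b q²)); a constant-f mode exists for closed-form tests.
  Hydration-layer and excluded-volume corrections of crystallographic
  SAXS predictors are deliberately absent — curves are for
  self-consistent R_g work and method testing and differ systematically
  from experimental solution scattering.
* **DSSP** implements the Kabsch–Sander hydrogen-bond energy
  (0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, bond if
  < −0.5) with amide hydrogens rebuilt from the preceding C=O and the
  minimal-helix rule (two consecutive n-turns). `helix_fraction()`
  counts H only by default; 3₁₀ (G) can be included with
  `include_310 = TRUE` since conventions differ across studies and the
  choice materially changes reported helicities.
* **iRED** eigendecomposes the matrix M_ij = ⟨P₂(û_i·û_j)⟩ over frames.
  The five largest eigenmodes of this matrix are the reorientational
  (tumbling) modes — for a rigid body the matrix is exactly rank 5 by
  the spherical-harmonic addition theorem — so
  S²_i = 1 − Σ_{internal} λ_m m_i², summing over all *but* the five
  largest modes, clipped to [0, 1]. A finite site count M biases S²
  upward by roughly (5/M)(1 − S²) because the tumbling modes absorb a
  share of internal amplitude; the cone-validation tests therefore use
  M = 100 sites. Optional contiguous block-averaging reports mean ± sd
  across blocks.
* **Kabsch superposition** uses the SVD of the 3×3 covariance with the
  determinant correction for proper rotations; collinear selections
  (second singular value ≈ 0) are an error. RMSF superposes all frames
  onto an iterated mean structure (two passes).
* **Secondary shifts**: (Cα_obs − Cα_rc) − (Cβ_obs − Cβ_rc) per
  residue; positive = helical, negative = β. Glycine, lacking Cβ,
  reports the Cα secondary shift alone and is flagged. The bundled
  random-coil table is a coarse synthetic composite for tests and
  examples; real analyses should supply a sequence- and
  condition-corrected reference.

## Synthetic generators: what they do and do not emulate

The generators make every claim testable offline:

* `make_toy_topology()` builds residues with correct atom names and
  connectivity but *generic element-based parameters* and a ψ
  correction (n = 1, k = 2.0 kJ/mol) on every residue. Tests built on
  it assert relations — ratios, deltas, conservation laws, set
  algebra — never absolute energies, so no published parameter set is
  redistributed and none of the conclusions depend on one.
* `ideal_helix_coords()` / `extended_coords()` grow backbones by
  internal coordinates (N–CA 0.1458, CA–C 0.1525, C–N 0.1329,
  C=O 0.1231 nm; φ/ψ = −57/−47° or 180/180°), verified by re-measuring
  the dihedrals to within 1°.
* `gaussian_chain()` produces freely jointed chains with
  ⟨R_g²⟩ → n b²/6, the standard test bed for R_g and Guinier work.
* `rigid_tumbling_trajectory()` applies Haar-random global rotations
  (no internal motion: the iRED rigid limit, S² = 1).
  `wobble_trajectory()` additionally draws each N–H vector i.i.d.
  *uniformly within a cone* per frame — the equilibrium distribution of
  diffusion-in-cone, for which S = cosθ(1 + cosθ)/2 holds exactly —
  rather than integrating a diffusion process, whose transient would
  only converge to the same average.

What passing these tests does **not** show: agreement with real
proteins. The toy topologies have no realistic charges or equilibrium
geometry, the trajectories have no physics in them, and the SAXS curves
lack solvent corrections. The package validates the *machinery*
(selection rules, parameter arithmetic, estimator implementations);
scientific validation of a force field still requires long simulations
compared against NMR/SAXS data.

## Numerical choices and problem sizes

Tolerance and size choices used by the test suite and the acceptance
script, chosen to keep everything well-conditioned on one CPU core:

* Energy identities at 1e-9–1e-12 relative; exclusion-masked pairs are
  hard-zeroed so excluded overlaps cannot generate NaNs.
* Guinier fits need ≥ 5 points; non-positive intensities in the window
  are an error rather than silently dropped.
* iRED validation uses 100 N–H sites with 2 000 frames per cone angle
  (15°, 30°, 45°) and 10⁴ frames for the rigid limit; Gaussian-chain
  statistics use 300–500 chains of 1 000 beads.
* All generators take explicit seeds, restore the caller's RNG state,
  and are bitwise reproducible.

## Known limitations

* The topology subset is the one these workflows touch; exotic
  directives (`#ifdef` branches, pairtypes-dependent 1-4 handling) are
  preserved but not interpreted.
* The oracle's Coulomb term is unscreened vacuum electrostatics — by
  design, see above.
* DSSP here covers helix and strand classes; bends (S) and the full
  ladder/sheet bookkeeping of the reference implementation are not
  reproduced.
* iRED S² carries the finite-M bias noted above; with the ~70+ amide
  vectors of a typical protein it is well under experimental
  uncertainty, but for short peptides it is visible.
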