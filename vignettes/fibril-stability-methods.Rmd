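---
title: "Methods: helical geometry, solvation stability, and polymorph comparison of amyloid fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helical geometry, solvation stability, and polymorph comparison of amyloid fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilstab)
```

# Scope

`fibrilstab` analyzes cross-β amyloid fibril models built from two
proteolytic transthyretin (TTR) fragments per layer, with four gate
polymorphs (closed, open, absent, broken) distinguished by the
conformation of the C-terminal segment around Leu58–Gly67. The package
covers five connected analyses:

1. helical geometry — twist/rise operators, crossover distances,
   symmetry expansion, and parameter re-estimation from coordinates;
2. solvation stabilization energy of a chain in its fibril context;
3. superposition-based polymorph comparison (overall and per-residue
   r.m.s.d. over a common core);
4. filament tracing from STAR particle tables and polymorph
   co-occurrence statistics;
5. synthetic fibril and particle-table generators used both as fixtures
   and as the desk-scale stand-in for deposited models.

This vignette records the model, the numerical procedures, and the
design decisions a reader needs to interpret the outputs.

# Helical geometry

A fibril is a stack of layers related by a screw operator: rotation by
the twist θ (degrees per subunit, negative = left-handed) about the
fibril axis plus a translation by the rise h (Å). The crossover
distance — the axial length over which the projected fibril rotates by
180° — follows directly:

$$d_{\mathrm{crossover}} = \frac{180}{|\theta|}\, h .$$

For the absent-gate fold (θ = −1.3°, h = 4.93 Å) this gives 683 Å after
rounding. Note the relation is exact in the package; printed parameter
triples in the literature are often rounded independently, so we never
force a published crossover to match a published (θ, h) pair.

`expand_symmetry()` applies the operator about the z-axis through the
Cα centroid of the input layer. `estimate_helical_parameters()` inverts
it: each consecutive layer pair is superposed by least squares (Kabsch),
the rotation is decomposed into screw axis/angle, and the rise is the
translation component along the axis. The axis is oriented so the rise
is positive; stacks with |θ| below a tolerance (default 0.01°) are
flagged `untwisted` because the axis of a near-identity rotation is
numerically undefined. On noise-free synthetic stacks of 5–20 layers the
round-trip recovers twist to 0.01° and rise to 0.01 Å (see the test
suite).

# Solvent accessible surface area

SASA is computed with the Shrake–Rupley quadrature in compiled code:
`n_points` (default 960) points are placed on each expanded sphere of
radius r_atom + r_probe (probe 1.4 Å) via a golden-spiral lattice, and
the accessible fraction times the sphere area is the atom's SASA.
United-atom van der Waals radii (C 1.9, N 1.7, O 1.4, S 1.8 Å) are the
default and can be replaced from a YAML table. Correctness is pinned by
closed forms (isolated sphere; two-sphere spherical caps) and by a
brute-force latitude–longitude surface grid oracle at 0.1 Å spacing,
with agreement within 2% on small clusters.

# Stabilization energy

The stabilization energy of a chain is the sum over atoms of buried
area times an atomic solvation parameter (ASP):

$$E = \sum_i -\sigma_i \, \Delta A_i / 1000 \quad \text{(kcal/mol)},$$

with σ in cal mol⁻¹ Å⁻² from the Eisenberg–McLachlan set (C +16, N/O
−6, O⁻ −24, N⁺ −50, S +21), shipped as a YAML config with provenance.
Two conventions required decisions the source description leaves open:

* **Sign.** We report stabilizing burial as *negative* kcal/mol, the
  convention used when quoting fibril chain energies as, e.g., −70 to
  −55 kcal/mol. σ > 0 atoms (apolar C, S) gain stability when buried;
  charged groups (O⁻, N⁺) pay a desolvation penalty. The chosen
  convention is recorded in the result's `context`.
* **Reference state.** Buried area is ΔA = A(reference) −
  A(assembly). The default reference `isolated_chain` is the target
  layer alone in the same conformation, so ΔA measures inter-chain
  burial only. A `fully_extended` reference (each residue in a
  tripeptide context) is available for comparison with unfolded-state
  conventions; it buries strictly more area. The choice is recorded in
  `context$reference`.

Energies are scored for the *central* layer of a
(2·⌊stack_layers/2⌋+1)-layer helically expanded stack (default 5
layers): central-layer burial is converged to ~1% by 5 layers, and
boundary layers trigger a warning. Per-atom energies are summed to
per-residue and per-chain values; sums are exactly additive.
`residue_energy_colormap()` bins per-residue energies symmetrically
about zero for structure coloring.

# Polymorph comparison

`kabsch_superpose()` is a standard SVD-based least-squares fit with the
determinant correction to exclude reflections; degenerate (collinear or
<3 point) inputs error. `common_core()` pairs residues present in both
models, flagging the default common core Leu12–Lys35 ∪ Gly67–Val122.
`fold_rmsd()` fits once — on all shared residues or on the common core
(`fit_set`) across a configurable number of layers (default 3) — and
then reports per-residue deviations for *all* shared residues under
that single fit, so gate displacements are visible rather than absorbed
into the fit. `deviation_matrix()` assembles the symmetric,
zero-diagonal pairwise r.m.s.d. matrix plus per-residue profiles.

# Filament tracing and co-occurrence

`read_star()`/`write_star()` handle RELION-style STAR particle tables
(coordinates, micrograph, helical tube ID, 3D-class number; unassigned
classes round-trip as −1). Segments are grouped into filaments either
by tube ID or by single-linkage proximity clustering within a
micrograph; segments are ordered along the filament by projection onto
its principal axis. A filament with ≥2 distinct assigned classes is
*mixed*; the mixed fraction is mixed/(pure+mixed). When class coverage
is partial, the recovered fraction is a *lower bound* on the true mixed
fraction (unobserved segments can only reveal more mixing), and the
summary flags this with a caveat.

# Synthetic generators as study conditions

The generators are first-class: their defaults define the synthetic
study conditions and are never tuned toward any expected output.

* **Layers.** Each fragment is a 2D serpentine trace: 3.8 Å Cα steps,
  12-residue strands joined by 4-step 180° U-turns (≈9.2 Å inter-strand
  spacing). The N fragment anchors at (0, 0), the C-terminal core
  (Gly67 onward) at (0, −20). Gate states modify only the segment
  N-terminal of the Gly67 hinge, walked backward from the anchor:
  `closed` curls it (three escape steps then a −36°-per-step arc),
  `open`/`broken` extend it straight, `absent` omits it. All folds walk
  the same maximal ranges and subset afterwards, so residues shared
  between states sit at *identical* coordinates — comparisons between
  gate states are then attributable to the gate alone. Idealized
  backbone N/CA/C/O atoms and alternating ±z Cβ (by residue-number
  parity; none for Gly) complete the layer, with a self-avoidance check
  (≥3.5 Å between non-adjacent Cα).
* **Sequence.** The mature 127-residue TTR sequence with the I84S
  substitution by default.
* **Fibrils.** `make_fibril()` expands a layer with a chosen helical
  operator and optionally adds seeded i.i.d. Gaussian noise;
  deterministic for a fixed seed.
* **Particle tables.** `star_spec()` defaults: 15 micrographs × 10
  filaments × 20 segments, mixed-filament probability 0.3, classes
  {1, 2} switched along the filament as a Markov chain (switch
  probability 0.1, resampled so a designated mixed filament realizes
  ≥2 classes), 30% of class labels removed, 4096² px micrographs.
  `make_star_fixture()` returns particles plus the ground-truth
  filament table used to validate recovery.

# Problem sizes and runtimes

All analyses run at desk scale: layers of ~90–100 residues (≈460
atoms), 3–7 layer stacks, SASA at 960 points (≈0.2 s per
stabilization-energy profile), particle tables of ≈3,000 segments. The
full pipeline (`run_pipeline()`) over four folds completes in about a
second and writes a JSON report embedding the normalized config for
reproducibility.

# Limitations

* Energies use a rigid-body, implicit-solvent surface model; no
  conformational relaxation, electrostatics, or entropy terms.
* The synthetic layers are flat idealized traces, not refined
  coordinates; they support method validation and relative comparisons,
  not absolute structural claims.
* The shipped stability atlas snapshot is a synthetic, clearly labelled
  stand-in distributed for offline reproducibility of the statistical
  workflow, not measured values.
* Mixed-fraction estimates under partial class coverage are reported
  only as lower bounds.
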