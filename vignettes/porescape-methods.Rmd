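---
title: "Methods: pore mapping, hydrophobicity and gating analytics in porescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore mapping, hydrophobicity and gating analytics in porescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescape)
```

porescape characterizes the conduction pathway of an ion channel — its
radius, its surface hydrophobicity and the collective motions that gate it —
from static structures or molecular-dynamics trajectories.  This vignette
explains the models and algorithms, the parameters that matter, the design
choices made where several reasonable options existed, and what the
synthetic test systems do and do not establish about real channels.

## Pore detection and mapping

The pore is found on a coarse occupancy grid.  A cell (default edge
3.4 Å) is occupied if it contains at least one heavy-atom centre; at this
cell size the atomic radius is absorbed by the cell itself, so no
van-der-Waals inflation is applied.  The lattice is registered on the
structure's bounding-box centre with odd cell counts per axis, which places
the box centre at a cell centre; without this registration a narrow axial
pore can straddle cell boundaries and escape detection.

Unoccupied cells split into *bulk solvent* and *cavities*.  Bulk is
identified per z-layer by a 4-connected in-plane flood fill from the layer's
lattice boundary: anything reachable from outside in the membrane plane is
solvent (or membrane), anything enclosed by protein in its layer is cavity.
This deliberately leaves the axial column of an open channel classified as
cavity even though it communicates with solvent above and below — channels
are open-ended.  Cavities then grow by 6-connectivity (face neighbours
only, which prevents diagonal leakage through single-cell wall defects).
Because a closed gate splits the lumen into stacked vestibules, cavities
whose xy-projections share at least one projected cell are merged
transitively, and the largest merged cavity is taken as the pore.  Ties
break towards the larger z-extent, then the lowest cell index, so the
result is deterministic.

The molecular surface is a dot representation: each atom's van der Waals
sphere carries a deterministic spiral (Fibonacci) lattice of dots at the
requested density (default 3 dots/Å²), and a dot survives if a probe
sphere (default radius 1.4 Å) placed tangent along the outward normal
clears every other atom's probe-extended sphere.  This keeps the contact
surface and approximates reentrant patches by probe rejection; it is not a
tessellated analytic molecular surface, but for mapping purposes only the
dot positions, areas and exposure matter.  Each dot carries an equal share
of its atom's sphere area, so an isolated atom's dots sum to exactly
4&pi;r².  The lattice is seed-free: identical inputs give bit-identical
surfaces.

Dots lying in pore cells or any of their 26 neighbouring cells form the
pore border S.  The border is profiled in slabs: for each elevation z
(default −20 to 20 Å in steps of dz = 0.5 Å) the slab S_z holds the dots
with |z_dot − z| ≤ dz — a sliding window of width 2·dz, per the
overlapping-slab convention.  Then

* C(z) is the mean point of S_z (the local pore centre),
* R(z) is the mean in-plane (xy) distance from C(z) to the slab dots, and
* H(z) is the mean per-dot hydrophobicity.

R(z) uses in-plane distances because the slab is thin relative to pore
curvature; a full 3-D distance option is available (`dist = "3d"`).
Slabs with no dots are flagged undefined rather than zero-filled, and
undefined map cells serialize as `NaN`.  A mean-distance radius on a dot
cloud is not identical to a maximal-inscribed-sphere radius; on idealized
cylinders of radius 2–8 Å the two agree to better than 0.5 Å (the test
suite checks this against an independent sphere-maximization oracle), and
the mean-distance form degrades more gracefully on non-circular
cross-sections.

Two 2-D unrollings are provided.  The cylindrical map bins border dots by
(azimuth α about the C(z) centreline, elevation z) for one conformation;
the dynamic map stacks per-frame profiles into a (time, z) matrix, with
per-frame failures (no cavity) yielding undefined columns rather than
aborting the run.  `occluded_bands()` reads gates off a profile as
contiguous runs that are undefined or narrower than a cutoff radius
(default 1 Å, below the water-probe scale); runs narrower than 1 Å in z
are discarded because an isolated empty slab at the shoulder of a
constriction is a dot-coverage artifact, not a gate.  `detect_opening()`
reports the first frame at which the radius at a gate elevation becomes
defined and exceeds a threshold (default 1.5 Å).

Structures whose pore axis is not already along z can be aligned with
`align_pore_axis()`: the dominant principal axis of a selection is rotated
onto z, and a `"c4"` mode additionally verifies 4-fold symmetry by
nearest-neighbour RMS under a 90° rotation.  Principal-axis alignment
assumes the channel is longer than it is wide; for squat particles the
axis should be supplied by construction.

## Molecular Hydrophobicity Potential

The MHP at a point p is a distance-weighted sum of empirical atomic
hydrophobicity constants over all atoms,

MHP(p) = &Sigma;_i f_i · exp(−d(i, p) / &lambda;),

with d the distance from the atom centre and &lambda; = 2 Å by default.
The exponential distance function is the convention of
octanol/water-derived surface-potential methods; &lambda; is a
configuration knob, and because MHP is linear in the constants any
alternative table can be swapped in as a plain-text file.  Positive values
mark hydrophobic surface, negative hydrophilic, in logP-derived units.

The bundled constants are class-based: each protein heavy atom is mapped
by residue/atom-name rules to a class (aliphatic CH3/CH2/CH, aromatic CH
and substituted carbons, carbonyl/carboxyl carbons, amide/aromatic/charged
nitrogens, carbonyl/hydroxyl/carboxylate oxygens, sulfur) carrying a
fragment-style constant with implicit hydrogens.  Unclassifiable atoms
fall back to an element-level constant and finally to zero with a warning,
so an unmapped ligand cannot silently poison a map.

The unit of the scale is fixed by a calibration on n-alkane model
compounds: `methylene_calibration()` builds the dot surface of each
compound, sums per-dot MHP, and regresses the total against carbon count.
The united-alkane constant in the bundled table was chosen once so that
this slope equals 50 MHP units per methylene group at the default surface
parameters (density 3/Å², probe 1.4 Å, &lambda; = 2 Å); the acceptance
script re-derives the slope from scratch.  The alkane geometry is the
ideal all-anti chain (C–C 1.53 Å, C–C–C 111.6°), built by
`make_alkane()`.

Surface-MHP distributions (`mhp_distribution()`) are area-weighted
histograms: each bin holds summed dot area, deliberately unnormalized so
that bin heights are surface areas and two histograms over the same breaks
subtract bin-wise into a differential profile whose integral is the net
area change.

## Solvation energetics and the heat-capacity estimator

Per-residue solvation energies use the atomic-solvation-parameter
formalism: E_solv(residue) = &Sigma;_atoms ASP(class) × ASA(atom).  ASA is
Shrake–Rupley point counting on the same deterministic spiral lattice (960
points per atom by default, probe 1.4 Å); ASP values are the five-class
Eisenberg–McLachlan set (C +16, N/O −6, O⁻ −24, N⁺ −50, S +21
cal·mol⁻¹·Å⁻²), and energies are reported in kcal/mol so that the
heat-capacity arithmetic below comes out in conventional units.
`rank_solvation_change()` averages residue energies over the frames of two
trajectories (two states) and ranks by |&Delta;mean|; the cut is a
configurable top-k or threshold because any fixed count is
trajectory-specific.

The heat-capacity estimator converts a change in total surface MHP between
two states into methylene-group equivalents using the calibration above
(&Delta;MHP / 50 per CH2) and then into &Delta;C_P at 15 cal·mol⁻¹·K⁻¹
per methylene transferred into water, reported in kcal·mol⁻¹·K⁻¹.  Both
steps are exact arithmetic; their value lies in the calibrated scale, not
in the conversion.  The estimator can be scoped to the pore border or to
all solvent-accessible dots of a selection — both scopes are exposed, as
the appropriate one depends on whether the question is about the pore or
the whole protein.

## Correlated motions and gate geometry

Collective motions are summarized by the generalized correlation
coefficient from linear mutual information.  For residues i and j with
3×3 displacement covariances C_i, C_j and joint 6×6 covariance C_ij
(computed from C&alpha; coordinates, optionally after rigid-body
superposition of every frame onto frame 1 using a stationary fit
selection),

LMI(i, j) = ½ [ln det C_i + ln det C_j − ln det C_ij],
r_LMI = sqrt(1 − exp(−2·LMI / 3)) &isin; [0, 1].

For an isotropically coupled Gaussian pair with per-axis correlation
&rho;, det C_ij = (1 − &rho;²)³ and r_LMI = |&rho;| exactly; the test
suite verifies this closed form by Monte Carlo at &rho; = 0, 0.5 and 0.95.
Covariances are regularized by adding 10⁻⁸ Å² to the diagonal before the
Cholesky log-determinants, and the Fischer inequality (LMI ≥ 0) is
enforced against numerical noise.  The superposition fit selection is the
caller's choice and should be a region that is stationary relative to the
motions of interest; fitting on the analysed atoms themselves subtracts
the signal.  `correlated_region()` reports, per chain, the residues whose
r_LMI with a reference residue reaches a threshold (default 0.7), so
single-subunit (asymmetric) patterns are visible directly.

Gate geometry uses three metrics.  The quadrilateral area spanned by four
gate atoms (one per chain) orders the points by azimuth about the pore
axis and sums the two triangles across a diagonal; collinear input
degenerates to zero with a warning, and a projected-shoelace variant gives
identical areas on planar convex quadrilaterals (tested against an
independent shoelace oracle).  Per-chain distances to the pore axis are
perpendicular distances to the vertical line through the per-frame
centroid of a reference selection, reported individually per chain — not
averaged — because gating asymmetry is precisely the signal of interest.
The helix bend angle splits an ordered C&alpha; trace at a pivot, fits a
least-squares 3-D line to each flank (minimum 4 residues) and reports the
inter-axis angle; this is a deliberate simplification of local-curvature
helix analyses, adequate for kink onset and magnitude but blind to
curvature distributed along the helix.  Least-squares flank axes are
phase-biased on windows much shorter than two helical turns, so flanks
should span at least two turns where possible.

## The synthetic test systems

`make_channel()` builds four-fold symmetric channel walls as pseudo-atom
shells: rings stacked along z whose accessible radius follows a prescribed
profile, with per-ring hydrophobic/hydrophilic labels mapping to fixture
constants of +1/−1, chains A–D as angular quadrants, and optional plug
disks that occlude the lumen.  Walls default to three concentric shells
(2.4 Å apart) because a single-atom-thin wall lets the cavity's
26-neighbourhood reach the channel's exterior surface and contaminate the
pore border — a thick wall emulates the bulk of a real membrane protein.
`make_trajectory()` adds Gaussian common modes with prescribed
cross-correlation, optional single-chain step displacements and
independent noise; `make_gating_trajectory()` clears the plug radially at
a known onset frame.  All generators are deterministic under a fixed seed
and restore the session RNG state.

These fixtures establish that the algorithms recover known ground truth:
radii within sampling error, gates and opening frames at their constructed
positions, correlation structure at its constructed strength, and the
open-minus-closed increase of hydrophobic pore surface when a hydrophobic
gate clears.  They do not establish performance on real data — cryo-EM
structures have irregular cross-sections, fractional occupancies, missing
loops and thermal disorder that the ideal geometry lacks, and the fixture
hydrophobicity constants (±1) are labels, not calibrated logP values.
The interface to real data is unchanged (PDB in, same pipeline), but
quantitative claims there inherit the usual uncertainties of the input
models.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `cell_size` | 3.4 | Å | occupancy-grid cell; coarse enough to absorb atomic radii |
| `dot_density` | 3 | dots/Å² | surface sampling density |
| `probe` | 1.4 | Å | water-sized probe for surface and ASA |
| `z_min`, `z_max`, `dz` | −20, 20, 0.5 | Å | profile range and slab half-width |
| `lambda` | 2 | Å | MHP exponential decay length |
| `mhp_per_ch2` | 50 | MHP units | methylene calibration constant |
| `cp_per_ch2` | 15 | cal/(mol·K) | heat-capacity increment per CH2 |
| `sphere_points` | 960 | — | ASA lattice points per atom |
| `r_lmi_threshold` | 0.7 | — | correlated-region cutoff |
| `eps` | 1e-8 | Å² | covariance regularization |

## Problem sizes and determinism

The test suite runs entirely on generated fixtures: channels of roughly
2–4 thousand pseudo-atoms, trajectories of 3–10 frames for the mapping
pipeline and 10³–10⁴ frames for the statistical estimators (two to one
hundred tracked atoms).  These sizes were chosen so that every stochastic
check sits well inside its tolerance at a fixed seed while the whole suite
remains quick to run; the estimators themselves scale to full-size systems
(the per-frame mapping cost is dominated by the dot surface, which is
linear in atom count with a neighbour-list constant).  All randomness in
the package flows through explicit seeds; the surface and ASA lattices are
seed-free and bit-reproducible.

## Known limitations

* The dot surface approximates reentrant (probe-rolling) geometry by
  rejection rather than constructing toroidal patches; areas of deeply
  creviced surfaces are slightly underestimated at low dot densities.
* Cavity detection is grid-based: pores narrower than about half a cell
  may be missed under unfavourable registration, and the reported border
  includes dots up to one cell away from the cavity.
* R(z) is a mean border distance, not a maximal inscribed sphere; on
  strongly non-circular cross-sections the two diverge by design.
* The LMI estimator is linear: nonlinearly coupled motions with zero
  linear correlation are reported as uncorrelated.
* The bend angle is a two-segment kink metric, not a local curvature
  profile.
* Only the largest merged cavity is mapped; the tool does not enumerate
  side pockets or fenestrations.
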