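# porescape

Pore profiling, hydrophobicity mapping and gating analytics for ion
channels.

Temperature- and ligand-gated channels such as TRPV1 open and close by
rearranging the residues that line their conduction pathway.  Two kinds of
quantities describe that process: the *geometry* of the pore (where it is,
how wide, where it is pinched shut) and the *physical chemistry* of its
lining (how much hydrophobic surface the pore exposes to water, which
residues change their solvation, which parts of the protein move
together).  porescape computes both families from standard inputs — PDB
structures and multi-model-PDB trajectories — and is aimed at
computational structural biologists analysing channel gating in MD
ensembles or between cryo-EM states.

## What it computes

**Pore detection and profiles.**  Cavities are detected on a 3-D occupancy
grid (cell 3.4 Å); cavities overlapping in the membrane (xy) plane are
merged so a closed gate does not sever the pathway, and the largest merged
cavity is the pore.  A dot Connolly-type surface (3 dots/Å², probe 1.4 Å)
restricted to pore cells and their neighbours forms the pore border S,
profiled in z-slabs (S_z = dots with |z_dot − z| ≤ dz, dz = 0.5 Å):

- pore centre `C(z)` = mean point of S_z,
- pore radius `R(z)` = mean in-plane distance from C(z) to S_z,
- pore hydrophobicity `H(z)` = mean dot MHP over S_z,

plus cylindrical (α, z) maps for single conformations and dynamic
(time, z) maps over trajectories, with gate occlusions and opening frames
read off automatically.

**Molecular Hydrophobicity Potential.**  MHP(p) = Σᵢ fᵢ·exp(−d(i,p)/λ)
with per-atom logP-derived constants fᵢ and λ = 2 Å.  Surface-MHP
distributions are area-weighted (bin heights are Å² of pore surface), and
the scale is calibrated so that one methylene group contributes 50 MHP
units of dot-surface total on n-alkane model compounds.

**Solvation energetics and ΔC_P.**  E_solv(residue) = Σ ASP(i)·ASA(i)
(five-class Eisenberg–McLachlan parameters, Shrake–Rupley areas), with
trajectory-averaged open/closed rankings.  A change in total surface MHP
converts to methylene equivalents (ΔMHP / 50) and to a heat-capacity
change at 15 cal·mol⁻¹·K⁻¹ per CH2 — e.g. ΔMHP = 400 units ⇒ 8 CH2 ⇒
ΔC_P = 0.12 kcal·mol⁻¹·K⁻¹.

**Correlated motions and gate geometry.**  Generalized correlations from
linear mutual information, r_LMI = sqrt(1 − exp(−2·LMI/3)) ∈ [0, 1], built
from 3×3/6×6 Cα displacement covariances (r_LMI = |ρ| exactly for an
isotropically coupled pair); per-chain correlated regions above a
threshold; gate quadrilateral areas (a square of Cα atoms with side 3.9 Å
has area 15.2 Å²); per-chain distances to the pore axis; helix bend
angles.

**Synthetic ground truth.**  A generator module builds four-fold channels
with prescribed radius profiles, hydrophobic belts and plug gates, alkane
calibration compounds, and trajectories with prescribed correlations and a
known opening frame — so the entire pipeline is testable offline.

## Worked example

```r
library(porescape)

# a closed channel: accessible radius 5 A, hydrophobic belt, gates at +/-8 A
spec <- channel_spec(radius_profile = function(z) rep(5, length(z)),
                     ring_pattern = function(z) if (abs(z) <= 10) "phobic" else "philic",
                     plugs = c(-8, 8))
ch <- assign_constants(make_channel(spec))

dots   <- surface_mhp(dot_surface(ch), ch)       # dot surface with MHP
cavity <- detect_pore(build_grid(ch))            # grid-based pore detection
border <- pore_border(dots, cavity)              # the pore border S
prof   <- pore_profile(border)                   # C(z), R(z), H(z)

occluded_bands(prof)
#>   band z_lo z_hi
#> 1    1   -9   -7
#> 2    2    7    9

range(prof$R[prof$defined & abs(prof$z) < 6])    # open section: true radius 5
#> [1] 4.451063 5.018196

# methylene calibration on pentane + hexane, and the heat-capacity arithmetic
cal <- methylene_calibration(list(make_alkane(5), make_alkane(6)))
cal$slope
#> [1] 50.00018
delta_cp(methylene_equivalents(400, cal$slope), 15)
#> [1] 0.1199996
```

The two occluded bands are the constructed gates; between them the profile
recovers the built accessible radius (5 Å) to within dot-sampling error.
The calibration slope is the surface-MHP increment of one CH2 group, and
the last line converts a 400-unit hydrophobic-surface gain into a
heat-capacity change of ~0.12 kcal·mol⁻¹·K⁻¹.

The `analysis/` directory holds numbered drivers that run the full story
on the synthetic systems — fixtures (01), pore profiles and maps (02),
MHP calibration and thermodynamics (03), solvation rankings (04), and
correlated motions with gate metrics (05) — writing tables under
`results/`.

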