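---
title: "Grid-based local membrane property analysis: methods and design"
author: "memgrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based local membrane property analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memgrid)
```

# Overview

Molecular-dynamics simulations of lipid bilayers are usually summarised by
spatial averages — mean thickness, mean area per lipid (APL), chain-averaged
deuterium order parameters.  memgrid instead maps these properties *locally*
onto a two-dimensional grid spanning the membrane plane, so that
perturbations caused by embedded peptides or proteins, cholesterol, or
undulations remain visible.  The workflow is:

1. represent each lipid by the centre of mass (COM) of a user-chosen atom
   group (whole lipid, head group, or a single phosphorus atom);
2. split lipids into top and bottom leaflets;
3. label every grid cell with the nearest lipid (or eligible protein atom)
   in the membrane plane, minimum-image distances in periodic boxes;
4. derive per-cell thickness, APL, order parameters and curvature, and
   accumulate statistics over trajectory frames.

All internal lengths are nm (PDB ångströms converted on read), times ps.

# Grid mapping

Leaflet assignment uses the mean-plane rule by default: a lipid is *top*
when its reference COM lies above the mean reference coordinate along the
bilayer normal (the z box axis unless configured otherwise).  For visibly
undulating membranes this rule misassigns lipids whose leaflet dips through
the global mean plane; the alternative tail-vector rule classifies by the
sign of the vector from the tail-atom COM to the lipid COM along the
normal and is exact whenever chains point away from the leaflet surface.
Assignment is recomputed every frame by default; a `freeze_leaflets` flag
reuses the first frame's assignment to guard against spurious flips in
near-planar systems.

The grid spans the in-plane box lengths of each frame (cells
`((i+1/2)dx, (j+1/2)dy)`), or, with the *breathing* option, the bounding
box of the frame's outermost lipid COMs.  Frames without box information
inherit the first frame's box.  Distances in the cell competition are
two-dimensional — the normal coordinate is ignored — because the grid is a
planar partition; in box mode they use the minimum-image convention, and
lipid COMs are wrapped into the primary box.  Breathing grids use plain
distances since their extent need not match the periodic cell.  Distance
ties are broken towards the lowest lipid index, and protein atoms lose
ties to lipids, making outputs deterministic and independent of input
order.  Every cell always has an occupant, so per-leaflet lipid areas plus
the protein area tile the grid area exactly — an invariant the test suite
asserts as an identity, not a tolerance.

Protein atoms enter the competition only if membrane-embedded by the
*precision* criterion: within a user radius (in-plane, minimum image) the
atom must see at least one same-leaflet lipid above it and one beneath it
along the normal.  This keeps solvent-exposed atoms off the grid while
letting transmembrane atoms compete near their own leaflet.

# Thickness and area per lipid

Per cell, thickness is the difference of top- and bottom-occupant normal
coordinates when both occupants are lipids; a user value for
protein/protein cells (default 0, flagging the protein footprint); and a
scaled difference (`scaling_value` in (0, 1], default 1) for mixed cells,
which damps the apparent thickness where flexible protein parts
transiently cover one leaflet.  The occupant's stored COM coordinate is
used directly — no interpolation — matching the per-cell difference
definition.  For mixed cells the protein side contributes the atom's own
coordinate; projecting onto a fitted leaflet surface was considered and
rejected as it would smuggle a smoothing model into a per-cell definition.

A lipid's area is its cell count times the cell area.  Conservation is
exact by construction.  Time statistics (mean, standard deviation, count)
are accumulated per cell **only over frames in which the cell held a
lipid**, so cells transiently covered by protein average only their lipid
frames.  The standard deviation is the population form (divide by N);
`sd_type = "sample"` switches to N−1.  Grid resolution: per-lipid and
protein areas computed at cell areas of 10 Å² and 1 Å² agree within a few
percent once averaged over a trajectory, so cells of 1–10 Å² are a
reasonable default; finer grids sharpen the Voronoi-like cell boundaries
without changing the estimates.

# Deuterium order parameters

United-atom and coarse force fields carry no hydrogens, yet ²H-NMR order
parameters are defined for C–D bonds.  memgrid reconstructs S_CD from
heavy-atom geometry via the order tensor

$$S_{ij} = \tfrac{1}{2}\langle 3\cos\theta_i \cos\theta_j - \delta_{ij}\rangle,$$

where θ_i is the angle between molecular-frame axis *i* and the bilayer
normal.  For a methylene carbon C_i the frame is: z along
C_(i+1)−C_(i−1), x normal to the three-carbon plane, y = z × x.  The two
C–D bonds sit symmetrically about the carbon plane with a tetrahedral
D–C–D angle, giving

$$S_{CD} = \tfrac{2}{3} S_{xx} + \tfrac{1}{3} S_{yy}.$$

For a cis double bond C_i=C_(i+1) the frame has z along the bond and x
normal to the sp² plane, and the deuteriums lie on the bisectors of the
actual instantaneous heavy-atom angles, with half-angles
α₁ = (π − ∠C_(i−1)C_iC_(i+1))/2 and α₂ = (π − ∠C_iC_(i+1)C_(i+2))/2:

$$S_{C_iD_1} = \cos^2\!\alpha_1\, S_{yy} + \sin^2\!\alpha_1\, S_{zz}
  - 2\cos\alpha_1 \sin\alpha_1\, S_{yz},$$
$$S_{C_{i+1}D_2} = \cos^2\!\alpha_2\, S_{yy} + \sin^2\!\alpha_2\, S_{zz}
  + 2\cos\alpha_2 \sin\alpha_2\, S_{yz}.$$

Using the measured angles (rather than assuming fixed 120° geometry)
removes one modelling assumption; the fixed-angle expressions are the
α = 30° special case.  The sign conventions above are tied to the frame
construction `x = normalize((C_i − C_(i−1)) × (C_(i+1) − C_i))` and to cis
geometry (both flanking carbons on the same side of the bond), which is
the configuration of biological unsaturated acyl chains.

The central correctness check is an *explicit-deuterium oracle*: place D
atoms geometrically (symmetric tetrahedral pair for methylenes, in-plane
bisector for sp² carbons), evaluate the definition ⟨3cos²θ_CD − 1⟩/2
directly, and compare with the tensor contractions.  Both agree to
machine precision on thousands of random conformers.  Two notes on the
oracle's validity domain: the methylene identity is exact when the two
C–C bonds have equal lengths (they do, to high accuracy, in simulations
and exactly in our fixtures); the sp² identity is exact for planar cis
fragments with any bond angles.

Averaging order: grid maps accumulate *instantaneous* per-frame S_CD
values per cell, so the only-lipid-frames rule is well defined; the
per-lipid report likewise averages per-frame values over time.  Applying
the contractions to the time-averaged tensor instead gives identical
results for saturated carbons (the contraction is linear) and differs for
unsaturated carbons only through the frame-frozen α coefficients; both
tensors are available via `order_tensor()`.  Terminal carbons have no
molecular frame and are reported as `NA`.  Lipids compete for cells via
their reference group once per frame — not per carbon — so all carbons of
one lipid map to the same cells.

# Curvature

Each leaflet's occupant coordinates along the normal form a height field
h(x, y) — a Monge patch S(x, y) = (x, y, h).  Central finite differences
(periodic wrap-around in box mode, one-sided at breathing-grid edges)
give S_x, S_y, S_xx, S_yy, S_xy, from which the fundamental forms follow:
E = 1 + h_x², F = h_x h_y, G = 1 + h_y², unit normal
N = (−h_x, −h_y, 1)/√(EG − F²), L = h_xx N_z, M = h_xy N_z, N₂ = h_yy N_z.
Mean and Gaussian curvature are

$$J = \frac{E N_2 + G L - 2 F M}{2 (E G - F^2)}, \qquad
  K = \frac{L N_2 - M^2}{E G - F^2}.$$

The denominator of J is 2(EG − F²) — the standard mean-curvature
combination, validated against closed forms: a sphere cap of radius R
gives |J| = 1/R and K = 1/R² (within 0.01 % at 100×100 bins), a cylinder
patch |J| = 1/(2R) with K = 0, a plane J = K = 0 exactly.  The form
2(EG − F)² sometimes seen in print fails these checks and is treated as a
typographical variant.  Normal orientation: N keeps a positive component
along the +normal axis for the top leaflet and negative for the bottom,
so both leaflets of a rigidly bent membrane report the same sign of J;
with this convention an upward bulge on the top leaflet has J < 0.

Undulation modes are separated by an ideal (brick-wall) Fourier filter:
the height field is transformed with a 2-D FFT, modes outside the band
are zeroed, and the inverse transform feeds the curvature calculation.
Bands are given either as fractions r ∈ [0, 1] of the available modes —
radial index r(m, n) = √((m/m_max)² + (n/n_max)²)/√2 over signed mode
indices, a choice we document because square or per-axis conventions are
equally defensible — or as absolute wave vectors q (nm⁻¹), converted
per axis to mode counts m_q = q·L_x/2π, n_q = q·L_y/2π (an elliptical
band; a mode (m, n) passes when q_low ≤ 2π√((m/L_x)² + (n/L_y)²) ≤
q_high).  The DC mode is kept only when the band's lower edge is exactly
zero.  The filter is a projection — idempotent and linear to 10⁻¹⁰ —
and an all-pass band reproduces the input bit-for-bit at print precision.

# Synthetic fixtures

`make_membrane()` generates geometric membranes with analytically known
properties; it emulates the *geometry* of bilayer snapshots, not their
thermodynamics.  Lipids sit on jittered lattices (jitter ≤ 20 % of the
spacing so the nearest-lipid partition stays unambiguous); head atoms lie
exactly on the analytic surface (flat, sinusoid, sphere cap, cylinder
patch); united-atom chains are all-trans zigzags with tetrahedral
backbone angles, built in a plane that *spins uniformly about the chain
director*.  The spin matters: a rigid planar chain rotated only about the
lab normal has strictly constant S_CD (rotations about the normal leave
every cos θ_i unchanged), and only director-spin averaging yields the
classic axial result S_CD = −(3cos²θ − 1)/4 for chains tilted by θ.
Chains with one cis double bond carry an exact planar 120° sp² fragment.

`embedded_cylinder` adds a cylindrical atom array spanning the bilayer,
with atom rings every 0.2 nm in z (one ring exactly at each leaflet
plane, so the precision criterion finds flanking lipids there) and
surface atoms at radius r − 0.2 nm, while an annular ring of lipids hugs
the cylinder at r + 0.2 nm — mimicking van-der-Waals contact, with the
nearest-distance boundary at the nominal radius r, so the counted protein
area converges to πr².  The annulus rotates rigidly by a uniform random
angle each frame, emulating annular lipid diffusion; without it, each
ring lipid would be pinned to a fixed sector of the square lattice and
its time-averaged area would carry a sector-specific grid bias.
Head-group z-jitter (0.1 nm in protein fixtures, zero elsewhere so flat
thickness stays exact) emulates the normal fluctuations that make the
above-and-beneath test meaningful.

What the fixtures do **not** emulate: thermal chain disorder, protrusions,
area fluctuations, realistic radial distribution functions.  Passing
tests therefore demonstrate correctness of the geometry → property
mapping, not force-field realism.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: a 7×7-lipids-per-leaflet
flat patch in a 5.3 × 5.3 nm² box (the scale of a ~100-lipid DMPC patch);
a 100-frame embedded-cylinder trajectory in a 6.4 × 6.4 nm² box analysed
at 10 Å² and 1 Å² cells (bins chosen as round(L/√a)); curvature closed
forms on 100×100 grids; 1000 random conformers for the order-parameter
oracle.  Sphere/cylinder curvature is evaluated on the central 21×21
cell block because those analytic surfaces are non-periodic and the
wrap-around stencil is only meaningful away from the box edges.
Tolerances asserted: identities (conservation, oracle equality at equal
bond lengths, tracelessness) at 10⁻¹²–10⁻⁶; discretised closed forms at
1 %; grid-convergence comparisons at 5 %.  Degenerate inputs error
early: collinear carbons (undefined molecular frame), 180° bond angles,
zero-mass COM groups, degenerate breathing extents, triclinic boxes.

# Known limitations

- Only rectangular boxes; triclinic cells are rejected on read.
- Only relatively flat membranes: leaflets must be height fields over the
  grid plane, so vesicles and stalks require pre-processing.
- Trajectory formats are multi-model PDB, multi-frame GRO and DCD;
  compressed Gromacs formats (XTC/TRR) have no reader in this toolchain
  and must be converted beforehand (e.g. `gmx trjconv`).
- No explicit-hydrogen trajectories: S_CD is reconstructed from heavy
  atoms (the oracle builds deuteriums only for validation).
- Saturation flags come from user configuration, not bond-order
  inference; no topology files are parsed.
- The per-frame parallel contract (`--threads`) is not implemented; all
  computations are vectorised single-thread and deterministic.

# A worked example

```{r example, eval = FALSE}
fix <- make_membrane("flat", n_side = 7, separation = 3.6, seed = 1)
maps <- map_frames(fix$frames, fix$sel, bins = 50)
th <- thickness_frame(maps[[1]]$top, maps[[1]]$bottom)
mean(th$values)        # 3.6 nm, exactly the construction separation
ap <- apl_frame(maps[[1]]$top)
sum(ap$lipid_areas)    # 28.09 nm^2 = the whole box area
```
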