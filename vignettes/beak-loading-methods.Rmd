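---
title: "Methods: finite-element analysis of bite loading in finch beaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element analysis of bite loading in finch beaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beakfem)
```

## The model

`beakfem` asks an engineering question about a biological structure: given
the forces a finch's jaw muscles can produce, how close does the bony upper
beak come to its failure stress, and how does that margin depend on beak
shape? The pipeline has four stages.

**Muscle forces.** Each dissected jaw-muscle bundle contributes a maximal
force through its physiological cross-sectional area,

$$\mathrm{PCSA} = \frac{m}{\rho\, l}, \qquad F = \sigma \cdot \mathrm{PCSA},$$

with bundle mass $m$ (g), mean fiber length $l$ (mm), muscle density
$\rho = 1036$ kg/m³ and specific tension $\sigma = 30$ N/cm². Because
pennate muscles are already split into their bundles in the dissection
table, no pennation-angle correction is applied. Two anatomical pathways
load the upper beak during jaw closing: the external adductor and
pseudotemporalis complex acts *indirectly*, through the jugal bar, so only
the component along the jugal is transmitted ($F_j = \cos\theta \sum F$);
the pterygoid/palatine complex acts *directly* ($F_p$). The depressor (jaw
opener, MDM) never contributes to closing loads, and the protractor (MPPtQ)
is excluded by default — whether it assists closing is not documented, so it
is left out of the palatine sum and the choice is configurable in the
packaged muscle table.

**Calibration of the pathway geometry.** The three-dimensional lines of
action behind the per-species muscle orientations are not published, so the
two-pathway model exposes exactly two effective parameters per species: the
jugal projection angle and a palatine transfer coefficient, calibrated so
that the resolved loads reproduce the published model input forces
($F_j$, $F_p$) for each of the eight species with dissection data.
`calibrate_angles()` inverts the model in closed form. Two caveats are
recorded in the outputs rather than hidden: the jugal angle only exists when
the target does not exceed the summed indirect force (otherwise an error —
no angle can produce it), and for two species the published palatine force
slightly exceeds the summed pterygoid force at 30 N/cm² (G. fuliginosa:
3.2 N target vs ~2.4 N available; C. parvulus marginally). The transfer
coefficient is therefore allowed above 1 and flagged
(`exceeds_raw_sum = TRUE`); forcing it to 1 would silently fail to reproduce
the published loading conditions.

**Finite elements.** The solver implements small-strain linear elasticity on
4-node (constant-strain) tetrahedra with two isotropic materials,
E_bone = 7.3 GPa and E_keratin = 1.7 GPa, in a consistent N–mm–MPa unit
system. Poisson ratios are not published with those moduli; the defaults
ν_bone = 0.30 and ν_keratin = 0.40 are the values conventionally used for
cortical bone and β-keratin in avian-beak FE work, are exposed in
`beak_materials()`, and are carried into every stress summary through the
configuration hash. The back rim of the beak is fully constrained (a
multi-node fixed patch, which also suppresses rotation), the bite patch is
fully constrained in translation (its reaction is the model bite force), and
the muscle loads are applied as statically equivalent equal nodal forces
over the attachment patches — regions of interest are far from the
attachments, so by Saint-Venant's principle the local distribution is
immaterial. The linear system is solved by sparse Cholesky factorization; a
solve is rejected unless the relative residual on free DOFs is below 1e-8.
Stresses are constant per element and evaluated at centroids, with no nodal
averaging before percentile extraction.

**Reporting.** Von Mises stresses are recorded on bone only, in three
regions: near the active bite point (vM1), on top of the nasal hinge (vM2),
and on the nasal bone (vM3) — both sides under the central tip bite, only
the ipsilateral side under the unilateral base bite, because a bird could
unload the contralateral side by tuning its bite and modelling that tuning
is out of scope. Regional "maxima" are 98th percentiles to avoid
constraint-driven outliers. Bone strength comes from the linear relation
$0.0061 \cdot E$, i.e. 44.53 MPa at 7.3 GPa, reported and used as 45 MPa at
two significant figures; the safety factor is strength over the peak of
vM1–vM3.

## The synthetic geometry

The study's original geometries are micro-CT segmentations; this package
replaces them with a parametric idealization so the pipeline is
self-contained and the shape→stress relationship can be probed
systematically. A beak is a superelliptical cross-section (exponent 2.5)
lofted along an axis with quadratic droop (`curvature` = tip drop / length)
and power-law taper (`taper_exponent`, default 0.8, with an 8% floor that
keeps a small open tip instead of degenerate slivers). The section depth is
split 40% dorsal / 60% ventral so that the thick palatal keratin of crushing
beaks (bottom keratin up to ~43% of total depth) fits inside the section.
Radially, each section carries an outer keratin sheath whose dorsal and
ventral thicknesses follow `ker_top_ratio`/`ker_bottom_ratio` (interpolated
around the circumference and tapering with the profile), a thin bony wall
(`bone_wall_ratio`, default 0.02 of length — no wall thickness is published,
so this is a configurable modelling choice), and an open internal cavity.
The bony core ends at 88% of length; the distal piece is solid keratin, so
the tip bite sits "close to the tip of the bony core" rather than at the
keratin tip. A dorsal-basal band (axial fractions 0.05–0.15) with the bone
wall smoothly thinned by up to 55% realizes the nasal hinge that lets the
upper beak flex.

Group defaults reproduce the published functional-group means (crushing:
depth/length 0.22, width/length 0.406, bottom keratin 0.095, top keratin
0.023; probing: 0.120/0.304/0.029/0.018; and so on), and `finch_cohort()`
draws one beak per species by jittering its group's means with the group's
published standard deviations (clamped at ±2 SD), so the synthetic cohort
spans the observed parameter ranges. Absolute beak lengths are not
published per species; every synthetic beak defaults to 15 mm, which is
irrelevant in the size-scaled scenario and stated explicitly here because it
*does* set absolute stress levels in physiological runs.

Load attachments (jugal left/right, palatine) sit on the ventro-lateral
surface at axial fractions 0.15–0.22 — distal to the nasal hinge — so that
the downward muscle pull rotates the upper beak about the hinge onto the
bite support. Placing them proximal to the hinge (the other geometrically
defensible reading of the attachment anatomy) starves the bite point of
load and nearly erases the tip/base contrast; the distal placement
reproduces the physically expected lever behaviour (base bite force ≈ 9.5 N
vs tip ≈ 1.1 N for 22.8 N of input on the default crushing beak) and is the
package's design choice.

The unilateral base bite is placed at axial fraction 0.25 of beak length —
a straight axial fraction, not arc length along the curved tomial edge; the
alternative reading would shift the station tip-ward by a few percent of
length and is not exposed. The patch has a fixed physical axial half-width
(2.4% of length) so its extent does not shrink under refinement, and the
side (default left) is recorded although the generated meshes are
symmetric.

**What the generator does not emulate.** Real beak cross-sections are not
superellipses; the bony core contains trabecular struts and local wall
thickness variation; keratin is layered, anisotropic and
hydration-dependent; bone density (and hence local stiffness and strength)
varies spatially — the gray-value normalization utility exists precisely
because the source imaging could only support a qualitative density scale.
Consequently, absolute stresses from synthetic geometry are not comparable
to CT-based values (the published scaled models reach ~100 MPa where the
synthetic cohort stays near 10–50 MPa), and the tests deliberately assert
only arithmetic replays of published values, orderings (tip vs base),
convergence behaviour, and correlation signs — not absolute synthetic
stresses. Passing tests therefore validate the pipeline's mechanics and the
shape→safety direction of effect, not a claim that a 15 mm superellipse is a
finch.

## Numerical choices

- **Meshing** is fully structured (loft grid × circumference × radial
  layers, each hexahedral cell split into six tetrahedra by the Freudenthal
  subdivision, which is conforming on structured grids) and deterministic;
  the seed only drives optional node jitter, which defaults off. Radial
  layers: one element layer per material below 20000 target elements, two
  above; convergence studies pin this (`radial_layers = 4`) so refinement
  acts on the surface directions at fixed through-wall resolution.
- **Percentile convention**: linear interpolation at rank
  $1 + p\,(n - 1)$ over sorted values (R's type-7 quantile); the published
  analysis names the percentile but not the convention. On 1..100 at
  p = 0.98 this gives 98.02.
- **Safety-factor rounding**: round-half-up to one decimal for reported
  values, full precision stored. Replaying the 16 published physiological
  stress rows through max → 45 MPa → SF reproduces 14 of the 16 published
  one-decimal SFs; the two exceptions (G. difficilis tip: 2.4 computed vs
  2.3 printed; C. parvulus base: 2.0 vs 2.1) cannot be produced from the
  printed integer stresses under any single rounding convention, which
  indicates the source computed SFs from unrounded percentile stresses. The
  tests assert exactly this state rather than papering over it.
- **"Natural loading"** is taken as base biting for all eight physiological
  models when computing the 1–2.5 safety-factor range, matching the source's
  own usage ("natural loading regimes (i.e. base biting)").
- **Stress pooling** is per element and volume-unweighted (a volume-weighted
  pool is a one-line change but is off, as the convention is unstated).
  Regions refuse keratin elements outright rather than filtering silently.
- **Bonferroni control** uses m = 4 within each safety-factor row of the
  correlation table, following the published note (0.05/4) even though
  eight tests appear across the two rows; the discrepancy is inherited from
  the source and documented here.
- **Surface normalization** for the size-scaled scenario uses the outer
  keratin skin area (scale factor $s = \sqrt{A_{ref}/A}$); normalizing on
  the bone surface instead is exposed via the `material` argument of
  `scale_to_reference()`.
- **Degenerate inputs** error early and descriptively: non-positive element
  volumes name the offending parameter combination, empty bite patches
  report the resolution, constant gray values refuse normalization,
  singular systems and residuals above 1e-8 abort the solve.

## Verification and problem sizes

The solver's contract is tested against independent oracles: a
hand-assembled B-matrix element stiffness, a dense brute-force assembly and
solve (meshes ≤ 200 DOF, agreement to 1e-10), the exact patch test under
consistent surface tractions (uniform stress to 1e-10; equal nodal loads
are *not* traction-consistent at face corners, which is why
`consistent_face_loads()` exists), a slender cantilever against the
Euler–Bernoulli deflection (L/h = 10; within 10% at the 60×6×6 reference
grid and improving under refinement — constant-strain tetrahedra converge
from the stiff side in bending), exact 1/s² stress scaling under uniform
geometric scaling, and frame invariance of von Mises stresses under rigid
rotation.

The mesh-convergence criterion (peak regional stress and bite force both
changing < 5% on a final doubling of element count) is met on the default
crushing beak over 8000 → 16000 → 32000 → 64000 elements at four radial
layers. The comparative cohort runs 13 beaks × 2 bite modes at 2500
elements each. These sizes are the package's verification conditions — far
below the millions of elements appropriate for CT geometries, and chosen as
the smallest sizes at which the monitored quantities are stable; anyone
reusing the pipeline on real geometries should redo the convergence check
at their own resolutions.

## Known limitations

- Linear elasticity, no contact at the seed, no geometric nonlinearity, no
  dynamics, first-order elements only.
- Single effective jugal angle and palatine scale per species instead of
  per-muscle 3-D lines of action (those are unpublished); the calibration
  reproduces the published input forces by construction, so it validates
  load *magnitudes*, not orientations.
- No density-dependent moduli or strength: bone is homogeneous, and the
  gray-value utility is retained only as a min–max normalization.
- Safety factors share the source's own caveats: moduli measured on a
  different estrildid species, a linear strength–modulus approximation, and
  preserved (not fresh) tissue.
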