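---
title: "Quantifying cortical osteolytic lesions by surface reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical osteolytic lesions by surface reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortlesion)
```

## The problem

Cancers that colonise bone (myeloma, breast-cancer metastases) drive
osteoclasts to erode focal holes — osteolytic lesions — through the cortical
shell. In murine models these lesions are imaged ex vivo by micro-CT at
single-digit-micrometre voxels, and therapy studies need the number of
lesions and the total lesion area as a fraction of the bone surface,
measured reproducibly. The traditional workflow renders the bone, captures
2-D screenshots from a few sides, and measures holes in ImageJ; it samples
only part of the surface, depends on the chosen views and clip planes, and
its inter-user variability is large. `cortlesion` instead analyses the full
3-D volume: it reconstructs what the cortical surface would look like
without lesions, subtracts the actual bone, and measures what was filled
in.

## The reconstruction model

The input is a binary bone-occupancy grid $X$ on an isotropic voxel lattice
(voxel edge $s$ µm), produced by a user-chosen intensity threshold and
restricted to one 26-connected component. The single scientific parameter
is the **maximum lesion diameter** $D_{\max}$ (µm): no hole wider than
$D_{\max}$ is considered a lesion. It sets the expansion radius in voxels

$$r = \left\lfloor \frac{D_{\max}}{2s} \right\rfloor ,$$

floored so that nothing wider than $D_{\max}$ is ever bridged (at the
reference scanner settings, $D_{\max} = 900$ µm and $s = 4.3$ µm give
$r = 104$ voxels).

Reconstruction is a two-stage volumetric diffusion realised through exact
Euclidean distance transforms:

1. **Outward expansion.** $E = \{v : d(v, X) \le r\}$, the distance-
   transform level set equal to dilation by a Euclidean ball of radius $r$.
   Every surface hole or pit of diameter at most $D_{\max}$ is bridged on
   the expanded outer surface.
2. **Locally optimised inward contraction.** For integer depths
   $d \in \{0, \dots, r\}$ the contraction family is
   $C_d = \{v \in E : d(v, E^c) > d\}$. Cubic windows of side
   $W$ (default $W = D_{\max}$) are tiled over the expanded surface with
   50 % overlap, and each window keeps the depth $d^\*$ maximising the
   overlap ratio
   $$\rho(d) = \frac{|C_d \cap X|_W}{|C_d|_W},$$
   with ties broken toward the smaller depth (less contraction). Window
   depths are blended by trilinear interpolation into a per-voxel depth
   field, and the contracted volume keeps the voxels deeper than the local
   depth. Windows whose shell is so thin that $\rho \equiv 0$ fall back to
   full contraction $d = r$.

The reconstruction is the union of the contracted volume with the original,
so it is extensive by construction. Because $X$ is always contained in
$C_r$ (the erosion of the dilation — closing extensivity), $\rho(d)$ is
non-decreasing in $d$ wherever the window actually shrinks, and every
informative window selects full contraction. The adaptive machinery
therefore coincides with the **global morphological closing** by a ball of
radius $r$ on all the geometries exercised here; `morph_close()` implements
that closing independently and the test suite asserts voxel-for-voxel
equality on flat and convex phantoms, with `morph_close()` itself checked
against a brute-force shift-based dilate/erode oracle. The window/overlap
formulation is retained because it is the method's defined procedure, it
produces the per-window depth/overlap diagnostics (`depth_field`), and it
is where thin-shell degeneracies are handled explicitly.

Two interpretation choices deserve note, as the procedure's prose admits
several readings:

* The overlap ratio is computed on **volumes** within the window
  (precision-like), not on surface voxels; volume overlap is robust on thin
  shells and reduces to the closing in the flat limit.
* Contraction depth is measured from **all** background of the expanded
  volume, not only from the border-reachable exterior. Measuring from the
  exterior alone would leave the dilation lining of the medullary canal in
  place and merge every through-hole with a canal-lining component; a
  hollow bone is only reconstructed sensibly if the endosteal surface is
  restored too.

## Lesion measurement

The difference $R \setminus X$ (reconstruction minus original) is labelled
into 26-connected components. Components smaller than `min_lesion_vox`
(default 8 voxels) are discarded as threshold noise: with the additive
noise levels emulated here, isolated misclassified voxels produce
difference components of a few voxels at most. Components with **no
exposed face on the reconstructed outer surface** are also discarded: an
osteolytic lesion is by definition a breach of the outer cortex, while
enclosed difference components are either filled interior cavities or
voxel-scale residue of the closing along the curved endosteal wall.

Each surviving lesion is measured two ways:

* `cap_area_um2` — the **en-face area of the opening**: exposed difference
  voxels are grouped into connected surface patches, and the largest patch
  is projected along its dominant face normal; the count of projected cells
  times $s^2$ is the cap area. For a flat opening this equals the mouth
  disc exactly; for the bowl-shaped cap left by a deep fill it still equals
  the mouth disc, because the bowl projects onto it. Raw exposed-face
  counts would overestimate deep caps up to three-fold and double-count the
  two mouths of a hole through a thin plate, which is why the projected
  area is the reported per-lesion area (the raw exposed-face area is kept
  alongside as `exposed_faces_um2`).
* `fill_vox` — the filled volume in voxels, reported because area and
  volume answer different biological questions and the method's area
  definition is a convention.

The denominator of the headline percentage is the surface area of the
**reconstructed** volume, so the reference area does not shrink as disease
grows. Surface area is estimated by counting foreground faces adjacent to
border-reachable background (enclosed cavities are not surface) and
applying the standard $2/3$ correction for the $3/2$ expected
overestimation of face counting on smooth surfaces; the uncorrected value
is always reported alongside. The correction is exact in expectation for
isotropically oriented surfaces and conservative for axis-aligned plates;
for a cylinder aligned with a grid axis it underestimates by about 15 %.
Numerator and denominator are conventions of the same order, and the
percentage is used comparatively.

De-selection of natural holes (nutrient vessels) is deliberately manual:
`deselect()` flags records and recomputes totals, `pick_lesion()` maps a
voxel coordinate to a lesion id (nearest lesion within $D_{\max}/2$,
ties to the lower id). Nothing is removed automatically, because widened
natural canals in diseased bone cannot be distinguished algorithmically
from lesions.

## The 2-D baseline

`render_face()` + `measure_2d()` reimplement the screenshot method
digitally: the volume is clipped in half along a viewing axis, the
near-camera half is projected orthographically, and lesions are the
interior background regions of the silhouette (background not connected to
the image border); the result is 100 × lesion pixels / (bone + lesion
pixels). The three face labels (concave, fibular, flat) map to fixed
viewing directions. The baseline exists to demonstrate the mechanism of
its own unreliability: on one phantom the three faces disagree and moving
the clip plane changes the answer, while the 3-D measurement of the same
volume is a single deterministic number.

## What the phantoms emulate — and what they do not

`make_phantom()` builds hollow cortical shells with exact ground truth: a
capped cylindrical shaft (wall thickness default 28 voxels) around a
capsule-shaped medullary canal whose ends are hemispherical, so the
interior contains no concavity sharper than the canal radius and the
closing restores the endosteal wall exactly. Through-holes are right
cylinders normal to the wall, because their mouth areas have closed-form
truth on the voxel lattice; an optional narrow canal plays the nutrient
vessel. Grayscale contrast is 0.8 vs 0.1 with additive Gaussian noise, all
randomness fixed by a seed.

The standard validation battery (`phantom_battery_specs()`) uses 20 such
shells with 2–4 holes of 8–24-voxel diameter on distinct walls and noise
up to 10 % of contrast, analysed at $D_{\max} = 24$ voxels. The wall
thickness is a geometric necessity, not a tuning: a closing fills a
through-hole of radius $a$ only if the two cap dips
$r - \sqrt{r^2 - a^2}$ (one per side) do not meet inside the wall, and at
$a = r$ each dip equals $r$, so the wall must exceed $2r$ (here 24 voxels)
for the largest admissible hole to seal; 28 voxels leaves a safety margin. Real cortical bone at
4.3 µm voxels is of comparable voxel thickness.

Phantoms do not emulate trabecular architecture, beam hardening, ring
artefacts, partial-volume blur, or irregular lesion shapes. Passing the
battery therefore demonstrates the correctness of the geometry pipeline
(thresholding, component selection, reconstruction, labeling,
measurement) under realistic noise, not robustness to scanner physics; on
real scans the user still owns the threshold and $D_{\max}$ choices, which
are exactly the two inputs the original inter-user comparison identified
as the remaining sources of variation.

## Numerical choices and degenerate inputs

* µm→voxel rounding is `floor` for the expansion radius, so a user-stated
  $D_{\max}$ is an upper bound; the derived radius is logged.
* A $D_{\max}$ spanning fewer than 2 voxels is an error; fewer than 4
  voxels warns, following the 4:1 object-to-resolution guidance for
  reliable detection (the smallest asserted hole in the battery spans 8).
* Ties in the window optimum go to the smaller depth; ties in patch
  dominant-axis selection go to the slice axis; `pick_lesion()` ties go to
  the lower id. All are documented, fixed, and deterministic — two runs on
  identical input are bit-identical, which is the limiting case of the
  reproducibility argument once the manual inputs are fixed.
* Discrete Euclidean balls of different radii do not nest exactly, so the
  filled volume is strictly monotone in $D_{\max}$ only at scale; at radii
  of 2–4 voxels a few-voxel decrease is possible and tolerated in the
  tests.
* The acute-angle wedge fixture (`make_acute_angle_phantom()`) carves a
  20° V-notch and then regularises the surface with a closing at a small
  rounding radius (3 voxels), mirroring the voxel-scale smoothing complex
  datasets receive. This makes the known-failure demonstration sharp in
  both directions: a $D_{\max}$ spanning the crease opening reports
  spurious lesions confined to the crease, while a $D_{\max}$ at twice the
  rounding radius reports exactly nothing, by closing idempotence. Without
  regularisation, a digitised sharp V reports staircase residue at every
  radius, which is the same limitation at a different scale.

## Problem sizes

The determinism check runs the full pipeline twice on a ~200³-voxel shell
(~7.2 M voxels, a few seconds per run); the battery uses 20 shells of
96 × 96 × 148 voxels; the selectivity sweep spans hole diameters 4–40
voxels at $D_{\max} = 24$. These sizes make the whole validation suite run
in minutes on one CPU while keeping every geometric margin (wall vs dip,
canal vs radius) at realistic proportions.

## Known limitations

* Trabecular bone and vertebrae are out of scope: closing-based
  reconstruction treats any sub-$D_{\max}$ concavity as a lesion, and
  trabecular space is all concavity.
* Acute re-entrant geometry is reported as lesions (demonstrated by the
  wedge fixture) — on such anatomy the output needs expert review.
* Enclosed cavities smaller than $D_{\max}$ are filled by the
  reconstruction but never reported (no surface breach); very large
  lesions approaching $D_{\max}$ in a thin wall may fail to seal, in which
  case they remain open and are reported only via their rim fill.
* Anisotropic voxels are rejected rather than resampled.
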