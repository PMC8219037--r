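---
title: "Quantifying 3D puzzle-cell morphogenesis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D puzzle-cell morphogenesis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleromorph)
```

## The biological problem

Nut shells such as walnut owe their toughness to sclereids that transform,
over a few weeks of fruit development, from small isodiametric cells into
large polylobate "3D puzzle cells" whose lobes interlock with neighbouring
cells. Quantifying this transformation needs per-cell 3D shape descriptors
computed from labeled segmentation volumes (e.g. from serial block-face
electron microscopy), plus chemical imaging of the walls (Raman
microspectroscopy) and stage-comparison statistics. `scleromorph`
implements that full analysis chain and, because segmentation stacks of
this kind are rarely public, ships a synthetic phantom generator with
exact ground truth so that every descriptor is validated end to end.

All volumes are indexed `(z, y, x)` with physical spacing `(sz, sy, sx)`
in µm; voxel `(i, j, k)` (0-based) occupies the closed cell with center
`((i + 0.5) sz, (j + 0.5) sy, (k + 0.5) sx)`. Anisotropic spacing is
honoured everywhere by weighted distance transforms and per-orientation
face areas; nothing is resampled to an isotropic grid.

## Shape descriptors

**Volume** is voxel count times the physical voxel volume. **Surface
area** comes from a triangulated iso-surface: the binary mask is lifted to
a smooth indicator with a Gaussian (default sigma 1.2 voxels) and
triangulated at level 0.5 by marching tetrahedra on the Kuhn six-tetrahedra
subdivision, which is face-consistent across grid cells and therefore
yields watertight meshes. Counting exposed voxel faces instead would
overestimate curved surfaces by up to ~50%; that count is retained only as
an internal upper-bound oracle (`voxel_face_area()`). On a digital sphere
of 40 voxels radius the mesh area is within a fraction of a percent of
4*pi*r^2.

**Solidity** — cell volume over convex-hull volume, the standard lobedness
measure (1 for convex shapes, decreasing as lobes and indents grow) — is
measured on that same iso-surface: enclosed mesh volume divided by the
volume of the convex hull of the mesh vertices. Measuring both terms on
one surface is deliberate. A hull taken over raw voxel corner points fills
the staircase cavities of the digitized boundary and deflates the solidity
of even a perfect ball by ~4–5% at realistic resolution, a bias that would
contaminate developmental comparisons; the surface-based ratio scores a
ball at ~0.999. The corner-point hull remains available as
`corner_hull_volume()` — it is exactly defined on the voxel model and is
the quantity our tests verify to 1e-9 against an independent computational
geometry implementation.

**Largest empty sphere (LES).** The diameter of the biggest sphere that
fits inside the cell — a 3D proxy for the maximal turgor-induced wall
stress — is twice the maximum of the anisotropic Euclidean distance
transform over cell voxels (distance from voxel center to the nearest
non-cell voxel center), with ties broken toward the lexicographically
smallest `(z, y, x)`. This is the inscribed-sphere ("Thickness")
convention; we always report diameters. The no-lobe baseline
`les_baseline()` extrapolates a reference stage isometrically:
`c = mean(les / volume^(1/3))` over reference cells, prediction
`c * V^(1/3)`. Isometry is our choice — the functional form of the
original "extrapolation" is not documented — and it is conservative: any
allometric exponent below 1/3 would only lower the baseline.

**Contact areas.** A contact face is a shared face between 6-adjacent
voxels of two different cells; areas are physical and per-orientation.
Faces of one cell pair are grouped into patches with 26-adjacency required
on both sides of the interface, so faces meeting only along an edge still
count as one "single area" — matching how fragmented contacts are read
visually. Intercellular space (ICS) breaks 6-adjacency and therefore
contact.

**Wall thickness.** Local thickness follows the largest-inscribed-sphere
definition: the thickness at a wall voxel is the diameter of the largest
ball containing it that fits inside the wall, computed as a distance
transform followed by a sphere-coverage sweep (largest radii painted
first). `thickness_excess_mask()` with the default threshold (the map
mean) isolates above-average thickenings — the cellulosic "loops" that
appear in developing walls.

## Lobe counting by anchored skeletonization

Main lobes are counted as endpoints of a pruned curve skeleton, after
morphological smoothing (closing then opening with a discrete ball,
default radius 2 voxels) removes segmentation-scale artefacts so that only
main lobes are counted. The discrete ball uses the midpoint convention
(voxels within r + 1/2): a ball of radius exactly r has single-voxel
lattice tips, and opening with such a ball provably cannot remove a
single-voxel pimple from a flat face.

Plain homotopic thinning, however, cannot do this job on its own: a
star-convex cell with surface bumps erodes layer by layer and collapses to
a point or short path before any lobe tip becomes a one-voxel curve end —
endpoints never form. Commercial centreline-tree implementations solve
this with tube-penalty parameters that seed branches at protruding tips.
We use the same idea in a transparent form: **anchored homotopic
thinning**. One anchor voxel is planted per main lobe and may never be
deleted; thinning (simple-point deletion in increasing distance-transform
order, preserving object and background topology with 26/6-connectivity)
then retracts the cell onto a medial tree whose branches reach every
anchor, and standard length pruning removes whatever shorter spurs remain.

Anchors come from the *radial excess*
`e(v) = |pos(v) − c| − r_ellipsoid(u_v)`: the protrusion beyond the
ellipsoid fitted to the cell's second moments (centroid `c`, semi-axes
from the eigenvalues of the position covariance). The ellipsoid
reference is exact for any unlobed ellipsoid, so smooth elongation of an
isodiametric cell generates no excess and no anchors — such cells keep
their conventional 2 "lobes". Candidate voxels must be weak local maxima
of the excess (suppressing the rims and saddles of smooth caps) and
exceed 0.35 of the maximum excess, with a floor of 1.25 voxels that
silences digitization staircase; greedy non-maximum suppression then
accepts peaks in order of decreasing excess, skipping candidates within
30 degrees of an accepted peak as seen from `c`. Two bumps that have
genuinely merged into one protrusion are counted once — which is the
biologically sensible reading.

The two user-facing knobs remain those of the original workflow:
`smoothing_radius` (voxels, default 2) and `min_branch_len` (µm, default
half the LES radius of the cell — scale-adaptive, so the same setting
works across a 13-fold volume range). Cells whose pruned skeleton has
fewer than two endpoints are scored as 2: an isodiametric cell has "two
ends" by convention, and a thinned ball degenerates to a short path or
point. On phantoms with K planted lobes of amplitude 0.35 the recovered
count equals K (within the ±2 band used for acceptance) in effectively
all runs for K in {4, 8, 12}.

## The synthetic phantom generators

The generators define the study conditions under which everything is
tested; they emulate structure, not texture.

* **Lobed cells** are star-convex:
  `r(u) = r_ellipsoid(u) (1 + A Σ_k g_k(u))` with unit-height von
  Mises–Fisher angular bumps `g_k` (concentration `bump_sharpness`,
  default 12 — bump half-width ~20°, comfortably separable up to ~14
  lobes) centred on Fibonacci-sphere directions jittered by the seed.
  Defaults: 10 µm mean radius, 0.6 µm voxels (~17 voxels per radius, the
  single-cell scale of a downsampled ~1000×1000×100 acquisition).
  Amplitude 0.35 for mature-cell emulation. The truth record carries the
  lobe count, bump directions, and a 20 000-direction quadrature estimate
  of the continuous volume.
* **Tissues** are Voronoi partitions of points sampled with a minimum
  separation; walls are carved by per-cell erosion (half the wall
  thickness per side), and a seeded fraction (`ics_fraction`) of each
  interface is opened into ICS as parallel stripes across the interface.
  Stripes — rather than round holes — were chosen because an interior
  hole does not disconnect a contact patch, whereas channel-like ICS
  (what net-forming intercellular space actually looks like) slices
  interfaces into separate patches; patch counts then rise monotonically
  with `ics_fraction`, and `ics_fraction = 1` severs all contact.
* **Reference spectra** are sums of Gaussian bands. The default
  six-entry library (cellulose, xylan, glucomannan, three pectins) is
  synthetic but places the diagnostic bands at their literature
  positions: cellulose at 378, 1095, 1380 cm⁻¹ plus the CH stretch;
  pectin ester marker near 850 cm⁻¹ shifting with the degree of
  esterification (856 cm⁻¹ for low, 853 cm⁻¹ for very high ester
  content) and the C=O band at ~1740 cm⁻¹.
* **Hyperspectral cubes** mix library spectra under smooth Gaussian-blob
  abundance maps, with multiplicative Gaussian noise (Raman shot noise
  scales with intensity; one relative-sd knob) and single-pixel,
  single-band cosmic-ray spikes of 20–100× the local intensity at seeded
  positions.

What passing these tests shows — and what it does not: the phantoms
validate geometry, topology and recovery logic under known truth; they do
not emulate segmentation errors, membrane-contrast failures, anisotropic
point-spread functions, or fluorescence backgrounds of real data. Real
stacks should be inspected with the same QC exports (meshes, skeleton
overlays, thickness maps) before trusting descriptor tables.

## Raman workflow

Despiking uses a per-pixel running-median filter (window 5) on
intensity-relative residuals with a robust (MAD) scale: cosmic spikes are
isolated single- or double-band excursions of 2000%+, while genuine band
curvature at ~2 cm⁻¹ sampling produces at most ~13% relative residual, so
the scale floor of 0.02 with the default z-threshold 8 separates the two
cleanly and makes the filter idempotent. Band-integral images are
per-pixel trapezoids (optionally above a linear chord); the CH-stretch
window 2831–3009 cm⁻¹ images total organic material.

NMF unmixing factorizes the pixels × bands matrix by multiplicative
updates on the Frobenius loss from a seeded non-negative start; the
objective trace is non-increasing and every factor stays non-negative.
The default k = 6 follows the reference workflow's six basic spectra; all
k endmembers are reported with cosine-similarity assignments to the
library (`match_endmembers()`), leaving component selection to the user
since no published selection criterion exists. Library fitting uses
orthogonal matching pursuit constrained to non-negative coefficients
(concentrations cannot be negative): atoms are added by largest positive
correlation with the residual and all coefficients refit by non-negative
least squares. Marker-band positions are localized by a three-point
parabola around the window argmax, giving sub-sample resolution — enough
to separate the 853 vs 856 cm⁻¹ esterification markers at 2 cm⁻¹
sampling.

## Statistics

Stage comparisons use the Kruskal–Wallis one-way ANOVA on ranks
(tie-corrected, chi-square approximation with df = g − 1; advisory
minimum group size n ≥ 5) followed by Dunn's all-pairs z on the pooled
mid-ranks with the standard tie term. Because reference software rarely
documents whether its Dunn p-values are multiplicity-adjusted, both the
unadjusted and Bonferroni-adjusted columns are emitted and the
significance flag uses the conservative Bonferroni column. Under the
null, the empirical type-I error of the omnibus test at alpha 0.05 is
calibrated to 0.05 ± 0.02 over 2000 simulations in the acceptance suite.

## Numerical choices and degenerate inputs

* Distance transforms use the exact separable lower-envelope algorithm
  with per-axis physical weights.
* The incremental 3D convex hull treats points within 1e-9 of a facet
  plane (relative to the bounding-box diagonal) as interior; coplanar and
  duplicated inputs are safe.
* Iso-surface meshes interpolate between grid values bracketing the 0.5
  level; masks are padded with a background layer first so surfaces are
  always closed.
* Label containers: 16-bit TIFF by default, auto-promoted to 32-bit for
  labels above 65535; labels beyond the 32-bit signed range are refused
  rather than truncated. Hyperspectral cubes are stored band-sequentially
  as 32-bit quantized intensities with the scale in the wavenumber
  sidecar (round-trip error ~2e-10 of full scale).
* Cells touching the volume border are excluded at measure time — their
  descriptors would be truncated.
* All generators and every stochastic algorithm take explicit integer
  seeds; the pipeline derives per-stage seeds deterministically from one
  global seed, and a rerun of the same configuration is byte-identical.

## Problem sizes

The shipped tests and the acceptance script run on grids of roughly
40–90 voxels per side (single cells), 8-cell tissues at ~36³, 24×24×1401
hyperspectral cubes, 20 seeds per lobe-count condition, and 2000 null
simulations for the statistical calibration — sizes chosen so the whole
validation runs comfortably on a laptop while every recovery experiment
retains its discriminating power.

## Known limitations

* Lobe anchoring assumes a star-convex-ish cell (radial excess measured
  from the LES center); strongly bent or dumbbell cells may need manual
  `min_branch_len` tuning.
* The solidity of extremely flat or single-voxel cells is undefined
  (degenerate hulls are refused with an explicit error).
* Despiking assumes spikes are spectrally narrow (≤ 2 bands); broad
  detector artefacts are not addressed.
* The synthetic reference library is a geometric stand-in — band
  positions are right, relative band intensities are not calibrated to
  any measured compound.
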