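---
title: "Methods: 3D micro-CT morphometry of cortical bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D micro-CT morphometry of cortical bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cortmorph)
```

## Scope and model

`cortmorph` quantifies the 3D microstructure of cortical bone from
high-resolution micro-CT reconstructions. The tissue is modelled as three
mutually exclusive phases inside a volume of interest (VOI):

* **mineralized matrix** — the bright phase;
* **vessel pores** — the intracortical canal network (Haversian/Volkmann-type
  channels, radii of roughly 10–50 µm) that carries the blood supply;
* **osteocyte lacunae** — ellipsoidal cavities of 30–8,000 µm³ housing
  osteocytes, at densities around 20,000–28,000 per mm³.

The coordinate convention is fixed throughout: the array is indexed
`[x, y, z]`, axis `z` is the anatomical long axis, `x` lies in the
bone-surface plane, voxels are isotropic, and the physical position of voxel
`(i, j, k)` (1-based) is `(i-1, j-1, k-1) * voxel_size_um` (voxel-centre
convention). Anatomy is metadata supplied at load time; the package never
infers it from image content, and registration/alignment of tilted samples is
out of scope. Anisotropic voxels are rejected.

## Segmentation

1. **Binarization.** Global Otsu on a 256-bin intensity histogram (the
   standard choice for bimodal micro-CT data; a fixed threshold is available).
   Foreground is the mineral phase. On a plateau between well-separated modes
   the midpoint of the arg-max set is taken, so the threshold is stable.
2. **Mineral-mask closing.** Pores are filled with Euclidean distance maps
   coupled to thresholding: dilation (`EDT(foreground) <= r`) followed by
   erosion (`EDT(complement) > r`), united with the input. Cavities with
   local radius up to `max_pore_radius_um` (default 60 µm, above the largest
   expected canal radius) are filled; wide outer background is re-opened by
   the erosion and thus preserved.
3. **Vessel pores.** `mineral_mask & !binary`, minus 26-connected pore
   components at lacunar scale (volume at or below 8,000 µm³), which are left
   to the lacuna extractor. This one rule prevents double counting: lacunae
   are bounded above by 8,000 µm³, canal systems are far larger.
4. **Lacunae.** A bottom-hat transform (grayscale closing minus the image)
   highlights dark blobs smaller than the structuring element; the response
   is thresholded at `mean + k*sd` (default `k = 3`) of its values inside the
   mineral mask, followed by 26-connected component analysis and the
   size/shape filter: volume in `[30, 8000]` µm³ (inclusive), principal
   length `L1 < 130` µm and principal width `L2 < 30` µm. Length and width
   are ellipsoid-equivalent principal-axis lengths, not Feret diameters — an
   interpretation, chosen for consistency with the shape analysis.

Two refinements stabilise the lacuna stage and are worth explaining because
they address systematic biases rather than tuning:

* **Half-maximum boundary refinement** (`refine_halfmax = TRUE`). The
  detection cutoff sits far down the blur skirt of each blob, so the raw
  component is systematically thicker than the cavity, which biases the
  short axis up and the axis ratios down. Each detected component is
  therefore re-delineated at the half-depth intensity contour between the
  local pore minimum and the mineral level; under a symmetric point-spread
  function this contour sits on the true phase boundary. Validated against
  exactly voxelized ellipsoids, the refined ratios are unbiased to within
  discretization error. The trade-off: at strongly curved surfaces the blur
  moves the half-depth contour slightly inward (curvature flow), so volumes
  of small lacunae are mildly underestimated.
* **Vessel guard band** (`vessel_margin_um = 3`). Within about two blur
  widths of a canal wall, the wall's own blur skirt produces a bottom-hat
  response indistinguishable from a lacuna; thin curved wall fragments would
  pass the size/shape filter. Voxels within 3 µm of the vessel mask are
  therefore excluded from lacuna candidacy.

The bottom-hat structuring element is a **cube** of half-width 15 µm
(covering the maximal lacuna half-width), implemented as separable running
max/min filters in O(n). A ball element differs only at the corners of the
window; for dark-blob detection the response inside lacunae is saturated
either way, and the separable form is what makes 256³ volumes tractable.

## Gross morphometry

All phase volumes are voxel counts times the voxel volume. `TV` is the
volume of the segmented envelope (all three phases), `BV` the mineral
volume; porosities are expressed relative to `BV` (`VV/BV*100`,
`LcV/BV*100`). Lacunar density is `count / BV` exactly.

**Cumulative distance statistics.** The Euclidean distance from every source
voxel to the nearest reference voxel (exact EDT, not chamfer) is accumulated
into a volume-weighted histogram with one-voxel bins; the reported distance
at fraction `f` is found by linear interpolation within the bin, so results
are stable at the reported (integer-µm) precision. The *mineral distance*
uses mineral as source and vessel pores as reference: the distance below
which 50%/95% of the mineral volume lies. The *vessel distance* measures
vessel-lumen voxels to the nearest lumen wall — an internal canal-radius
statistic, consistent with observed magnitudes (about 9–29 µm at 50%); the
interpretation is configurable by passing other masks.

**Surface area.** The co-area (smoothed-gradient) estimator: the binary mask
is Gaussian-smoothed (sigma 1.2 voxels) and `SA = sum(|grad u|) * voxel^2`.
Naive voxel-face counting overestimates smooth surfaces by up to 1.5×; the
co-area estimator is within ~5% for spheres at practical resolutions and
recovers flat faces exactly in the interior. Validated against the sphere
closed form, the face-count bound for a cube, and `SA/VV = 2/r` for
cylinders.

## Lacunar shape

For each component the second central moment matrix of its voxel-centre
coordinates is eigen-decomposed; a solid ellipsoid with semi-axis `a` has
moment `a²/5`, so the full axis lengths are `L_i = 2*sqrt(5*lambda_i)`,
sorted `L1 >= L2 >= L3`, with ratios `r13 = L1/L3` etc. (`r13 = r12*r23`
holds by construction). Moments use voxel centres without intra-voxel
correction, which is accurate to a few percent from roughly 10 voxels per
axis — adequate at the 640 nm-class voxel sizes where shape is analysed.
Coplanar/degenerate components are flagged with `L3` set to one voxel.

## Vessel-network orientation

The vessel mask is thinned to a one-voxel-wide, 26-connected curve skeleton
by homotopic thinning: simple points (deletions that preserve topology, via
the standard two-condition local test) are removed in order of increasing
distance-transform value, with curve endpoints preserved. Loop structure is
therefore retained. The skeleton splits into branch segments at voxels with
three or more skeleton neighbours (adjacent junction voxels merge into one
node).

Per segment: polyline arc length, cord length (endpoint distance), mean
thickness (twice the mean distance-transform value along the centerline),
attributed pore volume (nearest-segment propagation over the vessel mask),
and the two angles. The segment direction is the undirected endpoint
difference (cords are robust to skeleton jitter): `phi` is the angle to the
long axis (`phi = 0` means parallel to `z`), `theta` the projected angle to
the `x` axis in the x–y plane (`theta = 0` means parallel to the bone
surface), both folded to [0°, 90°] since segments are undirected. Segments
parallel to `z` have no x–y projection; their `theta` is flagged and dropped
from the theta histogram.

Orientation histograms span [0°, 90°] in 36 bins (2.5°/bin) and weight
segments by length (default; volume and count available). `s_phi` and
`s_theta` are the population variances (divisor = number of bins) of the
normalized amplitude vectors, and the level of alignment is their product,
`LOA = s_phi * s_theta`: aligned networks concentrate weight in few bins and
give large LOA; uniformly distributed orientations give LOA near zero. Bin
count and variance convention are configuration choices (reported magnitudes
of ~10⁻³ per-angle variances arise at this bin count); comparisons should
keep them fixed, as the bundled cohort tables do.

## Permeability

The absolute permeability tensor of the vessel-pore space is assembled from
three creeping-flow solves (unit body force along x, y, z). The solver is a
single-relaxation (BGK) D3Q19 lattice-Boltzmann scheme with Guo forcing and
half-way bounce-back at solid voxels — a standard discretization of Stokes
flow in voxel geometries. Boundary conditions are periodic on all faces,
treating the VOI as representative of an extended material. The relaxation
time default `tau = 0.933` minimizes the bounce-back slip error in
channel-like geometries. Iteration stops when the relative change of the
mean velocity falls below `tolerance` (default 1e-5) or at `max_iter`
(default 1e6); convergence metadata is reported.

Each solve yields a tensor column `K_j = nu * <u_j> / g` (superficial,
whole-domain mean velocity), converted to µm². Closed-form validation:
plane channel `K = h²/12` (with the averaging volume that excludes the
walls, i.e. the pore-averaged velocity), circular tube `K = pi r⁴ / (8 A)`,
and the `s²` eigenvalue scale law under geometric scaling. The assembled
tensor is symmetrized as `(K + K')/2`; eigenvalues are sorted descending and
clamped at zero (with a warning) below the numerical floor. Anisotropy is
summarized by `ratio_EV_mean = ((E2/E1) + (E3/E1))/2` and its inverse. A
non-percolating direction (checked by 6-connected face-to-face labeling)
yields a zero column with a flag rather than a failed solve. Geometry above
`max_dim = 128` voxels per axis is max-pooled first, which preserves
percolation.

## The synthetic phantom

The generator exists so that every pipeline stage can be tested against
known ground truth without the original scans. It emulates: a bright
mineral matrix; straight tubular vessel pores whose directions follow an
axial von Mises–Fisher distribution about `+z` with concentration `kappa`
(0 = isotropic); ellipsoidal lacunae with truncated log-normal volumes and
Gaussian axis ratios, long axes drawn from the same axial distribution
(osteocytes align with lamellae; configurable); then Gaussian blur and
additive Gaussian noise emulating detector blur and photon noise.

Defaults (the simulated study conditions): voxel 2.27 µm; tube radii
N(20, 5) µm truncated at 5 µm; `kappa = 20`; lacunar density 22,000 per mm³;
lacuna volumes log-normal with `meanlog = log(450)`, `sdlog = 0.6`,
truncated to [30, 8000] µm³; axis ratios N(3.0, 0.8) and N(1.4, 0.25);
intensities mineral 200 / pore 50, noise SD 10; blur sigma of one voxel of
the rasterization grid (the point spread of a real setup tracks its voxel
size, and a sub-voxel point spread would be unphysical — this is also what
makes the two-voxel-size experiment meaningful: the same specimen imaged at
a coarser voxel size is also imaged more blurrily, and its smallest lacunae
drop below the detection limit). The volume
distribution was chosen so that it genuinely spans the full filter window:
its mean (~520 µm³) sits in the observed 300–850 µm³ range while a real left
tail (a few percent below 150 µm³) exists — without that tail, all lacunae
would be comfortably above any scanner's detection limit and cross-resolution
comparisons would be meaningless.

All geometry is drawn in physical units before rasterization. Consequently
`rasterize_phantom()` can re-voxelize the *same* continuous specimen at a
different voxel size, which is how the voxel-size experiment is run: segment
the same phantom at 2.27 µm and 0.64 µm and compare lacuna counts. The
expected Poisson count uses the analytic (not rasterized) vessel volume for
the same reason. Lacunae are resampled when they would intersect a vessel
lumen or another lacuna; identical spec and seed give bit-identical volumes.

What the phantom does **not** model: osteonal/lamellar spatial clustering of
lacunae, curved or branching canal topology, canaliculi (below both voxel
sizes), beam-hardening or ring artifacts, and local variations in
mineralization. Passing recovery tests therefore demonstrates correctness of
the measurement chain on geometrically faithful, artifact-free data — not
robustness to every pathology of real scans.

## Statistics

Per-sample metric tables (columns `sample_id`, `patient_id`, `site` with one
AB and one FB row per patient) drive `group_summary()` (mean/min/max per
site), `paired_t_test()` (classical paired t on per-patient differences,
sample SD, `df = n-1`, two-sided) and `unpaired_t_test()` (pooled by
default; Welch available), both thin wrappers over `stats::t.test` with
explicit degenerate-input errors (zero-variance differences raise an error
rather than returning p = 0). `build_paper_tables()` reassembles the result
tables of a paired AB/FB comparison — site means with p-values,
cross-resolution density ratios, LOA with FB/AB ratios per patient, and
permeability inverts — from the per-sample values. For patient-paired
metrics the paired test is the default report (it reproduces the reference
density p-value from the printed per-sample values); both variants are
always computed.

The bundled cohort tables (`cohort_tables()`) carry the per-sample printed
values of a published eight-patient paired AB/FB synchrotron micro-CT
cohort, so the statistics stage runs without any raw scans.

## Numerical choices and edge cases

* Exact squared EDT via the separable lower-envelope algorithm; distances in
  voxel units scaled once.
* Component labeling: 26-connectivity for pores/lacunae (6-connectivity for
  percolation checks, the stricter and conventional choice for flow paths).
* Degenerate inputs error loudly: Otsu on constant volumes, empty reference
  masks in distance maps, empty report collections, zero-variance t tests,
  non-positive LOA denominators.
* Ties and flags: empty vessel phase flags distance/SA ratios as `NA`
  (missing), never 0; non-percolating flow directions yield flagged zero
  columns.
* Problem sizes in the shipped tests: phantom recovery runs one 256³
  rasterization (640 nm-equivalent) plus six paired 72³/256³ segmentations
  for the voxel-size experiment; permeability validation uses 24³-scale
  grids where the closed forms are already within tolerance. These sizes
  were chosen as the smallest at which the measured quantities are stable;
  all scale linearly if increased.

## Known limitations

* The vessel-distance definition (internal lumen radius statistic) is one of
  two plausible readings of "vessel distance"; the other (vessel-to-vessel
  spacing) can be obtained by passing other masks to
  `cumulative_distance()`.
* Lacunar volumes from the half-max refinement are biased slightly low for
  small, strongly curved lacunae (curvature flow under blur); axis ratios
  are unbiased.
* The LBM solver targets creeping flow only; no non-Newtonian or multiphase
  behaviour, and no canalicular-scale flow.
* Real scans need artifact-free VOIs; VOI selection is user input by design.
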