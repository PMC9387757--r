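---
title: "Methods: locating, projecting, labeling and template-warping intracranial electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating, projecting, labeling and template-warping intracranial electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ielec)
```

## The problem

Stereo-EEG (sEEG) and electrocorticography (ECoG) recordings are only
interpretable once each recording contact has a position relative to the
patient's brain anatomy. Four ingredients are involved: a pre-implant MR
(anatomy), a post-implant CT (contacts show up as bright metal blobs), the
channel names from the recording system, and — for group analyses — a
template brain. `ielec` implements the full headless chain:

1. **register** — align the CT to the MR by mutual-information (MI)
   maximization over an affine transform;
2. **snap** — refine each roughly-marked contact to the center of mass of
   its CT blob;
3. **project** — compensate ECoG "brain shift" by projecting grid contacts
   onto a leptomeningeal surface;
4. **label** — assign anatomical labels from a segmentation volume and
   color lookup table;
5. **warp** — map contact positions to a template brain through a symmetric
   diffeomorphic registration (SDR).

Everything is validated end-to-end on a synthetic head phantom with known
ground truth; the phantom generator is part of the package, not a test
afterthought.

## Coordinate conventions

Voxel indices are 0-based; world coordinates are scanner RAS in mm as given
by the NIfTI affine (sform preferred when both header codes are valid,
qform otherwise — the common neuroimaging convention; the file format does
not force a choice). Montage positions and mesh vertices live in the MR
subject frame unless tagged otherwise. A per-volume FreeSurfer-style
"surface RAS" offset is *not* applied anywhere: meshes are expected in
scanner RAS, and the phantom generator always writes them that way. All
distances (search radii, region caps, sampling balls) are computed in world
mm, so anisotropic voxels are handled correctly throughout.

## Affine registration

CT-to-MR alignment maximizes the joint-histogram mutual information
(`bins = 32` equal-width bins per axis spanning each volume's 1st–99th
percentile range, values outside clipped into the end bins, plain counts
without Parzen smoothing). The optimum is searched coarse-to-fine over a
Gaussian pyramid (smoothing sigma = factor/2 voxels for factors 4, 2, 1).
Two empirical properties of histogram MI shaped the level design:

* **sample count**: a 16³ grid yields 4096 samples — far too few for a
  trustworthy 2D histogram — so levels subsample by at most 2 regardless
  of their smoothing scale, and coarse levels use 16 bins instead of 32;
* **scale of rotation information**: at the heaviest smoothing a 10–15
  degree pose change barely alters the image and the MI optimum there can
  sit several degrees off (measured directly on phantom profiles), so the
  coarsest level fits translation only, and rotations enter at the
  factor-2 level through an exhaustive Euler-angle sweep (±13.5° in 3°
  steps around the current estimate, narrowed to ±3° by 1° at full
  resolution). MI over rotations is multimodal; the sweep, not the local
  search, is what guarantees the right basin.

Within each level the active parameters (translation; + Euler angles about
the fixed volume's world-space center; + log-scales and shears for the
affine stage) are refined by derivative-free coordinate descent in scaled
natural units (mm / degrees / percent), with line acceleration along
improving directions, step halving when a sweep fails, a floor of 0.01
scaled units, and a budget of 300 MI evaluations per stage per level. A
final Nelder–Mead simplex polish at full resolution finishes the job —
coordinate moves stall on the coupled rotation/translation ridges of the
MI surface. Only improving steps are accepted, so the MI trace is
non-decreasing within a level and the returned transform can never be
worse than its seed. Everything is deterministic.

Without a user seed, the search starts from the translation aligning the
two intensity centers of mass. If, after seeding, fewer than 10% of fixed
voxels map inside the moving volume, the fields of view barely overlap and
registration aborts with an explicit suggestion to provide a manual
pre-alignment — the same escape hatch clinical workflows use for unusual
poses (a 90-degree misalignment seeded with the true rotation converges to
sub-voxel residual; unseeded, the global MI landscape at such poses is
beyond the sweep's capture range and the search may settle in a wrong
basin).

Two findings from validation worth knowing: binning *interpolated*
intensities is the right choice here — partial-volume weighting of the
joint histogram grid-locks at zero rotation when both volumes share a
voxel size, and stochastic sample jitter destabilizes the coarse levels.
And when the true relationship is rigid (intra-subject CT to MR), register
with `stages = c("translation", "rigid")`: the affine stage's scale and
shear are unidentifiable on such data, and their ~1% drift leaks one to
two degrees into the rotation component of the result. The test suite's
rigid-recovery checks do exactly this; on twelve seeded phantom poses the
worst-case residual is 0.19 mm and 0.77 degrees.

Rotations are intrinsic Euler angles about the fixed volume's world-space
center; this pins down the covariance property (pre-rotating the moving
volume by a rigid `T` changes the result by exactly `T^-1`, which the test
suite checks).

## Snap-to-center

Given a seed near a contact, `find_local_peak` returns the brightest voxel
whose center lies within 5 mm (default) of the seed; ties resolve to the
voxel nearest the seed, then lexicographically. Equally bright neighbouring
contacts are the common real-world case — CT values are quantized — and
the distance tie-break is what makes the operation deterministic there.

`snap_to_center` then grows a region outward from the peak over
26-connected neighbours, admitting a voxel reached from region voxel `v`
iff its intensity does not exceed `v`'s (non-strict monotone decrease), is
at least `intensity_floor = 0.25` of the peak, and lies within
`max_region_radius = 5` mm of the peak. Admission depends only on
intensities — a voxel joins if *any* neighbour path admits it — so the
region is a fixed point independent of traversal order; the package ships
both a fixed-point iteration and a queue-based BFS and the suite checks
they agree on randomized volumes. The floor and radius cap are this
package's additions: a pure monotone criterion can leak along
partial-volume ridges into the skull. The snapped position is the
intensity-weighted centroid of the region ("center of mass" taken
literally, mass = intensity), which makes the operation idempotent to well
under a voxel and insensitive to where in the blob's basin the user
clicked.

## Brain-shift projection

ECoG grids sit deeper in the post-implant CT than the pre-implant pial
surface because the craniotomy changes intracranial pressure. Compensation
moves each selected contact to the **exact nearest point** on the
leptomeningeal mesh (point-to-triangle projection over all triangles,
vertex/edge/interior cases handled in compiled code; full scan — at the
mesh sizes involved a spatial index buys nothing and exactness is trivially
preserved). Projection is idempotent and never ray-casts along normals,
which would require a normal definition the data does not supply.

The leptomeningeal surface itself is produced from a pial mesh by
cotangent-weighted Laplacian smoothing in shrink/anti-shrink pairs
(Taubin-style, weights frozen from the input mesh) with a per-iteration
global rescale pinning the enclosed volume, followed by a minimal uniform
inflation until at least 99% of the input vertices are enclosed. On a
subdivided icosahedron sphere the scheme is a fixed point to about
3e-3 of the radius (the 12 valence-5 vertices respond slightly differently
from the rest — unavoidable on any closed triangulated sphere); dents are
smoothed (radial spread strictly reduced) and the enclosure pass costs the
filled sulcal volume, a few percent for shallow dents.

## Anatomical labels

Labels are sampled in a world-mm ball (default radius 2 mm, a documented
choice — about one contact length) around each position; fractions are
voxel counts over the ball, radius 0 degenerates to the nearest voxel, and
positions outside the volume return `Unknown`. Ties in the dominant label
resolve to the lower label id. `shaft_label_sequence` orders contacts by
their numeric suffix — contact 1 is the deepest by the field's numbering
convention — and reports each contact's dominant label.

## Template warping (SDR)

Subject-to-template mapping uses a greedy symmetric demons scheme on
intensity-normalized volumes (clamped to the 1st–99th percentile, rescaled
to (0, 1); same-modality MR-to-MR, so sum-of-squared-differences is the
appropriate match term). Per iteration the symmetric force
`(F - M)(∇F + ∇M)/2 / (|∇(F+M)/2|² + (F - M)²)` is capped at one voxel,
smoothed by a Gaussian of `field_sigma = 2` mm, and composed into the
forward displacement field; the backward field is maintained as the
fixed-point inverse of the forward one, which guarantees the
forward-backward round-trip stays below half a voxel for in-brain points.
The field lives on the fixed (template) grid at final resolution with
displacements in mm, so point warping is grid-independent: a subject-frame
point is carried through the pre-affine and then the sampled displacement
(points outside the field grid fall back to the affine with a warning
flag).

The iteration budget is (30, 30, 25) over pyramid factors (4, 2, 1),
chosen by running the budget up until the recovery error plateaued on the
default phantom: smaller budgets leave the greedy scheme visibly
under-converged at 1 mm resolution (worst-case contact error 1.64 mm at
(10, 10, 5) and 1.52 mm at (20, 20, 15), versus 1.42 mm at the default
with a ~1.40 mm plateau), while runtime stays under ten seconds at 64³.

`compare_linear_vs_sdr` quantifies the classic claim that a nonlinear warp
beats a linear (Talairach-style) transform: on the phantom's smooth
nonlinear ground-truth deformation, the mean SDR point error is roughly
half that of the *least-squares optimal* affine — a deliberately strong
baseline fitted on the ground-truth pairs themselves.

## The phantom: what it emulates and what it does not

`make_phantom` builds, deterministically from one integer seed, every input
the pipeline needs plus ground truth: a spherical brain (radius 22.5 mm)
with smooth sinusoidal internal texture inside an *ellipsoidal* skull shell
(dark in MR, bright in CT, with a smooth directional intensity modulation);
a subcutaneous fat layer (bright in MR); a 10-contact sEEG shaft and a
depressed 4x4 ECoG grid as Gaussian CT blobs (amplitude 1000 over a soft-
tissue floor of 40, sigma 0.9 mm); concentric segmentation shells with a
FreeSurfer-style LUT; pial/leptomeningeal icosphere meshes; a CT grid
related to the MR by a seeded rigid pose (rotation 5–15 degrees,
translation 5–20 mm, stored as ground truth); and a template MR produced by
warping the subject MR with a known smooth sinusoidal displacement field
(amplitude 3 mm, wavelength 40 mm, analytically invertible).

Deliberate design points, each mirroring a property of real data:

* **CT intensities are integers** (Hounsfield-like quantization) and the
  sEEG shaft lies on CT voxel centers with an integer 4 mm pitch, so
  equally bright neighbouring contact peaks tie *exactly* and the
  documented distance tie-break — not luck — selects the intended contact
  when seeds are jittered by up to 2 mm. CT noise defaults to 0: with the
  shaft laid out this way, independent voxel noise would make "brightest
  voxel within 5 mm" a coin flip between identical neighbouring peaks,
  which is a property of that selection rule, not of the noise level.
* **Faint CT soft-tissue texture correlated with the MR** gives the MI
  metric rotational information away from the skull (real CTs have weak
  but nonzero soft-tissue contrast); it is suppressed within 3 mm of every
  contact, where metal dominates real CTs, preserving the exact peak ties.
* **The skull is ellipsoidal and intensity-modulated** because a perfectly
  spherical, uniform head makes rotation unidentifiable for any intensity
  metric — real skulls are neither.
* **A 0.6 mm Gaussian point-spread function** is applied to the noise-free
  volumes before quantization and noise: scanners do not produce
  step-function edges, and analytically sharp boundaries interact with
  trilinear resampling to create spurious similarity optima degrees away
  from the true pose that no real acquisition would show. The PSF is
  linear and shift-invariant, so the exact contact-peak intensity ties are
  preserved.
* **The shaft is a chord** (both ends near the surface, middle deep): a
  10-contact shaft with tie-safe 4 mm pitch cannot be monotone in depth
  inside a 22.5 mm brain. Deep-to-superficial numbering is a naming
  convention and is unaffected.
* **Segmentation shells are concentric only**, so label boundaries are
  invariant to the seeded CT pose rotation and every contact keeps a
  ~1 mm margin to the nearest boundary across seeds.
* The MR carries Gaussian noise (sigma 5 on a ~400-intensity brain), and
  subject and template carry *independent* noise draws.

What the phantom does **not** emulate: gyral/sulcal geometry (dents are
shallow sinusoids), CT beam-hardening and metal-artifact streaks, partial
volume at 1 mm scale beyond trilinear sampling, bias fields, and
anatomically realistic segmentation shapes. Passing the suite therefore
demonstrates the correctness of the geometry, optimization and bookkeeping
of the pipeline under controlled conditions — not clinical-grade robustness
on pathological scans.

Problem sizes were chosen so the whole validation runs comfortably on one
CPU: 64³ voxels at 1 mm, a 642-vertex / 1280-triangle icosphere, 26
contacts. A full pipeline run (registration, snapping, projection,
labeling, SDR warp) takes well under a minute at this scale.

## Numerical choices and degenerate inputs

* Out-of-bounds resampling fills 0 (air), keeping MI histograms
  well-defined; label volumes always resample nearest-neighbour so no new
  ids can appear.
* A constant volume has zero MI with anything (degenerate histogram range
  collapses to one bin) — returned as exactly 0, not an error.
* An all-equal-intensity search ball makes the monotone region the full
  admissible ball and the snap returns its centroid (documented, not an
  error).
* Ties: peak selection (distance, then lexicographic index), dominant
  label (lower id), nearest triangle (lower id) are all pinned so results
  are deterministic and reproducible bit-for-bit; the pipeline manifest
  records materialized defaults and output checksums, and re-running a
  manifest reproduces outputs byte-identically.
* The phantom seed, the pipeline seed and every stochastic test fixture are
  explicit; registration itself is deterministic.

## Known limitations

* The MI optimizer is a local search: poses beyond the capture range
  (roughly the 15-degree / 20-mm regime it is validated on) need a manual
  pre-alignment, exactly as the overlap guard suggests.
* The affine stage may trade ~1% of scale for interpolation-induced MI
  gains; residuals stay well inside the half-voxel acceptance band but the
  transform is not constrained to be rigid.
* SDR is scoped to same-modality subject-MR to template-MR warping; no
  cross-modality metric is provided.
* The brain-shift model is purely geometric (nearest surface point); it
  does not model the physics of the shift, does not correct sEEG depth
  electrodes, and does not resolve collisions between projected contacts
  (pairs closer than 1 mm are only warned about).
* `smooth_to_leptomeningeal` assumes a closed, star-shaped-ish input mesh;
  its enclosure test uses nearest-triangle normals and is not a general
  point-in-polyhedron routine.
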