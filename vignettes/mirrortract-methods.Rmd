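---
title: "Lesion-mirrored tractography: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-mirrored tractography: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic phantoms can and cannot tell you, and
where the design was genuinely open.

## The measurement model

The quantity of interest is a per-patient *tract-count asymmetry*. The
healthy hemisphere acts as the patient's own control: the lesion ROI is
mirrored across the sagittal mid-plane, the mirrored ROI (intersected
with white matter) seeds deterministic multi-fiber tractography, and the
distal territories that those streamlines reach define data-driven
target ROIs. Whole-brain tractograms are then pruned to the streamlines
whose two endpoints connect the ROI pair, once per hemisphere (the
affected hemisphere uses the sagittal mirrors of the same ROIs), and the
percentage decrease

$$\mathrm{pct} = 100\,\frac{n_\mathrm{healthy}-n_\mathrm{lesioned}}{n_\mathrm{healthy}}$$

is the outcome. Dividing by the tumor volume (cm³) gives a damage
density that is comparable across lesions of different size; this
weighted value is what is regressed on the MIB-1 proliferation index.

Assumptions worth stating explicitly:

* **Mid-plane alignment.** Mirroring is performed in grid-index space
  (`i -> Nx - 1 - i` on the declared left–right axis). The volumes must
  have been aligned so the inter-hemispheric plane is the grid
  mid-plane; the package does not estimate that registration. Which axis
  is left–right is part of the grid metadata (`grid_spec(lr_axis=)`).
* **Anatomical mirror symmetry.** The healthy hemisphere is a valid
  reference only to the extent that the tract under study is roughly
  mirror-symmetric. The wide (10 mm) sphere targets exist precisely to
  absorb moderate left/right asymmetry of endpoint territories.
* **Counting unit.** A "tract count" is the number of retained
  streamlines, i.e. (seed voxel, peak) launches surviving the
  length filter and the endpoint pruning. It is a relative measure —
  meaningful as a ratio between hemispheres of one subject, not as an
  absolute fiber count.

## Tracking rules

Propagation is FACT-style: at each 0.5-step the peak of the *current
voxel* with maximal `|dot|` against the incoming direction is followed
(sign chosen to keep moving forward; ties go to the lowest peak slot).
Stopping rules: anisotropy below `fa_min`, a bend of more than
`max_turn` degrees across a voxel (the candidate direction is compared
against the direction with which the streamline *entered* the current
voxel, so the limit applies to the accumulated within-voxel turn), or
entry into a voxel outside the brain mask. The terminal point is the
first point inside the violating voxel, which is what endpoint pruning
against the dilated lesion ROI needs. Every launch runs in both
directions from the seed and the halves are concatenated; unidirectional
seeding would halve bundle recovery for seeds in mid-tract.

| parameter | default | unit | rationale |
|---|---|---|---|
| `fa_min` | 0.2 | – | classical white-matter anisotropy floor |
| `max_turn` | 60 | deg/voxel | excludes biologically implausible bends |
| `step` | half the smallest voxel | mm | finest step that still respects per-voxel semantics |
| `min_length` | 10 | mm | the analysis targets medium/long-range connectivity |
| `n_last` | 10 | voxels | endpoint neighbourhood harvested per streamline end |
| `exclusion_mm` | 20 | mm | peri-lesional shell excluded from target generation |
| `sphere_diam_mm` | 10 | mm | target ROI width, tolerant of hemispheric asymmetry |
| `opposed_angle` | 120 | deg | operationalisation of "diametrically opposed" |
| `dilation_factor` | 1.2 | ratio | single-target homolog ROI growth |
| `resample_threshold` | 0.9 | – | conservative mask transfer between grids |
| `kappa` | 80 | – | axial dispersion (~4.5° sd) of probabilistic steps |
| `iterations` | 1000 | – | probabilistic repetitions per launch |

The step size, the bidirectional seeding, the tie-break, and the
per-voxel turn accounting are implementation decisions: the per-voxel
phrasing of the turn rule fixes peak lookup at the nearest voxel (no
directional interpolation), and 0.5 voxel is the largest step for which
two consecutive points cannot skip a voxel.

## Target generation

Terminal voxels (the last `n_last` *distinct* voxels entered per end —
distinct voxels rather than points, because the step is smaller than a
voxel) are collected outside the exclusion shell and clustered in world
coordinates. k-means (Lloyd, 10 seeded restarts) is run for k up to
`k_max = 4`; k is chosen by mean silhouette width, with a fallback to
k = 1 when the best silhouette is below 0.5 — a single endpoint
territory is the correct answer for a seed station, and the silhouette
threshold prevents inventing structure in one diffuse cloud. For
silhouette evaluation on more than 2000 points a deterministic
subsample is used (the distance matrix is quadratic in n).

"Diametrically opposed" is made concrete as: the bearings of the two
most-populated centroids, seen from the seed's center of mass, subtend
at least 120°. Opposed pairs give a two-target analysis (the
contralateral region is an interconnecting node); otherwise the
majority centroid alone is the target and the 1.2×-dilated homolog ROI
is the second endpoint (seed-station case). Both the angle and k_max
are exposed in `run_config()` because they are judgment calls, not
measured quantities. In the affected hemisphere the dilated ROI is
mirrored back by default; `affected_endpoint = "lesion"` switches to
the original lesion ROI.

## The synthetic phantom

The phantom emulates the *geometry* of the study design, not the MRI
physics: it emits peak fields directly (no diffusion signal, no noise
floor, no b-vectors, no reconstruction step). One case is a 64³ grid at
1 mm isotropic (the clinical 1.0 × 1.0 × 1.5 mm geometry is available
through `grid_spec`), holding a gently curved bundle (a tube around a
spline centerline; every voxel within the radius carries a unit tangent
peak and anisotropy 0.8) built in the affected hemisphere, mirrored
exactly into the other hemisphere, and then lesioned on one side only:

* **Infiltration** deletes whole *fiber lines* — voxel columns indexed
  by the quantised cross-section offset in a parallel-transported frame
  — independently with the removal probability, only inside the lesion
  mask; voxels left without peaks get anisotropy drawn below 0.2.
  Deleting per fiber rather than per voxel thins the bundle the way
  graded infiltration does, and makes the deleted count exactly
  binomial in the number of crossing fibers.
* **Displacement** applies a radial push of the stated magnitude with a
  C¹ bump profile decaying to zero at twice the lesion radius; peaks
  are re-oriented by the local Jacobian of the forward map, the field is
  pulled back with an axis-aware trilinear interpolation, and the
  lesion core is emptied (anisotropy 0). The push is checked for
  invertibility (`magnitude * 1.5396 / (2 * radius) < 1`).

The reference case (`reference_phantom()`) uses a bundle spanning the
full anteroposterior extent of one hemisphere with a 2 mm arc sag, its
plane on voxel centers. The defaults were chosen once as the study
conditions: the infiltration case uses a 4.5 mm-radius bundle with a
7 mm lesion centered on it, so that *every* fiber line crosses the
lesion and there are enough (~80) independent lines for the binomial
deletion statistics to be stable at desk scale; the displacement case
uses a slimmer 2.5 mm bundle beside a large (7.5 mm) lesion whose
surface reaches the centerline, pushed 3 mm — an extra-axial mass
effect that slides the whole bundle without transecting it. Both
geometries put the bundle ends beyond the 2 cm exclusion shell, so
target generation resolves an opposed pair, which is the configuration
in which a blocked fiber actually fails the endpoint test (under
endpoint-in semantics, a fiber stopped *inside* a dilated lesion ROI
still counts as reaching it, so a single-target geometry cannot
register infiltration losses; the single-target branch is exercised by
its own unit tests).

What passing phantom tests does **not** show about real data: no
crossing-fiber ambiguity at the lesion (single-bundle lesions), no
imaging noise or reconstruction error in the peaks, perfect mid-plane
alignment, and exactly mirror-symmetric anatomy. The phantom validates
the pipeline's logic and its statistical behaviour under known truth,
not its robustness to acquisition artifacts.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based with the voxel-center convention; a voxel's
  world position is the affine image of its integer index. Masks are
  written as uint8 NIfTI with the affine in the sform; any nonzero
  value reads as true.
* `dilate_mm` uses an exact Euclidean distance transform (separable
  lower-envelope algorithm) with per-axis physical spacing, so
  anisotropic voxels are measured in mm.
* `dilate_to_factor` iterates 6-connected one-voxel dilation until the
  voxel count reaches the factor, returning the first iterate at or
  above the bound.
* Mask resampling interpolates the 0/1 field trilinearly and binarises
  at 0.9 — deliberately conservative, shrinking transferred masks at
  boundaries; the interpolation scheme is an assumption, stated here
  because only the threshold is prescribed by the procedure.
* ODF peak extraction takes strict local maxima over the tessellation
  neighbour graph (level-3 icosphere by default), refines each maximum
  by a quadratic fit in log-values on the tangent plane, and greedily
  enforces a 25° axial separation and a 0.25 relative floor; peaks are
  reported with the first nonzero component positive. An isotropic
  function has no strict maxima and yields zero peaks.
* Degenerate cases are reported, not hidden: a seed voxel without peaks
  yields a degenerate streamline with reason `low_anisotropy`; a case
  with zero healthy-hemisphere tracts is returned with
  `status = "uninformative"` and an `NA` decrease, with a warning.
* The probabilistic per-step model is an axial tangent-plane Gaussian
  with sd `1/sqrt(2*kappa)` — a Watson-like dispersion, exact in the
  large-`kappa` limit where it reproduces deterministic tracking; the
  parametric family is a design choice since only "a parametric model
  of uncertainty" is prescribed.
* Probabilistic runs are seed-reproducible (a dedicated Mersenne
  Twister in the compiled core); the case-level connection-probability
  images are accumulated in compiled code without materialising the
  ~10⁶ streamlines.

## Problem sizes

The shipped tests and the acceptance script run entirely on 64³
phantoms: deterministic case analysis takes a few seconds; one
1,000-iteration probabilistic hemisphere takes a few minutes on one
CPU. These sizes were chosen so that a full validation cycle fits in an
interactive session; all of them scale linearly in the number of
(voxel, peak) launches.

## Known limitations

* Streamline counts are a coarse proxy for axonal integrity; the method
  is a *relative* asymmetry measure and inherits all count-based
  tractography caveats.
* Nearest-voxel peak lookup makes individual trajectories sensitive to
  half-voxel geometry at bundle edges; the acceptance oracle therefore
  compares terminal voxels (within one voxel per axis) against a
  10×-finer integrator on interior trajectories.
* A displaced bundle squeezed into a thin peritumoral shell can defeat
  voxel-grid tracking even though the continuum field is integrable —
  visible in phantoms as a count decrease of order 10–20 % under pure
  displacement. Real meningioma cases show the same order of decrease,
  but the phantom cannot separate how much of that is biology versus
  discretisation.
* The k chosen by silhouette and the 120° opposition threshold are
  heuristics standing in for the visual inspection steps of an
  interactive workflow; they are logged and configurable rather than
  hidden.
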