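# mirrortract

Atlas-free quantification of tumor-induced white-matter damage from
diffusion-MRI fiber-orientation fields.

Brain tumors alter the white matter around and inside them in two very
different ways: extra-axial masses (typically meningiomas) *displace*
fiber bundles while leaving them largely intact, whereas infiltrative
gliomas *destroy* fibers in place. When a lesion does not sit on a
well-known tract, atlas-guided tractography has nothing to anchor to.
`mirrortract` implements a lesion-driven alternative for neuroimaging
researchers: the lesion mask itself, mirrored into the healthy
hemisphere, defines where to look, and the healthy hemisphere provides
the per-patient reference against which the damaged side is counted.

## Method

For one case (lesion mask, white-matter mask, brain mask, and a
per-voxel multi-fiber orientation field with up to three unit peaks and
an anisotropy scalar per voxel, all co-registered):

1. **Mirror seed.** The lesion ROI is reflected across the sagittal
   mid-plane and intersected with white matter; masks arriving on a
   different grid are resampled and conservatively thresholded at 0.9.
2. **Tumor-out tracking.** Deterministic multi-fiber streamline tracking
   is seeded from every voxel of the homolog ROI, one streamline per
   orientation peak, stepping at half a voxel with the classic stopping
   rules: anisotropy < 0.2, a bend of more than 60° across a voxel, or
   exit from the brain mask.
3. **Data-driven targets.** The last ten voxels of each streamline,
   outside a 2 cm peri-lesional exclusion shell, are clustered with
   k-means (silhouette-selected k). If the two dominant centroids are
   diametrically opposed as seen from the seed (≥ 120°), both become
   10 mm-diameter sphere targets; otherwise only the majority centroid
   does.
4. **Two-ROI counting.** Whole-brain tractography is pruned by endpoint
   membership in the target pair (or in the 1.2×-dilated homolog ROI
   plus the single target). The targets are sagittally mirrored and the
   same count is made in the lesioned hemisphere. The outcome is

   ```
   pct_decrease = 100 * (n_healthy - n_lesioned) / n_healthy
   ```
5. **Cohort statistics.** Per case, the decrease is weighted by tumor
   volume (cm³, from the lesion mask) and regressed against the MIB-1
   proliferation index; group contrasts use a pooled two-sample t-test.
6. **Probabilistic cross-check.** The same two-ROI analysis can be run
   with an axial angular-dispersion model (1,000 repetitions per launch),
   producing per-hemisphere connection-probability images whose support
   should contain the deterministic tracts.

Because no patient imaging is distributable, the package ships a
synthetic phantom generator (`reference_phantom()`,
`make_symmetric_case()`) that builds mirror-symmetric two-hemisphere
orientation fields with curved bundles and applies either a displacing
(invertible radial push) or an infiltrating (per-fiber deletion) lesion
with known ground truth.

## Worked example

A glioma-like phantom in which half of the fibers crossing the lesion
are deleted:

```r
library(mirrortract)

case <- reference_phantom("infiltrate", magnitude = 0.5, rng_seed = 1)
case
#> <phantom_case> 64x64x64 @ 1x1x1 mm; lesion mode infiltrate (magnitude 0.5), seed 1

res <- run_phantom_case(case, run_config(rng_seed = 1))
res
#> <case_result> phantom (opposed_pair)
#>   tracts healthy/lesioned: 3373 / 1766
#>   pct decrease: 47.64%   tumor volume: 1.42 cm^3
```

The endpoint clusters were diametrically opposed (`opposed_pair`), so
both hemispheres were counted between the two sphere targets; the
measured 47.6 % decrease recovers the simulated 50 % fiber removal, and
the tumor volume comes from the lesion mask geometry.

Cohort-level statistics on the packaged 16-case clinical table:

```r
cohort <- read_cohort(cohort_fixture_path())
regress_mib1(cohort)
#> <mib1_fit> r = 0.835, p = 5.73e-05 (n = 16)

group_summary(cohort)
#> # A tibble: 3 × 4
#>   group          n mean_pct sd_pct
#>   <chr>      <int>    <dbl>  <dbl>
#> 1 HGG            4     93.5   2.79
#> 2 LGG            7     61.9  28.1
#> 3 meningioma     5     17.8   9.17
```

The correlation of 0.83 says that the more proliferative the tumor
(higher MIB-1), the larger the volume-weighted share of fibers lost; the
group means separate displacing meningiomas (≈18 % decrease) from
low-grade (≈62 %) and high-grade (≈94 %) gliomas.

A command-line front end is installed as `exec/mirrortract` with
subcommands `simulate-case`, `track`, `make-targets`, `run-case`,
`run-case-prob` and `cohort-stats`; every output directory carries the
resolved configuration and RNG seed needed to reproduce it.

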