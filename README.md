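# fibrefab

Full-volume mapping of fiber orientation and degree of anisotropy in
segmented 3D voxel volumes — the kind of binary masks produced by
segmenting collagen fiber bundles or trabecular bone in high-resolution
(e.g. synchrotron phase-contrast) micro-CT.  It is written for tissue
biomechanics and morphometry work where individual fibers cannot be
traced, but their collective directional organization can be measured
statistically.

## What it computes

The core statistic is the **Mean Intercept Length (MIL) fabric
tensor**.  For a test direction **n**, parallel lines are traced through
the binary volume and MIL(**n**) is the mean length of uninterrupted
material runs along them.  Directional MIL is summarized by the
ellipsoid fit

    1 / MIL(n)^2 = nᵀ M n

whose eigenvectors are the principal material directions and whose
length-scale eigenvalues λ₁ ≥ λ₂ ≥ λ₃ > 0 (λᵢ = 1/√μᵢ in µm) are their
characteristic intercept lengths.  The degree of anisotropy is
DA = 1 − λ₃/λ₁ ∈ [0, 1] (0 isotropic, → 1 perfectly aligned), and the
magnitude attached to each sample is λ₁.

Around this core the package provides:

* a sliding-window **orientation field** (primary eigenvector,
  eigenvalues, DA, material fraction per window) with CSV export;
* **axial directional statistics**: dominant-axis fractions along the
  anatomical axes (X lateral–medial, Y ventral–dorsal, Z
  cranial–caudal), projections onto the sagittal YZ / frontal XZ /
  transverse XY planes, rose histograms weighted by fiber frequency or
  summed magnitude, anisotropy summaries, and regional contrasts
  (e.g. rim vs center of a disc);
* **morphometry**: exact tissue volume, anatomical extents, local
  thickness and separation by the largest-inscribed-sphere definition
  (Tb.Th / Tb.Sp conventions), volume fraction, and a global fabric DA;
* **synthetic phantoms** with known ground truth (parallel and
  block-crossed fiber bundles, isotropic sphere packings, trabecular
  lattices, and a biconcave disc with circumferential reinforcement
  rims) used throughout the tests to validate recovery;
* TIFF stack I/O with JSON sidecar metadata, and a deterministic
  end-to-end pipeline (`run_pipeline()`) plus a thin CLI
  (`inst/cli/fibrefab.R`).

## Worked example

```r
library(fibrefab)

# a phantom with known truth: fibers along X, 30% volume fraction
ph <- generate_phantom(phantom_spec("parallel_fibers",
                                    shape = c(64, 64, 64),
                                    target_volume_fraction = 0.3,
                                    primary_axis = "X", seed = 7))
ph
#> <phantom_volume> parallel_fibers, 64 x 64 x 64 voxels, fraction 0.302, seed 7

field <- map_orientation_field(ph, window = window_spec(32, 16),
                               directions = sample_directions(128))
field
#> <orientation_field> 27 samples (of 27 windows; 0 low-fraction, 0 degenerate skips), edge 32 vox, spacing 1 um

dominant_axis_fractions(field)
#> <axis_summary> total 27 vectors: X 100.0%, Y 0.0%, Z 0.0%
summarize_anisotropy(field)
#> <anisotropy_summary> mean 0.569 median 0.584 sd 0.027 (n = 27)

# whole-volume fabric at a 6.48 um voxel
ft <- fit_fabric_tensor(compute_mil(ph$mask, 6.48, sample_directions(128)))
ft
#> <fabric_tensor> eigenvalues (um): 116.27, 43.4798, 39.3423 | DA: 0.6616 | primary axis: 1 0.005316 -0.00436
```

Every retained window recovered the X axis (the phantom's truth), with
a prolate fabric (λ₁ ≫ λ₂ ≈ λ₃, as expected for rod-like structures)
and a whole-volume DA of 0.66.  The windowed mean DA (0.569) is lower
than the global value because each 32-voxel window truncates runs at
its own boundary.

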