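---
title: "Mapping fiber anisotropy with Mean Intercept Length fabric tensors"
author: "fibrefab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fiber anisotropy with Mean Intercept Length fabric tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibrefab)
```

## The problem

Dense fibrous tissues -- the fibrocartilage of a temporomandibular joint
disc, trabecular bone beneath its cartilage -- owe their mechanics to the
direction in which their material is laid down.  High-resolution
phase-contrast micro-CT can resolve collagen fiber bundles and bone
struts across a whole specimen, and deep-learning segmentation turns
those scans into binary masks.  Individual fibers, however, remain
impractical to segment one by one in a woven network, so the question
"which way does the tissue point here, and how strongly?" has to be
answered statistically.  `fibrefab` answers it with the classic
stereological tool for exactly this situation: the Mean Intercept
Length (MIL) fabric tensor, evaluated in sliding windows to produce an
orientation vector field over the whole volume, followed by the
directional and morphometric statistics used to summarize such fields.

## The model

**Mean Intercept Length.**  For a test direction $\mathbf{n}$, a family
of parallel lines (perpendicular spacing `line_spacing_vox`, default 2
voxels) is traced through the bounding box of the material phase.
Along each line the mask is sampled every half voxel with
nearest-voxel lookup; a maximal run of material samples is one
*intercept*.  Then

$$\mathrm{MIL}(\mathbf{n}) \;=\;
  \frac{\text{total sampled material length}}{\text{number of intercepts}}.$$

Structures elongated along $\mathbf{n}$ give long intercepts along
$\mathbf{n}$ and short ones across it.  Runs truncated by the volume
boundary count as one intercept; this convention only matters in the
solid-volume limit and is covered by the tests.  Directions with zero
intercepts are dropped from the fit rather than imputed.

**Fabric tensor.**  Directional MIL is summarized by the ellipsoid fit

$$\frac{1}{\mathrm{MIL}(\mathbf{n})^2} = \mathbf{n}^\top M \,\mathbf{n},$$

solved by least squares over all sampled directions (a spherical
Fibonacci set on the upper hemisphere, default $n = 128$; fiber
orientations are axial, so one hemisphere suffices).  The reported
length-scale eigenvalues are $\lambda_i = 1/\sqrt{\mu_i}$ for the
eigenvalues $\mu_i$ of $M$, sorted $\lambda_1 \ge \lambda_2 \ge
\lambda_3 > 0$; the eigenvector paired with $\lambda_1$ is the primary
material direction.  The degree of anisotropy is

$$\mathrm{DA} = 1 - \lambda_3/\lambda_1 \in [0, 1],$$

0 for an isotropic fabric and approaching 1 for perfect alignment.
The scalar *magnitude* attached to each orientation sample is
$\lambda_1$ in micrometres.  Both choices are fixed conventions of this
package: the anisotropy index is one of several normalized eigenvalue
ratios in use, chosen because it maps isotropy to 0 and extreme
alignment to 1; the magnitude is the primary eigenvalue itself rather
than a function of all three.

**Orientation field.**  The volume is tiled with cubic windows (default
edge 32 voxels, stride 16, i.e. 50% overlap).  Windows below a material
fraction of 0.05, or whose fit is degenerate, are skipped and counted --
never patched.  Each retained window contributes one sample at its
geometric center: primary eigenvector (sign-canonicalized so the
dominant component is positive, ties broken X before Y before Z),
eigenvalues, DA, and material fraction.  At a 6.48 µm voxel the default
window is ~0.2 mm, the scale at which fiber bundles in dense
fibrocartilage appear locally parallel.  Window edges should also not
exceed the width of the thinnest band being characterized, or windows
straddle structures and dilute their anisotropy -- the same rule that
sizes the crossed-phantom blocks relative to the window.  For the disc
phantom below, whose rim band is 15--22 voxels wide, the bundled
analyses use edge 24 / stride 12.

**Directional statistics.**  Orientations are axial ($\mathbf{v} \equiv
-\mathbf{v}$), so all angular statistics fold at 180°.  The package
reports dominant-axis fractions (each sample assigned to the anatomical
axis -- X lateral-medial, Y ventral-dorsal, Z cranial-caudal -- of its
largest $|e_1|$ component), projections onto the three anatomical
planes (sagittal YZ, frontal XZ, transverse XY; samples with in-plane
norm below $10^{-6}$ are counted as excluded, not dropped), rose
histograms in two weightings (*fiber frequency*: one count per sample;
*sum magnitude*: each sample weighted by $\lambda_1$, a proxy for total
reinforcement along that direction), anisotropy summaries (mean,
median, sample standard deviation; a single sample has sd 0 by
convention), and region contrasts such as rim minus center.

**Morphometry.**  Tissue volume is the exact voxel count times
spacing³.  Extents are axis-aligned bounding sizes in the anatomical
frame.  Local thickness uses the largest-inscribed-sphere definition of
trabecular morphometry: the thickness at a voxel is the diameter of the
largest sphere containing it that fits in the mask.  The inscribed
radius at a candidate center is its Euclidean distance to the nearest
background voxel center *minus half a voxel* (the distance to the phase
boundary), so an isolated voxel has thickness of exactly one voxel
spacing, a digitized ball of radius 10 has maximum thickness ~19--20
voxels, and an 8-voxel gap has separation 7.  Separation is thickness
of the void phase within an ROI.  Distance transforms are exact
(Felzenszwalb separable EDT in compiled code); sphere painting is
pruned by a neighbor-dominance test that cannot change the result.

## The synthetic phantoms

The raw specimen scans behind analyses of this kind are rarely
deposited, so the package ships generators whose ground truth is known
by construction.  They are first-class, tested code, and every
recovery claim in the test suite is made against their truth records.

* **Parallel fibers**: hard cylinders (default radius 4 voxels)
  rasterized along a chosen axis, each centerline tilted by at most
  `orientation_jitter_deg`; fibers are added until the realized volume
  fraction reaches the target (within about one fiber volume; a target
  below half a fiber volume yields the empty-mask limit).
* **Crossed fibers**: the volume is tiled into cubic blocks, each
  filled by one of two orthogonal families; the primary family gets
  `round(mixing_fraction * n_blocks)` blocks.  Blocks are segregated
  rather than interpenetrating so window-level dominant-axis truth is
  well defined; block edges must exceed the window edge.
* **Isotropic blobs**: a Boolean model of spheres with uniform random
  centers -- the null phantom for anisotropy.
* **Trabecular lattice**: a Gaussian-smoothed random field (FFT
  smoothing, kernel scale = `fiber_radius_vox`) thresholded at the
  exact target quantile; stretching the kernel along one axis (default
  stretch 3 when used) imposes a preferred strut orientation.
* **Biconcave disc**: a superellipse footprint (exponent 2.5, semi-axes
  0.46 of the grid, wider laterally than ventrodorsally like the real
  disc) with half-thickness profile $h(\rho) = h_c + (h_r - h_c)\rho^2$
  ($h_c = 0.18\,n_z$, $h_r = 0.45\,n_z$), so the center is thinner than
  the peripheral band.  The rim (outer `rim_width_fraction` of the
  radial coordinate) is filled with closed circumferential
  reinforcement rings that follow the contour with a gentle vertical
  undulation; the center is filled with short capsules whose
  orientations are uniform on the sphere, blended toward the local
  circumferential direction by `center_alignment`.  Both regions fill
  to 0.35 of their voxels.  The sampled center directions are stored in
  the truth record so their uniformity can be tested directly.

Randomness is counter-based: each fiber derives its own generator seed
from the phantom seed and the fiber index through three Lehmer
scrambling rounds, so adding fibers never reshuffles earlier ones and
neighbouring fibers get decorrelated streams.  Identical spec + seed
reproduces every phantom bit for bit.

What the phantoms do *not* emulate: X-ray physics, reconstruction
artifacts, noise textures, partial-volume gray levels, or fiber
diameter distributions of real tissue (fiber radii are free parameters,
not calibrated).  Passing recovery tests on phantoms therefore
demonstrates correctness of the estimator chain, not accuracy on any
particular scanner's output.

## Numerical choices

* Line sampling uses half-voxel steps with nearest-voxel lookup; the
  induced bias is below one step and is covered by the stated test
  tolerances.  The identical geometry is implemented independently in
  plain R in the test suite, and the compiled path must match it
  exactly (integer intercept counts, lengths to 1e-9).
* The least-squares fabric fit requires at least six usable directions
  spanning 3D; degenerate fits signal a typed condition carrying the
  fitted matrix.
* Eigenvector sign is canonicalized (dominant component positive, X >
  Y > Z on ties) to make axial data deterministic in CSV exports and
  tests.
* The CSV export serializes floats with 9 significant digits -- enough
  to round-trip the float32-level fidelity of the rest of the chain.
* TIFF storage: integer volumes are written losslessly at 8/16 bits;
  float volumes as 32-bit fixed point scaled to [0, 1] with the scale
  in a JSON sidecar (~1e-9 relative precision).  Spacing is never
  guessed: reading without a sidecar requires an explicit value.
* Pipeline outputs are byte-deterministic given the seed; the manifest
  records md5 checksums, per-stage counts, and the config echo.

## Problem sizes

The bundled validation runs use 128³ voxel phantoms with 128 sampling
directions and 32/16 windows for the parallel, crossed and isotropic
recoveries; 192 x 128 x 48 for the disc with 24/12 windows; 96³ for the
trabecular lattice; and small analytic solids (spheres, cylinders,
slabs) for morphometry.  These sizes were chosen so each recovery has
hundreds of windows while a full validation pass completes in minutes
on a single core; all of them are parameters, not limits.

## Known limitations

* MIL is a boundary-counting statistic: it needs a segmented (binary)
  volume and says nothing about gray-scale data.
* The window attribution is to the geometric center with no sub-window
  refinement; structures thinner than a window are blurred across it.
* The direction set is deterministic; its residual angular anisotropy
  (second moment within 0.02 of isotropy at n = 128, verified in the
  tests) bounds how precisely eigenvectors can be recovered (rotation
  tests allow 1°).
* Thickness assumes isotropic spacing and errors out otherwise.
* Statistics are descriptive, matching their usual role in specimen
  characterization; no inferential machinery across specimens is
  provided.
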