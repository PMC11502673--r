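---
title: "Quantifying B-cell immune synapses: methods and conventions"
author: "SynapseQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying B-cell immune synapses: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapseQuant)
```

## The measurement model

SynapseQuant quantifies the polarized response of a B cell engaging an
antigen-coated bead. All measurements operate on one shared
representation: a `Scene` holding co-registered `ChannelStack`s (3D
intensity grids indexed `[z, y, x]` with physical voxel size
`c(dz, dy, dx)` in µm), the bead geometry in physical coordinates, and an
optional cell mask. Three conventions are fixed once and used everywhere:

* **Axis order** is `[z, y, x]` for arrays; physical points are reported
  `(x, y, z)` in µm; voxel indices are 0-based with a voxel's centre at
  index × spacing. One stated convention prevents silent transposition
  bugs.
* **Anisotropy is carried, never resampled.** Volumes are voxel counts ×
  `dz·dy·dx`; in-plane areas are pixel counts × `dy·dx`. No isotropic
  interpolation is ever performed, so voxel-counting volumes mean exactly
  what they say.
* **No background subtraction by default.** An optional constant offset
  (`backgroundOffset` in the pipeline config) is subtracted and floored
  at zero when requested.

### Polarity index

For a label with fluorescence centre of mass $L$, cell centre of mass
$C$ (uniform weights over the cell mask) and bead centre of mass $B$
(from bead geometry), the index is the signed projection of $L - C$ onto
the unit axis $\hat u = (B - C)/\lVert B - C \rVert$, divided by the
axis length:

$$\mathrm{PI} = \frac{(L - C)\cdot \hat u}{\lVert B-C \rVert}.$$

It is $+1$ when $L = B$, $0$ when $L = C$, and $-1$ at the mirror point
of the bead through the cell centre. Components of $L$ orthogonal to the
axis do not contribute, and the index is invariant under rigid motion of
the whole configuration. A degenerate axis ($B = C$) is an error — no
index is reported. Raw values outside $[-1, 1]$ (label centre beyond the
bead along the axis, possible with blur bleeding past the contact point)
are **clamped and flagged** rather than excluded: clamping keeps group
means comparable while the flag preserves the information. Whether such
cells should instead be excluded is a genuinely open choice; the flag
lets users take either route.

The index is defined on 3D points; single-plane (epifluorescence-style)
data simply use points with a common z.

### Around-bead and extraction measurements

Lysosome accumulation at the synapse is the channel intensity, summed
over cell voxels whose $(x, y)$ lies within a disc concentric with the
bead, divided by total cell intensity. The printed "3.5 µm" of the
source procedure is read as the **radius** of that disc: a 3.5 µm radius
fully contains a 3 µm bead plus a docking rim, whereas a 3.5 µm diameter
would clip the bead itself. The radius is configurable
(`analysisRadius`), and the fraction is provably in $[0, 1]$ and
monotone in the radius.

Antigen extraction uses the same fixed disc on **sum projections** of
each time point's stack, normalized to 100 % at time 0; time 0 must be
present and non-zero or the series is rejected. Within a cohort the
baseline is the mean of the time-0 scenes of the same condition.

### Synaptic-plane metrics

The synaptic plane is supplied explicitly or chosen as the z-slice of
maximal integrated intensity of a template channel (the
actin/phalloidin channel in practice) — an automated stand-in for
selecting the slice by eye on the phalloidin label.

* **Spreading area**: shoelace area for polygon outlines, pixel count ×
  pixel area for masks.
* **Recruitment index**: fluorescence density in a central region over
  density in the whole outline, minus one; 0 for uniform, positive for
  central, negative (≥ −1) for peripheral distributions. The central
  region is the outline scaled about its centroid to ¼ of the total
  area — exactly factor 0.5 for polygons; for raster masks the factor is
  refined by bisection until the rasterized central region holds ¼ of
  the outline pixels, which keeps the ¼-area contract for arbitrary
  shapes. The source formula's primary definition (ratio vs difference
  of densities) is not fully specified upstream; the density-ratio-minus-one
  form is the default because it reproduces the stated sign semantics
  with 0 for uniform, and a log-ratio variant is available
  (`method = "log"`).
* **Circularity**: $4\pi A/P^2$. For polygons, $A$ and $P$ are exact.
  For raster masks $A$ is the pixel-count area and $P$ is measured on
  the marching-squares 0.5-level contour after a circular moving-average
  smoothing (window 5, applied only to contours of ≥ 40 vertices). The
  raw marching-squares length overestimates a disc's perimeter by ~5 %
  (staircase bias); smoothing brings disc and ellipse perimeters to
  within ~0.5 % of their analytic values, which the test suite verifies
  against an independent 4-direction Cauchy–Crofton estimator.
  Multi-component masks are rejected with instructions to pass the
  largest component.
* **Focus/particle counting**: Otsu or fixed threshold inside the
  outline, then 8-connected particles kept when their physical area lies
  in the closed window $[0.10, 4.00]$ µm² (both bounds inclusive — the
  printed closed range; comparisons use a 10⁻⁹ tolerance so exact-area
  particles are not lost to floating point).

### Segmentation and 3D compartments

The voxel-model chain mirrors the classical threshold → erode → z-link →
voxel-count procedure:

1. `thresholdStack`: Otsu (256-level histogram; global or per-slice) or
   fixed threshold; voxels are foreground iff intensity **strictly
   exceeds** the threshold. Constant channels are an error under Otsu
   (no separable classes). The original analysis used a trained
   random-forest pixel classifier for this step; a trained classifier is
   not portable, and the downstream metrics — not the classifier — are
   what this package implements, so thresholding plus an escape hatch
   for user-supplied masks (`readMask`) stands in its place.
2. `erodeSlices`: per-slice 2D erosion with a 3×3 square element,
   outside-image pixels treated as background (so border blobs erode
   too), iterated as configured.
3. `linkRoi3d`: connected components with 8-connectivity in-plane and
   face adjacency across consecutive slices (≥ 1 overlapping voxel
   column links two slices) — the minimal reading of "adjacent ROIs
   along z are connected", with no centroid-distance gating. In-plane
   connectivity is configurable to 4; 8 is the default since the
   upstream tool's convention is unstated. Component ids are sorted by
   size (largest first) with a stable tie-break on first-voxel order.

Compartment selection is **all-or-nothing**: a compartment "contains" a
marker when ≥ 1 of its voxels intersects the marker model — selection is
by contact, regardless of the amount of marker — and then its whole
volume counts. A `minOverlap` knob supports sensitivity analyses. The
nested readout reports (i) the volume of compartments containing
marker 1 as a percent of total compartment volume, and (ii) the voxel
intersection of those selected compartments with marker 2 as a percent
of the whole population's intersection with marker 2. Zero denominators
yield flagged `NA`s, never 0.

Volume binning uses edges `c(6, 12)` µm³ with bins $[0,6)$, $[6,12]$,
$(12,\infty)$; the printed labels "<6", "6–12", ">12" leave the
boundaries ambiguous, so the convention is fixed (boundary values fall
into the closed middle bin) and attached to every result as an
attribute.

### Colocalization

Pearson's $r$ is the sample correlation of paired voxel intensities over
the whole masked z-stack. Manders M1 is the fraction of a channel's
integrated intensity inside a binary reference label. Because the
upstream procedure does not state an intensity threshold for the
reference, the reference is a segmented `VoxelModel` whose provenance
(method, threshold, erosion) is carried along with the coefficient.
Percentages and M1 are reported per cell and summarized across cells as
mean ± SEM (`summarizeMetrics`), matching per-cell plotting practice;
voxels are never pooled across cells.

## The synthetic-scene generator

No imaging data ships with the package; `generateScene` renders scenes
with known truth instead. The generative model is deliberately the
simplest one that exercises every measurement pathway:

* The **cell** is an ellipsoid (default semi-axes 4 × 4 × 3.5 µm — a
  resting-size B cell of ~8 µm diameter).
* The **bead** (default radius 1.5 µm, i.e. a 3 µm bead) is tangent to
  the cell surface along a configurable direction; an optional
  bead-surface antigen shell (0.3 µm thick) is rendered into the "Ag"
  channel so extraction and around-bead metrics have a bead signal.
* **Compartments** are solid spheres with radius ~ N(0.35, 0.1²) µm
  (lysosome-sized), placed strictly inside the cell with bounded
  retries. With probability $p$ (`polarization`) a compartment's
  direction from the cell centre follows a von Mises–Fisher kernel
  (concentration `kappa = 8`) peaked at the bead direction, in the
  unit-ball frame of the ellipsoid; otherwise placement is uniform in
  the cell. The radial law is the uniform-in-ball law in both branches,
  so the expected index is continuous and monotone in $p$ — exactly the
  property needed for recovery testing. A mixture model keeps the map
  $p \mapsto \mathrm{PI}$ close to linear.
* **Markers** are assigned per compartment as independent Bernoulli
  draws from `markerTable` (defaults: LAMP1 always, Ag and SNX5 each
  with probability 0.5); compartments with no marker are flagged
  unlabeled.
* **Rendering**: unit-amplitude solid spheres summed per channel,
  convolved with a separable Gaussian PSF (σ defaults 0.2 µm lateral /
  0.5 µm axial — typical confocal scales), then Poisson shot noise
  (50 photons per intensity unit) and additive Gaussian read noise
  (σ = 0.01), clamped at zero. Noise is applied last.
* **Grid**: voxel size defaults to `c(dz = 0.35, dy = 0.15, dx = 0.15)`
  µm (within the 0.25–0.5 µm z-step range typical of these
  acquisitions), with a 1 µm clear margin so PSF tails stay away from
  the (circular-convolution) grid border.
* One **seed** drives a single RNG stream; the caller's RNG state is
  saved and restored, and identical specs yield voxel-identical scenes.

`SceneGroundTruth` is computed from the pre-noise geometry: compartment
centres/radii/volumes and marker membership, per-channel volume-weighted
centres of mass and the polarity index they imply, and pre-blur
voxelized marker models from which true overlap volumes are counted at
voxel resolution.

`expectedPolarity` is the matching oracle: it simulates placements only
(no rendering) and returns the Monte-Carlo mean ± sd of the index of the
volume-weighted compartment centre. At $p = 1$ the expected index is the
maximum attainable for this geometry — about 0.4–0.5, not 1, because
even fully bead-directed placement spreads mass over a cone and over
radius. A label reaches +1 only when its centre of mass coincides with
the bead centre, which is how the analytic bound is (and should be)
tested.

**What the generator does not emulate**: photobleaching and blinking,
realistic (Airy/Gibson–Lanni) PSFs, camera gain and offset calibration,
membrane-localized labels, touching/merging organelles with non-spherical
shapes, and cell-to-cell morphological variability. Passing tests
therefore demonstrate the correctness of the measurement chain on
geometrically explicit scenes, not segmentation robustness on real
microscopy; on real data the threshold/erosion settings (or supplied
masks) carry that burden.

## Problem sizes and numerical tolerances

The test suite runs the recovery study at 20 seeds per polarization
level in $\{0, 0.25, 0.5, 0.75, 1\}$ on the default generator (40
compartments, blur and noise on, grids of roughly 27 × 68 × 88 voxels),
comparing cohort means against `expectedPolarity` at 200 placement
simulations; these sizes give Monte-Carlo standard errors a few times
smaller than the 0.15 mean-absolute-error budget while keeping the whole
suite in a few minutes. Oracle-equivalence checks use ≥ 100 random grids
of up to ~10×12×12 voxels, where exact (not approximate) agreement is
asserted against scalar flood-fill and direct-formula oracles.
Geometry checks use a 1024-gon circle (circularity 1 within 10⁻⁴), the
analytic square (π/4), and a 5 µm disc rasterized at 0.05 µm pixels
(area within 1 % of 25π µm²).

Scenes round-trip through multi-page TIFF losslessly for integer
intensities up to 16 bits (and as 32-bit float with a recorded scale
otherwise); voxel size, channel names, beads and metadata travel in a
JSON sidecar, and reading a stack with neither sidecar nor configured
voxel size is an explicit error, never a silent default.

## Known limitations

* Thresholding stands in for trained pixel classification; heavily
  textured or low-SNR channels may need user-supplied masks.
* Watershed splitting of touching organelles is not implemented: two
  touching compartments form one 3D component, as in the voxel-counting
  procedure being reproduced.
* The Manders reference and the in-plane connectivity follow documented
  defaults where the upstream tools' conventions are unstated; both are
  configurable and recorded in provenance so results remain auditable.
* The pipeline emits per-cell metric tables only; hypothesis testing is
  intentionally out of scope.
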