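---
title: "Methods: volumetric registration and atlas quantification of cervical spinal cord imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric registration and atlas quantification of cervical spinal cord imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cordquant` implements an end-to-end analysis for serial-section
fluorescence imaging of the mouse cervical spinal cord: raw per-section
stacks are condensed to maximum-intensity projections, registered into a
symmetric average template, classified pixelwise into signal classes by a
random forest, and the classified signal is accumulated per atlas region
(cervical level x Rexed lamina x hemicord x motor pool) for nonparametric
group statistics. Because real cords produce hundreds of gigabytes per
animal, the package ships a synthetic phantom-cord generator with exact
ground truth; every stage is validated against it.

# The atlas model

Regions are enumerated as level (C1-C8) x lamina (1-10) x hemicord
(left/right), with lamina 6 absent at C1-C3; motor pools (trapezius,
phrenic, biceps, forearm flexor, forearm extensor, axial) are subregions of
lamina 9, and one white-matter tract region per level and hemicord carries
the axon reference signal. The builder is schema-driven rather than a
hard-coded region list: the published atlas this mirrors counts 94 regions
between C1 and C8, but its exact composition is not enumerable from public
sources, so the package derives regions from the schema and keeps the count
a property of the inputs. Region ids are assigned deterministically in
enumeration order; id 0 is background.

Voxel indices in the R API are 1-based `(z, y, x)` as is idiomatic in R; all
serialized interchange (fiducial CSV, transform JSON) is 0-based, which is
what downstream tooling expects. Z increases rostral to caudal. The midline
is a declared x-position, by default the half-integer centre of the x axis
so that mirror pairing is exact. Hemicord labels are anatomical
(left/right); ipsi/contralateral views are derived at aggregation time from
the per-sample injection side.

# The phantom generator

The generator is first-class, tested code, and its defaults define the
study conditions used throughout the tests:

* **Grid**: 50 sections of 256 x 256 pixels at 10 um in-plane and 40 um
  axially. This is a desk-scale stand-in for the real acquisition
  (0.875 um/px, 20 um sections, ~200 sections): all geometric properties
  of the pipeline are preserved while registration runs in minutes on one
  CPU. End-to-end cohort tests use 24 x 128 x 128 so a six-sample cohort
  completes in a few minutes; the registration-recovery checks use the full
  50 x 256 x 256 default.
* **Anatomy**: an elliptical outline and butterfly-shaped gray matter whose
  radii vary smoothly along z; laminae are dorsoventral bands of the gray
  mask with lamina 9 widest (it is the motoneuron territory), lamina 10
  around the central canal, and motor-pool disks carved out of the
  lamina-9 band at C2-C8.
* **Autofluorescence**: gray matter 180, white matter 120 intensity units
  (gray/white contrast 1.5), a bright rim at the tissue border
  (gain 1.5, 3 px), 0.8 px smoothing, additive Gaussian noise (sd 4) plus
  a Poisson-like shot component (variance 0.02 per intensity unit). The
  noise model is explicit and controllable because the real acquisition
  noise is not specified anywhere usable.
* **Signal**: isotropic Gaussian puncta with sigma 0.7-1.1 voxels and peak
  ~150 emulate presynaptic terminals (boutons are ~1 um, i.e. subvoxel at
  10 um; near-voxel-scale blobs are the smallest classifiable structure).
  Expected puncta counts are Poisson with per-region densities per 1000
  voxels following a lamina profile peaking in laminae 3-7 (3/1000) --
  chosen so that even small regions carry counts in the tens, as real
  terminal counts do, while keeping the classified area well below
  saturation so that summed probability intensity stays approximately
  proportional to terminal count. A curvilinear axon-like tube (a smooth
  spline path through the dorsal white matter) provides the axon class, and
  optional soma-like blobs (sigma 1.0-1.6 voxels, i.e. 20-35 um diameter)
  provide a motoneuron-restricted label for the lamina-9 validation.
* **Ground truth**: per-region sums are recorded from the pre-noise signal
  by direct mask accumulation, so conservation (sum over regions = total
  in-mask signal) holds exactly by construction; per-voxel class labels and
  the exact deformation parameters of every sample are kept.
* **Deformation**: per-sample rigid (rotation up to 4 degrees about z,
  in-plane translation up to 8 voxels) + anisotropic scale (up to 4%) +
  smooth elastic b-spline displacement (15 um amplitude, 600 um control
  spacing) -- the inter-animal variability registration must undo. The
  boundary sections lose a little mass under any z-shift, so the
  out-of-frame guard only rejects deformations losing more than 10% of
  tissue mass.

What the phantom does **not** emulate: optical PSF, tiling seams,
flat-field artifacts, vasculature and bone, intensity inhomogeneity along
z, or anatomically accurate lamina boundaries. Passing tests demonstrate
that the algorithms are correctly implemented and recover known truth
under realistic geometry, noise and deformation -- not that the specific
thresholds transfer to any particular real dataset.

# Registration

A multistep chain -- rigid (6 parameters), then affine (12), then cubic
b-spline free-form deformation -- is optimized against a mutual-information
metric, on a multiresolution pyramid (default 6 levels, halving per level,
capped so no axis drops below 8 voxels). Choices the underlying literature
leaves open are fixed as:

* **Metric**: joint histogram with 32 bins and first-order (linear) Parzen
  weighting on both axes, estimated from a random 10% of fixed voxels
  (capped at 10,000) per level; this keeps the metric continuous in the
  transform parameters. Sampling is seeded: a seed is a required
  configuration field and every stochastic draw derives from it.
* **Optimizer**: Nelder-Mead per level with parameter scaling (0.02 for
  rotations/matrix entries, two voxel-lengths for translations) and a
  simplex restart at the two finest levels; the b-spline stage uses
  L-BFGS-B over control-point displacements (default grid spacing
  1 x 1 x 1 mm, the final-resolution spacing) at the finest level.
* **Initialization**: intensity centre-of-mass alignment; per-section
  integer recentering (Otsu threshold on nonzero intensities, largest
  4-connected component) is available upstream as an initialization aid
  and deliberately avoids resampling blur.
* **Stage acceptance**: after each stage the metric is evaluated on a
  held-out deterministic sample; a stage that does not improve it is
  replaced by an identity placeholder, so the chain's metric is
  non-decreasing by construction.
* **Composition**: transforms map fixed-space physical coordinates to
  moving space (resampling convention) and are applied sequentially;
  intensities and probability maps are pulled back with trilinear
  interpolation, labels with nearest neighbour, out-of-frame voxels fill
  with 0 (padding sections are zero).
* **Landmark refinement**: the closed-form least-squares affine over >= 4
  non-coplanar fiducial pairs can be prepended as an additional stage
  (default), or replace the automated rigid/affine stages, behind a flag;
  the order is recorded in the chain itself.

On the default phantom, a known rigid map (up to 30 voxels, 10 degrees) is
recovered to well under one voxel and 0.1 degree, and anisotropic scales in
0.9-1.1 to under 1%.

# Template construction

The symmetric average template is built by iterative averaging and
re-registration (default 7 iterations; the convergence tests use 3, which
already show the mean pairwise MSE among warped samples falling below the
unregistered baseline). Mirroring replaces the left half with the reflected
right half -- the literal reading of building left-right symmetry from one
hemisphere -- and is the last intensity-shaping step before masking, so the
result is exactly reflection-invariant. Aspect factors (width 0.93, height
0.95) align annotation geometry to the template. Masking zeroes everything
outside the annotation extent and adds a Gaussian-smoothed bright rim just
inside the boundary to mimic tissue-border autofluorescence. Registration
inside template building defaults to a reduced rigid+affine, 4-level
schedule for speed; per-segment manual affine adjustments are supported as
user-supplied per-z-range transforms, not automated, because they were a
manual step in the original workflow.

# Pixel classification

One random forest (default 100 trees; the cohort tests use 40-50) is
trained per cohort from sparse brush labels on up to five representative
sections per sample, and applied to every section of every sample in the
cohort -- pipeline metadata asserts the single-model property. The feature
bank (per channel and scale: Gaussian, gradient magnitude,
Laplacian-of-Gaussian, Hessian eigenvalues, structure-tensor eigenvalues,
plus the raw image; default scales 0.7/1.0/1.6/3.5/5.0 px) mirrors the
interactive-toolkit convention the workflow replaces. Vote fractions are
exported as 8-bit probability maps, `floor(p * 255)`, so per-voxel class
sums lie in [255 - n_classes + 1, 255], within the [250, 255] contract for
up to five classes.

Order of operations follows the source workflow: predict at sample
resolution, warp the signal-class maps to template space (linear), then
threshold at tau = 86 (a visually determined constant in the original
study). Thresholding zeroes voxels below tau and **keeps** original values
at or above it, because quantification sums denoised map intensity --
binarizing would change the downstream statistic. The threshold applies to
the quantified signal classes; gray/white/background maps exist for
visualization only. Prediction can optionally be restricted to a dilated
tissue bounding box with a certain background fill, which changes nothing
within [250, 255] bookkeeping and saves most of the prediction time.

# Quantification and statistics

Per sample and class, region entries are the summed thresholded map
intensity within each region mask; background voxels are excluded and the
per-class sum over regions equals the total masked intensity exactly
(asserted in tests). Normalization modes: `total_signal` (per-sample grand
total; the default) and `axon_reference` (the sample's classified axon
signal within white-matter regions, a proxy for labelling strength);
the active mode is recorded on the object because the upstream publication
never states its formula.

Group comparisons use tie-corrected Kruskal-Wallis with Dunn's post hoc z
from the pooled tie-corrected rank variance, and Benjamini-Hochberg FDR
across the full declared family (all regions x all pairwise comparisons --
the broadest, most conservative family, stated explicitly because the
source is silent). If all values are identical the defined result is p = 1.
log10 fold changes are `log10((mean(A) + eps) / (mean(B) + eps))` with a
pseudocount eps of 1 intensity unit on the raw summed-intensity scale
(sparse ipsilateral regions contain zeros); fold changes therefore default
to the raw scale -- when comparing normalized values, pass a commensurate
eps. Fold changes of group means are computed after log10 scaling of the
displayed means, before/after per-sample normalization being the caller's
explicit choice. Laminar heatmap rows are ordered by agglomerative
clustering (Euclidean distance, complete linkage, the defaults of the
heatmap package this mirrors), with dendrograms exportable as Newick text.

A reporting convention of flagging p < 0.07 on graphs is supported as a
display threshold only; significance remains p < 0.05.

# Problem sizes and determinism

Test and acceptance runs use: full 50 x 256 x 256 phantoms for registration
recovery; 24 x 96 x 96 for the five-phantom template convergence check;
24 x 128 x 128 cohorts (n = 3 per group) for the end-to-end effect-recovery
study (20 sections for the soma-validation cohort); 1,000 null simulations
for type-I calibration. These sizes are the
package's chosen desk-scale study conditions; all are configurable. Every
stochastic stage takes a seed derived deterministically from one master
seed, so a full run (simulate through statistics) reproduces identical
outputs given identical configuration and seed.

# Known limitations

* Registration is intensity-based rigid/affine/b-spline only -- no
  diffeomorphic or symmetric-normalization machinery, no GPU path.
* The b-spline stage optimizes at the finest level with a numeric
  gradient; very large elastic mismatches are out of scope (the guarded
  stage falls back to identity rather than degrade the metric).
* Summed probability intensity saturates once classified structures tile a
  region; fold-change estimates compress toward zero in that regime. The
  generator defaults deliberately stay below saturation.
* The phantom's laminar geometry is schematic; anatomical accuracy of
  boundaries is a non-goal.
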