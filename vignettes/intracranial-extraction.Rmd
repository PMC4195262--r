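---
title: "Nonlocal intracranial cavity extraction: model and design notes"
author: "niceseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlocal intracranial cavity extraction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niceseg)
```

## The problem

Normalized regional brain volumes require dividing by the intracranial
cavity volume (ICV): the space inside the skull holding brain tissue,
brainstem and all cerebrospinal fluid, internal and external. Estimating
the intracranial mask from a T1-weighted MRI is hard because head shape and
size vary widely across subjects, ages and diseases. `niceseg` implements a
multi-template patch-based label-fusion approach: a library of intensity
images with validated intracranial masks, all linearly registered to one
stereotactic space and sharing one intensity scale, supplies labeled
exemplar patches, and each voxel of a new subject is labeled by a weighted
vote over similar patches found across the library.

All inputs are assumed preprocessed — denoised, bias-corrected, and
linearly registered to a common 1 mm isotropic grid. The package never
resamples between spaces: grid mismatches are errors, not interpolations.

## Intensity normalization

Patch similarity is intensity-driven, so subject and library must share one
intensity scale. `estimateTissueMeans()` estimates robust CSF/GM/WM class
means inside a brain region of interest (by default the library's majority
mask, standing in for a standard-space brain mask) with a three-class
alternating trimmed-mean scheme: assign each voxel to the nearest current
class mean, recompute each mean after discarding the 20% of its voxels
farthest from it — down-weighting partial-volume voxels at tissue
interfaces — and iterate until every mean moves by less than 0.01 intensity
units (at most 100 iterations), starting from the 10th/50th/90th intensity
percentiles. The trimming rule is this package's own robust-mean
construction; the trim fraction, convergence tolerance and initialisation
are exposed as parameters.

`buildIntensityMap()` then anchors the estimated means to target values
50 (CSF), 150 (GM) and 250 (WM) with a continuous, monotone
piecewise-linear map. The segment below the CSF mean passes through the
origin and the segment above the WM mean extends the GM-to-WM slope; both
endpoints are design choices, since only the three anchors are fixed by the
scheme. On a noiseless three-class volume the composition of estimation and
mapping is exact: the class means land on 50/150/250 to machine precision,
which is the package's primary self-check.

## The fusion model

For a target voxel (or block centre) $x_i$, candidates are all positions
$x_{s,j}$ inside a cubic search neighbourhood $V_i$ of half-width
`searchRadius` in each of the $N$ selected templates. The vote is

$$v(x_i) = \frac{\sum_{s=1}^{N}\sum_{j \in V_i} w(x_i, x_{s,j})\, l_{s,j}}
                {\sum_{s=1}^{N}\sum_{j \in V_i} w(x_i, x_{s,j})},$$

with $l_{s,j}$ the template label at the candidate centre, and the final
label is $v \ge 0.5$ (inclusive).

**Patches.** Cubic neighbourhoods of half-width `patchRadius`, clamped to
the grid; a candidate is admitted only if every offset the target patch
uses is in-bounds at the candidate, so patch vectors always align and no
boundary intensities are invented. The normalized squared patch distance is
$d^2 = \lVert P(x_i) - P(x_{s,j})\rVert^2 / n_{patch}$.

**Preselection.** Before any exponential is computed, the cheap
structural-similarity score
$ss = \frac{2\mu_i\mu_{s,j}}{\mu_i^2+\mu_{s,j}^2}\cdot
       \frac{2\sigma_i\sigma_{s,j}}{\sigma_i^2+\sigma_{s,j}^2}$
gates the candidate: weights are computed only when $ss \ge th$
(default 0.97; the printed formulation of the gate is contradictory in the
method's description, and the package follows the reading under which
similar patches are *kept*). Standard deviations are population-form
($1/n$). Degenerate conventions: a ratio term is 1 when both arguments are
0 and 0 when exactly one is, so two flat patches agree and a flat patch
never matches a textured one.

**Adaptive bandwidth.** $h(x_i) = \lambda \min_{s,j} d^2 + \varepsilon$
with $\lambda = 0.1$ and $\varepsilon = 10^{-6}$ (a small stabiliser whose
value is a package choice). The bandwidth is recomputed at every target
location from its own candidate set: where the library contains a
near-perfect match, $h$ collapses and only that match carries weight.

**Bilateral weight.** Because all images share one space, spatially closer
candidates are more trustworthy. The default weight combines both cues:

$$w = \exp\!\left[-\left(\frac{\lVert c_i - c_{s,j}\rVert}{\sigma_d}
      + \frac{d^2}{h}\right)\right],$$

with the Euclidean centre distance in mm (unsquared) and
$\sigma_d = 8$ mm. The classical intensity-only baseline
$w = \exp(-d^2/h^2)$ is retained (`weightMode = "classical"`) for
ablations; each form follows its own printed exponent convention
($h$ vs $h^2$), which is deliberate.

**Blockwise overcomplete voting.** Rather than one vote per weight
evaluation, the candidate's whole label block (edge `2*blockRadius + 1`,
default 3³) is pasted with its weight onto the target block, and every
voxel averages the weighted labels over all blocks covering it. This
regularises the labels — connected voxels are labeled together — and lets
block centres be spaced 2 voxels apart (the block grid covers the ROI
bounding box, with a terminal centre appended per axis whenever the last
regular block would not reach the edge), an eightfold reduction in weight
evaluations. With `blockRadius = 0` and `blockSpacing = 1` the blockwise
path reduces *exactly* to the voxelwise formula, which the test suite
checks bit-for-bit and against an independent brute-force triple-loop
implementation.

**Degenerate votes.** A voxel whose entire candidate set is gated out
receives the majority label of its candidate centres, ties to background —
a deterministic rule for a case the model leaves open; such voxels are
flagged in the result.

## Multiresolution pipeline

`segmentICV()` works coarse to fine over `pyramidScales = c(4, 2, 1)`
(integer block-average downsampling; masks threshold at 0.5 with ties to
foreground). Template preselection ranks the library by masked mean squared
intensity difference at the coarsest scale — the selection criterion is a
package design choice, deterministic with ties to the lower index — and
keeps `nTemplates` (default 30; the desk-scale experiments use 9). At the
coarsest level the ROI is the union of the selected template masks dilated
by 2 voxels, which contains the true boundary for registered inputs. Each
finer level re-estimates only a boundary band (Chebyshev width 2) around
the upsampled mask, freezing interior and exterior labels; per-level patch
radii are 1 and search radii 4/3/2 coarse to fine. These level parameters
are explicit configuration, documented as reconstructions of a standard
coarse-to-fine schedule rather than prescribed values. The final ICV is the
1-voxel count times the voxel volume.

## The phantom generator

`makePhantom()` builds nested-ellipsoid three-tissue head phantoms: skull
shell, external CSF shell, GM shell, WM core and two CSF ventricles, on a
64³ 1 mm grid by default, with tissue means already on the normalized scale
(background 10, skull 40, CSF 50, GM 150, WM 250). Inter-subject
variability is a smooth random deformation (per axis, the mean of three
sinusoidal modes with seeded integer frequencies and phases, capped at
2 voxels — labels pulled nearest-neighbour, intensities trilinearly, which
adds a thin partial-volume-like blend at interfaces) plus additive Gaussian
noise (sd 5, emulating residual noise after denoising) and a small
per-template jitter of the class means (sd 2, emulating residual
normalization error). These defaults were chosen once as a plausible
desk-scale emulation of a preprocessed, registered library and are the
conditions under which the test suite runs its leave-one-out study: ten
phantoms, each segmented with the remaining nine.

What the phantoms do *not* emulate: cortical folding and thin sulcal CSF,
bias fields, Rician noise, registration failures, pathology. Passing the
phantom suite therefore demonstrates the machinery is correct and the
method's ordering (bilateral blockwise at or above the classical voxelwise
baseline) holds under controlled variability — not that clinical accuracy
numbers transfer.

## Numerical choices and degenerate inputs

* Vote threshold is inclusive ($\ge$), as is the mask downsampling tie.
* Spatial distances use mm (index offset times voxel size), so
  $\sigma_d = 8$ coincides with 8 voxels only at 1 mm isotropic.
* Tissue-mean estimation errors out when fewer than three classes remain
  populated (e.g. bimodal input) or the T1 ordering CSF < GM < WM fails.
* Fusion requires a non-empty ROI and a validated, non-empty library whose
  masks are strictly binary and non-empty; errors name the offending
  template.
* Summation order in the compiled kernels is fixed (template-major,
  z/y/x), so repeated runs are bit-identical; template order only
  permutes summands and changes votes at the machine-epsilon level.

## Problem sizes

The bundled experiments run at desk scale, chosen so the full suite
completes in minutes on one CPU: 64³ phantoms for the leave-one-out and
test-retest studies, 32³ for library-construction checks, 12³ for
brute-force oracle comparisons. The method itself is resolution-agnostic;
a 181×217×181 standard-space volume uses the same code paths.

## Known limitations

* Template preselection and the multiresolution schedule are documented
  reconstructions; both are configurable where a site has better choices.
* The robust tissue-mean estimator is a stand-in for a published
  trimmed-mean segmentation whose exact trimming rule is not restated
  here; on well-separated classes the two agree by construction of the
  anchors.
* Only binary (intracranial / background) fusion is implemented; no
  multi-label extension, no nonlinear registration, no GPU path.
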