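# niceseg — nonlocal intracranial cavity extraction

`niceseg` estimates the intracranial cavity (IC) — brain tissue, brainstem
and *all* cerebrospinal fluid, internal and external — from a T1-weighted
MRI volume, and reports its volume (ICV), the quantity routinely used to
normalize regional brain measures for head size. It is aimed at
neuroimaging pipelines that already denoise, bias-correct and linearly
register their data to a common 1 mm stereotactic space and that maintain
(or simulate) a template library: intensity images with validated IC masks
on that common grid.

## The method

Each voxel of the subject is labeled by multi-template nonlocal label
fusion. For a target location `x_i`, candidates `x_{s,j}` range over a
cubic search neighbourhood `V_i` in each of `N` preselected templates, and
the fused vote is the weighted average of the candidate labels

    v(x_i) = Σ_s Σ_j w(x_i, x_{s,j}) l_{s,j}  /  Σ_s Σ_j w(x_i, x_{s,j})

thresholded at 0.5. The weight is *bilateral* — intensity and space:

    w = exp −( ‖c_i − c_{s,j}‖/σ_d  +  ‖P(x_i) − P(x_{s,j})‖²/h(x_i) )

with patch distance normalized by patch size, σ_d = 8 mm, and an adaptive
bandwidth `h(x_i) = λ·min d² + ε` (λ = 0.1) recomputed per location from
the best candidate match. A cheap structural-similarity gate
(mean/variance agreement, threshold 0.97) discards dissimilar candidates
before any exponential is computed. Votes are cast *blockwise*: one weight
labels a whole 3³ block, overlapping blocks are averaged per voxel
(overcomplete voting), and block centres sit on a 2-voxel grid — an
eightfold reduction in weight evaluations plus a regularization of the
labels. The whole scheme runs coarse-to-fine (4 → 2 → 1 mm) re-estimating
only a boundary band at each finer level. An intensity-only baseline
(`weightMode = "classical"`, `w = exp(−d²/h²)`) and a pure voxelwise mode
are retained for ablation.

Supporting machinery: tissue-anchored piecewise-linear intensity
normalization (robust CSF/GM/WM means mapped to 50/150/250), midsagittal
flip augmentation of the library, NIfTI-1 I/O with CSV/JSON library
manifests, a seeded nested-ellipsoid head-phantom generator for fully
self-contained validation, and Dice/sensitivity/specificity/volume
metrics.

## Worked example

```r
library(niceseg)

spec <- phantomSpec(dim = 48L, seed = 42L)   # noise sd 5, 2-voxel deformation
lib  <- makeLibrary(spec, 6)                 # 6 templates with ground truth
subject <- makePhantom(phantomSpec(dim = 48L, seed = 7L))

cfg <- fusionConfig(nTemplates = 5L)
res <- segmentICV(subject$intensity, lib, cfg)
res
#> SegmentationResult
#>   ICV: 23.932 mL
#>   mask: 23932 voxels
#>   templates used: 1, 4, 5, 3, 6

overlap(res@mask, subject$mask)
#> OverlapReport
#>   Dice 0.9713  sensitivity 0.9700  specificity 0.9924
#>   tp 23276 fp 656 fn 721 tn 85939 | volumes 23.93 / 24.00 mL
```

The segmentation recovers the phantom's ground-truth mask with Dice 0.971
from only five desk-scale templates; the ICV (23.93 mL at this toy grid
size) is the mask voxel count times the voxel volume. `res@votes` holds
the underlying real-valued vote field, and `res@provenance` the
configuration snapshot and selected template indices.

From a shell, the same operations are available through the bundled
script (`system.file("cli", "nice.R", package = "niceseg")`):

```sh
nice.R simulate --out-dir phantoms --n 10 --seed 7
nice.R extract  --subject subject.nii.gz --library phantoms/manifest.csv \
                --out mask.nii.gz --n-templates 9
nice.R evaluate --a mask.nii.gz --b truth.nii.gz --out report.csv
```

Every run writes a JSON manifest (command, configuration, inputs, seed)
next to its outputs.

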