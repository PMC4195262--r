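#' @useDynLib niceseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' 3D intensity volume
#'
#' A scalar T1-weighted (or phantom) image on a regular voxel grid, together
#' with its voxel size in millimetres. Before intensity normalization the
#' values are in arbitrary scanner units; after [applyIntensityMap()] they sit
#' on the tissue-anchored scale where CSF/GM/WM average 50/150/250.
#' An optional NIfTI header carried from disk is preserved verbatim on write
#' but never used for resampling: inputs are assumed already registered to a
#' common space and grid mismatches are errors.
#'
#' @slot data 3D numeric array of finite values.
#' @slot voxelSize positive numeric triple, voxel edge lengths in mm.
#' @slot header NIfTI header carried from disk (or `NULL`).
#'
#' @seealso [readVolume()], [BinaryMask-class], [TemplateLibrary-class]
#' @export
setClass("IntensityVolume",
    representation(data = "array", voxelSize = "numeric", header = "ANY"),
    prototype(voxelSize = c(1, 1, 1), header = NULL))

setValidity("IntensityVolume", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
        return("data must be a 3D array")
    if (any(dim(d) < 1L))
        return("all dimensions must be >= 1")
    if (!all(is.finite(d)))
        return("all intensities must be finite")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
        return("voxelSize must be a strictly positive triple")
    TRUE
})

#' @param data 3D numeric array.
#' @param voxelSize positive numeric triple (mm); default 1 mm isotropic.
#' @param header optional NIfTI header to carry along.
#' @rdname IntensityVolume-class
#' @export
IntensityVolume <- function(data, voxelSize = c(1, 1, 1), header = NULL) {
    storage.mode(data) <- "double"
    new("IntensityVolume", data = data, voxelSize = as.numeric(voxelSize),
        header = header)
}

#' Binary label volume
#'
#' A 0/1 mask aligned voxel-for-voxel with an [IntensityVolume-class]:
#' an intracranial-cavity ground truth, a template label, or a segmentation
#' output.
#'
#' @slot data 3D array whose values are exactly 0 or 1.
#' @slot voxelSize positive numeric triple, voxel edge lengths in mm.
#' @slot header NIfTI header carried from disk (or `NULL`).
#'
#' @export
setClass("BinaryMask",
    representation(data = "array", voxelSize = "numeric", header = "ANY"),
    prototype(voxelSize = c(1, 1, 1), header = NULL))

setValidity("BinaryMask", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
        return("data must be a 3D array")
    if (!all(d == 0 | d == 1))
        return("mask values must be exactly 0 or 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        return("voxelSize must be a strictly positive triple")
    TRUE
})

#' @param data 3D array of 0/1 values (logical arrays are accepted).
#' @param voxelSize positive numeric triple (mm).
#' @param header optional NIfTI header.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(data, voxelSize = c(1, 1, 1), header = NULL) {
    if (is.logical(data)) {
        dm <- dim(data)
        data <- array(as.integer(data), dim = dm)
    }
    if (!all(data == 0 | data == 1))
        stop("mask values must be exactly 0 or 1")
    storage.mode(data) <- "integer"
    new("BinaryMask", data = data, voxelSize = as.numeric(voxelSize),
        header = header)
}

#' Template library
#'
#' An ordered collection of (intensity volume, intracranial mask) pairs
#' sharing one grid: the labeled exemplars that label fusion draws its
#' candidate patches from. All pairs must share the library grid, every mask
#' must be strictly binary and non-empty, and the library itself non-empty.
#'
#' @slot intensities list of [IntensityVolume-class] objects.
#' @slot masks list of matching [BinaryMask-class] objects.
#' @slot tags character vector of per-template identifiers.
#'
#' @seealso [validateLibrary()], [flipAugment()], [makeLibrary()]
#' @export
setClass("TemplateLibrary",
    representation(intensities = "list", masks = "list", tags = "character"))

setValidity("TemplateLibrary", function(object) {
    n <- length(object@intensities)
    if (n == 0L) return("library is empty")
    if (length(object@masks) != n)
        return("intensities and masks differ in length")
    if (length(object@tags) != n)
        return("tags must have one entry per template")
    TRUE
})

#' @param intensities list of [IntensityVolume-class] objects.
#' @param masks list of [BinaryMask-class] objects, parallel to `intensities`.
#' @param tags optional identifiers; defaults to `template_1`, ...
#' @rdname TemplateLibrary-class
#' @export
TemplateLibrary <- function(intensities, masks,
                            tags = paste0("template_", seq_along(intensities))) {
    lib <- new("TemplateLibrary", intensities = intensities, masks = masks,
               tags = as.character(tags))
    validateLibrary(lib)
}

#' Fusion parameter set
#'
#' All tunable parameters of the label-fusion pipeline. Per-level vectors
#' (`patchRadius`, `searchRadius`) are indexed coarse to fine, parallel to
#' `pyramidScales`.
#'
#' @slot patchRadius integer per pyramid level; patch edge is `2r + 1` voxels.
#' @slot searchRadius integer per pyramid level; half-width of the search
#'   neighbourhood around each target location.
#' @slot nTemplates number of templates preselected for fusion.
#' @slot ssThreshold structural-similarity preselection gate in `[0, 1]`.
#' @slot lambdaH scale of the adaptive bandwidth.
#' @slot epsilonH small positive stabiliser added to the bandwidth.
#' @slot sigmaD spatial decay constant of the bilateral weight, in mm.
#' @slot blockRadius half-width of the label block; edge `2b + 1` voxels.
#' @slot blockSpacing voxels between adjacent block centres.
#' @slot voteThreshold label decision threshold on the fused vote.
#' @slot pyramidScales integer downsampling factors, strictly decreasing and
#'   ending in 1.
#' @slot boundaryBand half-width (voxels) of the refinement band at each
#'   finer level.
#' @slot weightMode `"bilateral"` (spatial + intensity) or `"classical"`
#'   (intensity only, bandwidth squared) weighting.
#' @slot seed integer seed recorded in provenance.
#'
#' @seealso [fusionConfig()], [readFusionConfig()]
#' @export
setClass("FusionConfig",
    representation(patchRadius = "integer", searchRadius = "integer",
        nTemplates = "integer", ssThreshold = "numeric", lambdaH = "numeric",
        epsilonH = "numeric", sigmaD = "numeric", blockRadius = "integer",
        blockSpacing = "integer", voteThreshold = "numeric",
        pyramidScales = "integer", boundaryBand = "integer",
        weightMode = "character", seed = "integer"))

setValidity("FusionConfig", function(object) {
    ps <- object@pyramidScales
    if (length(ps) < 1L || ps[length(ps)] != 1L)
        return("pyramidScales must end at 1")
    if (length(ps) > 1L && any(diff(ps) >= 0))
        return("pyramidScales must be strictly decreasing")
    if (length(object@patchRadius) != length(ps) ||
        length(object@searchRadius) != length(ps))
        return("patchRadius and searchRadius need one value per pyramid level")
    if (any(object@patchRadius < 0L) || any(object@searchRadius < 0L))
        return("patch and search radii must be non-negative")
    if (object@nTemplates < 1L)
        return("nTemplates must be positive")
    if (object@ssThreshold < 0 || object@ssThreshold > 1)
        return("ssThreshold must lie in [0, 1]")
    if (object@lambdaH <= 0 || object@epsilonH <= 0 || object@sigmaD <= 0)
        return("lambdaH, epsilonH and sigmaD must be strictly positive")
    if (object@blockRadius < 0L)
        return("blockRadius must be non-negative")
    if (object@blockSpacing < 1L)
        return("blockSpacing must be positive")
    if (object@blockSpacing > 2L * object@blockRadius + 1L)
        return("blockSpacing must not exceed the block edge (2*blockRadius + 1)")
    if (object@voteThreshold <= 0 || object@voteThreshold >= 1)
        return("voteThreshold must lie in (0, 1)")
    if (object@boundaryBand < 0L)
        return("boundaryBand must be non-negative")
    if (!object@weightMode %in% c("bilateral", "classical"))
        return("weightMode must be 'bilateral' or 'classical'")
    TRUE
})

#' Vote volume
#'
#' The real-valued result of label fusion: the fused vote `v(x)` in `[0, 1]`
#' at every processed voxel, the accumulated weight mass (the fusion
#' denominator), a processed-voxel indicator, and a flag marking voxels that
#' fell back to a majority vote because every candidate weight was gated out.
#'
#' @slot votes 3D numeric array, `v(x)` where processed, 0 elsewhere.
#' @slot weightMass 3D non-negative numeric array.
#' @slot processed 3D 0/1 indicator of voxels given a vote.
#' @slot fallback 3D 0/1 indicator of majority-vote fallbacks.
#' @slot voxelSize positive numeric triple (mm).
#'
#' @seealso [thresholdVotes()], [voxelwiseFusion()], [blockwiseFusion()]
#' @export
setClass("VoteVolume",
    representation(votes = "array", weightMass = "array", processed = "array",
        fallback = "array", voxelSize = "numeric"))

setValidity("VoteVolume", function(object) {
    p <- object@processed == 1
    v <- object@votes
    if (!identical(dim(v), dim(object@weightMass)) ||
        !identical(dim(v), dim(object@processed)))
        return("votes, weightMass and processed must share one shape")
    if (any(object@weightMass < 0))
        return("weightMass must be non-negative")
    if (any(v[p] < -1e-12 | v[p] > 1 + 1e-12))
        return("votes must lie in [0, 1] wherever processed")
    TRUE
})

#' Segmentation result
#'
#' Output of [segmentICV()]: the full-resolution intracranial mask, the vote
#' field from the finest refinement level, the intracranial cavity volume in
#' millilitres, and a provenance record (configuration snapshot and selected
#' template indices).
#'
#' @slot mask final [BinaryMask-class] at full resolution.
#' @slot votes [VoteVolume-class] from the finest level (votes over the
#'   refinement band; labels outside the band were inherited).
#' @slot icvMl intracranial cavity volume in mL.
#' @slot provenance list with the configuration snapshot, selected template
#'   indices and seed.
#'
#' @export
setClass("SegmentationResult",
    representation(mask = "BinaryMask", votes = "VoteVolume",
        icvMl = "numeric", provenance = "list"))

setValidity("SegmentationResult", function(object) {
    if (length(object@icvMl) != 1L || object@icvMl <= 0)
        return("icvMl must be a single positive number")
    TRUE
})

#' Robust tissue mean intensities
#'
#' CSF, GM and WM mean intensities estimated from a T1-weighted volume.
#' T1 contrast imposes the ordering CSF < GM < WM.
#'
#' @slot csf,gm,wm positive class means in input intensity units.
#'
#' @seealso [estimateTissueMeans()], [buildIntensityMap()]
#' @export
setClass("TissueMeans",
    representation(csf = "numeric", gm = "numeric", wm = "numeric"))

setValidity("TissueMeans", function(object) {
    if (any(c(object@csf, object@gm, object@wm) <= 0))
        return("tissue means must be positive")
    if (!(object@csf < object@gm && object@gm < object@wm))
        return("T1 ordering violated: need csf < gm < wm")
    TRUE
})

#' Piecewise-linear intensity map
#'
#' Monotone piecewise-linear mapping anchoring the estimated CSF/GM/WM means
#' to the normalized values 50/150/250, through the origin below CSF and
#' extending the GM-to-WM slope above WM.
#'
#' @slot source strictly increasing source-intensity knots.
#' @slot target matching target intensities.
#'
#' @seealso [buildIntensityMap()], [applyIntensityMap()]
#' @export
setClass("IntensityMap",
    representation(source = "numeric", target = "numeric"))

setValidity("IntensityMap", function(object) {
    if (length(object@source) != length(object@target))
        return("source and target knots differ in length")
    if (any(diff(object@source) <= 0))
        return("source knots must be strictly increasing")
    if (any(diff(object@target) < 0))
        return("map must be monotonically non-decreasing")
    TRUE
})

#' Overlap report between two binary masks
#'
#' Voxel-level agreement between a segmentation and a reference: the
#' confusion counts, Dice coefficient, sensitivity and specificity, and both
#' volumes in millilitres.
#'
#' @slot dice,sensitivity,specificity reals in `[0, 1]`.
#' @slot tp,fp,fn,tn non-negative voxel counts summing to the grid size.
#' @slot volumeA,volumeB volumes of the two masks in mL.
#'
#' @seealso [overlap()], [diceCoefficient()]
#' @export
setClass("OverlapReport",
    representation(dice = "numeric", sensitivity = "numeric",
        specificity = "numeric", tp = "numeric", fp = "numeric",
        fn = "numeric", tn = "numeric", volumeA = "numeric",
        volumeB = "numeric"))

#' Synthetic head-phantom specification
#'
#' Geometry and intensity description of a nested-ellipsoid three-tissue
#' head phantom: skull shell, external CSF shell, GM shell, WM core and
#' ventricles, on a 1 mm isotropic grid. The intracranial cavity is the union
#' of all CSF/GM/WM compartments (external CSF included), excluding skull and
#' background. Tissue means default to the normalized anchors (CSF 50,
#' GM 150, WM 250) with background 10 and skull 40.
#'
#' @slot dim integer grid shape (default 64^3).
#' @slot voxelSize voxel size in mm.
#' @slot semiAxes named list of ellipsoid semi-axes (voxels) for the
#'   `skull`, `ic` (inner skull / IC boundary), `gm`, `wm` and `ventricle`
#'   surfaces; strictly nested.
#' @slot means named numeric tissue means: `background`, `skull`, `csf`,
#'   `gm`, `wm`.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot deformAmplitude cap (voxels) on the smooth random deformation.
#' @slot seed integer seed.
#'
#' @seealso [phantomSpec()], [makePhantom()], [makeLibrary()]
#' @export
setClass("PhantomSpec",
    representation(dim = "integer", voxelSize = "numeric",
        semiAxes = "list", means = "numeric", noiseSd = "numeric",
        deformAmplitude = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (length(object@dim) != 3L || any(object@dim < 8L))
        return("grid must be 3D with at least 8 voxels per axis")
    need <- c("skull", "ic", "gm", "wm", "ventricle")
    if (!all(need %in% names(object@semiAxes)))
        return("semiAxes must name skull, ic, gm, wm and ventricle surfaces")
    ax <- object@semiAxes
    for (nm in c("ic", "gm", "wm"))
        if (any(unlist(ax[[nm]]) <= 0)) return("semi-axes must be positive")
    if (!all(unlist(ax$ic) < unlist(ax$skull)) ||
        !all(unlist(ax$gm) < unlist(ax$ic)) ||
        !all(unlist(ax$wm) < unlist(ax$gm)))
        return("shells must be strictly nested: wm < gm < ic < skull")
    if (any(unlist(ax$skull) + 1 > object@dim / 2))
        return("grid too small: outer shell does not fit with a margin")
    need <- c("background", "skull", "csf", "gm", "wm")
    if (!all(need %in% names(object@means)))
        return("means must name background, skull, csf, gm and wm")
    if (anyDuplicated(object@means[need]))
        return("tissue means must be distinct")
    if (object@noiseSd < 0 || object@deformAmplitude < 0)
        return("noiseSd and deformAmplitude must be non-negative")
    TRUE
})
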