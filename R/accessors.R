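#' Accessors for volumes, masks and libraries
#'
#' `voxelData()` returns the underlying 3D array, `voxelSize()` the voxel
#' edge lengths in mm. For a [TemplateLibrary-class], `length()` is the
#' number of templates and `[[` / `templatePair()` return one
#' (intensity, mask) pair.
#'
#' @param x an object of one of the package's classes.
#' @return `voxelData()`: a 3D array; `voxelSize()`: numeric triple.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
setMethod("voxelData", "IntensityVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelData", "BinaryMask", function(x) x@data)
#' @rdname accessors
setMethod("voxelData", "VoteVolume", function(x) x@votes)
#' @rdname accessors
setMethod("voxelSize", "IntensityVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "BinaryMask", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "VoteVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("dim", "IntensityVolume", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("length", "TemplateLibrary", function(x) length(x@intensities))

#' @param i template index.
#' @rdname accessors
#' @export
templatePair <- function(x, i) {
    stopifnot(is(x, "TemplateLibrary"))
    i <- as.integer(i)
    if (i < 1L || i > length(x))
        stop("template index ", i, " out of range")
    list(intensity = x@intensities[[i]], mask = x@masks[[i]],
         tag = x@tags[i])
}

#' @rdname accessors
#' @export
setMethod("[[", "TemplateLibrary", function(x, i) templatePair(x, i))

#' Subset a template library
#'
#' @param x a [TemplateLibrary-class].
#' @param i integer indices of the templates to keep, in order.
#' @param j,drop,... ignored.
#' @return a [TemplateLibrary-class] with the selected templates.
#' @export
setMethod("[", "TemplateLibrary", function(x, i, j, ..., drop = FALSE) {
    i <- as.integer(i)
    new("TemplateLibrary", intensities = x@intensities[i],
        masks = x@masks[i], tags = x@tags[i])
})

#' Intracranial cavity volume of a mask, in millilitres
#'
#' Counts the 1-voxels and multiplies by the voxel volume.
#'
#' @param mask a [BinaryMask-class].
#' @return volume in mL.
#' @export
maskVolumeMl <- function(mask) {
    stopifnot(is(mask, "BinaryMask"))
    sum(mask@data) * prod(mask@voxelSize) / 1000
}

setMethod("show", "IntensityVolume", function(object) {
    cat("IntensityVolume:", paste(dim(object@data), collapse = " x "),
        "voxels,", paste(format(object@voxelSize), collapse = " x "), "mm\n")
    cat("  intensity range:",
        paste(format(range(object@data), digits = 4), collapse = " .. "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
    cat("BinaryMask:", paste(dim(object@data), collapse = " x "),
        "voxels,", sum(object@data), "foreground (",
        format(maskVolumeMl(object), digits = 4), "mL )\n")
})

setMethod("show", "TemplateLibrary", function(object) {
    d <- dim(object@intensities[[1]]@data)
    cat("TemplateLibrary:", length(object), "templates on a",
        paste(d, collapse = " x "), "grid\n")
})

setMethod("show", "VoteVolume", function(object) {
    np <- sum(object@processed)
    cat("VoteVolume:", paste(dim(object@votes), collapse = " x "),
        "voxels,", np, "processed,", sum(object@fallback),
        "majority-vote fallbacks\n")
})

setMethod("show", "SegmentationResult", function(object) {
    cat("SegmentationResult\n")
    cat("  ICV:", format(object@icvMl, digits = 6), "mL\n")
    cat("  mask:", sum(object@mask@data), "voxels\n")
    cat("  templates used:",
        paste(object@provenance$selected, collapse = ", "), "\n")
})

setMethod("show", "TissueMeans", function(object) {
    cat("TissueMeans: CSF", format(object@csf, digits = 5),
        " GM", format(object@gm, digits = 5),
        " WM", format(object@wm, digits = 5), "\n")
})

setMethod("show", "OverlapReport", function(object) {
    cat("OverlapReport\n")
    cat(sprintf("  Dice %.4f  sensitivity %.4f  specificity %.4f\n",
        object@dice, object@sensitivity, object@specificity))
    cat(sprintf("  tp %d fp %d fn %d tn %d | volumes %.2f / %.2f mL\n",
        object@tp, object@fp, object@fn, object@tn,
        object@volumeA, object@volumeB))
})

setMethod("show", "FusionConfig", function(object) {
    cat("FusionConfig (", object@weightMode, "weights )\n")
    cat("  pyramid scales:", paste(object@pyramidScales, collapse = ", "),
        " patch radius:", paste(object@patchRadius, collapse = ", "),
        " search radius:", paste(object@searchRadius, collapse = ", "), "\n")
    cat("  N =", object@nTemplates, " th =", object@ssThreshold,
        " lambda =", object@lambdaH, " sigma_d =", object@sigmaD, "mm\n")
    cat("  block radius", object@blockRadius, "spacing", object@blockSpacing,
        " vote threshold", object@voteThreshold, "\n")
})
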