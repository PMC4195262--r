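#' Preselect the templates most similar to a subject
#'
#' Ranks the library by mean squared intensity difference to the subject
#' over a region of interest at the (coarsest) pyramid scale and returns
#' the indices of the `n` closest templates, ascending by distance with
#' ties broken by lower index.
#'
#' @param subject the normalized [IntensityVolume-class].
#' @param library a validated [TemplateLibrary-class].
#' @param n number of templates to select.
#' @param roi optional [BinaryMask-class] (full-resolution) over which the
#'   distance is computed; defaults to the union of the library masks.
#' @param scale integer downsampling factor at which to compare (the
#'   pipeline uses its coarsest pyramid scale).
#' @return integer vector of `n` template indices.
#' @export
selectTemplates <- function(subject, library, n, roi = NULL, scale = 1L) {
    library <- validateLibrary(library)
    n <- as.integer(n)
    if (n < 1L || n > length(library))
        stop(inputError(sprintf(
            "n = %d templates requested from a library of %d", n,
            length(library))))
    if (is.null(roi)) roi <- unionMask(library)
    subjC <- downsampleVolume(subject, scale)
    roiC <- downsampleMask(roi, scale)
    sel <- roiC@data == 1L
    if (!any(sel)) stop(inputError("selection roi is empty at coarse scale"))
    sv <- subjC@data[sel]
    msd <- vapply(seq_len(length(library)), function(s) {
        tv <- downsampleVolume(library@intensities[[s]], scale)@data[sel]
        mean((tv - sv)^2)
    }, 0)
    order(msd)[seq_len(n)]
}

.downFactorGrid <- function(d, f) as.integer(ceiling(d / f))

.blockAverage <- function(a, f) {
    d <- dim(a)
    dc <- .downFactorGrid(d, f)
    cellOf <- function(n) (seq_len(n) - 1L) %/% f          # 0-based cell index
    ids <- cellOf(d[1])[slice.index(a, 1)] +
        dc[1] * (cellOf(d[2])[slice.index(a, 2)] +
                 dc[2] * cellOf(d[3])[slice.index(a, 3)])
    sums <- rowsum(as.numeric(a), ids, reorder = TRUE)
    cnts <- rowsum(rep(1, length(a)), ids, reorder = TRUE)
    array(sums / cnts, dim = dc)
}

#' Integer-factor downsampling by block averaging
#'
#' Coarse voxel `(i, j, k)` is the mean of the `factor^3` fine voxels it
#' covers (partial edge cells average over the voxels that exist); the
#' coarse shape is `ceiling(shape / factor)` and the voxel size scales by
#' the factor. Masks are block-averaged then thresholded at 0.5, ties
#' going to 1 (the same inclusive convention as the vote threshold).
#'
#' @param volume an [IntensityVolume-class].
#' @param mask a [BinaryMask-class].
#' @param factor integer downsampling factor (1 is the identity).
#' @return the coarse-scale object of the same kind.
#' @export
downsampleVolume <- function(volume, factor) {
    stopifnot(is(volume, "IntensityVolume"))
    factor <- as.integer(factor)
    if (factor < 1L) stop(inputError("factor must be >= 1"))
    if (factor == 1L) return(volume)
    IntensityVolume(.blockAverage(volume@data, factor),
                    volume@voxelSize * factor)
}

#' @rdname downsampleVolume
#' @export
downsampleMask <- function(mask, factor) {
    stopifnot(is(mask, "BinaryMask"))
    factor <- as.integer(factor)
    if (factor < 1L) stop(inputError("factor must be >= 1"))
    if (factor == 1L) return(mask)
    avg <- .blockAverage(mask@data, factor)
    BinaryMask(array(as.integer(avg >= 0.5), dim = dim(avg)),
               mask@voxelSize * factor)
}

#' Nearest-neighbour mask upsampling
#'
#' Each coarse voxel is replicated `factor` times along every axis and the
#' result cropped to `targetShape`; the inverse of [downsampleMask()] on
#' factor-aligned solids.
#'
#' @param mask a coarse-scale [BinaryMask-class].
#' @param factor integer upsampling factor.
#' @param targetShape integer triple, the fine-grid shape.
#' @return a [BinaryMask-class] of shape `targetShape`.
#' @export
upsampleMask <- function(mask, factor, targetShape) {
    stopifnot(is(mask, "BinaryMask"))
    factor <- as.integer(factor)
    targetShape <- as.integer(targetShape)
    if (factor < 1L) stop(inputError("factor must be >= 1"))
    dc <- dim(mask@data)
    if (!identical(.downFactorGrid(targetShape, factor), dc))
        stop(inputError("target shape inconsistent with coarse shape"))
    ix <- lapply(1:3, function(a) ((seq_len(targetShape[a]) - 1L) %/% factor) + 1L)
    BinaryMask(mask@data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
               mask@voxelSize / factor)
}

# Chebyshev morphology by repeated 26-neighbour max/min; outside the grid
# counts as background for both, so erosion eats the image border
.shiftIdx <- function(n, s) seq_len(n)[seq_len(n) + s >= 1L &
                                       seq_len(n) + s <= n]

.dilate <- function(a, width) {
    d <- dim(a)
    for (w in seq_len(width)) {
        out <- a
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
            if (dx == 0 && dy == 0 && dz == 0) next
            xs <- .shiftIdx(d[1], dx)
            ys <- .shiftIdx(d[2], dy)
            zs <- .shiftIdx(d[3], dz)
            out[xs, ys, zs] <- pmax(out[xs, ys, zs],
                                    a[xs + dx, ys + dy, zs + dz])
        }
        a <- out
    }
    a
}

.erode <- function(a, width) {
    d <- dim(a)
    for (w in seq_len(width)) {
        out <- a
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
            if (dx == 0 && dy == 0 && dz == 0) next
            sh <- array(0L, dim = d)      # zero padding beyond the grid
            xs <- .shiftIdx(d[1], dx)
            ys <- .shiftIdx(d[2], dy)
            zs <- .shiftIdx(d[3], dz)
            sh[xs, ys, zs] <- a[xs + dx, ys + dy, zs + dz]
            out <- pmin(out, sh)
        }
        a <- out
    }
    a
}

#' Morphological dilation of a mask
#'
#' Chebyshev (26-neighbour) dilation by `width` voxels.
#'
#' @param mask a [BinaryMask-class].
#' @param width non-negative integer.
#' @return a [BinaryMask-class].
#' @export
dilateMask <- function(mask, width) {
    stopifnot(is(mask, "BinaryMask"))
    width <- as.integer(width)
    if (width < 0L) stop(inputError("width must be non-negative"))
    if (width == 0L) return(mask)
    BinaryMask(array(as.integer(.dilate(mask@data, width) > 0),
                     dim = dim(mask@data)), mask@voxelSize)
}

#' Boundary band of a mask
#'
#' All voxels within Chebyshev distance `width` of the mask boundary, on
#' both sides: the dilation minus the erosion (erosion treats outside the
#' grid as background, so a mask touching the grid edge has a band there).
#' This is the region the multiresolution scheme re-estimates at each finer
#' level. `width = 0` gives an empty band.
#'
#' @param mask a [BinaryMask-class].
#' @param width non-negative integer band half-width.
#' @return a [BinaryMask-class].
#' @export
boundaryBand <- function(mask, width) {
    stopifnot(is(mask, "BinaryMask"))
    width <- as.integer(width)
    if (width < 0L) stop(inputError("width must be non-negative"))
    d <- dim(mask@data)
    if (width == 0L)
        return(BinaryMask(array(0L, dim = d), mask@voxelSize))
    dil <- .dilate(mask@data, width) > 0
    ero <- .erode(mask@data, width) > 0
    BinaryMask(array(as.integer(dil & !ero), dim = d), mask@voxelSize)
}

#' Segment the intracranial cavity of a subject
#'
#' End-to-end multiresolution nonlocal label fusion. The pipeline
#' (1) preselects the `nTemplates` library templates closest to the subject
#' at the coarsest pyramid scale; (2) at that scale runs blockwise fusion
#' over an initial ROI, the union of the selected template masks dilated by
#' the boundary-band width; (3) thresholds, upsamples the mask to each
#' finer level and re-runs fusion only inside the boundary band of the
#' upsampled mask, keeping interior and exterior labels fixed; and
#' (4) thresholds the finest-level votes into the final mask and computes
#' the intracranial volume in mL. The run is deterministic: identical
#' inputs and configuration give bit-identical masks.
#'
#' @param subject an [IntensityVolume-class], registered to the library
#'   grid; intensity-normalized unless `normalize = TRUE`, in which case
#'   the tissue-anchored normalization is applied internally using the
#'   library's majority mask as ROI.
#' @param library a validated [TemplateLibrary-class].
#' @param config a [FusionConfig-class]; see [fusionConfig()].
#' @param normalize apply [normalizeVolume()] to the subject first.
#' @return a [SegmentationResult-class].
#' @export
segmentICV <- function(subject, library, config = fusionConfig(),
                       normalize = FALSE) {
    stopifnot(is(subject, "IntensityVolume"), is(config, "FusionConfig"))
    validObject(config)
    library <- validateLibrary(library)
    if (!identical(dim(subject@data), dim(library@intensities[[1]]@data)))
        stop(inputError("subject and library grids differ"))
    if (config@nTemplates > length(library))
        stop(inputError(sprintf(
            "nTemplates = %d exceeds library size %d",
            config@nTemplates, length(library))))
    if (normalize)
        subject <- normalizeVolume(subject, majorityMask(library))

    scales <- config@pyramidScales
    sel <- selectTemplates(subject, library, config@nTemplates,
                           roi = unionMask(library), scale = scales[1])
    selLib <- library[sel]

    mask <- NULL
    votes <- NULL
    for (l in seq_along(scales)) {
        f <- scales[l]
        subjL <- downsampleVolume(subject, f)
        libL <- new("TemplateLibrary",
            intensities = lapply(selLib@intensities, downsampleVolume, f),
            masks = lapply(selLib@masks, downsampleMask, f),
            tags = selLib@tags)
        if (l == 1L) {
            roiL <- dilateMask(unionMask(libL), config@boundaryBand)
        } else {
            up <- upsampleMask(mask, scales[l - 1L] %/% f,
                               dim(subjL@data))
            roiL <- boundaryBand(up, config@boundaryBand)
        }
        votes <- blockwiseFusion(subjL, libL, roiL,
            patchRadius = config@patchRadius[l],
            searchRadius = config@searchRadius[l],
            blockRadius = config@blockRadius,
            blockSpacing = config@blockSpacing,
            lambdaH = config@lambdaH, epsilonH = config@epsilonH,
            sigmaD = config@sigmaD, ssThreshold = config@ssThreshold,
            weightMode = config@weightMode)
        thr <- thresholdVotes(votes, config@voteThreshold)
        if (l == 1L) {
            mask <- thr
        } else {
            m <- up@data
            band <- roiL@data == 1L
            m[band] <- thr@data[band]
            mask <- BinaryMask(m, subjL@voxelSize)
        }
    }
    if (sum(mask@data) == 0L)
        stop("segmentation failed: final mask is empty")
    new("SegmentationResult", mask = mask, votes = votes,
        icvMl = maskVolumeMl(mask),
        provenance = list(config = configSnapshot(config), selected = sel,
                          tags = selLib@tags, seed = config@seed))
}
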