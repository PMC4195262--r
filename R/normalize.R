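#' Estimate robust CSF/GM/WM mean intensities
#'
#' Three-class alternating trimmed-mean estimation inside a region of
#' interest: voxels are assigned to the nearest current class mean, each
#' mean is recomputed after discarding the `trimFraction` of its assigned
#' voxels farthest from it (down-weighting partial-volume voxels at tissue
#' interfaces), and the two steps alternate until every mean moves by less
#' than 0.01 intensity units (at most 100 iterations). Means are
#' initialised at the 10th/50th/90th intensity percentiles of the ROI.
#'
#' @param volume an [IntensityVolume-class].
#' @param roi a non-empty [BinaryMask-class]; typically [majorityMask()] of
#'   the template library, standing in for a standard-space brain mask.
#' @param trimFraction fraction in `[0, 0.5)` of each class discarded per
#'   update; default 0.2.
#' @return a [TissueMeans-class] with csf < gm < wm.
#' @export
estimateTissueMeans <- function(volume, roi, trimFraction = 0.2) {
    stopifnot(is(volume, "IntensityVolume"), is(roi, "BinaryMask"))
    if (!identical(dim(volume@data), dim(roi@data)))
        stop(inputError("volume and roi shapes differ"))
    if (sum(roi@data) == 0L)
        stop(inputError("roi is empty"))
    if (trimFraction < 0 || trimFraction >= 0.5)
        stop(inputError("trimFraction must lie in [0, 0.5)"))
    x <- volume@data[roi@data == 1L]
    if (length(unique(x)) < 3L)
        stop(inputError("fewer than 3 distinct intensity levels in roi"))
    means <- unname(stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE))
    for (iter in seq_len(100L)) {
        # nearest-mean assignment; ties go to the lower class
        d <- abs(outer(x, means, `-`))
        cls <- max.col(-d, ties.method = "first")
        newMeans <- means
        for (k in 1:3) {
            xk <- x[cls == k]
            if (length(xk) == 0L) next
            dk <- abs(xk - means[k])
            keep <- dk <= stats::quantile(dk, 1 - trimFraction, names = FALSE)
            newMeans[k] <- mean(xk[keep])
        }
        moved <- max(abs(newMeans - means))
        means <- newMeans
        if (moved < 0.01) break
    }
    if (length(unique(cls)) < 3L)
        stop("tissue mean estimation collapsed: fewer than 3 populated classes")
    if (!(means[1] < means[2] && means[2] < means[3]))
        stop("tissue mean estimation failed: class means not ordered")
    new("TissueMeans", csf = means[1], gm = means[2], wm = means[3])
}

#' Build the tissue-anchored piecewise-linear intensity map
#'
#' Maps the estimated CSF/GM/WM means to the normalized anchors 50/150/250,
#' with the segment below CSF anchored through the origin and the segment
#' above WM extending the GM-to-WM slope. The map is continuous and
#' monotone over `[0, Inf)`.
#'
#' @param means a [TissueMeans-class].
#' @return an [IntensityMap-class].
#' @export
buildIntensityMap <- function(means) {
    stopifnot(is(means, "TissueMeans"))
    validObject(means)
    new("IntensityMap",
        source = c(0, means@csf, means@gm, means@wm),
        target = c(0, 50, 150, 250))
}

#' Apply a piecewise-linear intensity map
#'
#' Every voxel is passed through the map; inputs below the first knot clamp
#' to its target (0), inputs above the last knot follow the last segment's
#' slope. Shape and voxel size are preserved.
#'
#' @param volume an [IntensityVolume-class].
#' @param map an [IntensityMap-class].
#' @return the normalized [IntensityVolume-class].
#' @export
applyIntensityMap <- function(volume, map) {
    stopifnot(is(volume, "IntensityVolume"), is(map, "IntensityMap"))
    validObject(map)
    src <- map@source
    tgt <- map@target
    x <- as.numeric(volume@data)
    y <- stats::approx(src, tgt, xout = pmin(x, src[length(src)]),
                       rule = 2)$y
    k <- length(src)
    slope <- (tgt[k] - tgt[k - 1]) / (src[k] - src[k - 1])
    hi <- x > src[k]
    y[hi] <- tgt[k] + slope * (x[hi] - src[k])
    y <- pmax(y, 0)
    IntensityVolume(array(y, dim = dim(volume@data)), volume@voxelSize,
                    volume@header)
}

#' Normalize a volume onto the tissue-anchored intensity scale
#'
#' Convenience composition of [estimateTissueMeans()], [buildIntensityMap()]
#' and [applyIntensityMap()].
#'
#' @inheritParams estimateTissueMeans
#' @return the normalized [IntensityVolume-class].
#' @export
normalizeVolume <- function(volume, roi, trimFraction = 0.2) {
    applyIntensityMap(volume,
                      buildIntensityMap(
                          estimateTissueMeans(volume, roi, trimFraction)))
}
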