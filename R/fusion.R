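#' Extract a cubic intensity patch
#'
#' Returns the patch of half-width `radius` centred on `center` (1-based
#' voxel indices), clamped to the grid — no padding values are invented.
#' The patch carries its centre, its values in x-fastest order, and its
#' mean and (population) standard deviation, the sufficient statistics of
#' the structural-similarity gate.
#'
#' @param volume an [IntensityVolume-class] (or 3D array).
#' @param center integer triple of 1-based voxel indices.
#' @param radius non-negative integer half-width; patch edge `2r + 1`.
#' @return a list with elements `values`, `center`, `mu`, `sigma`.
#' @export
patchAt <- function(volume, center, radius) {
    a <- if (is(volume, "IntensityVolume")) volume@data else volume
    d <- dim(a)
    center <- as.integer(center)
    stopifnot(length(center) == 3L, all(center >= 1L), all(center <= d))
    lo <- pmax(center - radius, 1L)
    hi <- pmin(center + radius, d)
    v <- as.numeric(a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
    mu <- mean(v)
    list(values = v, center = center, mu = mu,
         sigma = sqrt(sum((v - mu)^2) / length(v)))
}

.patchValues <- function(p) if (is.list(p)) p$values else as.numeric(p)

.patchStats <- function(p) {
    if (is.list(p) && !is.null(p$mu)) return(c(p$mu, p$sigma))
    v <- .patchValues(p)
    mu <- mean(v)
    c(mu, sqrt(sum((v - mu)^2) / length(v)))
}

.ssTerm <- function(a, b) {
    if (a == 0 && b == 0) return(1)
    if (a == 0 || b == 0) return(0)
    2 * a * b / (a^2 + b^2)
}

#' Structural similarity between two patches
#'
#' The product of a mean-agreement and a variance-agreement ratio,
#' `ss = (2 mu1 mu2 / (mu1^2 + mu2^2)) * (2 s1 s2 / (s1^2 + s2^2))`,
#' used as a cheap preselection score before the exponential weight is
#' computed. Degenerate conventions: a ratio term is 1 when both of its
#' arguments are 0 and 0 when exactly one is.
#'
#' @param p,q patches from [patchAt()] (or plain numeric vectors).
#' @return the similarity score (1 for identical patches).
#' @export
structuralSimilarity <- function(p, q) {
    sp <- .patchStats(p)
    sq <- .patchStats(q)
    .ssTerm(sp[1], sq[1]) * .ssTerm(sp[2], sq[2])
}

#' Normalized squared patch distance
#'
#' The squared L2 distance between the two patch vectors divided by the
#' number of elements.
#'
#' @inheritParams structuralSimilarity
#' @return the mean squared element difference.
#' @export
patchDistance <- function(p, q) {
    vp <- .patchValues(p)
    vq <- .patchValues(q)
    if (length(vp) != length(vq))
        stop(inputError("patch lengths differ"))
    sum((vp - vq)^2) / length(vp)
}

#' Adaptive bandwidth for one target location
#'
#' `h = lambda * min_d2 + epsilon`, where `min_d2` is the smallest
#' normalized squared patch distance between the target patch and any
#' candidate. The bandwidth adapts to how well the library matches the
#' local anatomy: a near-perfect match shrinks `h` so only that match
#' carries weight.
#'
#' @param target a patch from [patchAt()].
#' @param candidates a non-empty list of candidate patches.
#' @param lambdaH bandwidth scale (default 0.1).
#' @param epsilonH small positive stabiliser.
#' @return the strictly positive bandwidth.
#' @export
adaptiveH <- function(target, candidates, lambdaH = 0.1, epsilonH = 1e-6) {
    if (length(candidates) == 0L)
        stop(inputError("candidate set is empty"))
    d2 <- vapply(candidates, function(q) patchDistance(target, q), 0)
    lambdaH * min(d2) + epsilonH
}

#' Bilateral and classical patch weights
#'
#' `bilateralWeight()` combines spatial proximity and intensity similarity:
#' `w = exp(-(||c_t - c_q||/sigmaD + d2/h))`, with the Euclidean centre
#' distance in mm. `classicalWeight()` is the intensity-only baseline,
#' `w = exp(-d2/h^2)`. Both are gated by the structural-similarity
#' preselection: if `ss < ssThreshold` the weight is 0 and the exponential
#' is never computed.
#'
#' @param target,candidate patches from [patchAt()] (with centres for the
#'   bilateral form).
#' @param h bandwidth from [adaptiveH()]; must be positive.
#' @param sigmaD spatial decay constant in mm.
#' @param ssThreshold preselection threshold.
#' @param voxelSize voxel edge lengths in mm.
#' @return a weight in `[0, 1]`.
#' @export
bilateralWeight <- function(target, candidate, h, sigmaD = 8,
                            ssThreshold = 0.97, voxelSize = c(1, 1, 1)) {
    stopifnot(h > 0, sigmaD > 0)
    if (structuralSimilarity(target, candidate) < ssThreshold) return(0)
    dmm <- sqrt(sum(((candidate$center - target$center) * voxelSize)^2))
    exp(-(dmm / sigmaD + patchDistance(target, candidate) / h))
}

#' @rdname bilateralWeight
#' @export
classicalWeight <- function(target, candidate, h, ssThreshold = 0.97) {
    stopifnot(h > 0)
    if (structuralSimilarity(target, candidate) < ssThreshold) return(0)
    exp(-patchDistance(target, candidate) / h^2)
}

.fusionInputs <- function(subject, library, roi) {
    stopifnot(is(subject, "IntensityVolume"), is(roi, "BinaryMask"))
    library <- validateLibrary(library)
    d <- dim(subject@data)
    if (!identical(d, dim(library@intensities[[1]]@data)) ||
        !identical(d, dim(roi@data)))
        stop(inputError("subject, templates and roi must share one grid"))
    if (sum(roi@data) == 0L)
        stop(inputError("roi is empty"))
    n <- length(library)
    tmpl <- numeric(prod(d) * n)
    labs <- numeric(prod(d) * n)
    for (s in seq_len(n)) {
        tmpl[(s - 1) * prod(d) + seq_len(prod(d))] <-
            as.numeric(library@intensities[[s]]@data)
        labs[(s - 1) * prod(d) + seq_len(prod(d))] <-
            as.numeric(library@masks[[s]]@data)
    }
    list(d = d, n = n, tmpl = tmpl, labs = labs,
         roi = as.integer(roi@data), vs = subject@voxelSize)
}

.voteVolume <- function(res, d, vs) {
    new("VoteVolume",
        votes = array(res$votes, dim = d),
        weightMass = array(res$mass, dim = d),
        processed = array(res$processed, dim = d),
        fallback = array(res$fallback, dim = d),
        voxelSize = vs)
}

#' Voxelwise nonlocal label fusion
#'
#' For every ROI voxel, the vote is the weighted mean of candidate centre
#' labels over the search neighbourhood of every template, with the
#' bandwidth recomputed per voxel from its own candidate set. Weights are
#' bilateral by default; `weightMode = "classical"` gives the intensity-only
#' baseline. Voxels whose entire candidate set is gated out receive the
#' majority label of the candidate centres (ties to 0) and are flagged in
#' the `fallback` slot.
#'
#' @param subject the normalized [IntensityVolume-class] to segment.
#' @param library a validated [TemplateLibrary-class] of selected templates
#'   (all of it is used; preselect with [selectTemplates()]).
#' @param roi a non-empty [BinaryMask-class] of voxels to estimate.
#' @param patchRadius,searchRadius patch and search half-widths (voxels).
#' @param lambdaH,epsilonH,sigmaD,ssThreshold weight parameters; see
#'   [fusionConfig()].
#' @param weightMode `"bilateral"` or `"classical"`.
#' @return a [VoteVolume-class].
#' @export
voxelwiseFusion <- function(subject, library, roi,
                            patchRadius = 1L, searchRadius = 2L,
                            lambdaH = 0.1, epsilonH = 1e-6, sigmaD = 8,
                            ssThreshold = 0.97, weightMode = "bilateral") {
    inp <- .fusionInputs(subject, library, roi)
    res <- cppVoxelwiseFusion(as.numeric(subject@data), as.integer(inp$d),
        inp$tmpl, inp$labs, inp$n, inp$roi,
        as.integer(patchRadius), as.integer(searchRadius),
        lambdaH, epsilonH, sigmaD, ssThreshold, inp$vs,
        identical(weightMode, "classical"))
    .voteVolume(res, inp$d, inp$vs)
}

.centerAxis <- function(lo, hi, spacing, radius) {
    cs <- seq.int(lo, hi, by = spacing)
    if (cs[length(cs)] + radius < hi) cs <- c(cs, hi)
    cs
}

#' Block centre grid over a region
#'
#' Centres are placed every `spacing` voxels along each axis of the ROI
#' bounding box, plus the last in-bounds position per axis whenever the
#' final regular block would not reach the box edge. These are the sites
#' where fusion weights are evaluated; spacing 2 gives one eighth as many
#' sites as spacing 1 (exactly, when each axis length divides evenly).
#'
#' @param roi a [BinaryMask-class] (its bounding box is used) or an integer
#'   triple taken as a full-grid shape.
#' @param spacing voxels between adjacent centres.
#' @param radius block half-width.
#' @return integer matrix with one centre (1-based x, y, z) per row.
#' @export
blockCenters <- function(roi, spacing = 2L, radius = 1L) {
    if (is(roi, "BinaryMask")) {
        w <- which(roi@data == 1L, arr.ind = TRUE)
        if (nrow(w) == 0L) stop(inputError("roi is empty"))
        lo <- apply(w, 2, min)
        hi <- apply(w, 2, max)
    } else {
        lo <- c(1L, 1L, 1L)
        hi <- as.integer(roi)
    }
    ax <- lapply(1:3, function(a)
        .centerAxis(lo[a], hi[a], as.integer(spacing), as.integer(radius)))
    as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                          KEEP.OUT.ATTRS = FALSE))
}

#' Blockwise overcomplete label fusion
#'
#' One weight per candidate is computed from the centre patches exactly as
#' in [voxelwiseFusion()], but it multiplies the candidate's entire label
#' block (edge `2*blockRadius + 1`): each covered ROI voxel accumulates the
#' weighted label and the weight itself over all blocks containing it, and
#' the vote is the accumulated ratio (overcomplete averaging). Labelling
#' whole blocks regularises the segmentation, and spacing the block grid
#' cuts the number of weight evaluations by `spacing^3`. With
#' `blockRadius = 0` and `blockSpacing = 1` this reduces exactly to
#' [voxelwiseFusion()].
#'
#' @inheritParams voxelwiseFusion
#' @param blockRadius label block half-width.
#' @param blockSpacing voxels between adjacent block centres; must not
#'   exceed the block edge.
#' @return a [VoteVolume-class].
#' @export
blockwiseFusion <- function(subject, library, roi,
                            patchRadius = 1L, searchRadius = 2L,
                            blockRadius = 1L, blockSpacing = 2L,
                            lambdaH = 0.1, epsilonH = 1e-6, sigmaD = 8,
                            ssThreshold = 0.97, weightMode = "bilateral") {
    if (blockSpacing > 2L * blockRadius + 1L)
        stop(inputError("blockSpacing must not exceed the block edge"))
    inp <- .fusionInputs(subject, library, roi)
    w <- which(roi@data == 1L, arr.ind = TRUE)
    lo <- apply(w, 2, min)
    hi <- apply(w, 2, max)
    ax <- lapply(1:3, function(a)
        .centerAxis(lo[a], hi[a], as.integer(blockSpacing),
                    as.integer(blockRadius)))
    res <- cppBlockwiseFusion(as.numeric(subject@data), as.integer(inp$d),
        inp$tmpl, inp$labs, inp$n, inp$roi,
        as.integer(ax[[1]] - 1L), as.integer(ax[[2]] - 1L),
        as.integer(ax[[3]] - 1L),
        as.integer(patchRadius), as.integer(searchRadius),
        as.integer(blockRadius),
        lambdaH, epsilonH, sigmaD, ssThreshold, inp$vs,
        identical(weightMode, "classical"))
    .voteVolume(res, inp$d, inp$vs)
}

#' Threshold a vote field into a binary mask
#'
#' Voxels whose fused vote reaches the threshold (default 0.5, inclusive)
#' become label 1; everything else, including voxels never processed,
#' becomes 0.
#'
#' @param votes a [VoteVolume-class].
#' @param voteThreshold decision threshold in (0, 1).
#' @return a [BinaryMask-class].
#' @export
thresholdVotes <- function(votes, voteThreshold = 0.5) {
    stopifnot(is(votes, "VoteVolume"))
    m <- (votes@votes >= voteThreshold) & (votes@processed == 1L)
    BinaryMask(array(as.integer(m), dim = dim(votes@votes)),
               votes@voxelSize)
}
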