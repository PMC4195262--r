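test_that("structural similarity follows its closed form and conventions", {
    p <- patchAt(array(stats::runif(27, 10, 20), dim = c(3, 3, 3)),
                 c(2, 2, 2), 1L)
    expect_equal(structuralSimilarity(p, p), 1.0)
    expect_equal(structuralSimilarity(stat_patch(100, 10),
                                      stat_patch(200, 10)), 0.8)
    expect_equal(structuralSimilarity(stat_patch(50, 0),
                                      stat_patch(50, 5)), 0)
    expect_equal(structuralSimilarity(stat_patch(50, 0),
                                      stat_patch(50, 0)), 1)
})

test_that("patch distance is the length-normalized squared L2 norm", {
    z <- list(values = rep(0, 27))
    t3 <- list(values = rep(3, 27))
    expect_equal(patchDistance(z, z), 0)
    expect_equal(patchDistance(z, t3), 9)
    set.seed(1)
    p <- list(values = stats::rnorm(27))
    q <- list(values = stats::rnorm(27))
    expect_equal(patchDistance(p, q), patchDistance(q, p))
    expect_error(patchDistance(p, list(values = stats::rnorm(8))),
                 "lengths")
})

test_that("the adaptive bandwidth tracks the best candidate match", {
    tgt <- list(values = rep(1, 27))
    same <- list(values = rep(1, 27))
    far <- list(values = rep(3, 27))     # d2 = 4
    expect_equal(adaptiveH(tgt, list(same, far)), 1e-6)
    expect_equal(adaptiveH(tgt, list(far)), 0.400001)
    expect_equal(adaptiveH(tgt, list(far), lambdaH = 1) - 1e-6,
                 10 * (adaptiveH(tgt, list(far), lambdaH = 0.1) - 1e-6))
    expect_error(adaptiveH(tgt, list()), "empty")
})

test_that("bilateral and classical weights evaluate to their closed forms", {
    a <- array(stats::runif(5^3, 100, 200), dim = c(5, 5, 5))
    tgt <- patchAt(a, c(2, 2, 2), 1L)
    self <- patchAt(a, c(2, 2, 2), 1L)
    expect_equal(bilateralWeight(tgt, self, h = 0.5), 1.0)
    # identical content displaced 8 mm with sigma_d = 8 decays to 1/e
    shifted <- self
    shifted$center <- self$center + c(8L, 0L, 0L)
    expect_equal(bilateralWeight(tgt, shifted, h = 0.5, sigmaD = 8),
                 exp(-1))
    # preselection gate: ss = 0.8 < 0.97 kills the weight outright
    expect_equal(bilateralWeight(stat_patch(100, 10, c(1, 1, 1)),
                                 stat_patch(200, 10, c(1, 1, 1)), h = 1), 0)
    expect_equal(classicalWeight(stat_patch(100, 10), stat_patch(200, 10),
                                 h = 1), 0)
    expect_equal(classicalWeight(tgt, self, h = 0.5), 1.0)
    # unit exponent: d2 = h^2 gives exactly 1/e (patches pass the gate)
    u <- list(values = rep(100, 27), mu = 100, sigma = 3)
    v <- list(values = c(rep(100, 26), 100 + sqrt(27 * 4)), mu = 100,
              sigma = 3)
    expect_equal(classicalWeight(u, v, h = 2, ssThreshold = 0), exp(-1))
})

test_that("voxelwise fusion matches the brute-force reference", {
    for (seed in c(7L, 21L)) {
        inst <- random_fusion_instance(seed)
        lib <- as_library(inst)
        sel <- inst$roi == 1L
        for (classical in c(FALSE, TRUE)) {
            or <- oracle_voxelwise(inst$subject, inst$tmplInts,
                                   inst$tmplMasks, inst$roi,
                                   classical = classical)
            vv <- voxelwiseFusion(IntensityVolume(inst$subject), lib,
                                  BinaryMask(inst$roi),
                                  weightMode = if (classical) "classical"
                                               else "bilateral")
            expect_lt(max(abs(voxelData(vv)[sel] - or[sel])), 1e-10)
            expect_true(all(voxelData(vv)[sel] >= 0 &
                            voxelData(vv)[sel] <= 1))
        }
    }
})

test_that("degenerate blocks reduce blockwise to voxelwise exactly", {
    inst <- random_fusion_instance(5L)
    lib <- as_library(inst)
    vv <- voxelwiseFusion(IntensityVolume(inst$subject), lib,
                          BinaryMask(inst$roi))
    bw <- blockwiseFusion(IntensityVolume(inst$subject), lib,
                          BinaryMask(inst$roi),
                          blockRadius = 0L, blockSpacing = 1L)
    expect_identical(voxelData(bw), voxelData(vv))
    expect_identical(bw@processed, vv@processed)
})

test_that("fusion conserves unanimous labels", {
    inst <- random_fusion_instance(9L)
    ones <- lapply(inst$tmplMasks, function(m)
        array(1L, dim = dim(m)))
    lib1 <- TemplateLibrary(lapply(inst$tmplInts, IntensityVolume),
                            lapply(ones, BinaryMask))
    bw <- blockwiseFusion(IntensityVolume(inst$subject), lib1,
                          BinaryMask(inst$roi))
    sel <- bw@processed == 1L
    expect_true(all(voxelData(bw)[sel] == 1))
    zeros <- lapply(inst$tmplMasks, function(m) {
        z <- array(0L, dim = dim(m)); z[1, 1, 1] <- 1L; z  # keep non-empty
    })
    lib0 <- TemplateLibrary(lapply(inst$tmplInts, IntensityVolume),
                            lapply(zeros, BinaryMask))
    vv <- voxelwiseFusion(IntensityVolume(inst$subject), lib0,
                          BinaryMask(inst$roi))
    expect_true(all(voxelData(vv)[inst$roi == 1L] == 0))
})

test_that("a self-matching template dominates the vote", {
    inst <- random_fusion_instance(13L)
    lib <- TemplateLibrary(list(IntensityVolume(inst$subject)),
                           list(BinaryMask(inst$tmplMasks[[1]])))
    # restrict to voxels whose whole search area shares the centre label,
    # where the vote must reproduce the template's label exactly
    vv <- voxelwiseFusion(IntensityVolume(inst$subject), lib,
                          BinaryMask(inst$roi), searchRadius = 1L)
    m <- inst$tmplMasks[[1]]
    d <- dim(m)
    uniform <- array(FALSE, dim = d)
    for (x in 3:(d[1] - 2)) for (y in 3:(d[2] - 2)) for (z in 3:(d[3] - 2))
        uniform[x, y, z] <-
            length(unique(as.vector(m[(x - 1):(x + 1), (y - 1):(y + 1),
                                      (z - 1):(z + 1)]))) == 1L
    sel <- inst$roi == 1L & uniform
    expect_true(any(sel))
    expect_equal(voxelData(vv)[sel], as.numeric(m[sel]))
})

test_that("weights decay monotonically with spatial offset", {
    a <- array(150, dim = c(30, 5, 5))
    tgt <- patchAt(a, c(15, 3, 3), 1L)
    w <- vapply(0:10, function(dx) {
        cand <- patchAt(a, c(15 + dx, 3, 3), 1L)
        bilateralWeight(tgt, cand, h = 0.5)
    }, 0)
    expect_true(all(diff(w) < 0 | (w[-1] == 0 & diff(w) <= 0)))
})

test_that("raising the preselection threshold never raises a weight", {
    set.seed(4)
    a <- array(stats::runif(7^3, 100, 200), dim = c(7, 7, 7))
    tgt <- patchAt(a, c(4, 4, 4), 1L)
    for (i in 1:20) {
        cand <- patchAt(a, c(sample(2:6, 1), sample(2:6, 1),
                             sample(2:6, 1)), 1L)
        ths <- c(0, 0.5, 0.9, 0.97, 0.999)
        w <- vapply(ths, function(th)
            bilateralWeight(tgt, cand, h = 0.5, ssThreshold = th), 0)
        expect_true(all(diff(w) <= 0))
    }
})

test_that("votes are invariant to template order", {
    inst <- random_fusion_instance(17L)
    lib <- as_library(inst)
    vv1 <- voxelwiseFusion(IntensityVolume(inst$subject), lib,
                           BinaryMask(inst$roi))
    vv2 <- voxelwiseFusion(IntensityVolume(inst$subject), lib[c(3, 1, 2)],
                           BinaryMask(inst$roi))
    sel <- inst$roi == 1L
    expect_lt(max(abs(voxelData(vv1)[sel] - voxelData(vv2)[sel])), 1e-12)
})

test_that("vote thresholding is inclusive at the threshold", {
    d <- c(2L, 2L, 1L)
    votes <- new("VoteVolume",
        votes = array(c(0.5, 0.4999, 1, 0), dim = d),
        weightMass = array(1, dim = d),
        processed = array(1L, dim = d),
        fallback = array(0L, dim = d), voxelSize = c(1, 1, 1))
    m <- thresholdVotes(votes)
    expect_identical(as.vector(voxelData(m)), c(1L, 0L, 1L, 0L))
    # unprocessed voxels always map to background
    votes@processed[1, 1, 1] <- 0L
    expect_identical(voxelData(thresholdVotes(votes))[1, 1, 1], 0L)
    # an all-ones vote field fills the processed region
    votes@votes[] <- 1
    votes@processed[] <- 1L
    expect_true(all(voxelData(thresholdVotes(votes)) == 1L))
})

test_that("the block grid covers the box and thins by spacing^3", {
    c1 <- blockCenters(c(64L, 64L, 64L), spacing = 1L, radius = 0L)
    c2 <- blockCenters(c(64L, 64L, 64L), spacing = 2L, radius = 1L)
    expect_equal(nrow(c1), 64^3)
    expect_equal(nrow(c1) / nrow(c2), 8)
    # odd axis: an extra terminal centre is appended to cover the edge
    ax <- blockCenters(c(9L, 9L, 9L), spacing = 3L, radius = 1L)
    expect_true(all(c(1L, 4L, 7L, 9L) %in% unique(ax[, "x"])))
})
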