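test_that("noiseless three-class volumes are a fixed point of the estimator", {
    tc <- three_class_volume(c(30, 90, 160), perClass = 500L)
    tm <- estimateTissueMeans(tc$volume, tc$roi)
    expect_equal(c(tm@csf, tm@gm, tm@wm), c(30, 90, 160))
})

test_that("noisy class means are recovered against the labelled oracle", {
    tc <- three_class_volume(c(30, 90, 160), perClass = 10000L,
                             noiseSd = 5, seed = 42L)
    tm <- estimateTissueMeans(tc$volume, tc$roi, trimFraction = 0.2)
    # oracle: sample class means from the generator's own labels
    truth <- tapply(tc$values, tc$labels, mean)
    expect_lt(abs(tm@csf - truth[[1]]), 1.0)
    expect_lt(abs(tm@gm - truth[[2]]), 1.0)
    expect_lt(abs(tm@wm - truth[[3]]), 1.0)
})

test_that("estimation is order-invariant and fails on degenerate input", {
    tc <- three_class_volume(c(30, 90, 160), perClass = 300L, noiseSd = 5,
                             seed = 7L)
    set.seed(8)
    perm <- sample(length(tc$values))
    shuffled <- IntensityVolume(array(tc$values[perm],
                                      dim = dim(voxelData(tc$volume))))
    a <- estimateTissueMeans(tc$volume, tc$roi)
    b <- estimateTissueMeans(shuffled, tc$roi)
    expect_equal(c(a@csf, a@gm, a@wm), c(b@csf, b@gm, b@wm))

    bimodal <- IntensityVolume(array(rep(c(30, 90), each = 500),
                                     dim = c(1000, 1, 1)))
    roi <- BinaryMask(array(1L, dim = c(1000, 1, 1)))
    expect_error(estimateTissueMeans(bimodal, roi), "classes|distinct")
    expect_error(estimateTissueMeans(tc$volume,
        BinaryMask(array(0L, dim = dim(voxelData(tc$volume))))), "empty")
})

test_that("the intensity map hits its anchors and interpolates linearly", {
    tm <- new("TissueMeans", csf = 30, gm = 90, wm = 160)
    map <- buildIntensityMap(tm)
    probe <- function(x) {
        v <- IntensityVolume(array(x, dim = c(1, 1, 1)))
        voxelData(applyIntensityMap(v, map))[1]
    }
    expect_equal(probe(30), 50)
    expect_equal(probe(90), 150)
    expect_equal(probe(160), 250)
    expect_equal(probe((90 + 160) / 2), 200)     # midpoint of gm-wm segment
    expect_equal(probe(0), 0)
    # above wm the gm->wm slope is extended
    slope <- 100 / 70
    expect_equal(probe(200), 250 + slope * 40)
    expect_error(buildIntensityMap(new("TissueMeans", csf = 90, gm = 30,
                                       wm = 160)), "ordering|csf < gm")
})

test_that("the map is monotone and constant volumes map to anchors", {
    tm <- new("TissueMeans", csf = 30, gm = 90, wm = 160)
    map <- buildIntensityMap(tm)
    x <- sort(stats::runif(200, -10, 400))
    y <- voxelData(applyIntensityMap(
        IntensityVolume(array(x, dim = c(200, 1, 1))), map))
    expect_true(all(diff(as.vector(y)) >= 0))
    const <- IntensityVolume(array(30, dim = c(4, 4, 4)))
    expect_true(all(voxelData(applyIntensityMap(const, map)) == 50))
})

test_that("normalization then re-estimation reproduces the anchors exactly", {
    tc <- three_class_volume(c(30, 90, 160), perClass = 500L)
    norm <- normalizeVolume(tc$volume, tc$roi)
    tm2 <- estimateTissueMeans(norm, tc$roi)
    expect_equal(c(tm2@csf, tm2@gm, tm2@wm), c(50, 150, 250))
    # near-identity on already-normalized data
    map2 <- buildIntensityMap(tm2)
    again <- applyIntensityMap(norm, map2)
    expect_lt(max(abs(voxelData(again) - voxelData(norm))), 1)
})
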