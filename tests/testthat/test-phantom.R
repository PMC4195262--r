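test_that("noiseless undeformed phantoms are exact", {
    spec <- phantomSpec(dim = 32L, noiseSd = 0, deformAmplitude = 0)
    ph <- makePhantom(spec)
    wm <- ph$labels == 4L
    expect_true(any(wm))
    expect_true(all(voxelData(ph$intensity)[wm] == 250))
    csf <- ph$labels == 2L
    expect_true(all(voxelData(ph$intensity)[csf] == 50))
    # mask = all intracranial tissue, skull and background excluded
    expect_identical(voxelData(ph$mask),
                     array(as.integer(ph$labels >= 2L),
                           dim = dim(ph$labels)))
})

test_that("the IC mask matches the analytic ellipsoid count", {
    spec <- phantomSpec(dim = 32L, noiseSd = 0, deformAmplitude = 0)
    ph <- makePhantom(spec)
    # independent voxelised count of the inner-skull ellipsoid
    d <- spec@dim
    ctr <- (d + 1) / 2
    semi <- spec@semiAxes$ic
    cnt <- 0L
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3])
        if (((x - ctr[1]) / semi[1])^2 + ((y - ctr[2]) / semi[2])^2 +
            ((z - ctr[3]) / semi[3])^2 <= 1) cnt <- cnt + 1L
    expect_identical(sum(voxelData(ph$mask)), cnt)
})

test_that("phantom generation is seed-deterministic", {
    spec <- phantomSpec(dim = 24L, noiseSd = 5, deformAmplitude = 2,
                        seed = 77L)
    a <- makePhantom(spec)
    b <- makePhantom(spec)
    expect_identical(voxelData(a$intensity), voxelData(b$intensity))
    expect_identical(voxelData(a$mask), voxelData(b$mask))
    spec2 <- phantomSpec(dim = 24L, noiseSd = 5, deformAmplitude = 2,
                         seed = 78L)
    expect_false(identical(voxelData(a$intensity),
                           voxelData(makePhantom(spec2)$intensity)))
})

test_that("libraries are populated, distinct, and collapse when variability is off", {
    spec <- phantomSpec(dim = 24L, noiseSd = 2, deformAmplitude = 1.5,
                        seed = 9L)
    lib <- makeLibrary(spec, 6)
    expect_identical(length(lib), 6L)
    for (i in 1:6) expect_gt(sum(voxelData(lib@masks[[i]])), 0L)
    expect_false(identical(voxelData(lib@intensities[[1]]),
                           voxelData(lib@intensities[[2]])))
    # zero variability: all templates identical
    spec0 <- phantomSpec(dim = 24L, noiseSd = 0, deformAmplitude = 0,
                         seed = 9L)
    lib0 <- makeLibrary(spec0, 3, deformAmplitude = 0,
                        intensityJitterSd = 0)
    expect_identical(voxelData(lib0@intensities[[1]]),
                     voxelData(lib0@intensities[[3]]))
    expect_identical(voxelData(lib0@masks[[1]]),
                     voxelData(lib0@masks[[3]]))
    expect_error(makeLibrary(spec, 0), "n must be")
})

test_that("deformation moves the mask but stays amplitude-bounded", {
    spec <- phantomSpec(dim = 32L, noiseSd = 0, deformAmplitude = 2,
                        seed = 15L)
    ph <- makePhantom(spec)
    ph0 <- makePhantom(phantomSpec(dim = 32L, noiseSd = 0,
                                   deformAmplitude = 0))
    expect_false(identical(voxelData(ph$mask), voxelData(ph0$mask)))
    # a 2-voxel displacement cap keeps the deformed mask inside the
    # 2-voxel dilation of the undeformed one
    grown <- dilateMask(ph0$mask, 3L)
    expect_true(all(voxelData(ph$mask) <= voxelData(grown)))
    # and volumes stay comparable
    expect_lt(abs(sum(voxelData(ph$mask)) / sum(voxelData(ph0$mask)) - 1),
              0.2)
})
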