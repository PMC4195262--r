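test_that("class validity enforces the core invariants", {
    expect_error(IntensityVolume(array(c(1, NA), dim = c(2, 1, 1))),
                 "finite")
    expect_error(IntensityVolume(array(1, dim = c(2, 2)), c(1, 1, 1)),
                 "3D")
    expect_error(IntensityVolume(array(1, dim = c(2, 2, 2)),
                                 voxelSize = c(1, 0, 1)), "positive")
    expect_error(BinaryMask(array(0.5, dim = c(2, 2, 2))), "0 or 1")
    m <- BinaryMask(array(TRUE, dim = c(2, 2, 2)))
    expect_identical(unique(as.vector(voxelData(m))), 1L)
})

test_that("validateLibrary returns consistent libraries unchanged", {
    lib <- tiny_library(3L)
    expect_identical(validateLibrary(lib), lib)
})

test_that("validateLibrary names the offending template", {
    lib <- tiny_library(3L)
    bad <- lib@masks[[2]]
    d <- voxelData(bad)
    storage.mode(d) <- "double"
    d[1, 1, 1] <- 0.5
    bad@data <- d                       # bypass constructor checks
    lib@masks[[2]] <- bad
    expect_error(validateLibrary(lib), "template 2.*0/1")

    lib2 <- tiny_library(3L)
    lib2@intensities[[3]] <-
        IntensityVolume(array(0, dim = c(9, 8, 8)))
    expect_error(validateLibrary(lib2), "template 3.*shape")

    lib3 <- tiny_library(2L)
    lib3@masks[[1]]@data <- array(0L, dim = c(8, 8, 8))
    expect_error(validateLibrary(lib3), "template 1.*empty")
})

test_that("flip augmentation doubles the library and mirrors exactly", {
    lib <- tiny_library(4L, d = 10L, seed = 3L)
    aug <- flipAugment(lib)
    expect_identical(length(aug), 2L * length(lib))
    # flipping twice recovers the originals bit-identically
    again <- flipAugment(aug[seq_len(length(lib)) + length(lib)])
    back <- again[seq_len(length(lib)) + length(lib)]
    for (i in seq_len(length(lib))) {
        expect_identical(voxelData(back[[i]]$intensity),
                         voxelData(lib[[i]]$intensity))
        expect_identical(voxelData(back[[i]]$mask),
                         voxelData(lib[[i]]$mask))
    }
    # mirroring is a permutation: volumes and histograms preserved
    for (i in seq_len(length(lib))) {
        orig <- aug[[i]]
        flip <- aug[[i + length(lib)]]
        expect_identical(sum(voxelData(flip$mask)), sum(voxelData(orig$mask)))
        expect_identical(sort(as.vector(voxelData(flip$intensity))),
                         sort(as.vector(voxelData(orig$intensity))))
    }
})

test_that("fusion configuration validates its invariants", {
    expect_error(fusionConfig(pyramidScales = c(4L, 2L)), "end at 1")
    expect_error(fusionConfig(pyramidScales = c(2L, 4L, 1L)), "decreasing")
    expect_error(fusionConfig(blockRadius = 0L, blockSpacing = 2L),
                 "blockSpacing")
    expect_error(fusionConfig(weightMode = "fancy"), "weightMode")
    expect_error(fusionConfig(voteThreshold = 1), "voteThreshold")
})

test_that("configurations round-trip through YAML and JSON losslessly", {
    cfg <- fusionConfig(nTemplates = 7L, lambdaH = 0.25,
                        searchRadius = c(5L, 2L, 1L), blockSpacing = 3L,
                        blockRadius = 2L, weightMode = "classical")
    for (ext in c("yaml", "json")) {
        path <- file.path(tempdir(), paste0("cfg.", ext))
        writeFusionConfig(cfg, path)
        back <- readFusionConfig(path)
        for (s in slotNames(cfg))
            expect_equal(slot(back, s), slot(cfg, s), info = s)
    }
    # omitted keys fall back to defaults
    path <- file.path(tempdir(), "partial.yaml")
    yaml::write_yaml(list(n_templates = 4L), path)
    part <- readFusionConfig(path)
    expect_identical(part@nTemplates, 4L)
    expect_identical(part@sigmaD, fusionConfig()@sigmaD)
    expect_error(readFusionConfig(file.path(tempdir(), "nope.yaml")),
                 "not found")
})
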