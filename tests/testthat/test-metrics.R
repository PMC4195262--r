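test_that("overlap counts, Dice and rates agree with direct counting", {
    d <- c(10L, 10L, 10L)
    a <- array(0L, dim = d); a[1:100] <- 1L
    b <- array(0L, dim = d); b[21:120] <- 1L      # |A|=|B|=100, overlap 80
    rep <- overlap(BinaryMask(a), BinaryMask(b))
    expect_equal(rep@dice, 0.8)
    expect_equal(rep@sensitivity, 0.8)
    expect_equal(rep@tp + rep@fp + rep@fn + rep@tn, prod(d))
    expect_equal(rep@specificity, 880 / 900)   # tn = 1000 - 80 - 20 - 20
    expect_equal(rep@volumeA, 0.1)                # 100 voxels of 1 mm^3

    same <- overlap(BinaryMask(a), BinaryMask(a))
    expect_equal(c(same@dice, same@sensitivity, same@specificity),
                 c(1, 1, 1))
    disjoint <- array(0L, dim = d); disjoint[900:1000] <- 1L
    expect_equal(overlap(BinaryMask(a), BinaryMask(disjoint))@dice, 0)
})

test_that("Dice is symmetric with the empty-empty convention", {
    set.seed(3)
    d <- c(8L, 8L, 8L)
    a <- BinaryMask(array(as.integer(stats::runif(prod(d)) > 0.6), dim = d))
    b <- BinaryMask(array(as.integer(stats::runif(prod(d)) > 0.6), dim = d))
    expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
    empty <- BinaryMask(array(0L, dim = d))
    expect_equal(diceCoefficient(empty, empty), 1)
    expect_error(overlap(a, empty), "reference.*empty")
    expect_error(overlap(a, BinaryMask(array(0L, dim = c(9, 8, 8)))),
                 "shapes")
})

test_that("percent volume difference is symmetric and anchored at zero", {
    expect_equal(percentVolumeDifference(1400, 1400), 0)
    expect_equal(percentVolumeDifference(102, 98), 4)
    set.seed(6)
    for (i in 1:10) {
        v <- stats::runif(2, 500, 2000)
        expect_equal(percentVolumeDifference(v[1], v[2]),
                     percentVolumeDifference(v[2], v[1]))
        expect_lt(percentVolumeDifference(v[1], v[2]), 200)
        expect_gte(percentVolumeDifference(v[1], v[2]), 0)
    }
    expect_equal(percentVolumeDifference(102, 98, method = "reference"),
                 100 * 4 / 102)
    expect_error(percentVolumeDifference(0, 10), "positive")
})

test_that("volume correlation matches the covariance formula", {
    ref <- c(1, 2, 3)
    est <- c(2, 4, 6.1)
    # closed-form Pearson oracle
    oracle <- sum((est - mean(est)) * (ref - mean(ref))) /
        sqrt(sum((est - mean(est))^2) * sum((ref - mean(ref))^2))
    expect_equal(volumeCorrelation(est, ref), oracle)
    expect_equal(volumeCorrelation(ref, ref), 1)
    expect_equal(volumeCorrelation(-ref, ref), -1)
    expect_error(volumeCorrelation(c(1, 1, 1), ref), "constant")
    expect_error(volumeCorrelation(c(1, 2), c(1, 2)), "3 pairs")
    expect_error(volumeCorrelation(c(1, 2, 3), c(1, 2)), "lengths")
})
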