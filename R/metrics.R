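#' Voxel-overlap agreement between two masks
#'
#' Compares a segmentation `a` against a reference `b`:
#' Dice `2tp/(2tp + fp + fn)`, sensitivity `tp/(tp + fn)`, specificity
#' `tn/(tn + fp)`, the confusion counts, and both volumes in mL. The
#' reference must be non-empty (sensitivity is undefined otherwise); for
#' the bare Dice with the empty-vs-empty convention use
#' [diceCoefficient()].
#'
#' @param a the evaluated [BinaryMask-class].
#' @param b the reference [BinaryMask-class]; must be non-empty.
#' @param voxelSize voxel edge lengths in mm (defaults to the masks').
#' @return an [OverlapReport-class].
#' @export
overlap <- function(a, b, voxelSize = a@voxelSize) {
    stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
    if (!identical(dim(a@data), dim(b@data)))
        stop(inputError("mask shapes differ"))
    if (sum(b@data) == 0L)
        stop(inputError("reference mask is empty: sensitivity undefined"))
    av <- a@data == 1L
    bv <- b@data == 1L
    tp <- sum(av & bv)
    fp <- sum(av & !bv)
    fn <- sum(!av & bv)
    tn <- sum(!av & !bv)
    vv <- prod(voxelSize) / 1000
    new("OverlapReport",
        dice = 2 * tp / (2 * tp + fp + fn),
        sensitivity = tp / (tp + fn),
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
        tp = tp, fp = fp, fn = fn, tn = tn,
        volumeA = sum(av) * vv, volumeB = sum(bv) * vv)
}

#' Dice coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`, with two empty masks defined as in
#' perfect agreement (Dice 1).
#'
#' @param a,b [BinaryMask-class] objects on one grid.
#' @return the Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
    stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
    if (!identical(dim(a@data), dim(b@data)))
        stop(inputError("mask shapes differ"))
    sa <- sum(a@data)
    sb <- sum(b@data)
    if (sa + sb == 0L) return(1)
    2 * sum(a@data == 1L & b@data == 1L) / (sa + sb)
}

#' Percent volume difference
#'
#' Symmetric test-retest volume discrepancy,
#' `100 |v1 - v2| / ((v1 + v2)/2)`; with `method = "reference"` the
#' denominator is `v1` instead.
#'
#' @param v1,v2 positive volumes (any common unit).
#' @param method `"symmetric"` (default) or `"reference"`.
#' @return the percentage difference (0 iff equal; < 200 for the
#'   symmetric form).
#' @export
percentVolumeDifference <- function(v1, v2, method = c("symmetric",
                                                       "reference")) {
    method <- match.arg(method)
    if (v1 <= 0 || v2 <= 0)
        stop(inputError("volumes must be positive"))
    den <- if (method == "symmetric") (v1 + v2) / 2 else v1
    100 * abs(v1 - v2) / den
}

#' Pearson correlation of estimated against reference volumes
#'
#' @param estimates,references numeric vectors of equal length >= 3,
#'   neither constant.
#' @return the Pearson correlation coefficient.
#' @export
volumeCorrelation <- function(estimates, references) {
    if (length(estimates) != length(references))
        stop(inputError("series lengths differ"))
    if (length(estimates) < 3L)
        stop(inputError("need at least 3 pairs"))
    if (stats::sd(estimates) == 0 || stats::sd(references) == 0)
        stop(inputError("constant series: correlation undefined"))
    stats::cor(estimates, references)
}

#' Overlap report as a one-row data frame
#'
#' @param report an [OverlapReport-class].
#' @return a data frame with the report's fields, suitable for stacking
#'   into a batch CSV.
#' @export
asReportRow <- function(report) {
    stopifnot(is(report, "OverlapReport"))
    data.frame(dice = report@dice, sensitivity = report@sensitivity,
        specificity = report@specificity, tp = report@tp, fp = report@fp,
        fn = report@fn, tn = report@tn, volume_a_ml = report@volumeA,
        volume_b_ml = report@volumeB)
}
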