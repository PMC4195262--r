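#' Construct a phantom specification
#'
#' Defaults describe a desk-scale head on a 64^3 grid at 1 mm: a skull
#' shell around an intracranial cavity holding an external-CSF shell, a GM
#' shell, a WM core and a pair of CSF-filled ventricles. Tissue means sit
#' on the normalized scale (CSF 50, GM 150, WM 250; background 10,
#' skull 40), matching what the intensity normalization produces on real
#' data. Defaults of 5 units of additive Gaussian noise and a 2-voxel
#' smooth deformation emulate residual noise after denoising and the
#' anatomical variability left after linear registration.
#'
#' @param dim integer grid shape (scalar or triple).
#' @param voxelSize voxel size in mm.
#' @param semiAxes named list of ellipsoid semi-axes (voxels): `skull`,
#'   `ic`, `gm`, `wm`, `ventricle`; by default scaled to the grid (the
#'   values shown are for 64^3).
#' @param means named tissue means: `background`, `skull`, `csf`, `gm`,
#'   `wm`.
#' @param noiseSd additive Gaussian noise sd (intensity units).
#' @param deformAmplitude displacement cap (voxels) of the smooth random
#'   deformation.
#' @param seed integer seed.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = 64L, voxelSize = c(1, 1, 1),
                        semiAxes = NULL,
                        means = c(background = 10, skull = 40, csf = 50,
                                  gm = 150, wm = 250),
                        noiseSd = 5, deformAmplitude = 2, seed = 1L) {
    if (length(dim) == 1L) dim <- rep(dim, 3L)
    if (is.null(semiAxes)) {
        s <- dim / 64                       # reference geometry is 64^3
        semiAxes <- list(skull = s * c(27, 29, 25), ic = s * c(24, 26, 22),
                         gm = s * c(21, 23, 19), wm = s * c(16, 18, 14),
                         ventricle = s * c(4, 7, 4))
    }
    spec <- new("PhantomSpec", dim = as.integer(dim),
        voxelSize = as.numeric(voxelSize), semiAxes = semiAxes,
        means = means, noiseSd = as.numeric(noiseSd),
        deformAmplitude = as.numeric(deformAmplitude),
        seed = as.integer(seed))
    validObject(spec)
    spec
}

# inside-ellipsoid indicator on the voxel grid (1-based indices against a
# possibly fractional centre)
.insideEllipsoid <- function(d, center, semi) {
    X <- (slice.index(array(0L, d), 1) - center[1]) / semi[1]
    Y <- (slice.index(array(0L, d), 2) - center[2]) / semi[2]
    Z <- (slice.index(array(0L, d), 3) - center[3]) / semi[3]
    X^2 + Y^2 + Z^2 <= 1
}

# undeformed tissue labels: 0 bg, 1 skull, 2 csf (incl. ventricles),
# 3 gm, 4 wm
.phantomLabels <- function(spec) {
    d <- spec@dim
    ctr <- (d + 1) / 2
    ax <- spec@semiAxes
    lab <- array(0L, dim = d)
    lab[.insideEllipsoid(d, ctr, ax$skull)] <- 1L
    lab[.insideEllipsoid(d, ctr, ax$ic)] <- 2L
    lab[.insideEllipsoid(d, ctr, ax$gm)] <- 3L
    lab[.insideEllipsoid(d, ctr, ax$wm)] <- 4L
    voff <- d / 64 * c(5, 0, 2)             # ventricle offsets, grid-scaled
    for (off in list(-voff * c(1, -1, -1), voff))
        lab[.insideEllipsoid(d, ctr + off, ax$ventricle)] <- 2L
    lab
}

# smooth random displacement field: per axis the mean of 3 sinusoidal
# modes with seeded integer frequencies and phases, scaled by the
# amplitude so |disp| <= amplitude everywhere
.displacement <- function(d, amplitude) {
    base <- array(0, dim = d)
    X <- slice.index(base, 1) / d[1]
    Y <- slice.index(base, 2) / d[2]
    Z <- slice.index(base, 3) / d[3]
    lapply(1:3, function(a) {
        f <- base
        for (m in 1:3) {
            k <- sample(1:2, 3, replace = TRUE)
            phi <- stats::runif(1, 0, 2 * pi)
            f <- f + sin(2 * pi * (k[1] * X + k[2] * Y + k[3] * Z) + phi)
        }
        amplitude * f / 3
    })
}

.trilinear <- function(a, X, Y, Z) {
    d <- dim(a)
    X <- pmin(pmax(X, 1), d[1])
    Y <- pmin(pmax(Y, 1), d[2])
    Z <- pmin(pmax(Z, 1), d[3])
    x0 <- floor(X); y0 <- floor(Y); z0 <- floor(Z)
    fx <- X - x0; fy <- Y - y0; fz <- Z - z0
    x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
    at <- function(x, y, z) a[x + d[1] * (y - 1 + d[2] * (z - 1))]
    (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
                fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
        fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
              fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

.nearest <- function(a, X, Y, Z) {
    d <- dim(a)
    x <- pmin(pmax(round(X), 1), d[1])
    y <- pmin(pmax(round(Y), 1), d[2])
    z <- pmin(pmax(round(Z), 1), d[3])
    a[x + d[1] * (y - 1 + d[2] * (z - 1))]
}

#' Generate one synthetic head phantom
#'
#' Builds the nested-ellipsoid tissue labels, applies a smooth seeded
#' random deformation identically to labels (nearest-neighbour sampling)
#' and intensities (trilinear sampling of the tissue-mean image, which
#' introduces a thin partial-volume-like blend at interfaces), and adds
#' seeded Gaussian noise. The intracranial mask is the union of all CSF,
#' GM, WM and ventricle voxels — all intracranial tissue including
#' external CSF — excluding skull and background.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with `intensity` ([IntensityVolume-class]), `mask`
#'   ([BinaryMask-class], the ground-truth intracranial cavity) and
#'   `labels` (3D integer array: 0 background, 1 skull, 2 CSF, 3 GM,
#'   4 WM).
#' @export
makePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    d <- spec@dim
    lab0 <- .phantomLabels(spec)
    meanOf <- spec@means[c("background", "skull", "csf", "gm", "wm")]
    int0 <- array(meanOf[lab0 + 1L], dim = d)
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec@seed)
    if (spec@deformAmplitude > 0) {
        disp <- .displacement(d, spec@deformAmplitude)
        base <- array(0L, d)
        X <- slice.index(base, 1) + disp[[1]]
        Y <- slice.index(base, 2) + disp[[2]]
        Z <- slice.index(base, 3) + disp[[3]]
        lab <- array(.nearest(lab0, X, Y, Z), dim = d)
        int <- array(.trilinear(int0, X, Y, Z), dim = d)
    } else {
        lab <- lab0
        int <- int0
    }
    if (spec@noiseSd > 0)
        int <- int + array(stats::rnorm(prod(d), 0, spec@noiseSd), dim = d)
    int <- pmax(int, 0)
    list(intensity = IntensityVolume(int, spec@voxelSize),
         mask = BinaryMask(array(as.integer(lab >= 2L), dim = d),
                           spec@voxelSize),
         labels = lab)
}

#' Generate a perturbed phantom template library
#'
#' `n` phantoms from one base specification, each with an independently
#' seeded shape deformation, an independent noise realisation, and a small
#' per-tissue jitter of the class means emulating residual normalization
#' error across library subjects.
#'
#' @param base a [PhantomSpec-class]; its `seed` anchors all per-template
#'   seeds.
#' @param n number of templates.
#' @param deformAmplitude shape variability (voxels); defaults to the
#'   base's.
#' @param intensityJitterSd sd of the per-template tissue-mean jitter
#'   (intensity units).
#' @return a validated [TemplateLibrary-class] whose masks are the exact
#'   ground-truth intracranial masks.
#' @export
makeLibrary <- function(base, n, deformAmplitude = base@deformAmplitude,
                        intensityJitterSd = 2) {
    stopifnot(is(base, "PhantomSpec"))
    n <- as.integer(n)
    if (n < 1L) stop(inputError("n must be >= 1"))
    ints <- vector("list", n)
    msks <- vector("list", n)
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    seedBase <- (base@seed %% 1000003L) * 1000L   # keep derived seeds < 2^31
    for (i in seq_len(n)) {
        set.seed(seedBase + i)
        jit <- if (intensityJitterSd > 0)
            stats::rnorm(5, 0, intensityJitterSd) else numeric(5)
        means <- base@means
        means[c("background", "skull", "csf", "gm", "wm")] <-
            means[c("background", "skull", "csf", "gm", "wm")] + jit
        spec <- phantomSpec(dim = base@dim, voxelSize = base@voxelSize,
            semiAxes = base@semiAxes, means = means,
            noiseSd = base@noiseSd, deformAmplitude = deformAmplitude,
            seed = seedBase + i)
        ph <- makePhantom(spec)
        ints[[i]] <- ph$intensity
        msks[[i]] <- ph$mask
    }
    TemplateLibrary(ints, msks, tags = sprintf("phantom_%03d", seq_len(n)))
}
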