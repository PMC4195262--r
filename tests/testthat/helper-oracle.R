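# Brute-force reference implementations, independent of the package's
# compiled kernels: plain R triple loops over voxels, templates and search
# offsets. Used to pin down the fusion arithmetic on small volumes.

# patch values of the box clamped to the grid, x-fastest order
oracle_patch <- function(a, cx, cy, cz, r) {
    d <- dim(a)
    lo <- pmax(c(cx, cy, cz) - r, 1L)
    hi <- pmin(c(cx, cy, cz) + r, d)
    as.numeric(a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
}

oracle_ss <- function(p, q) {
    term <- function(a, b) {
        if (a == 0 && b == 0) return(1)
        if (a == 0 || b == 0) return(0)
        2 * a * b / (a^2 + b^2)
    }
    mp <- mean(p); mq <- mean(q)
    sp <- sqrt(sum((p - mp)^2) / length(p))
    sq <- sqrt(sum((q - mq)^2) / length(q))
    term(mp, mq) * term(sp, sq)
}

# voxelwise nonlocal fusion with bilateral (or classical) weights and the
# per-voxel adaptive bandwidth; returns the vote array (NA outside roi)
oracle_voxelwise <- function(subject, tmplInts, tmplMasks, roi,
                             patchRadius = 1L, searchRadius = 2L,
                             lambdaH = 0.1, epsilonH = 1e-6, sigmaD = 8,
                             ssThreshold = 0.97, voxelSize = c(1, 1, 1),
                             classical = FALSE) {
    d <- dim(subject)
    votes <- array(NA_real_, dim = d)
    r <- patchRadius
    for (tz in 1:d[3]) for (ty in 1:d[2]) for (tx in 1:d[1]) {
        if (roi[tx, ty, tz] != 1L) next
        # offset box the target patch uses
        lo <- pmax(c(tx, ty, tz) - r, 1L) - c(tx, ty, tz)
        hi <- pmin(c(tx, ty, tz) + r, d) - c(tx, ty, tz)
        tp <- oracle_patch(subject, tx, ty, tz, r)
        cand <- list()
        for (s in seq_along(tmplInts)) {
            for (cz in (tz - searchRadius):(tz + searchRadius)) {
                if (cz + lo[3] < 1L || cz + hi[3] > d[3]) next
                for (cy in (ty - searchRadius):(ty + searchRadius)) {
                    if (cy + lo[2] < 1L || cy + hi[2] > d[2]) next
                    for (cx in (tx - searchRadius):(tx + searchRadius)) {
                        if (cx + lo[1] < 1L || cx + hi[1] > d[1]) next
                        qp <- as.numeric(tmplInts[[s]][
                            (cx + lo[1]):(cx + hi[1]),
                            (cy + lo[2]):(cy + hi[2]),
                            (cz + lo[3]):(cz + hi[3])])
                        cand[[length(cand) + 1L]] <- list(
                            d2 = sum((tp - qp)^2) / length(tp),
                            ss = oracle_ss(tp, qp),
                            lab = tmplMasks[[s]][cx, cy, cz],
                            dist = sqrt(sum((((c(cx, cy, cz) -
                                c(tx, ty, tz)) * voxelSize)^2))))
                    }
                }
            }
        }
        h <- lambdaH * min(vapply(cand, `[[`, 0, "d2")) + epsilonH
        num <- 0; den <- 0
        for (c in cand) {
            w <- if (c$ss < ssThreshold) 0
                 else if (classical) exp(-c$d2 / h^2)
                 else exp(-(c$dist / sigmaD + c$d2 / h))
            num <- num + w * c$lab
            den <- den + w
        }
        votes[tx, ty, tz] <- if (den > 0) num / den else {
            labs <- vapply(cand, `[[`, 0, "lab")
            if (sum(labs > 0.5) > sum(labs <= 0.5)) 1 else 0
        }
    }
    votes
}

# small random fusion instance shared by several tests
random_fusion_instance <- function(seed, d = 12L, ntmpl = 3L) {
    set.seed(seed)
    subject <- array(stats::runif(d^3, 0, 300), dim = rep(d, 3L))
    tmplInts <- lapply(seq_len(ntmpl), function(s)
        subject + array(stats::rnorm(d^3, 0, 20), dim = rep(d, 3L)))
    tmplMasks <- lapply(seq_len(ntmpl), function(s) {
        m <- array(0L, dim = rep(d, 3L))
        m[3:(d - 3), 3:(d - 3), 3:(d - 3)] <- 1L
        # roughen the boundary so candidate labels disagree
        flip <- which(array(stats::runif(d^3), dim = rep(d, 3L)) < 0.1)
        m[flip] <- 1L - m[flip]
        if (sum(m) == 0L) m[5, 5, 5] <- 1L
        m
    })
    roi <- array(0L, dim = rep(d, 3L))
    roi[4:(d - 4), 4:(d - 4), 4:(d - 4)] <- 1L
    list(subject = subject, tmplInts = tmplInts, tmplMasks = tmplMasks,
         roi = roi)
}

as_library <- function(inst, voxelSize = c(1, 1, 1)) {
    TemplateLibrary(lapply(inst$tmplInts, IntensityVolume,
                           voxelSize = voxelSize),
                    lapply(inst$tmplMasks, BinaryMask,
                           voxelSize = voxelSize))
}
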