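# small in-code fixtures shared across test files

# a tiny consistent library of n constant-ish volumes with cube masks
tiny_library <- function(n = 3L, d = 8L, seed = 1L) {
    set.seed(seed)
    ints <- lapply(seq_len(n), function(i)
        IntensityVolume(array(stats::runif(d^3, 0, 300), dim = rep(d, 3L))))
    msks <- lapply(seq_len(n), function(i) {
        m <- array(0L, dim = rep(d, 3L))
        m[3:(d - 2), 3:(d - 2), 3:(d - 2)] <- 1L
        BinaryMask(m)
    })
    TemplateLibrary(ints, msks)
}

# three-class volume: equal-size blocks at the given class intensities
three_class_volume <- function(levels = c(30, 90, 160), perClass = 1000L,
                               noiseSd = 0, seed = 1L) {
    set.seed(seed)
    n <- 3L * perClass
    d <- c(n, 1L, 1L)
    lab <- rep(1:3, each = perClass)
    x <- levels[lab]
    if (noiseSd > 0) x <- x + stats::rnorm(n, 0, noiseSd)
    list(volume = IntensityVolume(array(x, dim = d)),
         roi = BinaryMask(array(1L, dim = d)),
         labels = lab, values = x)
}

# synthetic patch with prescribed summary statistics (for weight formulas)
stat_patch <- function(mu, sigma, center = c(1L, 1L, 1L)) {
    list(values = NULL, center = as.integer(center), mu = mu, sigma = sigma)
}
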