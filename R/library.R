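#' Validate a template library
#'
#' Checks the library invariants: non-empty, every (intensity, mask) pair on
#' the common grid with a common voxel size, every mask strictly binary and
#' containing at least one foreground voxel. Errors name the offending
#' template index.
#'
#' @param library a [TemplateLibrary-class].
#' @return the library, unchanged, if all invariants hold.
#' @export
validateLibrary <- function(library) {
    if (!is(library, "TemplateLibrary"))
        stop("not a TemplateLibrary")
    n <- length(library@intensities)
    if (n == 0L)
        stop(inputError("template library is empty"))
    grid <- dim(library@intensities[[1]]@data)
    vs <- library@intensities[[1]]@voxelSize
    for (i in seq_len(n)) {
        vol <- library@intensities[[i]]
        msk <- library@masks[[i]]
        if (!identical(dim(vol@data), grid) || !identical(dim(msk@data), grid))
            stop(inputError(sprintf(
                "template %d: grid shape mismatch (library grid %s)",
                i, paste(grid, collapse = "x"))))
        if (max(abs(vol@voxelSize - vs)) > 1e-9 ||
            max(abs(msk@voxelSize - vs)) > 1e-9)
            stop(inputError(sprintf("template %d: voxel size mismatch", i)))
        if (!all(msk@data == 0L | msk@data == 1L))
            stop(inputError(sprintf(
                "template %d: mask has values other than 0/1", i)))
        if (sum(msk@data) == 0L)
            stop(inputError(sprintf("template %d: mask is empty", i)))
    }
    library
}

#' Double a library by midsagittal flipping
#'
#' Mirrors every template (intensity and mask together) along the left-right
#' axis of the common grid, exploiting the approximate symmetry of the human
#' head, and appends the mirrored pairs after the originals. A library of 49
#' subjects becomes 98 labeled templates.
#'
#' @param library a validated [TemplateLibrary-class].
#' @param axis axis index of the left-right direction (1, 2 or 3; default 1,
#'   the x axis of an RAS-ordered grid).
#' @return a [TemplateLibrary-class] of exactly twice the size.
#' @export
flipAugment <- function(library, axis = 1L) {
    library <- validateLibrary(library)
    axis <- as.integer(axis)
    if (!axis %in% 1:3)
        stop(inputError("axis must be 1, 2 or 3"))
    flipArr <- function(a) {
        idx <- rep(list(quote(expr = )), 3)
        idx[[axis]] <- rev(seq_len(dim(a)[axis]))
        do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    ints <- library@intensities
    msks <- library@masks
    for (i in seq_along(library@intensities)) {
        v <- library@intensities[[i]]
        m <- library@masks[[i]]
        ints[[length(ints) + 1L]] <- IntensityVolume(flipArr(v@data),
            v@voxelSize, v@header)
        msks[[length(msks) + 1L]] <- BinaryMask(flipArr(m@data),
            m@voxelSize, m@header)
    }
    new("TemplateLibrary", intensities = ints, masks = msks,
        tags = c(library@tags, paste0(library@tags, "_flip")))
}

#' Union and majority masks of a library
#'
#' `unionMask()` marks voxels labeled intracranial in at least one template;
#' `majorityMask()` those labeled in more than half of the templates. The
#' majority mask is the package's stand-in for a standard-space brain mask
#' when estimating tissue means; the union mask bounds the region fusion
#' ever needs to visit.
#'
#' @param library a validated [TemplateLibrary-class].
#' @return a [BinaryMask-class] on the library grid.
#' @export
unionMask <- function(library) {
    library <- validateLibrary(library)
    acc <- Reduce(`+`, lapply(library@masks, function(m) m@data))
    BinaryMask(array(as.integer(acc > 0L), dim = dim(acc)),
               library@masks[[1]]@voxelSize)
}

#' @rdname unionMask
#' @export
majorityMask <- function(library) {
    library <- validateLibrary(library)
    acc <- Reduce(`+`, lapply(library@masks, function(m) m@data))
    BinaryMask(array(as.integer(acc > length(library) / 2), dim = dim(acc)),
               library@masks[[1]]@voxelSize)
}

# condition helper: user-input errors get a dedicated class so the CLI can
# map them to exit code 2
inputError <- function(msg) {
    structure(class = c("nicesegInputError", "error", "condition"),
              list(message = msg, call = sys.call(-1)))
}
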