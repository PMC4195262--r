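#' Read a 3D volume or mask from a NIfTI-1 file
#'
#' Volumes are read with their header (preserved verbatim on write) and
#' voxel sizes taken from `pixdim`. The tool operates on pre-registered
#' inputs: orientation metadata is never used to resample, and grid-shape
#' mismatches downstream are errors rather than silent interpolation.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return `readVolume()`: an [IntensityVolume-class]; `readMask()`: a
#'   [BinaryMask-class] (values are binarised by `> 0.5` to absorb datatype
#'   scaling, then validated).
#' @export
readVolume <- function(path) {
    if (!file.exists(path))
        stop(inputError(paste("file not found:", path)))
    img <- RNifti::readNifti(path, internal = FALSE)
    d <- dim(img)
    if (length(d) != 3L)
        stop(inputError(sprintf("%s: expected a 3D image, got %dD",
                                path, length(d))))
    data <- array(as.numeric(img), dim = d)
    if (!all(is.finite(data)))
        stop(inputError(paste(path, "contains non-finite values")))
    IntensityVolume(data, voxelSize = RNifti::pixdim(img),
                    header = RNifti::niftiHeader(img))
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
    vol <- readVolume(path)
    BinaryMask(array(as.integer(vol@data > 0.5), dim = dim(vol@data)),
               vol@voxelSize, vol@header)
}

.niftiReference <- function(obj) {
    if (!is.null(obj@header)) return(obj@header)
    list(pixdim = c(-1, obj@voxelSize, 0, 0, 0, 0))
}

#' Write volumes and masks as NIfTI-1 files
#'
#' Intensities are written as 32-bit float, masks as unsigned 8-bit so that
#' labels round-trip exactly. `writeMask()` takes the geometry (voxel size
#' and any preserved header) from a reference volume and requires the mask
#' to be aligned with it.
#'
#' @param volume an [IntensityVolume-class].
#' @param mask a [BinaryMask-class].
#' @param reference an [IntensityVolume-class] (or [BinaryMask-class])
#'   supplying the output geometry; defaults to the mask itself.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "IntensityVolume"))
    img <- RNifti::asNifti(volume@data, reference = .niftiReference(volume))
    RNifti::writeNifti(img, path, datatype = "float")
    invisible(path)
}

#' @rdname writeVolume
#' @export
writeMask <- function(mask, path, reference = mask) {
    stopifnot(is(mask, "BinaryMask"))
    if (!identical(dim(mask@data), dim(reference@data)))
        stop(inputError("mask and reference shapes differ"))
    img <- RNifti::asNifti(mask@data, reference = .niftiReference(reference))
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}

#' Load a template library from a manifest
#'
#' A manifest is a CSV file with columns `intensity`, `mask` and optionally
#' `tag` (or a JSON array of objects with those keys). Relative paths are
#' resolved against the manifest's directory. The loaded library is
#' validated; errors name the offending entry's tag.
#'
#' @param path manifest file (`.csv` or `.json`).
#' @return a validated [TemplateLibrary-class] in manifest order.
#' @export
loadLibrary <- function(path) {
    if (!file.exists(path))
        stop(inputError(paste("library manifest not found:", path)))
    entries <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else utils::read.csv(path, stringsAsFactors = FALSE)
    if (NROW(entries) == 0L)
        stop(inputError(paste("manifest lists no templates:", path)))
    if (!all(c("intensity", "mask") %in% names(entries)))
        stop(inputError("manifest needs 'intensity' and 'mask' columns"))
    if (is.null(entries$tag))
        entries$tag <- paste0("template_", seq_len(NROW(entries)))
    base <- dirname(normalizePath(path))
    resolve <- function(p)
        ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    ints <- vector("list", NROW(entries))
    msks <- vector("list", NROW(entries))
    for (i in seq_len(NROW(entries))) {
        fi <- resolve(entries$intensity[i])
        fm <- resolve(entries$mask[i])
        for (f in c(fi, fm))
            if (!file.exists(f))
                stop(inputError(sprintf("entry '%s': file not found: %s",
                                        entries$tag[i], f)))
        ints[[i]] <- readVolume(fi)
        msks[[i]] <- readMask(fm)
    }
    validateLibrary(new("TemplateLibrary", intensities = ints, masks = msks,
                        tags = as.character(entries$tag)))
}

#' Write a template library and its manifest to a directory
#'
#' @param library a validated [TemplateLibrary-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return the manifest path, invisibly.
#' @export
saveLibrary <- function(library, dir, prefix = "template") {
    library <- validateLibrary(library)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    n <- length(library)
    intensity <- sprintf("%s_%03d.nii.gz", prefix, seq_len(n))
    mask <- sprintf("%s_%03d_mask.nii.gz", prefix, seq_len(n))
    for (i in seq_len(n)) {
        writeVolume(library@intensities[[i]], file.path(dir, intensity[i]))
        writeMask(library@masks[[i]], file.path(dir, mask[i]),
                  reference = library@intensities[[i]])
    }
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(
        data.frame(intensity = intensity, mask = mask, tag = library@tags,
                   stringsAsFactors = FALSE),
        manifest, row.names = FALSE)
    invisible(manifest)
}
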