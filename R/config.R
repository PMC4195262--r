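#' Build a fusion configuration
#'
#' Returns a [FusionConfig-class] populated with the method defaults:
#' 30 preselected templates, structural-similarity gate 0.97, adaptive
#' bandwidth scale 0.1 with stabiliser 1e-6, spatial decay 8 mm, 3^3 label
#' blocks on a 2-voxel block grid, vote threshold 0.5, and a three-level
#' pyramid (4, 2, 1 mm) with patch radii 1 and search radii 4/3/2 coarse to
#' fine and a 2-voxel refinement band.
#'
#' @param patchRadius,searchRadius per-level radii (recycled to the number
#'   of pyramid levels).
#' @param nTemplates number of templates used for fusion.
#' @param ssThreshold structural-similarity preselection threshold.
#' @param lambdaH,epsilonH adaptive bandwidth scale and stabiliser.
#' @param sigmaD spatial decay constant in mm.
#' @param blockRadius,blockSpacing label block half-width and centre spacing.
#' @param voteThreshold label decision threshold.
#' @param pyramidScales downsampling factors, coarse to fine, ending at 1.
#' @param boundaryBand refinement band half-width in voxels.
#' @param weightMode `"bilateral"` or `"classical"`.
#' @param seed integer seed recorded in provenance.
#' @return a validated [FusionConfig-class].
#' @export
fusionConfig <- function(patchRadius = c(1L, 1L, 1L),
                         searchRadius = c(4L, 3L, 2L),
                         nTemplates = 30L, ssThreshold = 0.97,
                         lambdaH = 0.1, epsilonH = 1e-6, sigmaD = 8,
                         blockRadius = 1L, blockSpacing = 2L,
                         voteThreshold = 0.5, pyramidScales = c(4L, 2L, 1L),
                         boundaryBand = 2L, weightMode = "bilateral",
                         seed = 1L) {
    nl <- length(pyramidScales)
    cfg <- new("FusionConfig",
        patchRadius = as.integer(rep_len(patchRadius, nl)),
        searchRadius = as.integer(rep_len(searchRadius, nl)),
        nTemplates = as.integer(nTemplates),
        ssThreshold = as.numeric(ssThreshold),
        lambdaH = as.numeric(lambdaH), epsilonH = as.numeric(epsilonH),
        sigmaD = as.numeric(sigmaD),
        blockRadius = as.integer(blockRadius),
        blockSpacing = as.integer(blockSpacing),
        voteThreshold = as.numeric(voteThreshold),
        pyramidScales = as.integer(pyramidScales),
        boundaryBand = as.integer(boundaryBand),
        weightMode = as.character(weightMode), seed = as.integer(seed))
    validObject(cfg)
    cfg
}

# field names used in config files (snake_case on disk, slots in memory)
.configFields <- c(
    patch_radius = "patchRadius", search_radius = "searchRadius",
    n_templates = "nTemplates", ss_threshold = "ssThreshold",
    lambda_h = "lambdaH", epsilon_h = "epsilonH", sigma_d_mm = "sigmaD",
    block_radius = "blockRadius", block_spacing = "blockSpacing",
    vote_threshold = "voteThreshold", pyramid_scales = "pyramidScales",
    boundary_band = "boundaryBand", weight_mode = "weightMode",
    seed = "seed")

#' Read and write configuration files
#'
#' Configurations are stored as YAML (or JSON) with one key per parameter
#' (`patch_radius`, `search_radius`, `n_templates`, `ss_threshold`,
#' `lambda_h`, `epsilon_h`, `sigma_d_mm`, `block_radius`, `block_spacing`,
#' `vote_threshold`, `pyramid_scales`, `boundary_band`, `weight_mode`,
#' `seed`). Keys absent from the file take the package defaults, so a config
#' file only needs to list what it changes.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return `readFusionConfig()`: a [FusionConfig-class];
#'   `writeFusionConfig()`: the path, invisibly.
#' @export
readFusionConfig <- function(path) {
    if (!file.exists(path))
        stop(inputError(paste("config file not found:", path)))
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(.configFields))
    if (length(unknown))
        stop(inputError(paste("unknown config keys:",
                              paste(unknown, collapse = ", "))))
    args <- stats::setNames(vals, .configFields[names(vals)])
    do.call(fusionConfig, args)
}

#' @param config a [FusionConfig-class].
#' @rdname readFusionConfig
#' @export
writeFusionConfig <- function(config, path) {
    stopifnot(is(config, "FusionConfig"))
    vals <- lapply(.configFields, function(s) slot(config, s))
    if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
    else yaml::write_yaml(vals, path)
    invisible(path)
}

# plain-list snapshot for provenance/manifests
configSnapshot <- function(config) {
    lapply(stats::setNames(.configFields, names(.configFields)),
           function(s) slot(config, s))
}
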