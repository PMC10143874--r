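## JSON configuration blocks, NIfTI/CSV interchange, run manifests.
##
## Image orientation convention: arrays are row-major (y, x) with y
## increasing downward; NIfTI files store (x, y, metabolite, time). The
## convention is recorded in every sidecar.

.jsonRead <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.need <- function(cfg, keys, what) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop(sprintf("%s is missing required key(s): %s", what,
                 paste(missing, collapse = ", ")))
}

#' Read and write kinetic parameter / input-function configs
#'
#' The JSON block carries keys `kpl`, `t1_pyr`, `t1_lac`, `input_fwhm`,
#' `arrival_time`, `amplitude`, `gamma_shape`.
#'
#' @param path JSON file path.
#' @return `readKineticsConfig`: a list with `params` ([PKParams-class]) and
#'   `input` ([InputFunction-class]).
#' @export
readKineticsConfig <- function(path) {
  cfg <- .jsonRead(path)
  .need(cfg, c("kpl", "t1_pyr", "t1_lac"), paste0("kinetics config ", path))
  params <- pkParams(kpl = cfg$kpl, t1Pyr = cfg$t1_pyr, t1Lac = cfg$t1_lac)
  input <- inputFunction(
    fwhm = cfg$input_fwhm %||% 8,
    arrivalTime = cfg$arrival_time %||% 0,
    amplitude = cfg$amplitude %||% 1,
    gammaShape = cfg$gamma_shape %||% 4)
  list(params = params, input = input)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readKineticsConfig
#' @param params a [PKParams-class] object.
#' @param input an [InputFunction-class] object.
#' @export
writeKineticsConfig <- function(path, params, input) {
  jsonlite::write_json(list(
    kpl = params@kpl, t1_pyr = params@t1Pyr, t1_lac = params@t1Lac,
    input_fwhm = input@fwhm, arrival_time = input@arrivalTime,
    amplitude = input@amplitude, gamma_shape = input@gammaShape),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write acquisition protocol configs
#'
#' JSON keys mirror the [AcquisitionProtocol-class] fields: `encoding`,
#' `metabolites`, `flips` (named object, degrees), `intra_tr`,
#' `temporal_resolution`, `n_timepoints`, `matrix`, `fov` (mm), `ordering`,
#' `csi_tr` (all times in seconds).
#'
#' @param path JSON file path.
#' @return an [AcquisitionProtocol-class] object.
#' @export
readProtocolConfig <- function(path) {
  cfg <- .jsonRead(path)
  .need(cfg, c("encoding", "flips", "temporal_resolution", "n_timepoints",
               "matrix", "fov"), paste0("protocol config ", path))
  acquisitionProtocol(
    encoding = cfg$encoding,
    metabolites = cfg$metabolites %||% c("pyruvate", "lactate"),
    flips = unlist(cfg$flips),
    intraTR = cfg$intra_tr %||% 0.13,
    temporalResolution = cfg$temporal_resolution,
    nTimepoints = cfg$n_timepoints,
    matrixSize = cfg$matrix,
    fov = cfg$fov,
    ordering = cfg$ordering %||% "centric",
    csiTR = cfg$csi_tr)
}

#' @rdname readProtocolConfig
#' @param protocol an [AcquisitionProtocol-class] object.
#' @export
writeProtocolConfig <- function(path, protocol) {
  jsonlite::write_json(list(
    encoding = protocol@encoding, metabolites = protocol@metabolites,
    flips = as.list(protocol@flips), intra_tr = protocol@intraTR,
    temporal_resolution = protocol@temporalResolution,
    n_timepoints = protocol@nTimepoints, matrix = protocol@matrixSize,
    fov = protocol@fov, ordering = protocol@ordering,
    csi_tr = protocol@csiTR),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write phantom configs
#'
#' Region geometry is described parametrically: `strip` regions carry `x`
#' and `y` mm ranges, `disc` regions a `center` and `radius` in mm. The
#' background region (everything else) is implicit.
#'
#' @param path JSON file path.
#' @return a [PhantomDef-class] object.
#' @export
readPhantomConfig <- function(path) {
  cfg <- .jsonRead(path)
  .need(cfg, c("grid", "pitch_mm", "regions", "perfusion", "params"),
        paste0("phantom config ", path))
  n <- as.integer(cfg$grid); pitch <- cfg$pitch_mm
  xc <- (seq_len(n[2]) - 0.5) * pitch
  yc <- (seq_len(n[1]) - 0.5) * pitch
  X <- matrix(xc, n[1], n[2], byrow = TRUE)
  Y <- matrix(yc, n[1], n[2])
  masks <- lapply(cfg$regions, function(g) {
    switch(g$type,
      strip = X > g$x[1] & X <= g$x[2] & Y > g$y[1] & Y <= g$y[2],
      disc = (X - g$center[1])^2 + (Y - g$center[2])^2 <= g$radius^2,
      stop("unknown region type '", g$type, "'"))
  })
  masks$background <- !Reduce(`|`, masks)
  pk <- lapply(cfg$params, function(p)
    pkParams(kpl = p$kpl, t1Pyr = p$t1_pyr %||% 20, t1Lac = p$t1_lac %||% 30))
  if (is.null(pk$background)) pk$background <- pkParams(kpl = 0)
  perf <- unlist(cfg$perfusion)
  if (!"background" %in% names(perf)) perf <- c(perf, background = 0)
  phantomDef(gridSize = n, pitchMM = pitch, regions = masks,
             perfusion = perf, params = pk,
             noiseSD = cfg$noise_sd %||% 0.002, seed = cfg$seed %||% 1)
}

#' Write a dynamic image series as NIfTI + JSON sidecar
#'
#' Writes `<prefix>.nii.gz` with the data permuted to (x, y, metabolite,
#' time), `<prefix>_noisemask.nii.gz`, and `<prefix>.json` with `times`,
#' `flips`, `metabolites`, `voxel_mm`, `seed` and the orientation note.
#'
#' @param series a [DynamicImageSeries-class] object.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
writeSeries <- function(series, prefix) {
  stopifnot(is(series, "DynamicImageSeries"))
  arr <- aperm(series@data, c(4, 3, 1, 2))  # met,t,y,x -> x,y,met,t
  RNifti::writeNifti(arr, paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(t(series@noiseMask) * 1,
                     paste0(prefix, "_noisemask.nii.gz"))
  jsonlite::write_json(list(
    times = series@times, flips = as.list(series@flips),
    metabolites = series@metabolites, voxel_mm = series@voxelMM,
    seed = series@seed,
    orientation = "row-major (y, x), y increasing downward"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeSeries
#' @param prefix path prefix written by [writeSeries()].
#' @return `readSeries`: the reconstructed [DynamicImageSeries-class].
#' @export
readSeries <- function(prefix) {
  niiPath <- paste0(prefix, ".nii.gz")
  scPath <- paste0(prefix, ".json")
  if (!file.exists(niiPath)) stop("series image not found: ", niiPath)
  if (!file.exists(scPath)) stop("sidecar not found: ", scPath)
  sc <- .jsonRead(scPath)
  .need(sc, c("times", "flips", "metabolites", "voxel_mm"),
        paste0("sidecar ", scPath))
  arr <- as.array(RNifti::readNifti(niiPath))
  if (length(dim(arr)) != 4)
    stop("series image must be 4-D (x, y, metabolite, time), got ",
         length(dim(arr)), "-D")
  dat <- aperm(arr, c(3, 4, 2, 1))  # x,y,met,t -> met,t,y,x
  if (dim(dat)[1] != length(sc$metabolites) ||
      dim(dat)[2] != length(sc$times))
    stop("sidecar 'metabolites'/'times' lengths do not match the image dims")
  maskPath <- paste0(prefix, "_noisemask.nii.gz")
  mask <- if (file.exists(maskPath))
    t(as.array(RNifti::readNifti(maskPath))) > 0.5
  else matrix(FALSE, dim(dat)[3], dim(dat)[4])
  new("DynamicImageSeries", data = dat, metabolites = sc$metabolites,
      times = sc$times, flips = unlist(sc$flips), noiseMask = mask,
      voxelMM = sc$voxel_mm, seed = sc$seed %||% NA_real_)
}

#' Export a k-space weight map as CSV
#'
#' @param weights a [KSpaceWeights-class] object.
#' @param path output CSV path; columns are `ky`, `kx` (integer offsets)
#'   and `weight_au`.
#' @export
writeWeightsCSV <- function(weights, path) {
  w <- weights@weights
  enc <- orderPhaseEncodes(dim(w), "linear")
  utils::write.csv(data.frame(ky = enc$ky, kx = enc$kx,
                              weight_au = w[cbind(enc$row, enc$col)]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the package version, the command, the seed and the full parsed
#' input configurations, so an artifact directory is regenerable from its
#' manifest alone.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param seed RNG seed used.
#' @param inputs named list of parsed configuration objects.
#' @export
writeManifest <- function(dir, command, seed, inputs = list()) {
  jsonlite::write_json(list(
    package = "hpMRsim",
    version = as.character(utils::packageVersion("hpMRsim")),
    command = command, seed = seed, inputs = inputs,
    orientation = "row-major (y, x), y increasing downward"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
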