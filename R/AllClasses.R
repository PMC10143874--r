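#' @import methods
NULL

#' Pharmacokinetic parameters of the two-pool exchange model
#'
#' Holds the apparent pyruvate-to-lactate conversion rate \code{kpl} (1/s)
#' and the longitudinal relaxation times of the two chemical pools. The
#' derived relaxation rates are \code{R1P = 1/t1Pyr} and \code{R1L = 1/t1Lac}.
#'
#' @slot kpl apparent conversion rate constant k_PL (1/s), non-negative.
#' @slot t1Pyr pyruvate longitudinal relaxation time T1 (s), positive.
#' @slot t1Lac lactate longitudinal relaxation time T1 (s), positive.
#' @seealso [pkParams()]
#' @export
setClass("PKParams",
  representation(kpl = "numeric", t1Pyr = "numeric", t1Lac = "numeric"),
  prototype(kpl = 0.05, t1Pyr = 20, t1Lac = 30))

setValidity("PKParams", function(object) {
  msg <- character()
  if (length(object@kpl) != 1 || !is.finite(object@kpl) || object@kpl < 0)
    msg <- c(msg, "'kpl' must be a single finite value >= 0")
  if (length(object@t1Pyr) != 1 || is.na(object@t1Pyr) || object@t1Pyr <= 0)
    msg <- c(msg, "'t1Pyr' must be a single value > 0 (Inf allowed)")
  if (length(object@t1Lac) != 1 || is.na(object@t1Lac) || object@t1Lac <= 0)
    msg <- c(msg, "'t1Lac' must be a single value > 0 (Inf allowed)")
  if (length(msg)) msg else TRUE
})

#' Gamma-variate bolus input function
#'
#' Describes the arrival of fresh hyperpolarized pyruvate magnetization as a
#' gamma-distribution-shaped bolus. Only the full width at half maximum is
#' physiologically constrained; the gamma shape parameter controls the
#' rise/decay asymmetry and is exposed as a knob.
#'
#' @slot fwhm full width at half maximum of the bolus (s).
#' @slot arrivalTime bolus onset relative to the start of acquisition (s).
#' @slot amplitude total delivered longitudinal magnetization (arbitrary
#'   units); the sampled input integrates to this value.
#' @slot gammaShape shape parameter of the gamma density (> 1 so the mode is
#'   strictly after onset).
#' @seealso [inputFunction()], [sampleInput()]
#' @export
setClass("InputFunction",
  representation(fwhm = "numeric", arrivalTime = "numeric",
                 amplitude = "numeric", gammaShape = "numeric"),
  prototype(fwhm = 8, arrivalTime = 0, amplitude = 1, gammaShape = 4))

setValidity("InputFunction", function(object) {
  msg <- character()
  if (object@fwhm <= 0) msg <- c(msg, "'fwhm' must be > 0")
  if (object@amplitude < 0) msg <- c(msg, "'amplitude' must be >= 0")
  if (object@gammaShape <= 1) msg <- c(msg, "'gammaShape' must be > 1")
  if (!is.finite(object@arrivalTime)) msg <- c(msg, "'arrivalTime' must be finite")
  if (length(msg)) msg else TRUE
})

#' Dynamic acquisition protocol
#'
#' Describes one metabolite-specific EPI or CSI acquisition: per-metabolite
#' flip angles, timing, matrix/FOV geometry and, for CSI, the phase-encode
#' ordering and per-encode repetition time.
#'
#' @slot encoding `"epi_singleshot"` or `"csi"`.
#' @slot metabolites acquisition order of the excited chemical shifts, a
#'   subset of `c("urea", "pyruvate", "lactate")`.
#' @slot flips named numeric vector of flip angles in degrees, one entry per
#'   metabolite (for CSI a single shared `"all"` entry is used: the hard
#'   pulse is not metabolite-selective).
#' @slot intraTR spacing between successive metabolite excitations within one
#'   timepoint (s); the delay between the pyruvate and lactate pulses.
#' @slot temporalResolution spacing between dynamic timepoints (s).
#' @slot nTimepoints number of dynamic timepoints.
#' @slot matrixSize integer `(ny, nx)` acquisition matrix.
#' @slot fov field of view `(y, x)` in mm.
#' @slot ordering CSI phase-encode ordering, `"centric"` or `"linear"`.
#' @slot csiTR per-phase-encode repetition time (s, CSI only); defaults to
#'   `temporalResolution / (nx * ny)`.
#' @seealso [acquisitionProtocol()]
#' @export
setClass("AcquisitionProtocol",
  representation(encoding = "character", metabolites = "character",
                 flips = "numeric", intraTR = "numeric",
                 temporalResolution = "numeric", nTimepoints = "integer",
                 matrixSize = "integer", fov = "numeric",
                 ordering = "character", csiTR = "numeric"))

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  if (!object@encoding %in% c("epi_singleshot", "csi"))
    msg <- c(msg, "'encoding' must be \"epi_singleshot\" or \"csi\"")
  if (any(object@matrixSize < 2)) msg <- c(msg, "matrix dimensions must be >= 2")
  if (length(object@matrixSize) != 2) msg <- c(msg, "'matrixSize' must be (ny, nx)")
  if (length(object@fov) != 2 || any(object@fov <= 0))
    msg <- c(msg, "'fov' must be two positive lengths in mm")
  if (object@temporalResolution <= 0) msg <- c(msg, "'temporalResolution' must be > 0")
  if (object@nTimepoints < 1) msg <- c(msg, "'nTimepoints' must be >= 1")
  if (is.null(names(object@flips)) || any(!nzchar(names(object@flips))))
    msg <- c(msg, "'flips' must be a named vector (degrees)")
  if (object@encoding == "epi_singleshot") {
    needed <- setdiff(object@metabolites, names(object@flips))
    if (length(needed))
      msg <- c(msg, paste0("missing flip angle for: ", paste(needed, collapse = ", ")))
    nexc <- length(object@metabolites)
    if (object@intraTR * max(nexc - 1, 0) > object@temporalResolution)
      msg <- c(msg, "'temporalResolution' shorter than the intra-timepoint excitation train")
  }
  if (object@encoding == "csi") {
    if (!object@ordering %in% c("centric", "linear"))
      msg <- c(msg, "'ordering' must be \"centric\" or \"linear\"")
    if (object@csiTR <= 0) msg <- c(msg, "'csiTR' must be > 0")
    if (object@csiTR * prod(object@matrixSize) > object@temporalResolution + 1e-9)
      msg <- c(msg, "csiTR * (nx*ny) exceeds the temporal resolution")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated dynamic metabolite signal timecourse
#'
#' Post-excitation transverse signal magnitudes per timepoint, one series per
#' metabolite. Urea, when acquired, is an independent non-exchanging pool and
#' is excluded from all pharmacokinetic quantities.
#'
#' @slot times pyruvate excitation times of the timepoints (s).
#' @slot pyr pyruvate signal magnitude per timepoint.
#' @slot lac lactate signal magnitude per timepoint.
#' @slot urea urea signal magnitude per timepoint (length 0 when urea is not
#'   in the protocol).
#' @export
setClass("SignalTimecourse",
  representation(times = "numeric", pyr = "numeric", lac = "numeric",
                 urea = "numeric"),
  prototype(urea = numeric(0)))

setValidity("SignalTimecourse", function(object) {
  msg <- character()
  if (length(object@pyr) != length(object@times) ||
      length(object@lac) != length(object@times))
    msg <- c(msg, "'pyr' and 'lac' must have one value per timepoint")
  if (any(object@pyr < 0) || any(object@lac < 0))
    msg <- c(msg, "signal magnitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-metabolite k-space signal weighting
#'
#' Relative transverse signal magnitude at each k-space location of one
#' acquired frame. For single-shot EPI the weights are flat; for CSI the
#' hyperpolarized signal evolves across the phase-encode train and apodizes
#' k-space.
#'
#' @slot metabolite metabolite label.
#' @slot weights real non-negative matrix over (ky, kx); row/column 1
#'   corresponds to the most negative spatial frequency, the k-space centre
#'   sits at index `floor(n/2) + 1`.
#' @slot voxelMM nominal voxel size (mm) implied by FOV/matrix.
#' @export
setClass("KSpaceWeights",
  representation(metabolite = "character", weights = "matrix",
                 voxelMM = "numeric"))

setValidity("KSpaceWeights", function(object) {
  msg <- character()
  if (!all(is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "'weights' must be finite and non-negative magnitudes")
  if (object@voxelMM <= 0) msg <- c(msg, "'voxelMM' must be > 0")
  if (length(msg)) msg else TRUE
})

#' One-dimensional point-spread-function profile
#'
#' The y = 0 slice through a peak-normalized 2-D PSF, on a zero-centred
#' position grid whose pitch is the nominal voxel size divided by the
#' zero-fill factor.
#'
#' @slot positions positions (mm), zero at the PSF peak.
#' @slot magnitudes normalized magnitudes, max = 1.
#' @slot zeroFillFactor zero-filling factor used before the inverse DFT.
#' @export
setClass("PSFProfile",
  representation(positions = "numeric", magnitudes = "numeric",
                 zeroFillFactor = "integer"))

setValidity("PSFProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@magnitudes))
    msg <- c(msg, "'positions' and 'magnitudes' lengths differ")
  if (abs(max(object@magnitudes) - 1) > 1e-9)
    msg <- c(msg, "profile must be peak-normalized (max = 1)")
  if (length(msg)) msg else TRUE
})

#' PSF resolution metrics
#'
#' @slot fwhmMM full width at half maximum of the main lobe (mm).
#' @slot width10MM distance between the outermost crossings of 10% of the
#'   peak (mm); captures sidelobe extent, hence signal bleed.
#' @export
setClass("PSFMetrics",
  representation(fwhmMM = "numeric", width10MM = "numeric"))

setValidity("PSFMetrics", function(object) {
  if (object@width10MM < object@fwhmMM || object@fwhmMM <= 0)
    "must satisfy width10MM >= fwhmMM > 0" else TRUE
})

#' Dynamic 4-D metabolite image series
#'
#' Magnitude images indexed metabolite x time x y x x, with acquisition
#' times, flip angles and a noise-region mask (voxels outside the subject,
#' used for noise normalization).
#'
#' @slot data 4-D non-negative array `[metabolite, time, y, x]`.
#' @slot metabolites metabolite labels, one per first-dimension slice.
#' @slot times timepoint times (s).
#' @slot flips named per-metabolite flip angles (degrees).
#' @slot noiseMask logical `(y, x)` matrix marking the noise region.
#' @slot voxelMM voxel size (mm).
#' @slot seed RNG seed the series was generated with (NA if measured).
#' @export
setClass("DynamicImageSeries",
  representation(data = "array", metabolites = "character",
                 times = "numeric", flips = "numeric", noiseMask = "matrix",
                 voxelMM = "numeric", seed = "numeric"),
  prototype(seed = NA_real_))

setValidity("DynamicImageSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4)
    msg <- c(msg, "'data' must be a 4-D array [metabolite, time, y, x]")
  else {
    if (d[1] != length(object@metabolites))
      msg <- c(msg, "first dimension must match 'metabolites'")
    if (d[2] != length(object@times))
      msg <- c(msg, "second dimension must match 'times'")
    if (!all(dim(object@noiseMask) == d[3:4]))
      msg <- c(msg, "'noiseMask' must match the spatial dimensions")
  }
  if (any(object@data < 0)) msg <- c(msg, "'data' must be non-negative magnitudes")
  if (length(msg)) msg else TRUE
})

#' Result of an inputless k_PL fit
#'
#' @slot kplHat fitted apparent conversion rate (1/s).
#' @slot residualNorm sum of squared lactate residuals at the optimum.
#' @slot converged FALSE when the estimate is pinned at an optimizer bound.
#' @slot nPointsUsed number of lactate timepoints entering the residual.
#' @export
setClass("KplFitResult",
  representation(kplHat = "numeric", residualNorm = "numeric",
                 converged = "logical", nPointsUsed = "integer"))

#' Monte Carlo configuration for k_PL precision estimation
#'
#' @slot nIterations number of noise realizations (>= 2 for a defined sd).
#' @slot noiseSD additive Gaussian noise standard deviation in signal units;
#'   `NA` means "choose so that peak pyruvate SNR is about 50".
#' @slot seed RNG seed.
#' @export
setClass("MonteCarloConfig",
  representation(nIterations = "integer", noiseSD = "numeric", seed = "integer"),
  prototype(nIterations = 500L, noiseSD = NA_real_, seed = 1L))

setValidity("MonteCarloConfig", function(object) {
  msg <- character()
  if (object@nIterations < 1) msg <- c(msg, "'nIterations' must be >= 1")
  if (!is.na(object@noiseSD) && object@noiseSD < 0)
    msg <- c(msg, "'noiseSD' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Flip-angle / temporal-resolution optimization grid
#'
#' Relative SNR (sum of modelled magnitude signal over the dynamic run) and,
#' optionally, Monte Carlo k_PL-fit standard deviation for every combination
#' of pyruvate flip, lactate flip and temporal resolution.
#'
#' @slot pyrFlips pyruvate flip angle axis (degrees).
#' @slot lacFlips lactate flip angle axis (degrees).
#' @slot temporalResolutions temporal resolution axis (s).
#' @slot pyrSNR,lacSNR arrays `[pyr flip, lac flip, temporal resolution]`.
#' @slot kplSD same shape; NA where not computed.
#' @export
setClass("OptimizationGrid",
  representation(pyrFlips = "numeric", lacFlips = "numeric",
                 temporalResolutions = "numeric", pyrSNR = "array",
                 lacSNR = "array", kplSD = "array"))

setValidity("OptimizationGrid", function(object) {
  dims <- c(length(object@pyrFlips), length(object@lacFlips),
            length(object@temporalResolutions))
  for (nm in c("pyrSNR", "lacSNR", "kplSD"))
    if (!all(dim(slot(object, nm)) == dims))
      return(sprintf("'%s' dimensions must match the axes", nm))
  if (any(object@pyrSNR < 0, na.rm = TRUE) || any(object@lacSNR < 0, na.rm = TRUE))
    return("SNR values must be >= 0")
  TRUE
})

#' Digital mouse phantom definition
#'
#' A 2-D labelled phantom on a fine grid: a high-perfusion/low-k_PL vessel,
#' a moderate-perfusion/high-k_PL tumor, and background. Each region carries
#' its own kinetic parameters and perfusion amplitude (scaling of the bolus
#' input). Geometry values are package constants chosen to make the
#' vascular-bleed phenomenon robust; they are synthetic, not measured.
#'
#' @slot gridSize integer `(ny, nx)` of the fine simulation grid.
#' @slot pitchMM grid pitch (mm).
#' @slot regions named list of logical `(ny, nx)` masks (must be disjoint);
#'   requires at least `vessel` and `tumor`.
#' @slot perfusion named per-region input-amplitude scaling.
#' @slot params named list of [PKParams-class] per region.
#' @slot noiseSD complex-channel noise sd added per reconstructed frame.
#' @slot seed default RNG seed for forward imaging.
#' @export
setClass("PhantomDef",
  representation(gridSize = "integer", pitchMM = "numeric", regions = "list",
                 perfusion = "numeric", params = "list", noiseSD = "numeric",
                 seed = "integer"))

setValidity("PhantomDef", function(object) {
  msg <- character()
  if (!all(c("vessel", "tumor") %in% names(object@regions)))
    msg <- c(msg, "regions must include at least 'vessel' and 'tumor'")
  overlap <- Reduce(`+`, lapply(object@regions, function(m) m * 1))
  if (length(overlap) && max(overlap) > 1) msg <- c(msg, "region masks must be disjoint")
  for (m in object@regions)
    if (!all(dim(m) == object@gridSize)) msg <- c(msg, "mask dims must match gridSize")
  if (any(object@perfusion < 0)) msg <- c(msg, "perfusion amplitudes must be >= 0")
  if (!setequal(names(object@regions), names(object@perfusion)) ||
      !setequal(names(object@regions), names(object@params)))
    msg <- c(msg, "'perfusion' and 'params' must be named like 'regions'")
  if (object@noiseSD < 0) msg <- c(msg, "'noiseSD' must be >= 0")
  if (length(msg)) unique(msg) else TRUE
})

#' Line profile through an image with peak count
#'
#' @slot positions positions along the line (mm).
#' @slot values image values along the line.
#' @slot peakCount number of local maxima exceeding the prominence threshold.
#' @slot prominence prominence threshold used (fraction of the profile max).
#' @export
setClass("LineProfile",
  representation(positions = "numeric", values = "numeric",
                 peakCount = "integer", prominence = "numeric"))
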