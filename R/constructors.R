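#' Create a pharmacokinetic parameter set
#'
#' Defaults are the literature-anchored simulation values for preclinical
#' tumors: k_PL = 0.05 1/s, T1 pyruvate = 20 s, T1 lactate = 30 s.
#'
#' @param kpl apparent conversion rate (1/s).
#' @param t1Pyr pyruvate T1 (s).
#' @param t1Lac lactate T1 (s).
#' @return a [PKParams-class] object.
#' @examples
#' pkParams(kpl = 0.02)
#' @export
pkParams <- function(kpl = 0.05, t1Pyr = 20, t1Lac = 30) {
  new("PKParams", kpl = as.numeric(kpl), t1Pyr = as.numeric(t1Pyr),
      t1Lac = as.numeric(t1Lac))
}

#' Create a gamma-variate bolus input function
#'
#' @param fwhm bolus full width at half maximum (s); default 8 s.
#' @param arrivalTime bolus onset relative to acquisition start (s).
#' @param amplitude total delivered longitudinal magnetization (a.u.).
#' @param gammaShape gamma shape parameter (> 1); default 4, a realistic
#'   fast-rise/slow-decay asymmetry.
#' @return an [InputFunction-class] object.
#' @examples
#' inputFunction(fwhm = 8)
#' @export
inputFunction <- function(fwhm = 8, arrivalTime = 0, amplitude = 1,
                          gammaShape = 4) {
  new("InputFunction", fwhm = as.numeric(fwhm),
      arrivalTime = as.numeric(arrivalTime),
      amplitude = as.numeric(amplitude), gammaShape = as.numeric(gammaShape))
}

#' Create an acquisition protocol
#'
#' Two encodings are supported. `"epi_singleshot"` is the metabolite-specific
#' EPI scheme: each metabolite is excited by a spectrally selective pulse and
#' its whole k-space frame is read in one shot, metabolites spaced `intraTR`
#' apart within a timepoint. `"csi"` phase-encodes one k-space point per
#' excitation with a non-selective pulse (both pools excited every TR).
#'
#' @param encoding `"epi_singleshot"` or `"csi"`.
#' @param metabolites excitation order within a timepoint.
#' @param flips named flip angles in degrees; for CSI give a single unnamed
#'   value or a vector named `"all"`.
#' @param intraTR spacing between metabolite excitations within a timepoint
#'   (s). Default 0.13 s (a ~25 ms spectral-spatial pulse plus a ~100 ms EPI
#'   readout).
#' @param temporalResolution timepoint spacing (s).
#' @param nTimepoints number of timepoints.
#' @param matrixSize `(ny, nx)` acquisition matrix.
#' @param fov field of view in mm; a scalar is recycled to both axes.
#' @param ordering CSI phase-encode ordering (`"centric"` or `"linear"`).
#' @param csiTR per-encode repetition time (s); default
#'   `temporalResolution / prod(matrixSize)`.
#' @return an [AcquisitionProtocol-class] object.
#' @examples
#' epiProtocol()
#' csiProtocol()
#' @export
acquisitionProtocol <- function(encoding = c("epi_singleshot", "csi"),
                                metabolites = c("pyruvate", "lactate"),
                                flips = c(pyruvate = 10, lactate = 30),
                                intraTR = 0.13,
                                temporalResolution = 3,
                                nTimepoints = 18,
                                matrixSize = c(16, 16),
                                fov = 32,
                                ordering = "centric",
                                csiTR = NULL) {
  encoding <- match.arg(encoding)
  if (length(fov) == 1) fov <- rep(fov, 2)
  if (encoding == "csi") {
    if (is.null(names(flips))) names(flips) <- rep("all", length(flips))
    if (is.null(csiTR)) csiTR <- temporalResolution / prod(matrixSize)
  } else if (is.null(csiTR)) csiTR <- NA_real_
  new("AcquisitionProtocol", encoding = encoding, metabolites = metabolites,
      flips = flips, intraTR = as.numeric(intraTR),
      temporalResolution = as.numeric(temporalResolution),
      nTimepoints = as.integer(nTimepoints),
      matrixSize = as.integer(matrixSize), fov = as.numeric(fov),
      ordering = ordering, csiTR = as.numeric(csiTR))
}

#' @describeIn acquisitionProtocol the default dynamic metabolite-specific
#'   EPI protocol: 18 timepoints every 3 s, pyruvate 10 deg / lactate 30 deg.
#' @param ... overrides passed on to [acquisitionProtocol()].
#' @export
epiProtocol <- function(...) {
  acquisitionProtocol(encoding = "epi_singleshot", ...)
}

#' @describeIn acquisitionProtocol the default preclinical CSI protocol:
#'   8 x 8 matrix over a 3.2 cm FOV (4 mm nominal), flip 10 deg, centric
#'   ordering, 4.25 s temporal resolution (per-encode TR = 4.25/64 s).
#' @export
csiProtocol <- function(...) {
  args <- list(...)
  defaults <- list(encoding = "csi", flips = c(all = 10),
                   temporalResolution = 4.25, nTimepoints = 14L,
                   matrixSize = c(8, 8), fov = 32, ordering = "centric")
  defaults[names(args)] <- args
  do.call(acquisitionProtocol, defaults)
}

#' Create a Monte Carlo configuration
#'
#' @param nIterations number of noise realizations.
#' @param noiseSD additive Gaussian noise sd in signal units; `NA` (default)
#'   selects the sd giving peak pyruvate SNR of about 50.
#' @param seed RNG seed.
#' @return a [MonteCarloConfig-class] object.
#' @export
monteCarloConfig <- function(nIterations = 500, noiseSD = NA, seed = 1) {
  new("MonteCarloConfig", nIterations = as.integer(nIterations),
      noiseSD = as.numeric(noiseSD), seed = as.integer(seed))
}
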