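#' @rdname PKParams-class
#' @aliases kpl,PKParams-method
setMethod("kpl", "PKParams", function(object) object@kpl)

#' @rdname PKParams-class
setMethod("t1Pyr", "PKParams", function(object) object@t1Pyr)

#' @rdname PKParams-class
setMethod("t1Lac", "PKParams", function(object) object@t1Lac)

#' @rdname SignalTimecourse-class
setMethod("acqTimes", "SignalTimecourse", function(object) object@times)

#' @rdname DynamicImageSeries-class
setMethod("acqTimes", "DynamicImageSeries", function(object) object@times)

#' @rdname DynamicImageSeries-class
setMethod("flipAngles", "DynamicImageSeries", function(object) object@flips)

#' @rdname DynamicImageSeries-class
setMethod("flipAngles", "AcquisitionProtocol", function(object) object@flips)

#' @rdname DynamicImageSeries-class
setMethod("seriesData", "DynamicImageSeries", function(object) object@data)

#' @rdname DynamicImageSeries-class
setMethod("noiseMask", "DynamicImageSeries", function(object) object@noiseMask)

#' @rdname DynamicImageSeries-class
setMethod("metabolites", "DynamicImageSeries", function(object) object@metabolites)

#' @rdname KSpaceWeights-class
setMethod("weightMatrix", "KSpaceWeights", function(object) object@weights)

#' @rdname KSpaceWeights-class
setMethod("voxelSize", "KSpaceWeights", function(object) object@voxelMM)

#' @rdname DynamicImageSeries-class
setMethod("voxelSize", "DynamicImageSeries", function(object) object@voxelMM)

#' @rdname PSFMetrics-class
setMethod("fwhm", "PSFMetrics", function(object) object@fwhmMM)

#' @rdname PSFMetrics-class
setMethod("width10", "PSFMetrics", function(object) object@width10MM)

#' @rdname KplFitResult-class
setMethod("kplHat", "KplFitResult", function(object) object@kplHat)

#' @rdname PhantomDef-class
setMethod("regionMasks", "PhantomDef", function(object) object@regions)

setMethod("show", "PKParams", function(object) {
  cat(sprintf("PKParams: kPL = %.4g 1/s, T1 pyr = %.4g s, T1 lac = %.4g s\n",
              object@kpl, object@t1Pyr, object@t1Lac))
})

setMethod("show", "InputFunction", function(object) {
  cat(sprintf(
    "InputFunction: gamma(shape = %.3g), FWHM = %.3g s, arrival = %.3g s, amplitude = %.3g\n",
    object@gammaShape, object@fwhm, object@arrivalTime, object@amplitude))
})

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol [%s]\n", object@encoding))
  cat(sprintf("  matrix %d x %d over %.3g x %.3g mm (%.3g mm nominal)\n",
              object@matrixSize[1], object@matrixSize[2], object@fov[1],
              object@fov[2], object@fov[2] / object@matrixSize[2]))
  cat(sprintf("  %d timepoints every %.3g s; flips [deg]: %s\n",
              object@nTimepoints, object@temporalResolution,
              paste(names(object@flips), round(object@flips, 2),
                    sep = "=", collapse = ", ")))
  if (object@encoding == "csi")
    cat(sprintf("  %s ordering, per-encode TR %.4g s\n", object@ordering,
                object@csiTR))
})

setMethod("show", "SignalTimecourse", function(object) {
  cat(sprintf("SignalTimecourse: %d timepoints over %.3g s\n",
              length(object@times), max(object@times) - min(object@times)))
  cat(sprintf("  peak pyr %.4g @ %.3g s, peak lac %.4g @ %.3g s\n",
              max(object@pyr), object@times[which.max(object@pyr)],
              max(object@lac), object@times[which.max(object@lac)]))
})

setMethod("show", "KSpaceWeights", function(object) {
  cat(sprintf("KSpaceWeights [%s]: %d x %d, voxel %.3g mm, range [%.4g, %.4g]\n",
              object@metabolite, nrow(object@weights), ncol(object@weights),
              object@voxelMM, min(object@weights), max(object@weights)))
})

setMethod("show", "PSFMetrics", function(object) {
  cat(sprintf("PSFMetrics: FWHM = %.3f mm, width at 10%% = %.3f mm\n",
              object@fwhmMM, object@width10MM))
})

setMethod("show", "KplFitResult", function(object) {
  cat(sprintf("KplFitResult: kPL = %.5g 1/s (residual norm %.4g, %d points%s)\n",
              object@kplHat, object@residualNorm, object@nPointsUsed,
              if (object@converged) "" else ", PINNED AT BOUND"))
})

setMethod("show", "DynamicImageSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicImageSeries: %s | %d timepoints | %d x %d @ %.3g mm\n",
              paste(object@metabolites, collapse = "/"), d[2], d[3], d[4],
              object@voxelMM))
})

setMethod("show", "PhantomDef", function(object) {
  cat(sprintf("PhantomDef: %d x %d grid @ %.3g mm (%s)\n",
              object@gridSize[1], object@gridSize[2], object@pitchMM,
              paste(names(object@regions), collapse = ", ")))
  for (r in names(object@regions))
    cat(sprintf("  %-10s %4d px, perfusion %.3g, kPL %.3g 1/s\n", r,
                sum(object@regions[[r]]), object@perfusion[[r]],
                object@params[[r]]@kpl))
})

setMethod("show", "OptimizationGrid", function(object) {
  cat(sprintf("OptimizationGrid: %d pyr flips x %d lac flips x %d temporal resolutions\n",
              length(object@pyrFlips), length(object@lacFlips),
              length(object@temporalResolutions)))
  i <- which(object@lacSNR == max(object@lacSNR), arr.ind = TRUE)[1, ]
  cat(sprintf("  lactate-SNR max at pyr %g deg, lac %g deg, %g s\n",
              object@pyrFlips[i[1]], object@lacFlips[i[2]],
              object@temporalResolutions[i[3]]))
})
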