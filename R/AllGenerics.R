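#' @rdname PKParams-class
#' @param object a package object.
#' @export
setGeneric("kpl", function(object) standardGeneric("kpl"))

#' @rdname PKParams-class
#' @export
setGeneric("t1Pyr", function(object) standardGeneric("t1Pyr"))

#' @rdname PKParams-class
#' @export
setGeneric("t1Lac", function(object) standardGeneric("t1Lac"))

#' @rdname SignalTimecourse-class
#' @param object a package object.
#' @export
setGeneric("acqTimes", function(object) standardGeneric("acqTimes"))

#' @rdname DynamicImageSeries-class
#' @param object a package object.
#' @export
setGeneric("flipAngles", function(object) standardGeneric("flipAngles"))

#' @rdname DynamicImageSeries-class
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))

#' @rdname DynamicImageSeries-class
#' @export
setGeneric("noiseMask", function(object) standardGeneric("noiseMask"))

#' @rdname DynamicImageSeries-class
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname KSpaceWeights-class
#' @param object a package object.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @rdname KSpaceWeights-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname PSFMetrics-class
#' @param object a package object.
#' @export
setGeneric("fwhm", function(object) standardGeneric("fwhm"))

#' @rdname PSFMetrics-class
#' @export
setGeneric("width10", function(object) standardGeneric("width10"))

#' @rdname KplFitResult-class
#' @param object a package object.
#' @export
setGeneric("kplHat", function(object) standardGeneric("kplHat"))

#' @rdname PhantomDef-class
#' @param object a package object.
#' @export
setGeneric("regionMasks", function(object) standardGeneric("regionMasks"))
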