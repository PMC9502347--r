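#' Access the pixel matrix of an image
#' @param object a [SectionImage-class].
#' @return numeric matrix of grey values, rows top-down.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' Physical pixel size
#' @param object an object with a pixel scale.
#' @return micrometres per pixel.
#' @export
setGeneric("pixelScale", function(object) standardGeneric("pixelScale"))

#' Mean stratum corneum thickness in micrometres
#' @param object a [SctProfile-class].
#' @return numeric scalar (um).
#' @export
setGeneric("sctUm", function(object) standardGeneric("sctUm"))

#' SD of the per-line stratum corneum thickness in micrometres
#' @param object a [SctProfile-class].
#' @return numeric scalar (um).
#' @export
setGeneric("sctUmSd", function(object) standardGeneric("sctUmSd"))

#' Mean stratum corneum autofluorescence (AF-SC)
#' @param object a [SctProfile-class].
#' @return mean grey value per pixel along the measured SC lines.
#' @export
setGeneric("afSc", function(object) standardGeneric("afSc"))

#' AROSA: mean grey value per pixel after autofluorescence removal
#' @param object a [PenetrationMetrics-class].
#' @return numeric scalar (MGV/px).
#' @export
setGeneric("arosa", function(object) standardGeneric("arosa"))

#' Mean penetration depth in micrometres
#' @param object a [PenetrationMetrics-class].
#' @return numeric scalar (um).
#' @export
setGeneric("mpdUm", function(object) standardGeneric("mpdUm"))

#' Threshold used for autofluorescence removal
#' @param object a [PenetrationMetrics-class].
#' @return numeric grey level.
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))

#' Bookkeeping flags of a result object
#' @param object a [PenetrationMetrics-class].
#' @return character vector of flags (possibly empty).
#' @export
setGeneric("flags", function(object) standardGeneric("flags"))

#' True per-column surface rows of a synthetic render
#' @param object a [GroundTruth-class].
#' @return integer vector of 1-based rows.
#' @export
setGeneric("trueSurfaceRows", function(object) standardGeneric("trueSurfaceRows"))

#' Effective generator values used for a synthetic render
#' @param object a [GroundTruth-class].
#' @return named numeric vector.
#' @export
setGeneric("trueValues", function(object) standardGeneric("trueValues"))
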