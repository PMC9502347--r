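#' @describeIn SectionImage pixel matrix accessor
#' @param object a \code{SectionImage}.
#' @export
setMethod("pixels", "SectionImage", function(object) object@pixels)

#' @describeIn SectionImage pixel scale accessor (um/px)
#' @export
setMethod("pixelScale", "SectionImage", function(object) object@scaleUmPerPx)

#' @describeIn SctProfile pixel scale accessor (um/px)
#' @param object a \code{SctProfile}.
#' @export
setMethod("pixelScale", "SctProfile", function(object) object@scaleUmPerPx)

#' @describeIn SctProfile mean SC thickness in um
#' @export
setMethod("sctUm", "SctProfile", function(object)
  mean(object@sctPx) * object@scaleUmPerPx)

#' @describeIn SctProfile SD of the per-line SC thickness in um
#' @export
setMethod("sctUmSd", "SctProfile", function(object)
  stats::sd(object@sctPx * object@scaleUmPerPx))

#' @describeIn SctProfile mean AF-SC over the measured lines
#' @export
setMethod("afSc", "SctProfile", function(object) mean(object@afScPerLine))

#' @describeIn PenetrationMetrics AROSA accessor (MGV/px)
#' @param object a \code{PenetrationMetrics}.
#' @export
setMethod("arosa", "PenetrationMetrics", function(object) object@arosaMgvPerPx)

#' @describeIn PenetrationMetrics mean penetration depth accessor (um)
#' @export
setMethod("mpdUm", "PenetrationMetrics", function(object) object@mpdUm)

#' @describeIn PenetrationMetrics threshold accessor
#' @export
setMethod("thresholdValue", "PenetrationMetrics",
          function(object) object@thresholdValue)

#' @describeIn PenetrationMetrics flags accessor
#' @export
setMethod("flags", "PenetrationMetrics", function(object) object@flags)

#' @describeIn GroundTruth true surface rows accessor
#' @param object a \code{GroundTruth}.
#' @export
setMethod("trueSurfaceRows", "GroundTruth", function(object)
  object@surfaceRows)

#' @describeIn GroundTruth effective generator values accessor
#' @export
setMethod("trueValues", "GroundTruth", function(object) object@effective)

## show methods --------------------------------------------------------------

setMethod("show", "SectionImage", function(object) {
  cat(sprintf("SectionImage %s: %d x %d px, %.3g um/px, channel %s\n",
              ifelse(is.na(object@imageId), "<unnamed>", object@imageId),
              nrow(object@pixels), ncol(object@pixels),
              object@scaleUmPerPx, object@channel))
  if (!is.na(object@condition))
    cat(sprintf("  ear %s, condition %s, cut %s\n", object@earId,
                object@condition, object@cutIndex))
  cat(sprintf("  grey range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "GeneratorParams", function(object) {
  cat(sprintf("GeneratorParams: %d x %d px @ %.3g um/px\n",
              object@imageHeightPx, object@imageWidthPx, object@scaleUmPerPx))
  cat(sprintf("  SCT %.3g um (hydration %.2g), AF SC/tissue %.3g/%.3g\n",
              object@sctUm, object@hydrationIndex, object@afScLevel,
              object@afTissueLevel))
  cat(sprintf("  dye %.3g (decay %.3g um), noise SD %.3g, %d-bit\n",
              object@dyeAmount, object@dyeDecayUm, object@noiseSd,
              object@bitDepth))
})

setMethod("show", "SctProfile", function(object) {
  cat(sprintf("SctProfile: %d lines, SCT %.2f +/- %.2f um, AF-SC %.2f\n",
              length(object@lineColumns), sctUm(object),
              sctUmSd(object), afSc(object)))
})

setMethod("show", "PenetrationMetrics", function(object) {
  cat(sprintf(
    "PenetrationMetrics: threshold %.2f (%s), AROSA %.4f MGV/px, MPD %.2f um\n",
    object@thresholdValue, object@method, object@arosaMgvPerPx, object@mpdUm))
  cat(sprintf("  %d signal px%s\n", object@nSignalPx,
              if (length(object@flags))
                paste0("; flags: ", paste(object@flags, collapse = ", "))
              else ""))
})

setMethod("show", "ConditionPreset", function(object) {
  cat(sprintf("ConditionPreset %s (section %d, %s, %s)\n", object@label,
              object@skinSection, object@surrogate, object@timepoint))
  if (length(object@modifiers))
    cat("  modifiers:", paste(names(object@modifiers), "=",
                              signif(object@modifiers, 3), collapse = ", "),
        "\n")
})

setMethod("show", "StudyManifest", function(object) {
  cat(sprintf(
    "StudyManifest: %d ears x %d conditions (>= %d cuts, >= %d images/biopsy)\n",
    length(object@ears), length(object@presets), object@minCuts,
    object@minImages))
})

setMethod("show", "PenetrationStudy", function(object) {
  cat(sprintf("PenetrationStudy: %d images, %d conditions, %d ears\n",
              length(object@images),
              length(unique(object@truth$condition)),
              length(unique(object@truth$ear))))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s]: %s (stat %.4g, p %.4g) + %s post hoc\n",
              object@metric, object@omnibus, object@statistic, object@p,
              object@postHoc))
  if (nrow(object@pairwise)) {
    sig <- object@pairwise[object@pairwise$stars != "ns", , drop = FALSE]
    cat(sprintf("  %d pairs, %d significant at alpha = %.3g\n",
                nrow(object@pairwise), nrow(sig), object@alpha))
  }
})
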