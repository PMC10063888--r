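#' Accessors for rvgc classes
#'
#' Small read-only accessors: `icfValue()` and `icfKind()` for
#' [ConversionFactor-class], `odCenter()` and `meanODDiameter()` for
#' [OpticDisc-class], `vesselLabels()` and `mapMeta()` for
#' [VesselMap-class], `rvgcValues()` and `rvgcFlags()` for
#' [RVGCResult-class], and `vessels()` for [SyntheticEye-class].
#'
#' @param object the object to access.
#' @return the corresponding slot value; `meanODDiameter()` returns the
#'   mean of the horizontal and vertical disc diameters in px.
#' @name accessors
#' @aliases icfValue icfKind odCenter meanODDiameter vesselLabels mapMeta
#'   rvgcValues rvgcFlags vessels
#' @examples
#' icf <- individualICF(720)
#' icfValue(icf)
#' icfKind(icf)
NULL

#' @rdname accessors
setMethod("icfValue", "ConversionFactor", function(object) object@value)

#' @rdname accessors
setMethod("icfKind", "ConversionFactor", function(object) object@kind)

#' @rdname accessors
setMethod("odCenter", "OpticDisc", function(object) object@center)

#' @rdname accessors
setMethod("meanODDiameter", "OpticDisc", function(object) {
  (object@hDiameterPx + object@vDiameterPx) / 2
})

#' @rdname accessors
setMethod("vesselLabels", "VesselMap", function(object) object@labels)

#' @rdname accessors
setMethod("mapMeta", "VesselMap", function(object) object@meta)

#' @rdname accessors
setMethod("rvgcValues", "RVGCResult", function(object) object@values)

#' @rdname accessors
setMethod("rvgcFlags", "RVGCResult", function(object) object@flags)

#' @rdname accessors
setMethod("vessels", "SyntheticEye", function(object) object@vessels)

setMethod("show", "OpticDisc", function(object) {
  cat(sprintf("OpticDisc: center (%.1f, %.1f) px, h %.1f px, v %.1f px, mean %.1f px\n",
              object@center[1], object@center[2], object@hDiameterPx,
              object@vDiameterPx, meanODDiameter(object)))
})

setMethod("show", "ConversionFactor", function(object) {
  cat(sprintf("ConversionFactor (%s): %.4f um/px (reference disc %g um)\n",
              object@kind, object@value, object@referenceOdUm))
})

setMethod("show", "MeasurementZones", function(object) {
  cat(sprintf(paste0("MeasurementZones at (%.1f, %.1f):\n",
                     "  zone B: %.1f - %.1f px\n  zone C: %.1f - %.1f px\n"),
              object@center[1], object@center[2],
              object@zoneB[1], object@zoneB[2],
              object@zoneC[1], object@zoneC[2]))
})

setMethod("show", "SyntheticEye", function(object) {
  types <- vapply(object@vessels, function(v) v@vesselType, "")
  cat(sprintf(paste0("SyntheticEye (seed %d): disc %.0f um (%.1f px at %.2f um/px),\n",
                     "  %d arteries, %d veins\n"),
              object@seed, object@odDiameterUm,
              object@odDiameterUm / object@trueScale, object@trueScale,
              sum(types == "artery"), sum(types == "vein")))
})

setMethod("show", "VesselMap", function(object) {
  m <- object@meta
  cat(sprintf(paste0("VesselMap: %d x %d px, %s view, scale %.2f\n",
                     "  disc at (%.1f, %.1f), h %.0f px, v %.0f px\n"),
              nrow(object@labels), ncol(object@labels), m$centering,
              m$scaleFactor, m$odCenter[1], m$odCenter[2],
              m$odHDiameterPx, m$odVDiameterPx))
})

setMethod("show", "RVGCResult", function(object) {
  cat(sprintf("RVGCResult (%s ICF, %.4f um/px):\n", object@icfUsed@kind,
              object@icfUsed@value))
  v <- object@values
  cat(sprintf("  CRAE %.1f um  CRVE %.1f um  AVR %.3f\n",
              v["CRAE"], v["CRVE"], v["AVR"]))
  cat(sprintf("  CRAEoC %.1f um  CRVEoC %.1f um  AVRoC %.3f\n",
              v["CRAEoC"], v["CRVEoC"], v["AVRoC"]))
  cat(sprintf("  Df %.3f  Dfa %.3f  Dfv %.3f\n", v["Df"], v["Dfa"], v["Dfv"]))
  cat(sprintf("  STt %.4f  STa %.4f  STv %.4f\n", v["STt"], v["STa"], v["STv"]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "AgreementSummary", function(object) {
  cat(sprintf(paste0("AgreementSummary (n = %d): mean difference %.4g, ",
                     "SD %.4g\n  limits of agreement [%.4g, %.4g]\n",
                     "  bias p = %.4g, proportional-bias slope %.4g (p = %.4g)\n"),
              object@n, object@meanDiff, object@sdDiff, object@lowerLoa,
              object@upperLoa, object@biasP, object@propBiasSlope,
              object@propBiasP))
  if (object@degenerate) cat("  [degenerate: zero-variance differences]\n")
})

#' Convert an RVGCResult or AgreementSummary to a one-row data.frame
#'
#' @param x the object.
#' @param row.names,optional,... passed through for compatibility with the
#'   generic; unused.
#' @return one-row `data.frame`.
#' @export
as.data.frame.RVGCResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- as.data.frame(as.list(x@values))
  df$icf <- x@icfUsed@value
  df$icf_kind <- x@icfUsed@kind
  df$flags <- paste(x@flags, collapse = ";")
  df
}

#' @rdname as.data.frame.RVGCResult
#' @export
as.data.frame.AgreementSummary <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(mean_difference = x@meanDiff, sd = x@sdDiff,
             upper_limit = x@upperLoa, lower_limit = x@lowerLoa,
             one_sample_p = x@biasP, regression_slope = x@propBiasSlope,
             regression_p = x@propBiasP, n = x@n, degenerate = x@degenerate)
}

setMethod("as.data.frame", "RVGCResult", as.data.frame.RVGCResult)
setMethod("as.data.frame", "AgreementSummary", as.data.frame.AgreementSummary)
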