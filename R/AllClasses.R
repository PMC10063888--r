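#' @import methods
#' @importFrom stats rnorm runif sd lm coef shapiro.test t.test wilcox.test
#'   cor.test complete.cases qt
#' @importFrom utils write.csv
#' @useDynLib rvgc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RVGC_NAMES <- c("CRAE", "CRVE", "AVR", "CRAEoC", "CRVEoC", "AVRoC",
                "Df", "Dfa", "Dfv", "STt", "STa", "STv")

#' Optic disc geometry
#'
#' Center position and horizontal/vertical diameters of the optic disc,
#' all in pixels of the image the disc was measured on.  The disc is the
#' scale reference of the whole measurement chain: its mean diameter is
#' assumed to correspond to a fixed physical reference size (1800 um by
#' default), which yields the image conversion factor.
#'
#' @slot center numeric(2), (x, y) pixel position of the disc center.
#' @slot hDiameterPx,vDiameterPx horizontal and vertical disc diameters
#'   in pixels; both must be positive.
#' @seealso [opticDisc()], [meanODDiameter()], [individualICF()]
#' @export
setClass("OpticDisc", representation(
  center = "numeric", hDiameterPx = "numeric", vDiameterPx = "numeric"))

setValidity("OpticDisc", function(object) {
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    return("center must be a finite (x, y) pair")
  if (length(object@hDiameterPx) != 1L || !is.finite(object@hDiameterPx) ||
      object@hDiameterPx <= 0)
    return("hDiameterPx must be a single positive number")
  if (length(object@vDiameterPx) != 1L || !is.finite(object@vDiameterPx) ||
      object@vDiameterPx <= 0)
    return("vDiameterPx must be a single positive number")
  TRUE
})

#' Image conversion factor (um per pixel)
#'
#' A pixel-to-micron conversion factor derived from the optic disc: the
#' reference disc size (default 1800 um) divided by a disc diameter in
#' pixels.  `kind` records whether the denominator was the cohort-average
#' disc ("constant") or the disc of the analyzed eye itself ("individual").
#'
#' @slot value um per pixel, positive.
#' @slot kind `"constant"` or `"individual"`.
#' @slot referenceOdUm the assumed physical disc diameter, um.
#' @seealso [individualICF()], [constantICF()], [pxToUm()], [buildZones()]
#' @export
setClass("ConversionFactor", representation(
  value = "numeric", kind = "character", referenceOdUm = "numeric"))

setValidity("ConversionFactor", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value) ||
      object@value <= 0)
    return("value must be a single positive number (um per px)")
  if (!object@kind %in% c("constant", "individual"))
    return("kind must be 'constant' or 'individual'")
  if (length(object@referenceOdUm) != 1L || object@referenceOdUm <= 0)
    return("referenceOdUm must be a single positive number")
  TRUE
})

#' Measurement zones B and C
#'
#' Two concentric annuli around the optic disc center in which vessels are
#' measured.  Distances are defined against the reference disc: both zones
#' start 0.5 reference-disc diameters beyond the disc margin (radius 1.0
#' diameters from the center); zone B ends at radius 1.5 and zone C at
#' radius 2.5 diameters.  The conversion factor turns those physical radii
#' into pixels, so a large conversion factor (small disc) gives a small
#' pixel annulus.
#'
#' @slot center numeric(2) annulus center (the disc center), px.
#' @slot zoneB,zoneC numeric(2) inner and outer radii in px.
#' @seealso [buildZones()]
#' @export
setClass("MeasurementZones", representation(
  center = "numeric", zoneB = "numeric", zoneC = "numeric"))

setValidity("MeasurementZones", function(object) {
  if (length(object@zoneB) != 2L || length(object@zoneC) != 2L)
    return("zoneB and zoneC must be (inner, outer) radius pairs")
  if (any(c(object@zoneB, object@zoneC) <= 0))
    return("all radii must be positive")
  if (abs(object@zoneB[1] - object@zoneC[1]) > 1e-9)
    return("zones B and C must share the inner radius")
  if (object@zoneB[2] >= object@zoneC[2])
    return("zone B outer radius must be smaller than zone C outer radius")
  if (object@zoneB[1] >= object@zoneB[2])
    return("annulus inner radius must be smaller than outer radius")
  TRUE
})

#' Ground-truth vessel of a synthetic eye
#'
#' A single arteriole or venule, described by its centerline polyline in
#' native eye coordinates (px, disc center at origin, point spacing of at
#' most 1 px), a true caliber in um, and the sinusoidal tortuosity
#' parameters used to bend it.
#'
#' @slot vesselId integer id, unique within the eye.
#' @slot vesselType `"artery"` or `"vein"`.
#' @slot centerline n x 2 matrix of (x, y) points ordered from the disc
#'   outward.
#' @slot widthUm true caliber, um (at the vessel origin when tapering).
#' @slot taperRate fractional caliber loss per disc diameter of radial
#'   distance beyond the disc margin (0 = constant width).
#' @slot tortAmplitudePx,tortWavelengthPx sinusoidal perpendicular
#'   displacement amplitude and wavelength, native px.
#' @export
setClass("GroundTruthVessel", representation(
  vesselId = "integer", vesselType = "character", centerline = "matrix",
  widthUm = "numeric", taperRate = "numeric",
  tortAmplitudePx = "numeric", tortWavelengthPx = "numeric"))

setValidity("GroundTruthVessel", function(object) {
  if (!object@vesselType %in% c("artery", "vein"))
    return("vesselType must be 'artery' or 'vein'")
  if (object@widthUm <= 0) return("widthUm must be positive")
  if (ncol(object@centerline) != 2L || nrow(object@centerline) < 2L)
    return("centerline must be an n x 2 matrix with n >= 2")
  step <- sqrt(rowSums(diff(object@centerline)^2))
  if (max(step) > 1 + 1e-6)
    return("centerline point spacing must be <= 1 px")
  TRUE
})

#' Synthetic eye with known vessel geometry
#'
#' The ground truth from which labeled vessel maps are rendered: disc size
#' in um, the native um-per-pixel scale at which geometry is laid out, and
#' a list of [GroundTruthVessel-class] objects.  The seed fully determines
#' the eye.
#'
#' @slot trueScale um per native pixel.
#' @slot odCenter disc center in native coordinates (always c(0, 0)).
#' @slot odDiameterUm physical disc diameter, um.
#' @slot odAspect vertical/horizontal disc diameter ratio.
#' @slot vessels list of [GroundTruthVessel-class].
#' @slot seed integer seed used to generate the eye.
#' @slot params the generation parameter list (see [eyeParams()]).
#' @seealso [generateEye()], [renderView()]
#' @export
setClass("SyntheticEye", representation(
  trueScale = "numeric", odCenter = "numeric", odDiameterUm = "numeric",
  odAspect = "numeric", vessels = "list", seed = "integer",
  params = "list"))

setValidity("SyntheticEye", function(object) {
  if (object@odDiameterUm <= 0) return("odDiameterUm must be positive")
  if (object@trueScale <= 0) return("trueScale must be positive")
  if (!all(vapply(object@vessels, is, TRUE, "GroundTruthVessel")))
    return("vessels must all be GroundTruthVessel objects")
  TRUE
})

#' View specification for rendering
#'
#' How a synthetic eye is photographed: optic-disc-centered (`"ODC"`) or
#' macula-centered (`"MC"`) framing, field of view in degrees, an optional
#' explicit output size, and a resampling factor relative to the native
#' render scale.  In the MC framing the window is centered on the fovea,
#' placed 2.5 disc diameters temporal to the disc center on the horizontal
#' meridian.
#'
#' @slot centering `"ODC"` or `"MC"`.
#' @slot fovDeg field of view, degrees (the disc is taken to subtend 5
#'   degrees, so the field caps the rendered window).
#' @slot outputSize numeric(2) (width, height) px, or NA for the default
#'   window (the tightest frame containing zone C, capped by the field of
#'   view).
#' @slot scaleFactor unitless resampling factor; 2 doubles all pixel
#'   dimensions.
#' @seealso [viewSpec()], [renderView()]
#' @export
setClass("ViewSpec", representation(
  centering = "character", fovDeg = "numeric", outputSize = "numeric",
  scaleFactor = "numeric"))

setValidity("ViewSpec", function(object) {
  if (!object@centering %in% c("ODC", "MC"))
    return("centering must be 'ODC' or 'MC'")
  if (object@fovDeg <= 0) return("fovDeg must be positive")
  if (object@scaleFactor <= 0) return("scaleFactor must be positive")
  if (!(length(object@outputSize) == 2L || all(is.na(object@outputSize))))
    return("outputSize must be (width, height) or NA")
  TRUE
})

#' Labeled vessel map
#'
#' A raster label image with codes 0 (background), 1 (artery), 2 (vein)
#' and 3 (optic disc), indexed `[x, y]`, plus view metadata.  Required
#' metadata keys: `centering`, `fovDeg`, `scaleFactor`, `odCenter`,
#' `odHDiameterPx`, `odVDiameterPx`, `seed`.  Maps rendered from a
#' [SyntheticEye-class] additionally carry the ground truth vessel table
#' and the fraction of the (individual) zone C annulus clipped by the
#' frame.
#'
#' @slot labels integer matrix of label codes.
#' @slot meta named list of metadata.
#' @seealso [renderView()], [readVesselMap()], [writeVesselMap()]
#' @export
setClass("VesselMap", representation(labels = "matrix", meta = "list"))

VESSELMAP_META_KEYS <- c("centering", "fovDeg", "scaleFactor", "odCenter",
                         "odHDiameterPx", "odVDiameterPx", "seed")

setValidity("VesselMap", function(object) {
  lv <- object@labels
  if (!is.integer(lv)) return("labels must be an integer matrix")
  rng <- range(lv)
  if (rng[1] < 0L || rng[2] > 3L)
    return("labels must only contain the codes 0, 1, 2, 3")
  missing <- setdiff(VESSELMAP_META_KEYS, names(object@meta))
  if (length(missing))
    return(paste0("missing metadata keys: ", paste(missing, collapse = ", ")))
  TRUE
})

#' The twelve retinal vessel geometric characteristics of one image
#'
#' Central retinal artery and vein equivalents and their ratio measured in
#' zone B (CRAE, CRVE, AVR) and over the full zone C (CRAEoC, CRVEoC,
#' AVRoC), box-counting fractal dimensions of the zone C skeleton
#' (combined, arteries-only, veins-only), and mean simple tortuosity in
#' zone C (all segments, arteries, veins).  Equivalents are reported in um
#' via the conversion factor stored alongside.
#'
#' @slot values named numeric of length 12, names `CRAE, CRVE, AVR,
#'   CRAEoC, CRVEoC, AVRoC, Df, Dfa, Dfv, STt, STa, STv`.
#' @slot icfUsed the [ConversionFactor-class] applied.
#' @slot flags character vector of quality flags (big-six shortfall, zone
#'   clipping, missing vessel types).
#' @seealso [computeRVGC()]
#' @export
setClass("RVGCResult", representation(
  values = "numeric", icfUsed = "ConversionFactor", flags = "character"))

setValidity("RVGCResult", function(object) {
  if (!identical(names(object@values), RVGC_NAMES))
    return(paste0("values must be named ", paste(RVGC_NAMES, collapse = ", ")))
  v <- object@values
  if (is.finite(v["CRAE"]) && is.finite(v["CRVE"]) && is.finite(v["AVR"]) &&
      abs(v["AVR"] - v["CRAE"] / v["CRVE"]) > 1e-8)
    return("AVR must equal CRAE/CRVE")
  st <- v[c("STt", "STa", "STv")]
  if (any(is.finite(st) & st < 1 - 1e-9))
    return("simple tortuosity must be >= 1")
  if (is.finite(v["Df"]) && (v["Df"] <= 0 || v["Df"] > 2 + 1e-6))
    return("Df must lie in (0, 2]")
  TRUE
})

#' Paired measurement series
#'
#' Two measurements of the same quantity on the same images, aligned by
#' image label, as consumed by the agreement layer ([blandAltman()],
#' [pairedCompare()]).  Differences are taken as `x - y`.
#'
#' @slot labels image identifiers.
#' @slot x,y numeric values from method 1 and method 2, same units.
#' @export
setClass("PairedSeries", representation(
  labels = "character", x = "numeric", y = "numeric"))

setValidity("PairedSeries", function(object) {
  n <- length(object@labels)
  if (n < 3L) return("need at least 3 pairs")
  if (length(object@x) != n || length(object@y) != n)
    return("labels, x and y must have equal length")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  TRUE
})

#' Bland-Altman agreement summary
#'
#' Mean difference, its sample SD, symmetric 1.96-SD limits of agreement,
#' a one-sample t-test of the differences against zero (systematic bias)
#' and the slope test of the differences regressed on the pairwise means
#' (proportional bias).
#'
#' @slot meanDiff,sdDiff mean and sample SD of `x - y`.
#' @slot upperLoa,lowerLoa limits of agreement, `meanDiff +/- 1.96 sdDiff`.
#' @slot biasP one-sample t-test p-value of the differences vs 0.
#' @slot propBiasSlope,propBiasP slope of `(x - y) ~ (x + y)/2` and its
#'   p-value.
#' @slot n number of pairs.
#' @slot degenerate TRUE when the differences have zero variance, in which
#'   case the bias tests are undefined.
#' @seealso [blandAltman()]
#' @export
setClass("AgreementSummary", representation(
  meanDiff = "numeric", sdDiff = "numeric", upperLoa = "numeric",
  lowerLoa = "numeric", biasP = "numeric", propBiasSlope = "numeric",
  propBiasP = "numeric", n = "integer", degenerate = "logical"))

setValidity("AgreementSummary", function(object) {
  if (!object@degenerate) {
    if (object@lowerLoa > object@meanDiff || object@meanDiff > object@upperLoa)
      return("limits of agreement must bracket the mean difference")
    if (abs((object@upperLoa - object@meanDiff) -
            (object@meanDiff - object@lowerLoa)) > 1e-8)
      return("limits of agreement must be symmetric about the mean difference")
  }
  TRUE
})
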