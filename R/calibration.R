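#' Construct an optic disc object
#'
#' @param center (x, y) disc center in px.
#' @param hDiameterPx,vDiameterPx horizontal and vertical disc diameters
#'   in px, both positive.
#' @return an [OpticDisc-class].
#' @examples
#' disc <- opticDisc(c(512, 512), 700, 760)
#' meanODDiameter(disc)  # 730
#' @export
opticDisc <- function(center, hDiameterPx, vDiameterPx = hDiameterPx) {
  new("OpticDisc", center = as.numeric(center),
      hDiameterPx = as.numeric(hDiameterPx),
      vDiameterPx = as.numeric(vDiameterPx))
}

#' Individual image conversion factor
#'
#' The per-eye conversion factor: the reference disc size divided by the
#' disc diameter of the analyzed eye in pixels.  Scale-free measurements
#' converted with it are comparable across images with different
#' resolution, because a resampled image changes the disc diameter and the
#' vessel widths by the same factor.
#'
#' @param od either an [OpticDisc-class] (its mean diameter is used) or a
#'   single disc diameter in px.
#' @param referenceOdUm assumed physical disc diameter, um; 1800 by
#'   default (1850 is also in use in the literature).
#' @return a [ConversionFactor-class] with `kind = "individual"`.
#' @examples
#' icfValue(individualICF(638))   # 2.82 at 2 d.p.
#' icfValue(individualICF(1014))  # 1.78 at 2 d.p.
#' @export
individualICF <- function(od, referenceOdUm = 1800) {
  odPx <- if (is(od, "OpticDisc")) meanODDiameter(od) else as.numeric(od)
  if (length(odPx) != 1L || !is.finite(odPx) || odPx <= 0)
    stop("disc diameter must be a single positive number of pixels")
  new("ConversionFactor", value = referenceOdUm / odPx,
      kind = "individual", referenceOdUm = as.numeric(referenceOdUm))
}

#' Constant (cohort) image conversion factor
#'
#' The cohort-level conversion factor: the reference disc size divided by
#' the average disc diameter of the cohort.  Applied unchanged to every
#' image of the cohort, as in the standard operating procedure of vessel
#' assessment software.
#'
#' @param cohortOdPx numeric vector of disc diameters in px (or a list of
#'   [OpticDisc-class] objects), one per cohort image.
#' @param referenceOdUm assumed physical disc diameter, um.
#' @return a [ConversionFactor-class] with `kind = "constant"`.
#' @examples
#' icfValue(constantICF(c(900, 900)))  # 2.0
#' @export
constantICF <- function(cohortOdPx, referenceOdUm = 1800) {
  if (is.list(cohortOdPx))
    cohortOdPx <- vapply(cohortOdPx, meanODDiameter, 0)
  cohortOdPx <- as.numeric(cohortOdPx)
  if (!length(cohortOdPx)) stop("cohort must contain at least one disc")
  if (any(!is.finite(cohortOdPx) | cohortOdPx <= 0))
    stop("all disc diameters must be positive")
  new("ConversionFactor", value = referenceOdUm / mean(cohortOdPx),
      kind = "constant", referenceOdUm = as.numeric(referenceOdUm))
}

#' Convert a pixel length to microns
#'
#' `length_um = icf * length_px`, the conversion applied to the central
#' retinal equivalents for reporting.
#'
#' @param lengthPx length(s) in px, non-negative.
#' @param icf a [ConversionFactor-class].
#' @return length(s) in um.
#' @examples
#' pxToUm(100, constantICF(750))  # 240
#' @export
pxToUm <- function(lengthPx, icf) {
  stopifnot(is(icf, "ConversionFactor"))
  if (any(lengthPx < 0, na.rm = TRUE)) stop("lengths must be non-negative")
  lengthPx * icf@value
}

#' Build measurement zones B and C from a conversion factor
#'
#' Zone boundaries are defined in physical units against the reference
#' disc (diameter `referenceOdUm`, radius half of it): both zones begin
#' half a disc diameter beyond the disc margin, i.e. at radius 1.0
#' diameters from the center; zone B ends at radius 1.5 diameters and
#' zone C at 2.5 diameters.  Dividing by the conversion factor turns the
#' physical radii into pixels, so with an individual factor the inner
#' boundary equals the measured disc diameter of that eye, while a
#' constant factor yields the same fixed pixel annulus for every image.
#'
#' @param discCenter (x, y) disc center in px.
#' @param icf a [ConversionFactor-class].
#' @return a [MeasurementZones-class].
#' @examples
#' buildZones(c(0, 0), constantICF(900))  # B 900-1350 px, C 900-2250 px
#' @export
buildZones <- function(discCenter, icf) {
  stopifnot(is(icf, "ConversionFactor"))
  ref <- icf@referenceOdUm
  rInner <- 1.0 * ref / icf@value
  new("MeasurementZones", center = as.numeric(discCenter),
      zoneB = c(rInner, 1.5 * ref / icf@value),
      zoneC = c(rInner, 2.5 * ref / icf@value))
}
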