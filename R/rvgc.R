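#' Compute the twelve retinal vessel geometric characteristics
#'
#' The full measurement of one image under one conversion factor: vessel
#' widths are measured in the zone B annulus (CRAE, CRVE, AVR) and over
#' the full zone C annulus (CRAEoC, CRVEoC, AVRoC) via the six largest
#' vessels per type and the Knudtson pairing formula, converted to um;
#' the box-counting fractal dimension is taken on the zone C skeleton
#' (combined, arteries-only, veins-only); simple tortuosity is averaged
#' per type over the vessel segments in zone C (STt over all segments,
#' unweighted).  Big-six shortfalls are padded by repeating the smallest
#' measured width and flagged.
#'
#' @param map a [VesselMap-class].
#' @param icf the [ConversionFactor-class] to apply; it fixes both the
#'   pixel size of the measurement zones and the px-to-um conversion.
#' @param disc optional [OpticDisc-class]; defaults to the disc recorded
#'   in the map metadata.
#' @param pointTable optional precomputed [skeletonPointTable()]; pass it
#'   when measuring the same image under several conversion factors.
#' @param minPoints minimum within-annulus skeleton points per vessel.
#' @return an [RVGCResult-class].
#' @examples
#' eye <- generateEye(eyeParams(odDiameterUmMean = 900, odDiameterUmSd = 0,
#'                              trueScale = 3), seed = 11)
#' map <- renderView(eye, viewSpec("ODC"))
#' res <- computeRVGC(map, individualICF(opticDiscFromMap(map)))
#' res
#' @export
computeRVGC <- function(map, icf, disc = NULL, pointTable = NULL,
                        minPoints = 10L) {
  stopifnot(is(map, "VesselMap"), is(icf, "ConversionFactor"))
  if (is.null(disc)) disc <- opticDiscFromMap(map)
  zones <- buildZones(odCenter(disc), icf)
  if (is.null(pointTable)) pointTable <- skeletonPointTable(map)
  measB <- extractVessels(map, zones, "B", pointTable, minPoints)
  measC <- extractVessels(map, zones, "C", pointTable, minPoints)
  flags <- unique(c(attr(measB, "flags"), attr(measC, "flags")))

  equivalent <- function(meas, tp, zoneTag) {
    m <- meas[meas$vesselType == tp, , drop = FALSE]
    if (!nrow(m)) return(NA_real_)
    six <- selectBigSix(meas, tp)
    w <- six$widths
    if (six$shortfall) {
      flags <<- c(flags, sprintf("big_six_shortfall_%s_zone%s", tp, zoneTag))
      w <- c(w, rep(min(w), 6L - length(w)))
    }
    pxToUm(knudtsonEquivalent(w, tp), icf)
  }
  crae <- equivalent(measB, "artery", "B")
  crve <- equivalent(measB, "vein", "B")
  craeC <- equivalent(measC, "artery", "C")
  crveC <- equivalent(measC, "vein", "C")

  inC <- pointTable$radiusPx >= zones@zoneC[1] &
    pointTable$radiusPx <= zones@zoneC[2]
  dfOf <- function(sel) {
    co <- pointTable[sel, c("x", "y"), drop = FALSE]
    if (nrow(co) < 50L) return(NA_real_)
    tryCatch(fractalDimensionBoxcount(as.matrix(co)),
             error = function(e) NA_real_)
  }
  df <- dfOf(inC)
  dfa <- dfOf(inC & pointTable$vesselType == "artery")
  dfv <- dfOf(inC & pointTable$vesselType == "vein")

  st <- measC$tortuosity
  stByType <- function(tp) {
    v <- st[measC$vesselType == tp & !is.na(st)]
    if (length(v)) mean(v) else NA_real_
  }
  values <- c(
    CRAE = crae, CRVE = crve,
    AVR = if (is.finite(crae) && is.finite(crve)) crae / crve else NA_real_,
    CRAEoC = craeC, CRVEoC = crveC,
    AVRoC = if (is.finite(craeC) && is.finite(crveC)) craeC / crveC
            else NA_real_,
    Df = df, Dfa = dfa, Dfv = dfv,
    STt = if (any(!is.na(st))) mean(st, na.rm = TRUE) else NA_real_,
    STa = stByType("artery"), STv = stByType("vein"))
  new("RVGCResult", values = values, icfUsed = icf, flags = unique(flags))
}

#' Optic disc recorded in a vessel map's metadata
#'
#' @param map a [VesselMap-class].
#' @return an [OpticDisc-class] built from the metadata disc center and
#'   rendered horizontal/vertical diameters.
#' @export
opticDiscFromMap <- function(map) {
  m <- map@meta
  opticDisc(m$odCenter, m$odHDiameterPx, m$odVDiameterPx)
}
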