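# Per-vessel measurement from a labeled raster: skeletonization, width by
# distance transform, simple tortuosity, and big-six selection.

#' Skeleton point table of a vessel map
#'
#' Identifies vessels as connected components of the artery and vein
#' labels, skeletonizes each label mask (Zhang-Suen thinning), and
#' tabulates every skeleton point with its local vessel width (twice the
#' Euclidean distance-transform value at the point) and its radial
#' distance from the optic disc center.  All zone-dependent measurements
#' are aggregations of this table, so it is computed once per image and
#' reused across conversion factors.
#'
#' @param map a [VesselMap-class].
#' @return `data.frame` with columns `vesselId` (label type + component),
#'   `vesselType`, `x`, `y`, `widthPx`, `radiusPx`.
#' @seealso [extractVessels()], [computeRVGC()]
#' @export
skeletonPointTable <- function(map) {
  stopifnot(is(map, "VesselMap"))
  labels <- map@labels
  dc <- map@meta$odCenter
  # crop to the occupied region; heavy raster work scales with content
  occ <- which(labels != 0L, arr.ind = TRUE)
  if (!nrow(occ))
    return(data.frame(vesselId = character(), vesselType = character(),
                      x = numeric(), y = numeric(), widthPx = numeric(),
                      radiusPx = numeric()))
  x0 <- max(1L, min(occ[, 1]) - 2L); x1 <- min(nrow(labels), max(occ[, 1]) + 2L)
  y0 <- max(1L, min(occ[, 2]) - 2L); y1 <- min(ncol(labels), max(occ[, 2]) + 2L)
  crop <- labels[x0:x1, y0:y1]
  # widths are bounded by a fraction of the disc diameter; cap the
  # nearest-background search accordingly
  maxR <- max(16, 0.25 * (map@meta$odHDiameterPx + map@meta$odVDiameterPx) / 2)
  out <- vector("list", 2L)
  for (code in 1:2) {
    mask <- crop == code
    if (!any(mask)) next
    comp <- EBImage::bwlabel(mask)
    sk <- cpp_thin(mask)
    idx <- which(sk)
    if (!length(idx)) next
    co <- arrayInd(idx, dim(mask))
    d <- cpp_ridge_halfwidth(mask, co[, 1], co[, 2], maxR)
    px <- co[, 1] + x0 - 1L
    py <- co[, 2] + y0 - 1L
    res <- data.frame(
      vesselId = sprintf("%s_%d", c("a", "v")[code], as.integer(comp[idx])),
      vesselType = c("artery", "vein")[code],
      x = px, y = py,
      widthPx = 2 * d,
      radiusPx = sqrt((px - dc[1])^2 + (py - dc[2])^2))
    out[[code]] <- res[is.finite(res$widthPx), , drop = FALSE]
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

# Tortuosity of one skeleton component restricted to an annulus: trace the
# shortest 8-connected path between the innermost and outermost points,
# smooth the pixel chain (running mean) to remove rasterization jitter,
# subsample, and take arc length over chord length.
.componentTortuosity <- function(x, y, radius, smoothWindow = 9L,
                                 subsample = 5L) {
  i0 <- which.min(radius); i1 <- which.max(radius)
  path <- cpp_trace_path(cbind(as.integer(x), as.integer(y)), i0, i1)
  if (nrow(path) < 3L) return(NA_real_)
  xs <- .runmean(path[, 1], smoothWindow)
  ys <- .runmean(path[, 2], smoothWindow)
  keep <- unique(c(seq(1L, length(xs), by = subsample), length(xs)))
  simpleTortuosity(cbind(xs[keep], ys[keep]))
}

.runmean <- function(v, w) {
  if (length(v) <= w) return(v)
  h <- (w - 1L) %/% 2L
  pad <- c(rep(v[1], h), v, rep(v[length(v)], h))
  as.numeric(stats::filter(pad, rep(1 / w, w), sides = 2))[(h + 1):(h + length(v))]
}

#' Measure vessels inside a measurement annulus
#'
#' Aggregates the skeleton point table over one measurement zone: for
#' every vessel (connected component) with enough skeleton points inside
#' the annulus, the mean cross-sectional width and the simple tortuosity
#' of its within-annulus centerline.  Vessel types with no measurable
#' vessel are reported through the `flags` attribute rather than as an
#' error, mirroring how shortfalls are flagged rather than fixed.
#'
#' @param map a [VesselMap-class].
#' @param zones a [MeasurementZones-class] (see [buildZones()]).
#' @param zone `"B"` or `"C"`: which annulus to measure in.
#' @param pointTable optional precomputed [skeletonPointTable()].
#' @param minPoints minimum skeleton points inside the annulus for a
#'   component to count as a vessel segment (short-branch noise guard).
#' @return `data.frame` with columns `vesselId`, `vesselType`, `widthPx`,
#'   `tortuosity`, `nPoints`, `meanRadiusPx`, `angleDeg`, `zone`; the
#'   `flags` attribute carries quality flags.
#' @export
extractVessels <- function(map, zones, zone = c("B", "C"),
                           pointTable = NULL, minPoints = 10L) {
  zone <- match.arg(zone)
  stopifnot(is(zones, "MeasurementZones"))
  if (is.null(pointTable)) pointTable <- skeletonPointTable(map)
  ann <- if (zone == "B") zones@zoneB else zones@zoneC
  dc <- zones@center
  tbl <- pointTable[pointTable$radiusPx >= ann[1] &
                    pointTable$radiusPx <= ann[2], , drop = FALSE]
  flags <- character()
  if (!is.null(map@meta$clipFracZoneC) && zone == "C" &&
      map@meta$clipFracZoneC > 0.005)
    flags <- c(flags, sprintf("zoneC_clipped_%.3f", map@meta$clipFracZoneC))
  res <- lapply(split(tbl, tbl$vesselId), function(g) {
    if (nrow(g) < minPoints) return(NULL)
    data.frame(vesselId = g$vesselId[1], vesselType = g$vesselType[1],
               widthPx = mean(g$widthPx),
               tortuosity = .componentTortuosity(g$x, g$y, g$radiusPx),
               nPoints = nrow(g), meanRadiusPx = mean(g$radiusPx),
               angleDeg = atan2(mean(g$y) - dc[2], mean(g$x) - dc[1]) *
                 180 / pi)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(vesselId = character(), vesselType = character(),
                      widthPx = numeric(), tortuosity = numeric(),
                      nPoints = integer(), meanRadiusPx = numeric(),
                      angleDeg = numeric())
  rownames(res) <- NULL
  res$zone <- zone
  for (tp in c("artery", "vein"))
    if (!any(res$vesselType == tp))
      flags <- c(flags, sprintf("no_%s_zone%s", tp, zone))
  attr(res, "flags") <- flags
  res
}

#' Select the six largest vessels of a type
#'
#' The "big six": the six largest widths of the requested type, in
#' descending order, with ties broken by vessel id for determinism.  When
#' fewer than six vessels were measured all are returned and the
#' shortfall is flagged (the manual remedy of adding vessels by hand has
#' no batch analogue).
#'
#' @param measurements data.frame from [extractVessels()].
#' @param vesselType `"artery"` or `"vein"`.
#' @return list with `widths` (descending), `vesselIds`, and logical
#'   `shortfall`.
#' @export
selectBigSix <- function(measurements, vesselType = c("artery", "vein")) {
  vesselType <- match.arg(vesselType)
  m <- measurements[measurements$vesselType == vesselType, , drop = FALSE]
  if (!nrow(m)) stop("no measurements of type ", vesselType)
  m <- m[order(-m$widthPx, m$vesselId), , drop = FALSE]
  k <- min(6L, nrow(m))
  list(widths = m$widthPx[seq_len(k)], vesselIds = m$vesselId[seq_len(k)],
       shortfall = nrow(m) < 6L)
}

#' Central retinal equivalent by the Knudtson big-six formula
#'
#' Iterative pairing of the six largest vessel widths: at every round the
#' widths are sorted and the largest is paired with the smallest, each
#' pair combining to `coef * sqrt(w1^2 + w2^2)` with `coef = 0.88` for
#' arteries and `0.95` for veins; an odd middle value is carried to the
#' next round.  Three rounds reduce six widths to the single equivalent.
#'
#' @param widths exactly six positive widths, px (order irrelevant).
#' @param vesselType `"artery"` or `"vein"`.
#' @return the equivalent width in px; convert with [pxToUm()] for
#'   reporting.
#' @examples
#' knudtsonEquivalent(rep(10, 6), "artery")  # 17.485
#' knudtsonEquivalent(rep(10, 6), "vein")    # 21.377
#' @export
knudtsonEquivalent <- function(widths, vesselType = c("artery", "vein")) {
  vesselType <- match.arg(vesselType)
  if (length(widths) != 6L)
    stop("exactly six widths are required (pad shortfalls before calling)")
  if (any(!is.finite(widths) | widths <= 0))
    stop("widths must be positive")
  coef <- if (vesselType == "artery") 0.88 else 0.95
  w <- widths
  while (length(w) > 1L) {
    w <- sort(w, decreasing = TRUE)
    n <- length(w)
    k <- n %/% 2L
    paired <- coef * sqrt(w[seq_len(k)]^2 + w[n + 1L - seq_len(k)]^2)
    w <- if (n %% 2L) c(paired, w[k + 1L]) else paired
  }
  w
}

#' Arteriovenous ratio
#'
#' `CRAE / CRVE`; dimensionless, so the conversion factor cancels.
#'
#' @param crae,crve central retinal artery and vein equivalents (same
#'   units); `crve` must be positive.
#' @return the ratio.
#' @export
avr <- function(crae, crve) {
  if (any(crve <= 0, na.rm = TRUE)) stop("crve must be positive")
  crae / crve
}

#' Simple tortuosity of a polyline
#'
#' The ratio of the tracked path length of a vessel segment to the
#' straight-line (chord) length between its endpoints; 1 for a straight
#' segment.
#'
#' @param centerline n x 2 matrix of (x, y) points, n >= 2.
#' @return tortuosity, >= 1 up to numerical precision.
#' @examples
#' th <- seq(0, pi, length.out = 4000)
#' simpleTortuosity(cbind(cos(th), sin(th)))  # half circle: pi/2
#' @export
simpleTortuosity <- function(centerline) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L)
    stop("centerline must be an n x 2 matrix with n >= 2")
  chord <- sqrt(sum((centerline[nrow(centerline), ] - centerline[1, ])^2))
  if (chord <= .Machine$double.eps)
    stop("coincident endpoints: chord length is zero")
  arc <- sum(sqrt(rowSums(diff(centerline)^2)))
  arc / chord
}
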