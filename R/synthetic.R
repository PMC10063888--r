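# Synthetic fundus vasculature: ground-truthed eyes rendered as labeled
# vessel maps under controllable centering, resolution and field of view.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default generation parameters for synthetic eyes
#'
#' The defaults emulate the disc-size spread and vessel calibers of a
#' scanned-film screening cohort: disc diameters of 1800 +/- 135 um laid
#' out at 2.4 um per native pixel (so the mean disc is 750 px and the
#' individual conversion factor 2.4 +/- 0.18), seven arterioles and seven
#' venules per eye with calibers drawn per type so that the big-six
#' equivalents land near CRAE 163 um / CRVE 219 um and the arteriovenous
#' ratio below 1, and mild sinusoidal tortuosity giving simple tortuosity
#' around 1.08-1.10.
#'
#' @param odDiameterUmMean,odDiameterUmSd disc diameter distribution, um.
#' @param odAspectSd SD of the vertical/horizontal disc diameter ratio.
#' @param trueScale um per native pixel of the ground-truth layout.
#' @param nArteries,nVeins vessels per type; at least 6 each.
#' @param arteryWidthUmMean,arteryWidthUmSd,veinWidthUmMean,veinWidthUmSd
#'   caliber distributions, um.
#' @param widthMinUm lower truncation for drawn calibers, um.
#' @param tortAmplitudeRangePx,tortWavelengthRangePx uniform ranges for
#'   the sinusoidal perpendicular displacement, native px.  Set the
#'   amplitude range to `c(0, 0)` for perfectly straight radial vessels.
#' @param taperRate fractional caliber loss per disc diameter of radial
#'   distance beyond the disc margin; 0 (constant caliber) by default.
#' @param angleJitterDeg uniform jitter of the evenly spaced vessel exit
#'   angles, degrees.
#' @return named list of parameters for [generateEye()].
#' @export
eyeParams <- function(odDiameterUmMean = 1800, odDiameterUmSd = 135,
                      odAspectSd = 0.02, trueScale = 2.4,
                      nArteries = 7L, nVeins = 7L,
                      arteryWidthUmMean = 89, arteryWidthUmSd = 12,
                      veinWidthUmMean = 95, veinWidthUmSd = 13,
                      widthMinUm = 40,
                      tortAmplitudeRangePx = c(24, 52),
                      tortWavelengthRangePx = c(330, 470),
                      taperRate = 0, angleJitterDeg = 6) {
  as.list(environment())
}

truncNorm <- function(n, mean, sd, lower, upper = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

#' Generate a ground-truthed synthetic eye
#'
#' Draws a disc diameter, then lays out `nArteries + nVeins` vessels as
#' radial rays with alternating type, evenly spaced exit angles (with
#' jitter) and a sinusoidal perpendicular displacement.  Centerlines start
#' inside the disc (0.45 disc diameters from its center) and extend to
#' 3.1 disc diameters, well beyond the outer zone C boundary.  The eye is
#' fully determined by `(params, seed)`.
#'
#' @param params parameter list from [eyeParams()].
#' @param seed integer seed; required.
#' @return a [SyntheticEye-class].
#' @examples
#' eye <- generateEye(seed = 1)
#' eye
#' @export
generateEye <- function(params = eyeParams(), seed) {
  if (missing(seed)) stop("a seed is required")
  p <- utils::modifyList(eyeParams(), params)
  if (p$nArteries < 6L || p$nVeins < 6L)
    stop("at least 6 vessels per type are required")
  if (p$odDiameterUmMean <= 0 || p$trueScale <= 0 ||
      p$arteryWidthUmMean <= 0 || p$veinWidthUmMean <= 0)
    stop("distribution parameters must be positive")
  withSeed(seed, {
    odUm <- truncNorm(1, p$odDiameterUmMean, p$odDiameterUmSd,
                      max(1, p$odDiameterUmMean - 3 * p$odDiameterUmSd),
                      p$odDiameterUmMean + 3 * p$odDiameterUmSd)
    odAspect <- truncNorm(1, 1, p$odAspectSd, 0.9, 1.1)
    odPx <- odUm / p$trueScale
    n <- p$nArteries + p$nVeins
    types <- rep(c("artery", "vein"), length.out = n)
    baseAngle <- (seq_len(n) - 1) * 360 / n +
      runif(n, -p$angleJitterDeg, p$angleJitterDeg)
    widths <- ifelse(
      types == "artery",
      truncNorm(n, p$arteryWidthUmMean, p$arteryWidthUmSd, p$widthMinUm),
      truncNorm(n, p$veinWidthUmMean, p$veinWidthUmSd, p$widthMinUm))
    amp <- runif(n, p$tortAmplitudeRangePx[1], p$tortAmplitudeRangePx[2])
    wav <- runif(n, p$tortWavelengthRangePx[1], p$tortWavelengthRangePx[2])
    phase <- runif(n, 0, 2 * pi)
    vessels <- vector("list", n)
    r0 <- 0.45 * odPx
    r1 <- 3.1 * odPx
    for (i in seq_len(n)) {
      t <- seq(0, r1 - r0, by = 0.5)
      theta <- baseAngle[i] * pi / 180
      u <- c(cos(theta), sin(theta))
      perp <- c(-u[2], u[1])
      off <- amp[i] * sin(2 * pi * t / wav[i] + phase[i])
      # ramp the displacement in over the first half wavelength so the
      # vessel exits the disc radially
      ramp <- pmin(1, t / (wav[i] / 2))
      off <- off * ramp
      cl <- cbind((r0 + t) * u[1] + off * perp[1],
                  (r0 + t) * u[2] + off * perp[2])
      vessels[[i]] <- new("GroundTruthVessel", vesselId = i,
                          vesselType = types[i], centerline = cl,
                          widthUm = widths[i], taperRate = p$taperRate,
                          tortAmplitudePx = amp[i], tortWavelengthPx = wav[i])
    }
    new("SyntheticEye", trueScale = p$trueScale, odCenter = c(0, 0),
        odDiameterUm = odUm, odAspect = odAspect, vessels = vessels,
        seed = as.integer(seed), params = p)
  })
}

#' Mirror an eye into its fellow (contralateral) eye
#'
#' Produces the paired eye of the same patient for the right-vs-left
#' laterality analysis: same disc size and the same vessel calibers (up
#' to independent Gaussian noise), horizontally mirrored.  By default the
#' fellow eye's vessel courses (exit angles, tortuosity) are drawn
#' afresh, since the fellow vasculature shares calibers but not exact
#' geometry; with `independentShapes = FALSE` the result is the exact
#' mirror image.
#'
#' @param eye a [SyntheticEye-class].
#' @param widthNoiseUm SD of independent Gaussian caliber noise, um.
#' @param seed integer seed for the fellow eye.
#' @param independentShapes draw fresh vessel courses (default) or mirror
#'   the input geometry exactly.
#' @return a new [SyntheticEye-class].
#' @export
mirrorEye <- function(eye, widthNoiseUm = 2, seed, independentShapes = TRUE) {
  if (missing(seed)) stop("a seed is required")
  base <- if (independentShapes) {
    p <- utils::modifyList(eye@params,
                           list(odDiameterUmMean = eye@odDiameterUm,
                                odDiameterUmSd = 0))
    generateEye(p, seed = seed)
  } else eye
  noise <- withSeed(seed, rnorm(length(base@vessels), 0, widthNoiseUm))
  widths <- vapply(eye@vessels, function(v) v@widthUm, 0)
  vs <- Map(function(v, w0, dw) {
    cl <- v@centerline
    cl[, 1] <- -cl[, 1]
    initialize(v, centerline = cl,
               widthUm = max(eye@params$widthMinUm, w0 + dw))
  }, base@vessels, widths, noise)
  initialize(base, vessels = unname(vs), seed = as.integer(seed))
}

#' Construct a view specification
#'
#' @param centering `"ODC"` (optic-disc-centered) or `"MC"`
#'   (macula-centered; the window is centered on the fovea, 2.5 disc
#'   diameters temporal to the disc on the horizontal meridian).
#' @param fovDeg field of view, degrees; the disc is taken to subtend 5
#'   degrees, so the field caps the rendered window.
#' @param outputSize explicit (width, height) in px, or NA for the
#'   default window (tightest frame containing zone C, capped by the
#'   field of view).
#' @param scaleFactor resampling factor relative to the native render
#'   scale; 2 doubles every pixel dimension.
#' @return a [ViewSpec-class].
#' @export
viewSpec <- function(centering = c("ODC", "MC"), fovDeg = 60,
                     outputSize = NA_real_, scaleFactor = 1) {
  new("ViewSpec", centering = match.arg(centering),
      fovDeg = as.numeric(fovDeg), outputSize = as.numeric(outputSize),
      scaleFactor = as.numeric(scaleFactor))
}

# Distance from a point to an axis-aligned rectangle [1, W] x [1, H].
.rectDist <- function(pt, W, H) {
  dx <- max(1 - pt[1], 0, pt[1] - W)
  dy <- max(1 - pt[2], 0, pt[2] - H)
  sqrt(dx^2 + dy^2)
}

# Fraction of an annulus area lying outside the frame, by polar quadrature.
.annulusClipFrac <- function(center, rIn, rOut, W, H, nr = 24, na = 180) {
  r <- seq(rIn, rOut, length.out = nr + 1)
  rMid <- (r[-1] + r[-length(r)]) / 2
  a <- seq(0, 2 * pi, length.out = na + 1)[-1]
  x <- outer(rMid, cos(a)) + center[1]
  y <- outer(rMid, sin(a)) + center[2]
  outside <- x < 0.5 | x > W + 0.5 | y < 0.5 | y > H + 0.5
  wt <- matrix(rMid, nr, na)
  sum(wt * outside) / sum(wt)
}

#' Render a synthetic eye as a labeled vessel map
#'
#' Rasterizes the ground-truth geometry at `scaleFactor` times the native
#' resolution (a change of resolution is modeled as an ideal resampling:
#' all coordinates and widths scale linearly) into a label image with
#' codes 0 background, 1 artery, 2 vein, 3 optic disc.  Vessels are drawn
#' as bands of their true width (`width_px = width_um / true_scale *
#' scale_factor`); the disc is drawn last, on top.  Metadata records the
#' centering, scale factor, disc geometry as rendered (bounding-box
#' diameters of the disc label), the ground-truth vessel table, and the
#' fraction of the eye's own zone C annulus clipped by the frame.
#'
#' @param eye a [SyntheticEye-class].
#' @param view a [ViewSpec-class].
#' @return a [VesselMap-class].
#' @examples
#' eye <- generateEye(eyeParams(odDiameterUmMean = 900, odDiameterUmSd = 0),
#'                    seed = 1)
#' map <- renderView(eye, viewSpec("ODC"))
#' map
#' @export
renderView <- function(eye, view = viewSpec("ODC")) {
  validObject(eye); validObject(view)
  s <- view@scaleFactor
  odPx <- eye@odDiameterUm / eye@trueScale * s   # rendered disc diameter
  pxPerDeg <- odPx / 5                           # the disc subtends 5 deg
  fovHw <- view@fovDeg / 2 * pxPerDeg
  if (view@centering == "ODC") {
    winC <- c(0, 0)
    tight <- c(3.0, 3.0) * odPx
  } else {
    winC <- c(2.5 * odPx, 0)                     # fovea, temporal = +x
    tight <- c(5.3, 3.0) * odPx
  }
  hw <- pmin(tight, fovHw)
  if (all(is.finite(view@outputSize))) {
    W <- as.integer(round(view@outputSize[1]))
    H <- as.integer(round(view@outputSize[2]))
  } else {
    W <- 2L * as.integer(floor(hw[1])) + 1L
    H <- 2L * as.integer(floor(hw[2])) + 1L
  }
  if (W < 16L || H < 16L) stop("output size too small to render")
  # disc center in pixel coordinates of the frame
  cpx <- c((W + 1) / 2, (H + 1) / 2)
  disc <- -winC + cpx
  # the frame must intersect the zone B annulus (radii 1.0-1.5 disc
  # diameters): it may neither lie beyond the outer radius nor fit
  # entirely inside the inner circle
  corners <- rbind(c(1, 1), c(W, 1), c(1, H), c(W, H))
  maxCorner <- sqrt(max(rowSums(sweep(corners, 2, disc)^2)))
  if (.rectDist(disc, W, H) >= 1.5 * odPx || maxCorner <= 1.0 * odPx)
    stop("output size too small to contain zone B")
  labels <- matrix(0L, W, H)
  odNative <- eye@odDiameterUm / eye@trueScale
  for (v in eye@vessels) {
    cl <- v@centerline
    rad <- sqrt(rowSums(cl^2))
    wUm <- v@widthUm *
      pmax(0.15, 1 - v@taperRate * pmax(0, rad / odNative - 0.5))
    wPx <- wUm / eye@trueScale * s
    cpp_stamp_band(labels, cl[, 1] * s + disc[1], cl[, 2] * s + disc[2],
                   wPx / 2,
                   if (v@vesselType == "artery") 1L else 2L)
  }
  cpp_fill_ellipse(labels, disc[1], disc[2], (odPx - 1) / 2,
                   (odPx * eye@odAspect - 1) / 2, 3L)
  # disc geometry as rendered (what an operator would measure)
  dpx <- which(labels == 3L, arr.ind = TRUE)
  if (nrow(dpx)) {
    odH <- diff(range(dpx[, 1])) + 1
    odV <- diff(range(dpx[, 2])) + 1
  } else {
    odH <- odPx; odV <- odPx * eye@odAspect
  }
  discClipped <- !nrow(dpx) || min(dpx) <= 1L ||
    max(dpx[, 1]) >= W || max(dpx[, 2]) >= H
  meanOD <- (odH + odV) / 2
  truth <- data.frame(
    vesselId = vapply(eye@vessels, function(v) v@vesselId, 0L),
    vesselType = vapply(eye@vessels, function(v) v@vesselType, ""),
    widthUm = vapply(eye@vessels, function(v) v@widthUm, 0))
  meta <- list(
    centering = view@centering, fovDeg = view@fovDeg, scaleFactor = s,
    odCenter = disc, odHDiameterPx = odH, odVDiameterPx = odV,
    seed = eye@seed, umPerPx = eye@trueScale / s,
    discClipped = discClipped,
    clipFracZoneC = .annulusClipFrac(disc, meanOD, 2.5 * meanOD, W, H),
    vesselTruth = truth)
  new("VesselMap", labels = labels, meta = meta)
}
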