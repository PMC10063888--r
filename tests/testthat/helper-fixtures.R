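# Shared fixtures: a reduced eye (300 px disc at 3 um/px) keeps raster
# tests fast while exercising the same geometry as the full-size default.

smallEyeParams <- function(...) {
  utils::modifyList(
    eyeParams(odDiameterUmMean = 900, odDiameterUmSd = 60, trueScale = 3),
    list(...))
}

smallStraightParams <- function(...) {
  smallEyeParams(tortAmplitudeRangePx = c(0, 0), ...)
}

# A hand-built vessel map: one horizontal band of the requested type and
# width through a disc, enough for degenerate-input tests.
bandMap <- function(widthPx = 31, code = 2L, size = 901L, discPx = 300) {
  labels <- matrix(0L, size, size)
  c0 <- (size + 1L) %/% 2L
  half <- (widthPx - 1) / 2
  labels[, (c0 - half):(c0 + half)] <- code
  rvgc:::cpp_fill_ellipse(labels, c0, c0, (discPx - 1) / 2, (discPx - 1) / 2, 3L)
  new("VesselMap", labels = labels,
      meta = list(centering = "ODC", fovDeg = 60, scaleFactor = 1,
                  odCenter = c(c0, c0), odHDiameterPx = discPx,
                  odVDiameterPx = discPx, seed = 0L))
}

# Independent brute-force reimplementation of the iterative pairing
# (recursive, ascending sort) used as the oracle for the equivalents.
knudtsonOracle <- function(w, coef) {
  if (length(w) == 1L) return(w)
  w <- sort(w)
  n <- length(w)
  half <- n %/% 2L
  paired <- vapply(seq_len(half),
                   function(i) coef * sqrt(w[i]^2 + w[n + 1L - i]^2), 0)
  knudtsonOracle(c(paired, if (n %% 2L) w[half + 1L]), coef)
}
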