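test_that("equal-caliber eyes reproduce the pairing-coefficient ratio", {
  # with identical artery and vein calibers the arteriovenous ratio is
  # fixed by the pairing coefficients (0.88 vs 0.95 chains), about 0.818
  p <- smallStraightParams(arteryWidthUmMean = 110, arteryWidthUmSd = 0,
                           veinWidthUmMean = 110, veinWidthUmSd = 0)
  eye <- generateEye(p, seed = 21)
  map <- renderView(eye, viewSpec("ODC"))
  res <- computeRVGC(map, individualICF(opticDiscFromMap(map)))
  ratio <- knudtsonEquivalent(rep(1, 6), "artery") /
    knudtsonEquivalent(rep(1, 6), "vein")
  expect_equal(unname(rvgcValues(res)["AVR"]), ratio, tolerance = 0.02)
  expect_equal(unname(rvgcValues(res)["AVRoC"]), ratio, tolerance = 0.02)
})

test_that("equivalents in um are stable across resolutions under the
           individual factor", {
  eye <- generateEye(smallEyeParams(), seed = 22)
  m1 <- renderView(eye, viewSpec("ODC", scaleFactor = 1))
  m2 <- renderView(eye, viewSpec("ODC", scaleFactor = 1.5))
  r1 <- computeRVGC(m1, individualICF(opticDiscFromMap(m1)))
  r2 <- computeRVGC(m2, individualICF(opticDiscFromMap(m2)))
  for (v in c("CRAE", "CRVE", "CRAEoC", "CRVEoC")) {
    rel <- abs(rvgcValues(r2)[v] - rvgcValues(r1)[v]) / rvgcValues(r1)[v]
    expect_lt(unname(rel), 0.02)
  }
  # dimensionless characteristics are resolution-stable too
  expect_equal(unname(rvgcValues(r1)["AVR"]), unname(rvgcValues(r2)["AVR"]),
               tolerance = 0.02)
  expect_equal(unname(rvgcValues(r1)["STt"]), unname(rvgcValues(r2)["STt"]),
               tolerance = 0.005)
})

test_that("a disc at the cohort mean makes both factors agree", {
  eye <- generateEye(smallEyeParams(odDiameterUmSd = 0), seed = 23)
  map <- renderView(eye, viewSpec("ODC"))
  odPx <- meanODDiameter(opticDiscFromMap(map))
  pt <- skeletonPointTable(map)
  ri <- computeRVGC(map, individualICF(odPx), pointTable = pt)
  rc <- computeRVGC(map, constantICF(odPx), pointTable = pt)
  expect_equal(rvgcValues(ri), rvgcValues(rc))
})

test_that("with tapering vessels a larger factor measures wider vessels", {
  # a larger conversion factor shrinks the pixel annulus toward the
  # disc, where tapering vessels are anatomically wider
  p <- smallStraightParams(taperRate = 0.25, odDiameterUmSd = 0)
  eye <- generateEye(p, seed = 24)
  map <- renderView(eye, viewSpec("ODC"))
  pt <- skeletonPointTable(map)
  odPx <- meanODDiameter(opticDiscFromMap(map))
  icfs <- 900 / odPx * c(0.8, 1.0, 1.25)
  meanW <- vapply(icfs, function(v) {
    zones <- buildZones(mapMeta(map)$odCenter,
                        new("ConversionFactor", value = v,
                            kind = "constant", referenceOdUm = 900))
    mean(extractVessels(map, zones, "B", pointTable = pt)$widthPx)
  }, 0)
  expect_true(all(diff(meanW) > 0))
})

test_that("shortfalls below six vessels are padded and flagged", {
  map <- bandMap(code = 1L)  # two artery components only
  res <- computeRVGC(map, individualICF(opticDiscFromMap(map)))
  expect_true(any(grepl("big_six_shortfall_artery", rvgcFlags(res))))
  expect_true(any(grepl("no_vein", rvgcFlags(res))))
  expect_true(is.finite(rvgcValues(res)["CRAE"]))
  expect_true(is.na(rvgcValues(res)["CRVE"]))
  expect_true(is.na(rvgcValues(res)["AVR"]))
})
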