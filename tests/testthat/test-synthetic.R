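test_that("eye generation is deterministic in (params, seed)", {
  e1 <- generateEye(smallEyeParams(), seed = 1)
  e2 <- generateEye(smallEyeParams(), seed = 1)
  expect_identical(serialize(e1, NULL, version = 2),
                   serialize(e2, NULL, version = 2))
  e3 <- generateEye(smallEyeParams(), seed = 2)
  expect_false(identical(e1@odDiameterUm, e3@odDiameterUm))
})

test_that("generated eyes satisfy their structural invariants", {
  for (s in c(3, 11, 42)) {
    eye <- generateEye(smallEyeParams(), seed = s)
    types <- vapply(vessels(eye), function(v) v@vesselType, "")
    expect_gte(sum(types == "artery"), 6)
    expect_gte(sum(types == "vein"), 6)
    odPx <- eye@odDiameterUm / eye@trueScale
    for (v in vessels(eye)) {
      r <- sqrt(rowSums(v@centerline^2))
      expect_lt(r[1], 0.6 * odPx)           # starts near the disc
      expect_gt(max(r), 2.5 * odPx)         # extends beyond zone C
      expect_lte(max(sqrt(rowSums(diff(v@centerline)^2))), 1 + 1e-6)
    }
  }
  expect_error(generateEye(smallEyeParams(nArteries = 4L), seed = 1),
               "at least 6")
  expect_error(generateEye(smallEyeParams(odDiameterUmMean = -1), seed = 1),
               "positive")
})

test_that("zero tortuosity amplitude yields straight radial vessels", {
  eye <- generateEye(smallStraightParams(), seed = 7)
  for (v in vessels(eye)) {
    cl <- v@centerline
    a <- cl[1, ]; d <- cl[nrow(cl), ] - a
    d <- d / sqrt(sum(d^2))
    dev <- abs((cl[, 1] - a[1]) * d[2] - (cl[, 2] - a[2]) * d[1])
    expect_lt(max(dev), 1)
  }
  map <- renderView(eye, viewSpec("ODC"))
  res <- computeRVGC(map, individualICF(opticDiscFromMap(map)))
  expect_equal(unname(rvgcValues(res)["STt"]), 1, tolerance = 1e-3)
  expect_equal(unname(rvgcValues(res)["STa"]), 1, tolerance = 1e-3)
  expect_equal(unname(rvgcValues(res)["STv"]), 1, tolerance = 1e-3)
})

test_that("configured caliber distributions keep arteries narrower", {
  ratios <- vapply(1:100, function(s) {
    eye <- generateEye(seed = s)
    w <- vapply(vessels(eye), function(v) v@widthUm, 0)
    tp <- vapply(vessels(eye), function(v) v@vesselType, "")
    mean(w[tp == "artery"]) / mean(w[tp == "vein"])
  }, 0)
  expect_gt(mean(ratios), 0.6)
  expect_lt(mean(ratios), 0.95)
})

test_that("rendered band width matches the ground truth caliber", {
  # 150 um at 2.5 um/px should render as a 60 px band
  p <- smallStraightParams(trueScale = 2.5, odDiameterUmMean = 900,
                           odDiameterUmSd = 0,
                           arteryWidthUmMean = 150, arteryWidthUmSd = 0,
                           veinWidthUmMean = 150, veinWidthUmSd = 0)
  eye <- generateEye(p, seed = 2)
  map <- renderView(eye, viewSpec("ODC"))
  pt <- skeletonPointTable(map)
  odPx <- meanODDiameter(opticDiscFromMap(map))
  mid <- pt[pt$radiusPx > 1.2 * odPx & pt$radiusPx < 2.2 * odPx, ]
  perVessel <- tapply(mid$widthPx, mid$vesselId, mean)
  expect_true(all(perVessel >= 59 & perVessel <= 61))
})

test_that("resampling scales the rendered geometry linearly", {
  eye <- generateEye(smallEyeParams(), seed = 4)
  m1 <- renderView(eye, viewSpec("ODC", scaleFactor = 1))
  m2 <- renderView(eye, viewSpec("ODC", scaleFactor = 2))
  od1 <- meanODDiameter(opticDiscFromMap(m1))
  od2 <- meanODDiameter(opticDiscFromMap(m2))
  expect_equal(od2 / od1, 2, tolerance = 0.02)
  expect_equal(dim(vesselLabels(m2))[1] / dim(vesselLabels(m1))[1], 2,
               tolerance = 0.01)
})

test_that("macula centering displaces the disc by the fovea offset", {
  eye <- generateEye(smallEyeParams(), seed = 9)
  modc <- renderView(eye, viewSpec("ODC"))
  mmc <- renderView(eye, viewSpec("MC"))
  odPx <- meanODDiameter(opticDiscFromMap(mmc))
  ctr <- (dim(vesselLabels(mmc)) + 1) / 2
  disp <- sqrt(sum((mapMeta(mmc)$odCenter - ctr)^2))
  expect_equal(disp / odPx, 2.5, tolerance = 0.05)
  # zone C remains complete in both 60-degree views
  expect_lte(mapMeta(modc)$clipFracZoneC, 0.005)
  expect_lte(mapMeta(mmc)$clipFracZoneC, 0.005)
})

test_that("frames too small for zone B are refused", {
  eye <- generateEye(smallEyeParams(odDiameterUmSd = 0), seed = 5)
  # disc is 300 px; a 200 px frame ends inside the zone B inner circle
  expect_error(renderView(eye, viewSpec("ODC", outputSize = c(200, 200))),
               "zone B")
  # a narrow macula-centered field clips zone C and is flagged, not fatal
  mn <- renderView(eye, viewSpec("MC", fovDeg = 40))
  expect_gt(mapMeta(mn)$clipFracZoneC, 0.05)
})

test_that("rendering is deterministic", {
  eye <- generateEye(smallEyeParams(), seed = 6)
  m1 <- renderView(eye, viewSpec("ODC"))
  m2 <- renderView(eye, viewSpec("ODC"))
  expect_identical(vesselLabels(m1), vesselLabels(m2))
})
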