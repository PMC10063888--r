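test_that("mean disc diameter averages the two axes", {
  expect_equal(meanODDiameter(opticDisc(c(0, 0), 700, 760)), 730)
  expect_equal(meanODDiameter(opticDisc(c(0, 0), 722, 722)), 722)
  expect_equal(meanODDiameter(opticDisc(c(0, 0), 638, 638)), 638)
  expect_error(opticDisc(c(0, 0), -5, 700), "positive")
})

test_that("individual conversion factor divides the reference disc size", {
  cases <- list(c(638, 2.82), c(722, 2.49), c(782, 2.30), c(1014, 1.78),
                c(1800, 1.00))
  for (cs in cases)
    expect_equal(round(icfValue(individualICF(cs[1])), 2), cs[2])
  icf <- individualICF(opticDisc(c(0, 0), 700, 760))
  expect_equal(icfValue(icf), 1800 / 730)
  expect_identical(icfKind(icf), "individual")
  expect_equal(icfValue(individualICF(925, referenceOdUm = 1850)), 2)
  expect_error(individualICF(0), "positive")
  expect_error(individualICF(-10), "positive")
})

test_that("constant conversion factor uses the cohort mean disc", {
  expect_equal(icfValue(constantICF(c(900, 900))), 2.0)
  expect_equal(icfValue(constantICF(638)), icfValue(individualICF(638)))
  expect_identical(icfKind(constantICF(638)), "constant")
  # a cohort averaging 750 px reproduces the conversion factor 2.4
  expect_equal(icfValue(constantICF(c(700, 750, 800))), 2.4)
  expect_error(constantICF(numeric()), "at least one")
  expect_error(constantICF(c(700, -1)), "positive")
})

test_that("pixel-to-micron conversion is linear in length", {
  icf <- constantICF(750)  # 2.4 um/px
  expect_equal(pxToUm(100, icf), 240)
  expect_equal(pxToUm(0, icf), 0)
  expect_equal(round(pxToUm(67.92, icf)), 163)
  a <- runif(20, 0, 500); b <- runif(20, 0, 500)
  expect_equal(pxToUm(a + b, icf), pxToUm(a, icf) + pxToUm(b, icf))
  expect_error(pxToUm(-1, icf), "non-negative")
})

test_that("zones B and C follow the conversion factor", {
  z <- buildZones(c(0, 0), constantICF(900))  # icf = 2
  expect_equal(z@zoneB, c(900, 1350))
  expect_equal(z@zoneC, c(900, 2250))
  z1 <- buildZones(c(10, 20), individualICF(1800))  # icf = 1
  expect_equal(z1@zoneB, c(1800, 2700))
  expect_equal(z1@zoneC, c(1800, 4500))
  # with an individual factor the inner boundary is the measured disc
  z2 <- buildZones(c(0, 0), individualICF(720))
  expect_equal(z2@zoneB[1], 720)
  expect_equal(z2@zoneC[2], 2.5 * 720)
})

test_that("conversion-factor monotonicity and zone scaling hold", {
  od <- seq(500, 1200, by = 50)
  icfs <- vapply(od, function(x) icfValue(individualICF(x)), 0)
  expect_true(all(diff(icfs) < 0))  # larger disc, smaller factor
  # zone radii scale as 1/icf: a larger factor means a smaller zone
  radii <- vapply(icfs, function(v) {
    z <- buildZones(c(0, 0), constantICF(1800 / v))
    z@zoneC[2]
  }, 0)
  expect_true(all(diff(radii[order(icfs)]) < 0))
  # constant factor of a cohort equals the individual factor of its mean
  cohort <- c(640, 700, 820, 760)
  expect_equal(icfValue(constantICF(cohort)),
               icfValue(individualICF(mean(cohort))))
})
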