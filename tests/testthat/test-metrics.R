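test_that("big-six selection takes the largest widths deterministically", {
  meas <- data.frame(
    vesselId = sprintf("a_%d", 1:8), vesselType = "artery",
    widthPx = c(10, 9, 8, 7, 6, 5, 4, 3))
  six <- selectBigSix(meas, "artery")
  expect_equal(six$widths, c(10, 9, 8, 7, 6, 5))
  expect_false(six$shortfall)
  short <- selectBigSix(data.frame(vesselId = sprintf("a_%d", 1:4),
                                   vesselType = "artery",
                                   widthPx = c(5, 5, 5, 5)), "artery")
  expect_equal(short$widths, rep(5, 4))
  expect_true(short$shortfall)
  # tie at sixth place resolved by vessel id
  tie <- data.frame(vesselId = sprintf("a_%d", 1:7), vesselType = "artery",
                    widthPx = c(10, 9, 8, 7, 6, 5, 5))
  expect_identical(selectBigSix(tie, "artery")$vesselIds[6], "a_6")
  expect_error(selectBigSix(meas, "vein"), "no measurements")
})

test_that("the Knudtson equivalents match the pairing formula", {
  expect_equal(knudtsonEquivalent(rep(10, 6), "artery"), 17.4843,
               tolerance = 1e-4)
  expect_equal(knudtsonEquivalent(rep(10, 6), "vein"), 21.3761,
               tolerance = 1e-4)
  # a single pairing step: 0.88 * 10 * sqrt(2)
  expect_equal(knudtsonOracle(c(10, 10), 0.88), 12.4451, tolerance = 1e-4)
  expect_error(knudtsonEquivalent(rep(10, 5), "artery"), "six")
  expect_error(knudtsonEquivalent(c(rep(10, 5), -1), "artery"), "positive")
})

test_that("the equivalents agree with an independent pairing oracle", {
  set.seed(401)
  for (k in 1:200) {
    w <- runif(6, 5, 120)
    expect_equal(knudtsonEquivalent(w, "artery"), knudtsonOracle(w, 0.88),
                 tolerance = 1e-12)
    expect_equal(knudtsonEquivalent(w, "vein"), knudtsonOracle(w, 0.95),
                 tolerance = 1e-12)
  }
})

test_that("the equivalent is permutation-invariant and homogeneous", {
  set.seed(402)
  w <- runif(6, 10, 100)
  for (k in 1:10)
    expect_equal(knudtsonEquivalent(sample(w), "vein"),
                 knudtsonEquivalent(w, "vein"))
  expect_equal(knudtsonEquivalent(3.7 * w, "artery"),
               3.7 * knudtsonEquivalent(w, "artery"))
})

test_that("the arteriovenous ratio is the equivalent quotient", {
  expect_equal(avr(160, 200), 0.8)
  expect_equal(avr(173.2, 173.2), 1)
  expect_equal(avr(162, 208), 0.779, tolerance = 1e-3)
  expect_error(avr(160, 0), "positive")
})

test_that("simple tortuosity has its analytic limits", {
  expect_equal(simpleTortuosity(cbind(0:100, 0)), 1)
  th <- seq(0, pi, by = 1 / 500)  # half circle, ~1 px point spacing
  expect_equal(simpleTortuosity(500 * cbind(cos(th), sin(th))), pi / 2,
               tolerance = 1e-3)
  # one sine period vs numeric quadrature of the arc length
  a <- 10; lam <- 100
  x <- seq(0, lam, by = 0.5)
  st <- simpleTortuosity(cbind(x, a * sin(2 * pi * x / lam)))
  arc <- integrate(function(t) sqrt(1 + (2 * pi * a / lam)^2 *
                                      cos(2 * pi * t / lam)^2),
                   0, lam, rel.tol = 1e-10)$value
  expect_equal(st, arc / lam, tolerance = 1e-3)
  expect_error(simpleTortuosity(matrix(1, 1, 2)), "n >= 2")
  expect_error(simpleTortuosity(rbind(c(0, 0), c(1, 1), c(0, 0))),
               "coincident")
})

test_that("box counting needs a usable ladder and non-empty input", {
  expect_error(fractalDimensionBoxcount(matrix(FALSE, 10, 10)), "empty")
  expect_error(fractalDimensionBoxcount(matrix(TRUE, 20, 20)), "ladder")
})

test_that("a missing vessel type is flagged, not fatal", {
  map <- bandMap(code = 2L)  # veins only
  zones <- buildZones(mapMeta(map)$odCenter,
                      individualICF(opticDiscFromMap(map)))
  meas <- extractVessels(map, zones, "B")
  expect_false(any(meas$vesselType == "artery"))
  expect_true(any(meas$vesselType == "vein"))
  expect_true(any(grepl("no_artery", attr(meas, "flags"))))
})

test_that("measured band widths track the rendered width", {
  map <- bandMap(widthPx = 31, code = 1L)
  zones <- buildZones(mapMeta(map)$odCenter,
                      individualICF(opticDiscFromMap(map)))
  meas <- extractVessels(map, zones, "B")
  a <- meas[meas$vesselType == "artery", ]
  expect_true(all(abs(a$widthPx - 31) <= 1.5))
  expect_true(all(abs(a$tortuosity - 1) < 1e-3))  # a straight band
})
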