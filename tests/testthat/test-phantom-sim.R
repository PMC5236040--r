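test_that("decay correction follows the half-life law and inverts", {
  expect_equal(decayCorrect(40, 109.77, 109.77), 20)
  expect_equal(decayCorrect(40, 0, 109.77), 40)
  expect_equal(decayCorrect(20, -109.77, 109.77), 40)
  ## idempotence of correcting to a common time point
  a <- decayCorrect(decayCorrect(40, 35), -35)
  expect_equal(a, 40)
  expect_error(decayCorrect(40, 10, 0), "halfLife")
})

test_that("phantom rasterisation fills the cylinder from the bottom", {
  spec <- phantomSpec()
  state <- seriesStates(buildDilutionSeries())[[1]]
  ph <- buildPhantom(spec, state, 0.0969)
  expect_equal(ph$fillHeightCm, 120.2 / (pi * 2.5^2), tolerance = 1e-12)
  ## activity concentration at fill, no decay
  inMask <- ph$mask@values == 1
  expect_equal(unique(ph$activity@values[inMask]), 40000 / 120.2)
  expect_true(all(ph$activity@values[!inMask] == 0))
  expect_equal(unique(ph$mu@values[inMask]), 0.0969)
  ## discretised mask volume matches the fill volume within 1%
  voxVolMl <- prod(spec@spacingMm) / 1000
  expect_lt(abs(sum(inMask) * voxVolMl - 120.2) / 120.2, 0.01)
  ## top of the fill is below the bottle height
  zTop <- max(which(apply(ph$mask@values == 1, 3, any)))
  expect_lt(zTop * spec@spacingMm[3], spec@heightCm * 10)
  ## overfilling is refused
  big <- seriesStates(buildDilutionSeries(baseWaterVolume = 170))[[1]]
  expect_error(buildPhantom(spec, big, 0.0969), "exceeds")
})

test_that("projector matches the analytic chord integral of a disk", {
  mu <- 0.0969
  img <- diskImage(mu, "LAC_per_cm")
  ## canonical projection directions 0/45/90/135 degrees
  g <- parallelGeometry(nAngles = 4, nRadial = 128, radialSpacing = 1)
  p <- sinogramValues(forwardProject(img, g))[, , 1]
  s <- (seq_len(128) - 64.5) * 1
  expected <- mu * chordCm(s)
  sel <- abs(s) <= 0.9 * 25
  for (a in seq_len(nrow(p)))
    expect_lt(max(abs(p[a, sel] - expected[sel]) / expected[sel]), 0.01)
  ## off-lattice directions pick up edge-response aliasing; the envelope
  ## over a fine angular sweep stays within 1.5%
  gAll <- parallelGeometry(nAngles = 36, nRadial = 128, radialSpacing = 1)
  pAll <- sinogramValues(forwardProject(img, gAll))[, , 1]
  relErr <- sweep(abs(sweep(pAll[, sel], 2, expected[sel])), 2,
                  expected[sel], "/")
  expect_lt(max(relErr), 0.015)
  ## rays outside the disk integrate to zero
  expect_true(all(pAll[, abs(s) > 27] == 0))
})

test_that("projector is linear and rotation-consistent", {
  g <- smallGeom(nAngles = 36)
  x <- diskImage(1.7, "dimensionless", n = 64, radiusMm = 20, spacingMm = 2)
  y <- voxelImage(array(runif(64 * 64), c(64, 64, 1)), 2,
                  semantics = "dimensionless")
  px <- sinogramValues(forwardProject(x, g))
  py <- sinogramValues(forwardProject(y, g))
  both <- voxelImage(3 * x@values + 2 * y@values, 2,
                     semantics = "dimensionless")
  pb <- sinogramValues(forwardProject(both, g))
  expect_equal(pb, 3 * px + 2 * py, tolerance = 1e-9)
  ## centred disk: profiles are close to angle-independent; the residual
  ## spread is the edge-response anisotropy of 1 mm linear interpolation
  disk1 <- diskImage(1, "dimensionless")
  g1 <- parallelGeometry(nAngles = 36, nRadial = 128, radialSpacing = 1)
  p1 <- sinogramValues(forwardProject(disk1, g1))[, , 1]
  s1 <- (seq_len(128) - 64.5)
  inner <- abs(s1) <= 0.9 * 25
  spread <- apply(p1[, inner], 2,
                  function(col) diff(range(col)) / mean(col))
  expect_lt(max(spread), 0.025)
  ## HU images are refused
  hu <- voxelImage(array(0, c(8, 8, 1)), semantics = "HU")
  expect_error(forwardProject(hu, g), "HU")
})

test_that("attenuation factors are exp(path integral), 1 off the object", {
  img <- diskImage(0.0969, "LAC_per_cm")
  g <- parallelGeometry(nAngles = 4, nRadial = 128, radialSpacing = 1)
  acf <- sinogramValues(attenuationFactors(img, g))[, , 1]
  s <- (seq_len(128) - 64.5) * 1
  ## central ray: chord 5 cm through mu = 0.0969 -> 1.6234
  expect_equal(acf[1, which.min(abs(s))], 1.6234, tolerance = 0.01)
  expect_true(all(acf >= 1))
  expect_true(all(acf[, abs(s) > 27] == 1))
  ## 66 mM solution value
  img66 <- diskImage(0.09931, "LAC_per_cm")
  acf66 <- sinogramValues(attenuationFactors(img66, g))[, , 1]
  expect_equal(acf66[1, which.min(abs(s))], 1.6432, tolerance = 0.01)
  expect_error(attenuationFactors(
    voxelImage(array(1, c(4, 4, 1)), semantics = "kBq_per_ml"), g),
    "LAC_per_cm")
})

test_that("emission simulation attenuates the activity projection", {
  conc <- 332.8
  act <- diskImage(conc, "kBq_per_ml")
  mu <- diskImage(0.0969, "LAC_per_cm")
  g <- parallelGeometry(nAngles = 8, nRadial = 128, radialSpacing = 1)
  cs <- 10
  em <- simulateEmission(act, mu, g, countsScale = cs)
  s <- (seq_len(128) - 64.5) * 1
  central <- sinogramValues(em)[1, which.min(abs(s)), 1]
  expect_equal(central, cs * conc * 5 / 1.6234, tolerance = 0.01)
  ## zero counts scale -> empty sinogram
  em0 <- simulateEmission(act, mu, g, countsScale = 0)
  expect_true(all(sinogramValues(em0) == 0))
  ## grids must match
  muBad <- diskImage(0.0969, "LAC_per_cm", n = 64, spacingMm = 2)
  expect_error(simulateEmission(act, muBad, g), "grid")
})

test_that("Poisson emission is seed-reproducible and unbiased in the mean", {
  act <- diskImage(300, "kBq_per_ml", n = 64, radiusMm = 25, spacingMm = 2)
  mu <- diskImage(0.0969, "LAC_per_cm", n = 64, radiusMm = 25,
                  spacingMm = 2)
  g <- smallGeom(nAngles = 45)
  a <- simulateEmission(act, mu, g, countsScale = 10, seed = 11)
  b <- simulateEmission(act, mu, g, countsScale = 10, seed = 11)
  c <- simulateEmission(act, mu, g, countsScale = 10, seed = 12)
  expect_identical(sinogramValues(a), sinogramValues(b))
  expect_false(identical(sinogramValues(a), sinogramValues(c)))
  ## counts are non-negative integers
  expect_true(all(sinogramValues(a) >= 0))
  expect_equal(sinogramValues(a), round(sinogramValues(a)))
  ## mean of counts/expected over high-count bins within 3 sigma of 1
  expected <- sinogramValues(simulateEmission(act, mu, g, countsScale = 10))
  sel <- expected >= 100
  ratio <- sinogramValues(a)[sel] / expected[sel]
  se <- sqrt(sum(1 / expected[sel])) / sum(sel)
  expect_lt(abs(mean(ratio) - 1), 3 * se)
  ## caller RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulateEmission(act, mu, g, seed = 5))
  expect_identical(runif(1), before)
})
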