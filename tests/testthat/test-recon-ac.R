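## Shared small-scale phantom pieces for the correction-chain tests.
reconFixture <- function() {
  spec <- smallSpec()
  states <- seriesStates(buildDilutionSeries(recipe = c(0, 66)))
  g <- smallGeom()
  phs <- lapply(states, function(s)
    buildPhantom(spec, s, solutionLAC(s, 511)))
  cts <- mapply(function(ph, s) {
    hu <- huOfSolution(s)
    voxelImage(ph$mask@values * (hu + 1000) - 1000, ph$mask@spacing,
               ph$mask@origin, "HU")
  }, phs, states, SIMPLIFY = FALSE)
  list(spec = spec, states = states, g = g, phs = phs, cts = cts)
}

test_that("AC maps implement the three correction strategies", {
  f <- reconFixture()
  ac3 <- makeACMap("AC3", 2, f$cts, f$phs[[2]]$mask)
  expect_identical(imageSemantics(ac3), "LAC_per_cm")
  inMask <- f$phs[[2]]$mask@values == 1
  expect_true(all(ac3@values[inMask] == 0.1))
  expect_true(all(ac3@values[!inMask] == 0))
  ## AC1 and AC2 coincide at the contrast-free step
  ac1_0 <- makeACMap("AC1", 1, f$cts, f$phs[[1]]$mask)
  ac2_0 <- makeACMap("AC2", 1, f$cts, f$phs[[1]]$mask)
  expect_identical(ac1_0@values, ac2_0@values)
  ## AC2 at a later step still uses the 0 mM CT
  ac2_last <- makeACMap("AC2", 2, f$cts, f$phs[[2]]$mask)
  expect_identical(ac2_last@values, ac1_0@values)
  ## AC1 at the later step reflects that step's CT
  ac1_last <- makeACMap("AC1", 2, f$cts, f$phs[[2]]$mask)
  expect_gt(max(ac1_last@values), max(ac1_0@values))
  expect_error(makeACMap("AC9", 1, f$cts, f$phs[[1]]$mask), "unknown")
})

test_that("sinogram correction multiplies by the estimated ACF", {
  f <- reconFixture()
  ph <- f$phs[[2]]
  em <- simulateEmission(ph$activity, ph$mu, f$g, countsScale = 10)
  ## zero map: ACF = 1 everywhere, correction is the identity
  zeroMap <- voxelImage(ph$mu@values * 0, ph$mu@spacing, ph$mu@origin,
                        "LAC_per_cm")
  expect_equal(sinogramValues(correctSinogram(em, zeroMap, f$g)),
               sinogramValues(em))
  ## matched map: exp terms cancel, recovering the unattenuated projection
  corrected <- correctSinogram(em, ph$mu, f$g)
  expect_identical(sinogramSemantics(corrected), "corrected_counts")
  proj <- sinogramValues(forwardProject(ph$activity, f$g)) * 10
  expect_equal(sinogramValues(corrected), proj, tolerance = 1e-6)
  ## correcting 66 mM data with the 0 mM mu under-corrects by exp(-dmu*L)
  mu0 <- f$phs[[1]]$mu
  mu0on2 <- voxelImage(ph$mask@values * max(mu0@values), ph$mask@spacing,
                       ph$mask@origin, "LAC_per_cm")
  under <- correctSinogram(em, mu0on2, f$g)
  s <- (seq_len(64) - 32.5) * 2
  cen <- which.min(abs(s))
  ratio <- sinogramValues(under)[1, cen, 1] / sinogramValues(corrected)[1, cen, 1]
  dmu <- solutionLAC(f$states[[2]], 511) - solutionLAC(f$states[[1]], 511)
  expect_equal(ratio, exp(-dmu * 5), tolerance = 1e-3)
  expect_error(correctSinogram(corrected, ph$mu, f$g), "counts")
})

test_that("FBP round-trips a uniform disk within 1% in the interior", {
  conc <- 332.8
  act <- diskImage(conc, "kBq_per_ml", n = 64, spacingMm = 2, nz = 2)
  g <- smallGeom()
  p <- forwardProject(act, g)
  rec <- fbpReconstruct(p, g, act)
  expect_identical(imageSemantics(rec), "kBq_per_ml")
  xc <- (seq_len(64) - 32.5) * 2
  interior <- outer(xc^2, xc^2, "+") <= (25 - 2 * 2)^2
  for (z in 1:2) {
    vals <- imageValues(rec)[, , z]
    expect_lt(max(abs(vals[interior] - conc) / conc), 0.01)
  }
  ## linearity and the zero image
  scaled <- function(f) new("Sinogram", values = f(p@values),
                            angles = p@angles,
                            radialSpacing = p@radialSpacing,
                            semantics = "line_integral")
  rec2 <- fbpReconstruct(scaled(function(v) 2 * v), g, act)
  expect_equal(imageValues(rec2), 2 * imageValues(rec), tolerance = 1e-12)
  zero <- fbpReconstruct(scaled(function(v) v * 0), g, act)
  expect_true(all(imageValues(zero) == 0))
  expect_error(fbpReconstruct(attenuationFactors(
    diskImage(0.1, "LAC_per_cm", n = 64, spacingMm = 2), g), g, act),
    "attenuation_factor")
})

test_that("calibration makes the matched reconstruction read true kBq/ml", {
  f <- reconFixture()
  cal <- calibrateCounts(f$spec, f$g, f$states[[1]], countsScale = 10,
                         voiVolumeCm3 = 4)
  ph <- f$phs[[1]]
  em <- simulateEmission(ph$activity, ph$mu, f$g, countsScale = 10)
  acMap <- lacMapFromCT(f$cts[[1]])
  rec <- fbpReconstruct(correctSinogram(em, acMap, f$g), f$g, ph$mask,
                        calibration = cal)
  voi <- centralVOI(ph$mask, 4)
  truth <- trueConcentration(f$spec, f$states[[1]])
  expect_equal(voiStats(rec, voi)$mean / truth, 1, tolerance = 0.005)
  ## calibration cancels the abstract sensitivity: same kBq/ml either way
  cal2 <- calibrateCounts(f$spec, f$g, f$states[[1]], countsScale = 40,
                          voiVolumeCm3 = 4)
  em2 <- simulateEmission(ph$activity, ph$mu, f$g, countsScale = 40)
  rec2 <- fbpReconstruct(correctSinogram(em2, acMap, f$g), f$g, ph$mask,
                         calibration = cal2)
  expect_equal(voiStats(rec2, voi)$mean, voiStats(rec, voi)$mean,
               tolerance = 1e-9)
  ## and is independent of the activity level
  specHot <- phantomSpec(activityMBq = 80, grid = f$spec@grid,
                         spacingMm = f$spec@spacingMm)
  calHot <- calibrateCounts(specHot, f$g, f$states[[1]], countsScale = 10,
                            voiVolumeCm3 = 4)
  expect_equal(calHot, cal, tolerance = 1e-9)
})

test_that("raising the AC map LAC raises the reconstructed VOI mean", {
  f <- reconFixture()
  ph <- f$phs[[1]]
  em <- simulateEmission(ph$activity, ph$mu, f$g, countsScale = 10)
  voi <- centralVOI(ph$mask, 4)
  recMatched <- fbpReconstruct(correctSinogram(em, ph$mu, f$g), f$g,
                               ph$mask)
  ac3 <- makeACMap("AC3", 1, f$cts, ph$mask)
  recAC3 <- fbpReconstruct(correctSinogram(em, ac3, f$g), f$g, ph$mask)
  ## 0.1 > 0.0969: over-correction biases the mean upward
  expect_gt(voiStats(recAC3, voi)$mean, voiStats(recMatched, voi)$mean)
})
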