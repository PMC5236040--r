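test_that("attenuation table lookup aliases 511 keV to the 500 keV row", {
  tab <- defaultAttenuationTable()
  expect_equal(macAt(tab, 511), macAt(tab, 500))
  expect_equal(macAt(tab, 150)[["water"]], 0.1505)
  expect_equal(macAt(tab, 150)[["gd"]], 1.1)
  expect_error(macAt(tab, 300), "not in table")
  expect_error(attenuationTable(data.frame(
    energy_keV = 500, mac_water = 0.2, mac_gd = 0.1)), "exceed")
})

test_that("parent volume solves the additive-volume dilution relation", {
  ## oracle: root of 1000*M*x - c*(base + x) = 0, found numerically
  bisect <- function(conc, base, M) {
    uniroot(function(x) 1000 * M * x - conc * (base + x),
            c(0, 1000), tol = 1e-12)$root
  }
  expect_equal(parentVolumeForTarget(66, 120.2, 0.5), bisect(66, 120.2, 0.5),
               tolerance = 1e-9)
  expect_equal(parentVolumeForTarget(66, 120.2, 0.5), 18.2793,
               tolerance = 1e-5)
  expect_equal(parentVolumeForTarget(3, 120.2, 0.5), 0.725553,
               tolerance = 1e-5)
  expect_equal(parentVolumeForTarget(0, 120.2, 0.5), 0)
  expect_error(parentVolumeForTarget(500, 120.2, 0.5), "not below")
})

test_that("dilution series reproduces the phantom mass balance", {
  series <- buildDilutionSeries()
  states <- seriesStates(series)
  expect_length(states, 20)
  conc <- seriesConcentrations(series)
  expect_equal(conc, c(seq(0, 30, 3), seq(34, 66, 4)))

  s0 <- states[[1]]
  expect_equal(s0@wGd, 0)
  expect_equal(s0@parentVolumeAdded, 0)
  expect_equal(s0@totalVolume, 120.2)
  expect_equal(s0@density, 1.000)

  sLast <- states[[length(states)]]
  expect_equal(sLast@targetConcentration, 66)
  expect_equal(sLast@totalVolume, 138.48, tolerance = 1e-4)
  expect_equal(sLast@gdMass, 1.4372, tolerance = 1e-4)
  expect_equal(sLast@wGd, 0.010144, tolerance = 1e-4)
  expect_equal(sLast@density, 1.0231, tolerance = 1e-4)

  ## Gd conservation: cumulative mass equals the sum of per-step additions
  added <- diff(c(0, vapply(states, slot, numeric(1), "parentVolumeAdded")))
  gdFromSteps <- cumsum(added * gdMassPerMl(series@agent) / 1000)
  expect_equal(vapply(states, slot, numeric(1), "gdMass"), gdFromSteps,
               tolerance = 1e-9)

  ## density and 511 keV LAC strictly increase along the series
  dens <- vapply(states, slot, numeric(1), "density")
  lac <- vapply(states, solutionLAC, numeric(1), energy = 511)
  expect_true(all(diff(dens) > 0))
  expect_true(all(diff(lac) > 0))

  expect_error(buildDilutionSeries(recipe = c(0, 10, 5)), "increasing")
  expect_error(buildDilutionSeries(recipe = c(3, 6)), "start at 0")
})

test_that("mixture rule is linear in the weight fraction and bounded", {
  tab <- defaultAttenuationTable()
  expect_equal(mixtureMAC(0, 511), 0.0969, tolerance = 1e-3)
  expect_equal(mixtureMAC(1, 511), 0.1139)
  mac <- macAt(tab, 511)
  expect_equal(mixtureMAC(0.5, 511), mean(mac))
  w <- seq(0, 1, 0.05)
  vals <- mixtureMAC(w, 511)
  expect_true(all(vals >= mac[["water"]] & vals <= mac[["gd"]]))
  expect_true(all(vals[w > 0 & w < 1] > mac[["water"]]))
  expect_true(all(vals[w > 0 & w < 1] < mac[["gd"]]))
  ## exactly linear: second differences vanish
  expect_equal(diff(vals, differences = 2), rep(0, length(w) - 2))
  expect_error(mixtureMAC(1.2, 511), "wGd")
  expect_error(mixtureMAC(-0.1, 511), "wGd")
})

test_that("solution LAC matches the printed operating points", {
  states <- seriesStates(buildDilutionSeries())
  s0 <- states[[1]]
  sLast <- states[[length(states)]]
  expect_equal(solutionLAC(s0, 511), 0.0969, tolerance = 1e-3)
  expect_equal(solutionLAC(sLast, 511), 0.09931, tolerance = 1e-3)
  expect_equal(solutionLAC(sLast, 150), 0.16383, tolerance = 1e-3)
})

test_that("LAC increase over the series is ~2.5% at 511 keV, larger at CT energy", {
  series <- buildDilutionSeries()
  expect_equal(lacIncreasePercent(series, 511), 2.5, tolerance = 0.01)
  expect_equal(lacIncreasePercent(series, 150), 8.9, tolerance = 0.01)
  one <- buildDilutionSeries(recipe = 0)
  expect_equal(lacIncreasePercent(one, 511), 0)
})

test_that("with unit parent density the LAC rise collapses to the pure-MAC effect", {
  ## oracle: hand evaluation of the two-component rule at w_gd with density 1
  agent <- contrastAgent("DOTAREM", 0.5, 558.64, parentDensity = 1.000)
  series <- buildDilutionSeries(agent)
  sLast <- seriesStates(series)[[20]]
  expect_equal(sLast@density, 1.000, tolerance = 1e-12)
  mac <- macAt(defaultAttenuationTable(), 511)
  expected <- 100 * (mac[["gd"]] / mac[["water"]] - 1) * sLast@wGd
  expect_equal(lacIncreasePercent(series, 511), expected, tolerance = 1e-9)
  expect_equal(lacIncreasePercent(series, 511), 0.18, tolerance = 0.02)
})

test_that("mixture curve has one row per state-energy pair, monotone in concentration", {
  series <- buildDilutionSeries()
  curve <- mixtureCurve(series, energies = c(150, 511))
  expect_identical(nrow(curve), 2L * length(seriesStates(series)))
  for (e in c(150, 511)) {
    sub <- curve[curve$energy_keV == e, ]
    expect_true(all(diff(sub$lac_per_cm) > 0))
  }
  expect_equal(curve$lac_per_cm[curve$energy_keV == 511][1], 0.0969,
               tolerance = 1e-3)
})
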