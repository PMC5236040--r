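#' Construct an attenuation table
#'
#' @param entries data.frame with columns `energy_keV`, `mac_water`,
#'   `mac_gd` (MAC in cm^2/g), energies strictly increasing.
#' @return An [AttenuationTable-class].
#' @seealso [defaultAttenuationTable()]
#' @export
attenuationTable <- function(entries) {
  new("AttenuationTable",
      entries = entries[order(entries$energy_keV), , drop = FALSE])
}

#' Default mass attenuation coefficients of water and gadolinium
#'
#' Two tabulated Hubbell energies bracket the analysis: 150 keV, close to the
#' effective energy of a 140 kVp CT beam, where water and Gd differ markedly
#' (0.1505 vs 1.1 cm^2/g); and 500 keV, the last tabulated point below the
#' 511 keV annihilation energy, where they are similar (0.09687 vs
#' 0.1139 cm^2/g, a 14.95 percent relative gap). Lookups at 511 keV alias to
#' the 500 keV row. The water value at 500 keV is commonly quoted rounded as
#' 0.0969 cm^2/g.
#'
#' @return An [AttenuationTable-class] with the two bundled energies.
#' @examples
#' macAt(defaultAttenuationTable(), 511)
#' @export
defaultAttenuationTable <- function() {
  attenuationTable(data.frame(
    energy_keV = c(150, 500),
    mac_water = c(0.1505, 0.09687),
    mac_gd = c(1.1, 0.1139)))
}

#' @describeIn attenuationTable Look up the (water, Gd) MAC pair at an
#'   energy. Lookup is exact-match; 511 keV aliases to the 500 keV entry.
#' @param table an [AttenuationTable-class].
#' @param energy photon energy, keV.
#' @export
macAt <- function(table, energy) {
  stopifnot(is(table, "AttenuationTable"))
  checkScalar(energy, "energy", min = 0, strict = TRUE)
  if (energy == 511 && !(511 %in% table@entries$energy_keV)) energy <- 500
  i <- match(energy, table@entries$energy_keV)
  if (is.na(i))
    stop(sprintf("energy %g keV not in table (have: %s)", energy,
                 paste(table@entries$energy_keV, collapse = ", ")),
         call. = FALSE)
  c(water = table@entries$mac_water[i], gd = table@entries$mac_gd[i])
}

#' @describeIn attenuationTable Percent MAC gap between Gd and water,
#'   `100 * (mac_gd - mac_water) / mac_gd`.
#' @export
macDifferencePercent <- function(table, energy) {
  mac <- macAt(table, energy)
  100 * (mac[["gd"]] - mac[["water"]]) / mac[["gd"]]
}

setMethod("show", "AttenuationTable", function(object) {
  cat("AttenuationTable (MAC, cm^2/g):\n")
  print(object@entries, row.names = FALSE)
})

#' Parent-solution volume needed to reach a target concentration
#'
#' Solves `1000 * parentMolarity * x = concentration * (baseVolume + x)` for
#' the cumulative parent volume `x`, assuming additive volumes: the Gd placed
#' in solution by `x` ml of parent must equal the target concentration times
#' the final volume.
#'
#' @param concentration target Gd concentration, mM; must be below the parent
#'   stock concentration `1000 * parentMolarity`.
#' @param baseVolume GBCA-free base volume (water + tracer), ml.
#' @param parentMolarity parent solution molarity, mmol/ml.
#' @return parent volume, ml.
#' @examples
#' parentVolumeForTarget(66, 120.2, 0.5)  # 18.279 ml
#' @export
parentVolumeForTarget <- function(concentration, baseVolume, parentMolarity) {
  checkScalar(concentration, "concentration", min = 0)
  checkScalar(baseVolume, "baseVolume", min = 0, strict = TRUE)
  checkScalar(parentMolarity, "parentMolarity", min = 0, strict = TRUE)
  stock <- 1000 * parentMolarity
  if (concentration >= stock)
    stop(sprintf("target %g mM is not below the %g mM parent stock",
                 concentration, stock), call. = FALSE)
  concentration * baseVolume / (stock - concentration)
}

#' The default phantom dilution recipe
#'
#' 3 mM increments up to 30 mM followed by 4 mM increments up to 66 mM,
#' preceded by the contrast-free baseline: 20 concentrations in total.
#'
#' @return numeric vector of target concentrations, mM.
#' @export
defaultRecipe <- function() c(seq(0, 30, by = 3), seq(34, 66, by = 4))

#' Build the dilution series for the phantom experiment
#'
#' Starting from a base of distilled water plus a small tracer aliquot
#' (counted as water), contrast parent solution is added cumulatively to hit
#' each recipe concentration. Volumes are additive; the mass balance uses the
#' water density for the base and the parent density for the aliquots, giving
#' each state its total volume, mass, density, Gd mass and the Gd weight
#' fraction used by the mixture rule.
#'
#' @param agent a [ContrastAgent-class] (default DOTAREM).
#' @param recipe strictly increasing target concentrations starting at 0, mM.
#' @param baseWaterVolume distilled water volume, ml (default 120).
#' @param tracerVolume tracer solution volume, ml (default 0.2).
#' @param waterDensity water density, g/ml (default 1.000).
#' @return A [DilutionSeries-class] with one [SolutionState-class] per
#'   recipe concentration.
#' @examples
#' series <- buildDilutionSeries()
#' length(seriesStates(series))  # 21
#' @export
buildDilutionSeries <- function(agent = getAgent("DOTAREM"),
                                recipe = defaultRecipe(),
                                baseWaterVolume = 120, tracerVolume = 0.2,
                                waterDensity = 1.000) {
  stopifnot(is(agent, "ContrastAgent"))
  if (length(recipe) < 1L || recipe[1] != 0)
    stop("recipe must start at 0 mM", call. = FALSE)
  if (is.unsorted(recipe, strictly = TRUE))
    stop("recipe concentrations must be strictly increasing", call. = FALSE)
  base <- baseWaterVolume + tracerVolume
  baseMass <- base * waterDensity
  states <- lapply(recipe, function(conc) {
    x <- if (conc == 0) 0 else
      parentVolumeForTarget(conc, base, agent@molarity)
    totalVolume <- base + x
    totalMass <- baseMass + x * agent@parentDensity
    gdMass <- x * gdMassPerMl(agent) / 1000          # mg -> g
    wGd <- gdMass / totalMass
    new("SolutionState", targetConcentration = conc,
        baseWaterVolume = baseWaterVolume, tracerVolume = tracerVolume,
        parentVolumeAdded = x, totalVolume = totalVolume,
        totalMass = totalMass, density = totalMass / totalVolume,
        gdMass = gdMass, wGd = wGd, wWater = 1 - wGd)
  })
  new("DilutionSeries", agent = agent, states = states,
      waterDensity = waterDensity)
}

#' @describeIn buildDilutionSeries List of [SolutionState-class] objects.
#' @param series a [DilutionSeries-class].
#' @export
seriesStates <- function(series) series@states

#' @describeIn buildDilutionSeries Target concentrations of the series, mM.
#' @export
seriesConcentrations <- function(series)
  vapply(series@states, slot, numeric(1), "targetConcentration")

setMethod("length", "DilutionSeries", function(x) length(x@states))

setMethod("show", "DilutionSeries", function(object) {
  conc <- seriesConcentrations(object)
  cat(sprintf(paste0("DilutionSeries: %d states, %g-%g mM of %s\n",
                     "  final volume %.2f ml, final density %.4f g/ml\n"),
              length(conc), min(conc), max(conc), object@agent@name,
              object@states[[length(conc)]]@totalVolume,
              object@states[[length(conc)]]@density))
})

#' @describeIn buildDilutionSeries One row per state with the volume, mass,
#'   density and weight-fraction bookkeeping.
#' @param x a [DilutionSeries-class].
#' @param row.names,optional,... passed on conventionally (unused).
#' @export
setMethod("as.data.frame", "DilutionSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    do.call(rbind, lapply(x@states, function(s)
      data.frame(concentration_mM = s@targetConcentration,
                 parent_volume_ml = s@parentVolumeAdded,
                 total_volume_ml = s@totalVolume,
                 total_mass_g = s@totalMass,
                 density_g_per_ml = s@density,
                 gd_mass_g = s@gdMass, w_gd = s@wGd)))
  })

#' Mixture-rule mass attenuation coefficient of the solution
#'
#' Hubbell's weighted-average mixture rule for a homogeneous solution,
#' specialised to the two-component Gd + water form:
#' `mac_soln = mac_water * (1 - wGd) + mac_gd * wGd`. The result is bounded
#' by the pure-component coefficients. Chelator and tracer mass attenuate as
#' water; only the Gd weight fraction carries the Gd coefficient.
#'
#' @param wGd Gd weight fraction in \[0, 1\] (vectorised).
#' @param energy photon energy, keV (511 aliases to the 500 keV entry).
#' @param table an [AttenuationTable-class].
#' @return MAC of the solution, cm^2/g.
#' @examples
#' mixtureMAC(0, 511)       # pure water, 0.09687
#' mixtureMAC(0.0101, 511)  # 66 mM-like solution
#' @export
mixtureMAC <- function(wGd, energy, table = defaultAttenuationTable()) {
  if (!is.numeric(wGd) || any(!is.finite(wGd)) ||
      any(wGd < 0) || any(wGd > 1))
    stop("wGd must lie in [0, 1]", call. = FALSE)
  mac <- macAt(table, energy)
  mac[["water"]] * (1 - wGd) + mac[["gd"]] * wGd
}

#' Linear attenuation coefficient of a solution state
#'
#' `LAC = MAC x density`: the mixture-rule mass attenuation coefficient at
#' the requested energy times the state's solution density.
#'
#' @param state a [SolutionState-class].
#' @param energy photon energy, keV.
#' @param table an [AttenuationTable-class].
#' @return LAC, cm^-1.
#' @examples
#' s <- seriesStates(buildDilutionSeries())[[21]]
#' solutionLAC(s, 511)  # ~0.0993
#' @export
solutionLAC <- function(state, energy, table = defaultAttenuationTable()) {
  stopifnot(is(state, "SolutionState"))
  mixtureMAC(state@wGd, energy, table) * state@density
}

#' Percent LAC increase over a dilution series
#'
#' `100 * (LAC_last - LAC_first) / LAC_first` at the requested energy. For
#' the default series at 511 keV this is about 2.5 percent, the solution's
#' attenuation rise between 0 and 66 mM.
#'
#' @param series a [DilutionSeries-class].
#' @inheritParams solutionLAC
#' @return percent increase.
#' @export
lacIncreasePercent <- function(series, energy = 511,
                               table = defaultAttenuationTable()) {
  stopifnot(is(series, "DilutionSeries"))
  n <- length(series@states)
  if (n < 1L) stop("series is empty", call. = FALSE)
  if (n == 1L) return(0)
  first <- solutionLAC(series@states[[1]], energy, table)
  last <- solutionLAC(series@states[[n]], energy, table)
  100 * (last - first) / first
}

#' Mixture-rule attenuation curve over a dilution series
#'
#' One row per (state, energy) with the concentration, mixture MAC, density
#' and LAC, plus the volume bookkeeping: the model analogue of the measured
#' attenuation-versus-concentration curve.
#'
#' @param series a [DilutionSeries-class].
#' @param energies photon energies, keV.
#' @param table an [AttenuationTable-class].
#' @return data.frame with columns `concentration_mM`, `parent_volume_ml`,
#'   `total_volume_ml`, `density_g_per_ml`, `w_gd`, `energy_keV`,
#'   `mac_cm2_per_g`, `lac_per_cm`.
#' @export
mixtureCurve <- function(series, energies = 511,
                         table = defaultAttenuationTable()) {
  stopifnot(is(series, "DilutionSeries"))
  rows <- lapply(series@states, function(s) {
    do.call(rbind, lapply(energies, function(e) {
      mac <- mixtureMAC(s@wGd, e, table)
      data.frame(concentration_mM = s@targetConcentration,
                 parent_volume_ml = s@parentVolumeAdded,
                 total_volume_ml = s@totalVolume,
                 density_g_per_ml = s@density, w_gd = s@wGd,
                 energy_keV = e, mac_cm2_per_g = mac,
                 lac_per_cm = mac * s@density)
    }))
  })
  do.call(rbind, rows)
}
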