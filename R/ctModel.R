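#' Construct bilinear HU-to-LAC calibration parameters
#'
#' The CT scanner reports Hounsfield units at its effective beam energy; PET
#' attenuation correction needs LAC at 511 keV. The standard conversion is a
#' bilinear curve: water-like voxels (below the breakpoint) scale with one
#' slope through (-1000 HU, 0), bone-like voxels with a shallower slope. The
#' defaults describe a generic 140 kVp calibration: `slopeLow = 9.6e-5`
#' cm^-1/HU (so 0 HU maps to 0.096 cm^-1), breakpoint 47 HU, and a high
#' segment that is continuous at the breakpoint and maps 1000 HU to 0.125
#' cm^-1 (cortical-bone range). When `interceptHigh` is `NULL` it is derived
#' from the continuity condition.
#'
#' @param kvp tube voltage, kV.
#' @param breakpoint segment boundary, HU.
#' @param slopeLow low segment slope, cm^-1 per HU.
#' @param slopeHigh high segment slope, cm^-1 per HU.
#' @param interceptHigh high segment intercept, cm^-1, or `NULL` to enforce
#'   continuity at the breakpoint.
#' @return A [BilinearParams-class].
#' @examples
#' defaultBilinearParams()
#' @export
bilinearParams <- function(kvp = 140, breakpoint = 47, slopeLow = 9.6e-5,
                           slopeHigh = 2.571e-5, interceptHigh = NULL) {
  if (is.null(interceptHigh))
    interceptHigh <- (slopeLow - slopeHigh) * (breakpoint + 1000)
  new("BilinearParams", kvp = kvp, breakpoint = breakpoint,
      slopeLow = slopeLow, slopeHigh = slopeHigh,
      interceptHigh = interceptHigh)
}

#' @rdname bilinearParams
#' @export
defaultBilinearParams <- function() bilinearParams()

setMethod("show", "BilinearParams", function(object) {
  cat(sprintf(paste0("BilinearParams (%g kVp): breakpoint %g HU\n",
                     "  low: %.3e cm^-1/HU; high: %.3e cm^-1/HU + %.4f",
                     " cm^-1\n"),
              object@kvp, object@breakpoint, object@slopeLow,
              object@slopeHigh, object@interceptHigh))
})

#' Hounsfield units of a solution state at the CT surrogate energy
#'
#' Single-effective-energy CT model: the solution's linear attenuation at the
#' CT surrogate energy (default 150 keV, the tabulated point nearest a 140
#' kVp beam) is compared with water,
#' `HU = 1000 * (mu_soln - mu_water) / mu_water`. Beam hardening and the
#' polychromatic spectrum are not modelled.
#'
#' @param state a [SolutionState-class].
#' @param table an [AttenuationTable-class].
#' @param ctEnergy CT surrogate energy, keV (must be in the table).
#' @param waterDensity water density used for the HU reference, g/ml.
#' @return CT number, HU.
#' @examples
#' s <- seriesStates(buildDilutionSeries())[[21]]
#' huOfSolution(s)  # ~88.6 HU at 66 mM
#' @export
huOfSolution <- function(state, table = defaultAttenuationTable(),
                         ctEnergy = 150, waterDensity = 1.000) {
  stopifnot(is(state, "SolutionState"))
  muSoln <- mixtureMAC(state@wGd, ctEnergy, table) * state@density
  muWater <- macAt(table, ctEnergy)[["water"]] * waterDensity
  1000 * (muSoln - muWater) / muWater
}

#' Bilinear conversion from HU to 511 keV LAC
#'
#' Applies the piecewise-linear calibration: `slopeLow * (hu + 1000)` at or
#' below the breakpoint, `slopeHigh * (hu + 1000) + interceptHigh` above it.
#' Air (-1000 HU) maps to exactly zero; any negative result is clamped to
#' zero (physical non-negativity).
#'
#' @param hu CT numbers, HU (vectorised; must be >= -1000).
#' @param params a [BilinearParams-class].
#' @return LAC at 511 keV, cm^-1.
#' @examples
#' bilinearLAC(c(-1000, 0, 100))
#' @export
bilinearLAC <- function(hu, params = defaultBilinearParams()) {
  stopifnot(is(params, "BilinearParams"))
  if (any(!is.finite(hu)) || any(hu < -1000))
    stop("hu values must be finite and >= -1000", call. = FALSE)
  lac <- ifelse(hu <= params@breakpoint,
                params@slopeLow * (hu + 1000),
                params@slopeHigh * (hu + 1000) + params@interceptHigh)
  pmax(lac, 0)
}

#' Voxelwise bilinear conversion of a CT volume to a 511 keV LAC map
#'
#' @param huImage a [VoxelImage-class] tagged `"HU"`.
#' @param params a [BilinearParams-class].
#' @return A [VoxelImage-class] tagged `"LAC_per_cm"` with the same grid.
#' @export
lacMapFromCT <- function(huImage, params = defaultBilinearParams()) {
  stopifnot(is(huImage, "VoxelImage"))
  if (imageSemantics(huImage) != "HU")
    stop("lacMapFromCT needs an HU-tagged image, got '",
         imageSemantics(huImage), "'", call. = FALSE)
  vals <- huImage@values
  out <- array(bilinearLAC(as.vector(vals), params), dim = dim(vals))
  voxelImage(out, spacing = huImage@spacing, origin = huImage@origin,
             semantics = "LAC_per_cm")
}

#' CT-chain attenuation curve over a dilution series
#'
#' For each state: the single-energy CT number via [huOfSolution()] and its
#' bilinear conversion to 511 keV LAC - the synthetic analogue of scanning
#' each concentration step and converting the reconstructed HU.
#'
#' @param series a [DilutionSeries-class].
#' @param table an [AttenuationTable-class].
#' @param ctEnergy CT surrogate energy, keV.
#' @param params a [BilinearParams-class].
#' @param waterDensity water density for the HU reference, g/ml.
#' @return data.frame with columns `concentration_mM`, `hu`, `lac_per_cm`.
#' @export
ctDerivedCurve <- function(series, table = defaultAttenuationTable(),
                           ctEnergy = 150,
                           params = defaultBilinearParams(),
                           waterDensity = 1.000) {
  stopifnot(is(series, "DilutionSeries"))
  hu <- vapply(series@states, huOfSolution, numeric(1), table = table,
               ctEnergy = ctEnergy, waterDensity = waterDensity)
  data.frame(concentration_mM = seriesConcentrations(series), hu = hu,
             lac_per_cm = bilinearLAC(hu, params))
}
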