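## Molar mass of gadolinium, g/mol (one Gd ion per chelate complex).
GD_MOLAR_MASS <- 157.25

## Value-semantics tags for voxel images and sinograms.
VOXEL_SEMANTICS <- c("HU", "LAC_per_cm", "kBq_per_ml", "dimensionless")
SINOGRAM_SEMANTICS <- c("line_integral", "attenuation_factor", "counts",
                        "corrected_counts")

## Attenuation-correction strategy labels.
AC_METHODS <- c("AC1", "AC2", "AC3")

#' ContrastAgent: a gadolinium-based contrast agent parent solution
#'
#' Holds the composition of a GBCA parent solution: molarity of the Gd
#' complex, molecular weight of the active component, and the derived masses
#' of active compound and elemental Gd per ml of parent solution. The parent
#' density (g/ml) is not part of the product datasheet composition; it is
#' needed by the dilution-series density model and defaults to the DOTAREM
#' product value.
#'
#' @slot name agent name.
#' @slot molarity mmol of Gd complex per ml of parent solution.
#' @slot activeMW molecular weight of the active component, g/mol.
#' @slot activeMassPerMl mass of active component per ml of parent, mg/ml.
#' @slot gdMassPerMl mass of elemental Gd per ml of parent, mg/ml.
#' @slot parentDensity density of the parent solution, g/ml.
#' @exportClass ContrastAgent
setClass("ContrastAgent",
  representation(name = "character", molarity = "numeric",
                 activeMW = "numeric", activeMassPerMl = "numeric",
                 gdMassPerMl = "numeric", parentDensity = "numeric"))

setValidity("ContrastAgent", function(object) {
  msg <- character()
  for (s in c("name", "molarity", "activeMW", "activeMassPerMl",
              "gdMassPerMl", "parentDensity"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (object@molarity < 0) msg <- c(msg, "molarity must be non-negative")
  if (object@activeMW <= 0) msg <- c(msg, "activeMW must be positive")
  if (object@parentDensity <= 0) msg <- c(msg, "parentDensity must be positive")
  expected <- object@molarity * GD_MOLAR_MASS
  if (abs(object@gdMassPerMl - expected) >
      1e-6 * max(expected, .Machine$double.eps))
    msg <- c(msg, "gdMassPerMl must equal molarity x 157.25 g/mol (1e-6 rel)")
  if (object@activeMassPerMl < object@gdMassPerMl)
    msg <- c(msg, "activeMassPerMl must be >= gdMassPerMl")
  if (length(msg)) msg else TRUE
})

#' AttenuationTable: mass attenuation coefficients of water and gadolinium
#'
#' Tabulated mass attenuation coefficients (MAC, cm^2/g) of water and Gd per
#' photon energy. The default table carries the two energies the analysis
#' needs: 150 keV (surrogate for the 140 kVp CT beam) and 500 keV (used for
#' the 511 keV annihilation energy; lookups at 511 keV alias to the 500 keV
#' row).
#'
#' @slot entries data.frame with columns `energy_keV`, `mac_water`, `mac_gd`.
#' @exportClass AttenuationTable
setClass("AttenuationTable", representation(entries = "data.frame"))

setValidity("AttenuationTable", function(object) {
  e <- object@entries
  msg <- character()
  if (!all(c("energy_keV", "mac_water", "mac_gd") %in% names(e)))
    return("entries needs columns energy_keV, mac_water, mac_gd")
  if (nrow(e) < 1L) return("entries must have at least one row")
  if (any(e$energy_keV <= 0) || any(e$mac_water <= 0) || any(e$mac_gd <= 0))
    msg <- c(msg, "energies and MAC values must be positive")
  if (is.unsorted(e$energy_keV, strictly = TRUE))
    msg <- c(msg, "energies must be strictly increasing")
  if (any(e$mac_gd <= e$mac_water))
    msg <- c(msg, "mac_gd must exceed mac_water at every energy")
  if (length(msg)) msg else TRUE
})

#' SolutionState: one step of the phantom dilution series
#'
#' Mass and volume bookkeeping for the phantom solution at one Gd
#' concentration: cumulative parent-solution volume added to the water +
#' tracer base, the resulting total volume, mass, density, and the Gd weight
#' fraction that enters the mixture rule. The solution is treated as a
#' two-component Gd + water mixture, so the weight fractions sum to one.
#'
#' @slot targetConcentration Gd concentration, mM.
#' @slot baseWaterVolume distilled water volume, ml.
#' @slot tracerVolume radiotracer solution volume (counted as water), ml.
#' @slot parentVolumeAdded cumulative GBCA parent volume added, ml.
#' @slot totalVolume total solution volume (additive volumes), ml.
#' @slot totalMass total solution mass, g.
#' @slot density solution density, g/ml.
#' @slot gdMass elemental Gd mass in solution, g.
#' @slot wGd Gd weight fraction (dimensionless).
#' @slot wWater water weight fraction, `1 - wGd`.
#' @exportClass SolutionState
setClass("SolutionState",
  representation(targetConcentration = "numeric", baseWaterVolume = "numeric",
                 tracerVolume = "numeric", parentVolumeAdded = "numeric",
                 totalVolume = "numeric", totalMass = "numeric",
                 density = "numeric", gdMass = "numeric",
                 wGd = "numeric", wWater = "numeric"))

setValidity("SolutionState", function(object) {
  msg <- character()
  if (abs(object@wGd + object@wWater - 1) > 1e-12)
    msg <- c(msg, "wGd + wWater must equal 1")
  if (object@wGd < 0 || object@wGd >= 1)
    msg <- c(msg, "wGd must lie in [0, 1)")
  vol <- object@baseWaterVolume + object@tracerVolume +
    object@parentVolumeAdded
  if (abs(object@totalVolume - vol) > 1e-9 * vol)
    msg <- c(msg, "totalVolume must be the sum of its parts")
  conc <- 1e6 * object@gdMass / GD_MOLAR_MASS / object@totalVolume
  if (abs(conc - object@targetConcentration) >
      1e-9 * max(object@targetConcentration, 1e-12))
    msg <- c(msg, "gdMass inconsistent with targetConcentration")
  if (length(msg)) msg else TRUE
})

#' DilutionSeries: an ordered sequence of solution states
#'
#' @slot agent the [ContrastAgent-class] used for the series.
#' @slot states list of [SolutionState-class], ordered by concentration.
#' @slot waterDensity water density used by the mass model, g/ml.
#' @exportClass DilutionSeries
setClass("DilutionSeries",
  representation(agent = "ContrastAgent", states = "list",
                 waterDensity = "numeric"))

setValidity("DilutionSeries", function(object) {
  if (!all(vapply(object@states, is, logical(1), "SolutionState")))
    return("states must all be SolutionState objects")
  conc <- vapply(object@states, slot, numeric(1), "targetConcentration")
  if (length(conc) > 1L && is.unsorted(conc, strictly = TRUE))
    return("states must be ordered by strictly increasing concentration")
  TRUE
})

#' BilinearParams: bilinear HU to 511 keV LAC calibration
#'
#' Parameters of the piecewise-linear CT calibration that converts Hounsfield
#' units to linear attenuation coefficients at 511 keV. Below the breakpoint
#' the map is `slopeLow * (HU + 1000)` (so air at -1000 HU maps to exactly
#' zero); above it, `slopeHigh * (HU + 1000) + interceptHigh`.
#'
#' @slot kvp tube voltage the calibration refers to, kV.
#' @slot breakpoint HU value separating the two segments.
#' @slot slopeLow low segment slope, cm^-1 per HU.
#' @slot slopeHigh high segment slope, cm^-1 per HU.
#' @slot interceptHigh high segment intercept, cm^-1.
#' @exportClass BilinearParams
setClass("BilinearParams",
  representation(kvp = "numeric", breakpoint = "numeric",
                 slopeLow = "numeric", slopeHigh = "numeric",
                 interceptHigh = "numeric"))

setValidity("BilinearParams", function(object) {
  msg <- character()
  if (object@slopeLow < 0 || object@slopeHigh < 0)
    msg <- c(msg, "slopes must be non-negative")
  bp1000 <- object@breakpoint + 1000
  low <- object@slopeLow * bp1000
  high <- object@slopeHigh * bp1000 + object@interceptHigh
  if (high < low - 1e-9)
    msg <- c(msg, "map must be non-decreasing across the breakpoint")
  if (length(msg)) msg else TRUE
})

#' VoxelImage: a 3-D voxel grid with physical spacing and value semantics
#'
#' @slot values 3-D numeric array (x, y, z).
#' @slot spacing voxel spacing per axis, mm.
#' @slot origin world coordinate of the centre of voxel (1,1,1), mm.
#' @slot semantics one of `"HU"`, `"LAC_per_cm"`, `"kBq_per_ml"`,
#'   `"dimensionless"`.
#' @exportClass VoxelImage
setClass("VoxelImage",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 semantics = "character"))

setValidity("VoxelImage", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    return("values must be a 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (!(length(object@semantics) == 1L &&
        object@semantics %in% VOXEL_SEMANTICS))
    msg <- c(msg, sprintf("semantics must be one of %s",
                          paste(VOXEL_SEMANTICS, collapse = ", ")))
  else if (object@semantics %in% c("LAC_per_cm", "kBq_per_ml") &&
           any(object@values < -1e-9))
    msg <- c(msg, "LAC and activity images must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Sinogram: parallel-beam projection data
#'
#' Per-slice parallel-beam projections stored as an (angles x radial bins x
#' slices) array. Semantics distinguish raw line integrals, attenuation
#' correction factors (`exp(+integral of mu)`, so always >= 1), emission
#' counts, and attenuation-corrected counts.
#'
#' @slot values 3-D numeric array (angle, radial bin, slice).
#' @slot angles projection angles in degrees over \[0, 180).
#' @slot radialSpacing radial bin spacing, mm.
#' @slot semantics one of `"line_integral"`, `"attenuation_factor"`,
#'   `"counts"`, `"corrected_counts"`.
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "array", angles = "numeric",
                 radialSpacing = "numeric", semantics = "character"))

setValidity("Sinogram", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    return("values must be a 3-D array (angle x radial x slice)")
  if (dim(object@values)[1] != length(object@angles))
    msg <- c(msg, "first dimension must match the number of angles")
  if (any(object@angles < 0) || any(object@angles >= 180))
    msg <- c(msg, "angles must lie in [0, 180)")
  if (length(object@radialSpacing) != 1L || object@radialSpacing <= 0)
    msg <- c(msg, "radialSpacing must be a positive scalar")
  if (!(length(object@semantics) == 1L &&
        object@semantics %in% SINOGRAM_SEMANTICS))
    msg <- c(msg, sprintf("semantics must be one of %s",
                          paste(SINOGRAM_SEMANTICS, collapse = ", ")))
  else if (object@semantics == "attenuation_factor" &&
           any(object@values < 1 - 1e-9))
    msg <- c(msg, "attenuation factors must be >= 1")
  else if (object@semantics == "counts" && any(object@values < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ProjectionGeometry: 2-D parallel-beam acquisition geometry
#'
#' @slot angles projection angles in degrees over \[0, 180).
#' @slot nRadial number of radial bins.
#' @slot radialSpacing radial bin spacing, mm.
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry",
  representation(angles = "numeric", nRadial = "integer",
                 radialSpacing = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  msg <- character()
  if (length(object@angles) < 1L || any(object@angles < 0) ||
      any(object@angles >= 180))
    msg <- c(msg, "angles must lie in [0, 180)")
  if (object@nRadial < 2L) msg <- c(msg, "nRadial must be >= 2")
  if (object@radialSpacing <= 0) msg <- c(msg, "radialSpacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: the cylindrical phantom and acquisition bookkeeping
#'
#' Geometry of the thin plastic bottle (5 cm diameter, 8.5 cm height), the
#' activity placed in it at fill time, the tracer half-life, scan duration and
#' the voxel grid on which the phantom is rasterised.
#'
#' @slot diameterCm inner cylinder diameter, cm.
#' @slot heightCm inner cylinder height, cm.
#' @slot activityMBq activity at fill time, MBq.
#' @slot halfLifeMin tracer half-life, minutes (F-18: 109.77).
#' @slot scanDurationMin duration of each scan, minutes.
#' @slot grid voxel grid dimensions (nx, ny, nz).
#' @slot spacingMm voxel spacing per axis, mm.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(diameterCm = "numeric", heightCm = "numeric",
                 activityMBq = "numeric", halfLifeMin = "numeric",
                 scanDurationMin = "numeric", grid = "integer",
                 spacingMm = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@diameterCm <= 0 || object@heightCm <= 0)
    msg <- c(msg, "cylinder dimensions must be positive")
  if (object@activityMBq <= 0) msg <- c(msg, "activityMBq must be positive")
  if (object@halfLifeMin <= 0) msg <- c(msg, "halfLifeMin must be positive")
  if (length(object@grid) != 3L || any(object@grid < 1L))
    msg <- c(msg, "grid must be 3 positive integers")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' VOIBox: an axis-aligned volume of interest on a voxel grid
#'
#' @slot xRange,yRange,zRange inclusive voxel index ranges.
#' @slot nVoxels number of voxels in the box.
#' @slot volumeMm3 physical box volume, mm^3.
#' @exportClass VOIBox
setClass("VOIBox",
  representation(xRange = "integer", yRange = "integer", zRange = "integer",
                 nVoxels = "numeric", volumeMm3 = "numeric"))

#' PhantomStudy: results of a full simulated phantom experiment
#'
#' @slot results data.frame of per-step, per-method quantification results.
#' @slot calibration scalar image calibration factor (kBq/ml per
#'   reconstructed unit), from the matched-map reference reconstruction.
#' @slot series the [DilutionSeries-class] that was simulated.
#' @slot params list of run parameters (geometry, bilinear curve, seeds, ...).
#' @exportClass PhantomStudy
setClass("PhantomStudy",
  representation(results = "data.frame", calibration = "numeric",
                 series = "DilutionSeries", params = "list"))
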