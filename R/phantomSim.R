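#' Construct a phantom specification
#'
#' The physical phantom is a thin plastic bottle, 5 cm inner diameter and
#' 8.5 cm height (166.9 ml capacity), filled with the dilution-series
#' solution and 40 MBq of F-18 radiotracer. The bottle wall is thin and is
#' ignored: voxels are solution or air. The cylinder axis runs along z, the
#' world origin is on the axis at the bottom of the bottle.
#'
#' @param diameterCm inner diameter, cm (default 5).
#' @param heightCm inner height, cm (default 8.5).
#' @param activityMBq activity at fill time, MBq (default 40).
#' @param halfLifeMin tracer half-life, minutes (default 109.77, F-18).
#' @param scanDurationMin scan duration, minutes (default 3).
#' @param grid voxel grid (nx, ny, nz); default 128 x 128 x 85 at 1 mm.
#' @param spacingMm voxel spacing, mm (scalar recycled to 3).
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(diameterCm = 5, heightCm = 8.5, activityMBq = 40,
                        halfLifeMin = 109.77, scanDurationMin = 3,
                        grid = c(128L, 128L, 85L), spacingMm = 1) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  new("PhantomSpec", diameterCm = diameterCm, heightCm = heightCm,
      activityMBq = activityMBq, halfLifeMin = halfLifeMin,
      scanDurationMin = scanDurationMin, grid = as.integer(grid),
      spacingMm = spacingMm)
}

#' @describeIn phantomSpec Cylinder capacity, ml.
#' @param spec a [PhantomSpec-class].
#' @export
cylinderVolume <- function(spec)
  pi * (spec@diameterCm / 2)^2 * spec@heightCm

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: d %.3g cm, h %.3g cm (%.1f ml),",
                     " %.3g MBq at fill\n  grid %d x %d x %d at",
                     " %g x %g x %g mm\n"),
              object@diameterCm, object@heightCm, cylinderVolume(object),
              object@activityMBq, object@grid[1], object@grid[2],
              object@grid[3], object@spacingMm[1], object@spacingMm[2],
              object@spacingMm[3]))
})

#' Radioactive decay correction
#'
#' `activity x 2^(-dt / halfLife)`. Negative `dt` back-corrects (undoes one
#' interval of decay), so correcting every scan to a common time point and
#' re-correcting to the same point is the identity.
#'
#' @param activity activity (any unit; vectorised).
#' @param dt elapsed time, minutes (may be negative).
#' @param halfLife half-life, minutes (> 0).
#' @return decayed (or back-corrected) activity.
#' @examples
#' decayCorrect(40, 109.77, 109.77)  # 20: one half-life
#' @export
decayCorrect <- function(activity, dt, halfLife = 109.77) {
  checkScalar(halfLife, "halfLife", min = 0, strict = TRUE)
  activity * 2^(-dt / halfLife)
}

#' Rasterise the phantom at one dilution step
#'
#' Builds the voxelised phantom for one solution state: the solution
#' occupies the bottom `totalVolume / cross-section` of the cylinder
#' (voxels whose in-plane centre is within the cylinder radius and whose z
#' centre is below the fill height); everything else is air. The activity
#' image is uniform at `activityMBq x 1000 / totalVolume` kBq/ml inside the
#' solution, the attenuation image is uniform at `lac511` cm^-1, and the
#' mask tags the solution region.
#'
#' @param spec a [PhantomSpec-class].
#' @param state a [SolutionState-class]; its `totalVolume` is the fill
#'   volume and must not exceed the cylinder capacity.
#' @param lac511 solution LAC at 511 keV, cm^-1 (from [solutionLAC()]).
#' @param activityMBq activity in the solution at scan time, MBq; defaults
#'   to the fill activity (no decay).
#' @return list with components `activity`, `mu`, `mask`
#'   ([VoxelImage-class]s tagged `kBq_per_ml`, `LAC_per_cm`,
#'   `dimensionless`) and `fillHeightCm`.
#' @export
buildPhantom <- function(spec, state, lac511,
                         activityMBq = spec@activityMBq) {
  stopifnot(is(spec, "PhantomSpec"), is(state, "SolutionState"))
  checkScalar(lac511, "lac511", min = 0)
  fill <- state@totalVolume
  if (fill > cylinderVolume(spec))
    stop(sprintf("fill volume %.1f ml exceeds cylinder capacity %.1f ml",
                 fill, cylinderVolume(spec)), call. = FALSE)
  area <- pi * (spec@diameterCm / 2)^2                 # cm^2
  fillHeight <- fill / area                            # cm
  d <- spec@grid
  sp <- spec@spacingMm
  ## in-plane voxel centre coordinates, mm, origin on the cylinder axis
  xc <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  yc <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  r2 <- outer(xc^2, yc^2, "+")
  inDisk <- r2 <= (spec@diameterCm * 10 / 2)^2
  zc <- (seq_len(d[3]) - 0.5) * sp[3]                  # mm above bottom
  inFill <- zc <= fillHeight * 10
  mask <- array(0, d)
  mask[, , inFill] <- inDisk
  conc <- activityMBq * 1000 / fill                    # kBq/ml
  origin <- c(xc[1], yc[1], zc[1])
  list(activity = voxelImage(mask * conc, sp, origin, "kBq_per_ml"),
       mu = voxelImage(mask * lac511, sp, origin, "LAC_per_cm"),
       mask = voxelImage(mask, sp, origin, "dimensionless"),
       fillHeightCm = fillHeight)
}

#' Simulate an emission scan as an attenuated sinogram
#'
#' Expected counts per line of response are
#' `countsScale x (line integral of activity) / ACF`, the attenuated
#' forward projection of the activity image (ACF from the true attenuation
#' map, so `1/ACF` is the pair survival probability). With a `seed`, each
#' bin is replaced by a Poisson sample with that expectation; without one,
#' the expected (noise-free) sinogram is returned. `countsScale` is an
#' abstract detector sensitivity: no scanner model is implied, and the
#' calibration step of the reconstruction removes it.
#'
#' @param activity a [VoxelImage-class] tagged `"kBq_per_ml"`.
#' @param mu a [VoxelImage-class] tagged `"LAC_per_cm"` on the same grid.
#' @param geometry a [ProjectionGeometry-class].
#' @param countsScale counts per (kBq/ml x cm) of attenuated projection;
#'   the default 10 puts about 1e4 expected counts in a central bin of the
#'   default phantom.
#' @param seed integer seed for Poisson noise, or `NULL` for the noise-free
#'   expectation. The caller's RNG state is left untouched.
#' @return A [Sinogram-class] tagged `"counts"`.
#' @export
simulateEmission <- function(activity, mu, geometry, countsScale = 10,
                             seed = NULL) {
  stopifnot(is(activity, "VoxelImage"), is(mu, "VoxelImage"))
  if (imageSemantics(activity) != "kBq_per_ml")
    stop("activity image must be tagged kBq_per_ml", call. = FALSE)
  if (!identical(dim(activity@values), dim(mu@values)) ||
      !isTRUE(all.equal(activity@spacing, mu@spacing)))
    stop("activity and mu images must share one grid", call. = FALSE)
  checkScalar(countsScale, "countsScale", min = 0)
  proj <- forwardProject(activity, geometry)
  acf <- attenuationFactors(mu, geometry)
  expected <- countsScale * proj@values / acf@values
  vals <- if (is.null(seed)) expected else
    withSeed(seed,
             array(stats::rpois(length(expected), as.vector(expected)),
                   dim = dim(expected)))
  newSinogram(vals, geometry, "counts")
}
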