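#' Build an attenuation-correction map for one strategy
#'
#' The three correction strategies of the phantom study:
#' \describe{
#'   \item{AC1}{the CT-derived LAC map of the same concentration step -
#'     bilinear conversion of that step's CT volume.}
#'   \item{AC2}{the CT-derived LAC map of the 0 mM step (no contrast
#'     present), regardless of the current step - the clinical single
#'     pre-contrast map scenario.}
#'   \item{AC3}{a uniform 0.1 cm^-1 map inside the phantom mask - the
#'     soft-tissue value an MR-based segmentation would assign.}
#' }
#'
#' @param method `"AC1"`, `"AC2"` or `"AC3"`.
#' @param stepIndex 1-based concentration step index.
#' @param ctVolumes list of HU-tagged [VoxelImage-class]s indexed by step;
#'   only the entries a method needs must be present (AC1: `stepIndex`,
#'   AC2: 1, AC3: none).
#' @param mask solution-region mask ([VoxelImage-class], current step).
#' @param params a [BilinearParams-class] for the CT conversion.
#' @return A [VoxelImage-class] tagged `"LAC_per_cm"`.
#' @export
makeACMap <- function(method, stepIndex, ctVolumes, mask,
                      params = defaultBilinearParams()) {
  if (!(is.character(method) && length(method) == 1L &&
        method %in% AC_METHODS))
    stop("unknown AC method '", paste(method, collapse = ","),
         "'; expected AC1, AC2 or AC3", call. = FALSE)
  switch(method,
    AC1 = lacMapFromCT(ctVolumes[[stepIndex]], params),
    AC2 = lacMapFromCT(ctVolumes[[1L]], params),
    AC3 = {
      stopifnot(is(mask, "VoxelImage"))
      voxelImage(mask@values * 0.1, mask@spacing, mask@origin,
                 "LAC_per_cm")
    })
}

#' Attenuation-correct an emission sinogram
#'
#' Multiplies each emission bin by the estimated attenuation correction
#' factor derived from the supplied AC map:
#' `corrected = emission x exp(+ integral of mu_est dl)`. When the map
#' equals the attenuation actually applied in the simulation the correction
#' is exact and the corrected sinogram equals the unattenuated projection.
#'
#' @param emission a [Sinogram-class] tagged `"counts"`.
#' @param acMap a [VoxelImage-class] tagged `"LAC_per_cm"`.
#' @param geometry the [ProjectionGeometry-class] of the acquisition.
#' @return A [Sinogram-class] tagged `"corrected_counts"`.
#' @export
correctSinogram <- function(emission, acMap, geometry) {
  stopifnot(is(emission, "Sinogram"))
  if (sinogramSemantics(emission) != "counts")
    stop("emission sinogram must be tagged 'counts'", call. = FALSE)
  acf <- attenuationFactors(acMap, geometry)
  if (!identical(dim(acf@values), dim(emission@values)))
    stop("AC map and emission sinogram grids are inconsistent",
         call. = FALSE)
  newSinogram(emission@values * acf@values, geometry, "corrected_counts")
}

#' Filtered back-projection reconstruction
#'
#' Per-slice 2-D FBP with a band-limited ramp (Ram-Lak) filter: each
#' projection is convolved with the discrete ramp kernel and back-projected
#' with linear interpolation onto the grid of `template`. The result is
#' scaled by `calibration` (see [calibrateCounts()]) to express voxel values
#' in absolute kBq/ml; negative values from filter ringing are clamped to
#' zero.
#'
#' @param sinogram a [Sinogram-class] tagged `"corrected_counts"`,
#'   `"counts"` or `"line_integral"`.
#' @param geometry the [ProjectionGeometry-class] of the acquisition.
#' @param template a [VoxelImage-class] supplying the output grid, spacing
#'   and origin.
#' @param calibration scalar factor applied to the reconstruction
#'   (default 1, i.e. uncalibrated).
#' @return A [VoxelImage-class] tagged `"kBq_per_ml"`.
#' @export
fbpReconstruct <- function(sinogram, geometry, template, calibration = 1) {
  stopifnot(is(sinogram, "Sinogram"), is(template, "VoxelImage"))
  if (!sinogramSemantics(sinogram) %in%
      c("corrected_counts", "counts", "line_integral"))
    stop("cannot reconstruct a sinogram tagged '",
         sinogramSemantics(sinogram), "'", call. = FALSE)
  if (length(sinogram@values) == 0L)
    stop("empty sinogram", call. = FALSE)
  d <- dim(template@values)
  if (dim(sinogram@values)[3] != d[3])
    stop("sinogram slice count does not match the template grid",
         call. = FALSE)
  checkScalar(calibration, "calibration")
  vals <- mapSlices(sinogram@values, function(p)
    fbpSlice(p, geometry, d[1], d[2], template@spacing[1:2],
             template@origin[1:2]))
  voxelImage(pmax(vals * calibration, 0), template@spacing,
             template@origin, "kBq_per_ml")
}

#' Image calibration factor from a matched-map reference reconstruction
#'
#' One scalar per geometry/configuration that absorbs the abstract detector
#' sensitivity (`countsScale`) and the discretisation gain of the
#' projector/FBP chain, mirroring the cross-calibration between a dose
#' calibrator and a PET scanner. It is computed self-consistently: the
#' reference state (by default the contrast-free 0 mM step) is rasterised,
#' a noise-free emission scan is simulated, corrected with its own
#' CT-derived attenuation map (the matched, AC1-style correction), FBP
#' reconstructed without calibration, and the factor is
#' `true concentration / VOI mean`. By construction a matched noise-free
#' reconstruction then reads back the true kBq/ml; the factor is
#' independent of the activity level and of `countsScale`.
#'
#' @param spec a [PhantomSpec-class].
#' @param geometry a [ProjectionGeometry-class].
#' @param state reference [SolutionState-class]; default the 0 mM state of
#'   the default dilution series.
#' @param table an [AttenuationTable-class].
#' @param params a [BilinearParams-class] for the CT-derived map.
#' @param countsScale detector sensitivity used in the reference simulation.
#' @param voiVolumeCm3 VOI volume for the reference mean, cm^3.
#' @return calibration factor, kBq/ml per reconstructed unit.
#' @export
calibrateCounts <- function(spec, geometry,
                            state = seriesStates(buildDilutionSeries())[[1]],
                            table = defaultAttenuationTable(),
                            params = defaultBilinearParams(),
                            countsScale = 10, voiVolumeCm3 = 75) {
  stopifnot(is(spec, "PhantomSpec"))
  lac <- solutionLAC(state, 511, table)
  ph <- buildPhantom(spec, state, lac)
  hu <- huOfSolution(state, table)
  ct <- voxelImage(ph$mask@values * (hu + 1000) - 1000, ph$mask@spacing,
                   ph$mask@origin, "HU")
  acMap <- lacMapFromCT(ct, params)
  emission <- simulateEmission(ph$activity, ph$mu, geometry, countsScale)
  corrected <- correctSinogram(emission, acMap, geometry)
  recon <- fbpReconstruct(corrected, geometry, ph$mask)
  voi <- centralVOI(ph$mask, voiVolumeCm3)
  truth <- spec@activityMBq * 1000 / state@totalVolume
  truth / voiStats(recon, voi)$mean
}
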