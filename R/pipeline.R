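#' Run the full simulated phantom experiment
#'
#' End-to-end analogue of the physical study: for every dilution step the
#' phantom is rasterised with its mixture-rule 511 keV attenuation, a
#' synthetic CT volume is generated (single-effective-energy HU plus air
#' background), an emission sinogram is simulated (noise-free or Poisson),
#' corrected with each requested AC strategy, FBP-reconstructed, calibrated,
#' decay-corrected to the common time point (the first scan start), and
#' reduced to VOI statistics against the decay- and volume-corrected ground
#' truth.
#'
#' One 75 cm^3 VOI is derived from the 0 mM mask and reused for every step;
#' since later fill volumes only grow, the box stays inside the solution,
#' and per-step bias differences are then driven by the attenuation physics
#' rather than by VOI placement jitter.
#'
#' The optional `"matched"` rows correct each emission sinogram with the
#' same attenuation map that generated it - the self-consistency reference
#' whose residual bias is discretisation plus calibration only.
#'
#' @param series a [DilutionSeries-class] (default: the full 21-step
#'   recipe).
#' @param spec a [PhantomSpec-class].
#' @param geometry a [ProjectionGeometry-class]; default 180 angles at the
#'   voxel pitch of `spec`.
#' @param table an [AttenuationTable-class].
#' @param bilinear a [BilinearParams-class].
#' @param acMethods subset of `c("AC1", "AC2", "AC3")`.
#' @param includeMatched also report matched-map corrected rows (labelled
#'   `"matched"`).
#' @param countsScale detector sensitivity (see [simulateEmission()]).
#' @param noise `"none"` (expected-value sinograms) or `"poisson"`.
#' @param seed integer; with `noise = "poisson"`, step `k` uses substream
#'   `seed + k - 1`.
#' @param scanIntervalMin minutes between consecutive step scans (the
#'   paper-style schedule: one scan per step on a fixed interval).
#' @param voiVolumeCm3 VOI volume, cm^3.
#' @return A [PhantomStudy-class]; its `results` slot has one row per
#'   (step, method) as in [biasTable()].
#' @examples
#' \dontrun{
#' study <- runPhantomStudy()          # full 21-step run, a few minutes
#' studyResults(study)
#' }
#' @export
runPhantomStudy <- function(series = buildDilutionSeries(),
                            spec = phantomSpec(),
                            geometry = parallelGeometry(
                              nRadial = spec@grid[1],
                              radialSpacing = spec@spacingMm[1]),
                            table = defaultAttenuationTable(),
                            bilinear = defaultBilinearParams(),
                            acMethods = AC_METHODS,
                            includeMatched = FALSE,
                            countsScale = 10,
                            noise = c("none", "poisson"), seed = NULL,
                            scanIntervalMin = 10, voiVolumeCm3 = 75) {
  noise <- match.arg(noise)
  if (noise == "poisson" && is.null(seed))
    stop("poisson noise needs a seed", call. = FALSE)
  stopifnot(all(acMethods %in% AC_METHODS))
  states <- seriesStates(series)
  n <- length(states)

  ## reference pieces reused across steps
  cal <- calibrateCounts(spec, geometry, states[[1]], table, bilinear,
                         countsScale, voiVolumeCm3)
  ph0 <- buildPhantom(spec, states[[1]], solutionLAC(states[[1]], 511,
                                                    table))
  voi <- centralVOI(ph0$mask, voiVolumeCm3)
  makeCT <- function(ph, state) {
    hu <- huOfSolution(state, table, waterDensity = series@waterDensity)
    voxelImage(ph$mask@values * (hu + 1000) - 1000, ph$mask@spacing,
               ph$mask@origin, "HU")
  }
  ct0 <- makeCT(ph0, states[[1]])

  recons <- list()
  truths <- numeric(n)
  for (k in seq_len(n)) {
    state <- states[[k]]
    tScan <- (k - 1) * scanIntervalMin
    lacTrue <- solutionLAC(state, 511, table)
    ph <- buildPhantom(spec, state, lacTrue,
                       activityMBq = decayCorrect(spec@activityMBq, tScan,
                                                  spec@halfLifeMin))
    ctVols <- vector("list", n)
    ctVols[[1L]] <- ct0
    ctVols[[k]] <- if (k == 1L) ct0 else makeCT(ph, state)
    stepSeed <- if (noise == "poisson") seed + k - 1L else NULL
    emission <- simulateEmission(ph$activity, ph$mu, geometry, countsScale,
                                 stepSeed)
    undoDecay <- 2^(tScan / spec@halfLifeMin)
    methods <- c(acMethods, if (includeMatched) "matched")
    for (method in methods) {
      acMap <- if (method == "matched") ph$mu else
        makeACMap(method, k, ctVols, ph$mask, bilinear)
      corrected <- correctSinogram(emission, acMap, geometry)
      recon <- fbpReconstruct(corrected, geometry, ph$mask,
                              calibration = cal * undoDecay)
      recons[[length(recons) + 1L]] <-
        list(step = k, concentration = state@targetConcentration,
             method = method, image = recon)
    }
    truths[k] <- trueConcentration(spec, state, atTime = 0)
  }
  results <- biasTable(recons, truths, voi)
  new("PhantomStudy", results = results, calibration = cal,
      series = series,
      params = list(grid = spec@grid, spacingMm = spec@spacingMm,
                    nAngles = length(geometry@angles),
                    countsScale = countsScale, noise = noise, seed = seed,
                    scanIntervalMin = scanIntervalMin,
                    voiVolumeCm3 = voiVolumeCm3,
                    voi = voi,
                    bilinear = list(kvp = bilinear@kvp,
                                    breakpoint = bilinear@breakpoint,
                                    slopeLow = bilinear@slopeLow,
                                    slopeHigh = bilinear@slopeHigh,
                                    interceptHigh = bilinear@interceptHigh)))
}

#' @describeIn runPhantomStudy Per-(step, method) results accessor.
#' @param study a [PhantomStudy-class].
#' @export
studyResults <- function(study) study@results

#' @describeIn runPhantomStudy Calibration factor accessor.
#' @export
studyCalibration <- function(study) study@calibration

setMethod("show", "PhantomStudy", function(object) {
  r <- object@results
  cat(sprintf("PhantomStudy: %d steps x %d methods (%s noise)\n",
              length(unique(r$step)), length(unique(r$ac_method)),
              object@params$noise))
  for (m in unique(r$ac_method))
    cat(sprintf("  %-7s max |bias| %.2f%%\n", m,
                max(abs(r$bias_percent[r$ac_method == m]))))
})

#' Summarise a phantom study
#'
#' Per-method maximum absolute bias and trend, plus the AC1-vs-AC2 mean
#' difference when both are present: the numbers the study's conclusions
#' rest on.
#'
#' @param study a [PhantomStudy-class].
#' @return list with `max_abs_bias_percent` (named per method),
#'   `ac1_vs_ac2_mean_difference_percent` (or `NA`), and `trends` (per
#'   method, see [trendCheck()]).
#' @export
summarizeStudy <- function(study) {
  r <- studyResults(study)
  methods <- unique(r$ac_method)
  maxBias <- vapply(methods, function(m)
    max(abs(r$bias_percent[r$ac_method == m])), numeric(1))
  names(maxBias) <- methods
  acDiff <- if (all(c("AC1", "AC2") %in% methods))
    acPairMeanDifference(r, "AC1", "AC2") else NA_real_
  trends <- lapply(methods, function(m) trendCheck(r, m))
  names(trends) <- methods
  list(max_abs_bias_percent = maxBias,
       ac1_vs_ac2_mean_difference_percent = acDiff, trends = trends)
}
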