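#' Central volume of interest in the solution region
#'
#' Finds an axis-aligned box of the requested volume in the solution: the
#' mask is eroded by `margin` voxels (in-plane disc plus `margin` slices
#' axially) to locate the centre of the solution region, then box dimensions
#' are chosen, centred there and contained in the (uneroded) mask, whose
#' voxel count comes closest to the requested volume. The search fails if no
#' contained box gets within 2 percent of the request, or if the request is
#' not smaller than the eroded solution region.
#'
#' For the 5 cm phantom a 75 cm^3 box is close to the largest box the
#' 120.2 ml fill admits, so its corners approach the cylinder wall; slices
#' reconstruct independently, which keeps the axial extent harmless.
#'
#' @param mask a [VoxelImage-class] mask (non-zero = solution).
#' @param volumeCm3 requested VOI volume, cm^3 (default 75).
#' @param margin erosion margin in voxels used for centring (default 2).
#' @return A [VOIBox-class].
#' @export
centralVOI <- function(mask, volumeCm3 = 75, margin = 2) {
  stopifnot(is(mask, "VoxelImage"))
  checkScalar(volumeCm3, "volumeCm3", min = 0, strict = TRUE)
  m <- mask@values != 0
  d <- dim(m)
  voxVol <- prod(mask@spacing) / 1000                  # cm^3
  target <- volumeCm3 / voxVol                         # voxels
  zAll <- which(apply(m, 3, any))
  if (length(zAll) == 0L) stop("mask is empty", call. = FALSE)
  if (any(diff(zAll) != 1L))
    stop("mask must be axially contiguous", call. = FALSE)
  ## in-plane erosion by a disc of radius `margin` voxels
  M2 <- apply(m[, , zAll, drop = FALSE], c(1, 2), all)
  eroded <- M2
  if (margin > 0) {
    offs <- expand.grid(dx = -margin:margin, dy = -margin:margin)
    offs <- offs[offs$dx^2 + offs$dy^2 <= margin^2, ]
    for (k in seq_len(nrow(offs))) {
      sh <- matrix(FALSE, d[1], d[2])
      xs <- seq_len(d[1]) + offs$dx[k]
      ys <- seq_len(d[2]) + offs$dy[k]
      ok <- xs >= 1 & xs <= d[1]
      ok2 <- ys >= 1 & ys <= d[2]
      sh[ok, ok2] <- M2[xs[ok], ys[ok2]]
      eroded <- eroded & sh
    }
  }
  zEro <- zAll[seq(1 + margin, length.out = max(0, length(zAll) -
                                                  2 * margin))]
  erodedVox <- sum(eroded) * length(zEro)
  if (target >= erodedVox)
    stop(sprintf(
      "requested VOI (%.0f voxels) is not smaller than the eroded solution region (%.0f voxels)",
      target, erodedVox), call. = FALSE)
  idx <- which(eroded, arr.ind = TRUE)
  cx <- mean(range(idx[, 1]))
  cy <- mean(range(idx[, 2]))
  cz <- mean(range(zAll))
  best <- NULL
  bestDev <- Inf
  for (wx in seq_len(d[1])) {
    xr <- centerRange(cx, wx, d[1])
    if (is.null(xr)) break
    for (wy in seq_len(d[2])) {
      yr <- centerRange(cy, wy, d[2])
      if (is.null(yr)) break
      if (!all(M2[xr[1]:xr[2], yr[1]:yr[2]])) break
      wz <- max(1L, min(length(zAll), round(target / (wx * wy))))
      zr <- centerRange(cz, wz, d[3])
      if (is.null(zr) || zr[1] < zAll[1] || zr[2] > zAll[length(zAll)])
        next
      dev <- abs(wx * wy * wz - target)
      if (dev < bestDev) {
        bestDev <- dev
        best <- list(xr = xr, yr = yr, zr = zr, n = wx * wy * wz)
      }
    }
  }
  if (is.null(best) || bestDev / target > 0.02)
    stop(sprintf(
      "no contained box within 2%% of %.0f cm^3 (best deviation %.1f%%)",
      volumeCm3, 100 * bestDev / target), call. = FALSE)
  new("VOIBox", xRange = as.integer(best$xr), yRange = as.integer(best$yr),
      zRange = as.integer(best$zr), nVoxels = best$n,
      volumeMm3 = best$n * prod(mask@spacing))
}

setMethod("show", "VOIBox", function(object) {
  cat(sprintf(
    "VOIBox: x %d-%d, y %d-%d, z %d-%d; %d voxels, %.1f cm^3\n",
    object@xRange[1], object@xRange[2], object@yRange[1], object@yRange[2],
    object@zRange[1], object@zRange[2], object@nVoxels,
    object@volumeMm3 / 1000))
})

#' @describeIn centralVOI Mean, voxelwise SD and voxel count of an image
#'   over a VOI. The SD is across voxels (a noise indicator), not the SD of
#'   the mean.
#' @param image a [VoxelImage-class].
#' @param voi a [VOIBox-class].
#' @export
voiStats <- function(image, voi) {
  stopifnot(is(image, "VoxelImage"), is(voi, "VOIBox"))
  v <- image@values[voi@xRange[1]:voi@xRange[2],
                    voi@yRange[1]:voi@yRange[2],
                    voi@zRange[1]:voi@zRange[2]]
  list(mean = mean(v), sd = stats::sd(as.vector(v)), n = length(v))
}

#' True activity concentration of a solution state
#'
#' Ground truth for the image-based measurements: the activity placed in the
#' phantom, decayed to `atTime`, divided by the state's total volume - i.e.
#' decay-corrected and volume-corrected. At fixed time,
#' `truth x totalVolume` is constant across steps (the activity never
#' changes; only decay and dilution do).
#'
#' @param spec a [PhantomSpec-class].
#' @param state a [SolutionState-class].
#' @param atTime minutes since fill (default 0).
#' @return activity concentration, kBq/ml.
#' @examples
#' s <- seriesStates(buildDilutionSeries())[[1]]
#' trueConcentration(phantomSpec(), s)  # 40000 / 120.2 = 332.8
#' @export
trueConcentration <- function(spec, state, atTime = 0) {
  stopifnot(is(spec, "PhantomSpec"), is(state, "SolutionState"))
  decayCorrect(spec@activityMBq, atTime, spec@halfLifeMin) * 1000 /
    state@totalVolume
}

#' Tabulate VOI bias per concentration step and AC method
#'
#' Reduces reconstructed volumes to one row per (step, method): VOI mean and
#' voxelwise SD, the ground-truth concentration, and
#' `bias = 100 x (mean - truth) / truth`. Reconstruction values must already
#' be decay-corrected to the common time point of the truths. Rows are
#' sorted by step then method, so the output does not depend on the input
#' ordering.
#'
#' @param recons list of records, each a list with elements `step` (1-based
#'   index), `concentration` (mM), `method` (label) and `image`
#'   (a [VoxelImage-class]).
#' @param truths numeric vector of true concentrations (kBq/ml), one per
#'   step.
#' @param voi the common [VOIBox-class].
#' @return data.frame with columns `step`, `concentration_mM`, `ac_method`,
#'   `voi_mean_kBq_ml`, `voi_sd_kBq_ml`, `truth_kBq_ml`, `bias_percent`.
#' @export
biasTable <- function(recons, truths, voi) {
  if (length(recons) == 0L) stop("no reconstructions", call. = FALSE)
  rows <- lapply(recons, function(r) {
    if (is.null(r$image))
      stop("missing reconstruction entry", call. = FALSE)
    s <- voiStats(r$image, voi)
    truth <- truths[r$step]
    if (is.na(truth)) stop("missing truth for step ", r$step, call. = FALSE)
    data.frame(step = r$step, concentration_mM = r$concentration,
               ac_method = r$method, voi_mean_kBq_ml = s$mean,
               voi_sd_kBq_ml = s$sd, truth_kBq_ml = truth,
               bias_percent = 100 * (s$mean - truth) / truth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$step, out$ac_method), , drop = FALSE]
}

#' Mean percent difference between two AC methods
#'
#' Mean over steps of `100 x |mean_a - mean_b| / mean_a`, the summary used
#' to compare correction strategies pairwise.
#'
#' @param results a [biasTable()] data.frame.
#' @param methodA,methodB AC method labels.
#' @return mean percent difference.
#' @export
acPairMeanDifference <- function(results, methodA, methodB) {
  a <- results[results$ac_method == methodA, ]
  b <- results[results$ac_method == methodB, ]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both methods must be present in the results", call. = FALSE)
  m <- merge(a[, c("step", "voi_mean_kBq_ml")],
             b[, c("step", "voi_mean_kBq_ml")], by = "step")
  if (nrow(m) < nrow(a) || nrow(m) < nrow(b))
    stop("methods must cover the same steps", call. = FALSE)
  mean(100 * abs(m$voi_mean_kBq_ml.x - m$voi_mean_kBq_ml.y) /
         m$voi_mean_kBq_ml.x)
}

#' Trend of bias with concentration
#'
#' Least-squares slope of `bias_percent` against concentration for one AC
#' method, and a no-trend flag: the predicted bias drift over the full
#' concentration range must stay below 2 percentage points. This
#' operationalises "no visible trend with increasing contrast" as a slope
#' threshold.
#'
#' @param results a [biasTable()] data.frame.
#' @param method AC method label.
#' @param driftLimit allowed predicted drift over the range, percentage
#'   points (default 2).
#' @return list with `slope` (percent per mM), `drift` (percent over the
#'   range) and `noTrend` (logical).
#' @export
trendCheck <- function(results, method, driftLimit = 2) {
  r <- results[results$ac_method == method, ]
  if (nrow(r) < 3L)
    stop("need at least 3 steps for a trend estimate", call. = FALSE)
  fit <- stats::lm(bias_percent ~ concentration_mM, data = r)
  slope <- unname(stats::coef(fit)[2])
  drift <- slope * diff(range(r$concentration_mM))
  list(slope = slope, drift = drift, noTrend = abs(drift) < driftLimit)
}
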