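#' Construct a parallel-beam projection geometry
#'
#' The simulated acquisition is 2-D parallel-beam per axial slice: the
#' phantom cylinder is axially uniform in its filled region, so each line of
#' response is modelled as an in-plane ray. Angles are spread uniformly over
#' \[0, 180).
#'
#' @param nAngles number of projection angles (default 180).
#' @param nRadial number of radial bins.
#' @param radialSpacing radial bin spacing, mm (default 1, the voxel pitch).
#' @return A [ProjectionGeometry-class].
#' @export
parallelGeometry <- function(nAngles = 180, nRadial = 128,
                             radialSpacing = 1) {
  new("ProjectionGeometry",
      angles = seq(0, 180, length.out = nAngles + 1)[seq_len(nAngles)],
      nRadial = as.integer(nRadial), radialSpacing = radialSpacing)
}

## Radial bin centres, mm (centred on the rotation axis).
radialGrid <- function(geometry)
  (seq_len(geometry@nRadial) - (geometry@nRadial + 1) / 2) *
  geometry@radialSpacing

newSinogram <- function(values, geometry, semantics) {
  if (length(dim(values)) == 2L)
    dim(values) <- c(dim(values), 1L)
  new("Sinogram", values = values, angles = geometry@angles,
      radialSpacing = geometry@radialSpacing, semantics = semantics)
}

#' @describeIn parallelGeometry Sinogram value array accessor
#'   (angle x radial x slice).
#' @param sinogram a [Sinogram-class].
#' @export
sinogramValues <- function(sinogram) sinogram@values

#' @describeIn parallelGeometry Sinogram semantics tag accessor.
#' @export
sinogramSemantics <- function(sinogram) sinogram@semantics

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@values)
  cat(sprintf(paste0("Sinogram [%s]: %d angles x %d radial bins x %d",
                     " slices, bin %g mm\n  range [%.4g, %.4g]\n"),
              object@semantics, d[1], d[2], d[3], object@radialSpacing,
              min(object@values), max(object@values)))
})

## Project one slice: line integrals (value x cm) on the angle x radial grid.
## Ray-driven sampling at the in-plane voxel pitch with bilinear
## interpolation; samples outside the grid contribute zero.
projectSlice <- function(m, spacing, origin, geometry) {
  nR <- geometry@nRadial
  s <- radialGrid(geometry)                       # mm
  pitch <- min(spacing)                           # mm along the ray
  diag <- sqrt(sum((dim(m) * spacing)^2))
  t <- seq(-diag / 2, diag / 2, by = pitch)
  S <- matrix(s, nR, length(t))
  Tm <- matrix(t, nR, length(t), byrow = TRUE)
  out <- matrix(0, length(geometry@angles), nR)
  for (a in seq_along(geometry@angles)) {
    th <- geometry@angles[a] * pi / 180
    cs <- cos(th); sn <- sin(th)
    xw <- S * cs - Tm * sn
    yw <- S * sn + Tm * cs
    xi <- (xw - origin[1]) / spacing[1] + 1
    yi <- (yw - origin[2]) / spacing[2] + 1
    v <- interpBilinear(m, as.vector(xi), as.vector(yi))
    out[a, ] <- rowSums(matrix(v, nR)) * pitch / 10   # mm -> cm
  }
  out
}

## Apply `f` to each axial slice of a 3-D array, reusing the result for
## consecutive identical slices (the phantom is axially uniform in its
## filled region, so this collapses the per-slice cost).
mapSlices <- function(values, f) {
  nz <- dim(values)[3]
  out <- NULL
  prev <- NULL
  prevRes <- NULL
  for (z in seq_len(nz)) {
    sl <- values[, , z]
    res <- if (!is.null(prev) && identical(sl, prev)) prevRes else f(sl)
    if (is.null(out)) out <- array(0, c(dim(res), nz))
    out[, , z] <- res
    prev <- sl
    prevRes <- res
  }
  out
}

#' Forward-project a voxel image into a sinogram of line integrals
#'
#' Computes per-slice parallel-beam line integrals of the image along each
#' (angle, radial bin) ray, by ray-driven sampling at the voxel pitch with
#' bilinear interpolation. Integrals are in value x cm, so projecting an
#' attenuation map (cm^-1) yields the dimensionless optical path and
#' projecting an activity map (kBq/ml) yields kBq/ml x cm.
#'
#' @param image a [VoxelImage-class] tagged `"LAC_per_cm"`, `"kBq_per_ml"`
#'   or `"dimensionless"` (HU volumes are refused: project the converted LAC
#'   map instead).
#' @param geometry a [ProjectionGeometry-class].
#' @return A [Sinogram-class] tagged `"line_integral"`.
#' @export
forwardProject <- function(image, geometry) {
  stopifnot(is(image, "VoxelImage"), is(geometry, "ProjectionGeometry"))
  if (imageSemantics(image) == "HU")
    stop("cannot project an HU volume; convert to LAC first", call. = FALSE)
  vals <- mapSlices(image@values, function(sl)
    projectSlice(sl, image@spacing[1:2], image@origin[1:2], geometry))
  newSinogram(vals, geometry, "line_integral")
}

#' Attenuation correction factors of an attenuation map
#'
#' `ACF = exp(+ integral of mu dl)` along each line of response: the factor
#' that multiplies emission data to undo attenuation (the survival
#' probability of an annihilation pair along the ray is `1/ACF`). Rays that
#' miss the object have ACF exactly 1.
#'
#' @param mu a [VoxelImage-class] tagged `"LAC_per_cm"`.
#' @param geometry a [ProjectionGeometry-class].
#' @return A [Sinogram-class] tagged `"attenuation_factor"`.
#' @export
attenuationFactors <- function(mu, geometry) {
  stopifnot(is(mu, "VoxelImage"))
  if (imageSemantics(mu) != "LAC_per_cm")
    stop("attenuationFactors needs an LAC_per_cm image", call. = FALSE)
  p <- forwardProject(mu, geometry)
  newSinogram(exp(p@values), geometry, "attenuation_factor")
}

## Band-limited ramp (Ram-Lak) convolution kernel sampled at radial pitch
## ds (cm); the classic discrete form with h(0) = 1/(4 ds^2) and
## h(n) = -1/(pi n ds)^2 for odd n.
rampKernel <- function(nR, ds) {
  n <- -(nR - 1):(nR - 1)
  h <- numeric(length(n))
  h[n == 0] <- 1 / (4 * ds^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * ds)^2
  h
}

## Filter + backproject one sinogram slice onto an nx x ny grid.
fbpSlice <- function(p, geometry, nx, ny, spacing, origin) {
  nR <- geometry@nRadial
  ds <- geometry@radialSpacing / 10                  # cm
  h <- rampKernel(nR, ds)
  L <- 2^ceiling(log2(length(h) + nR))
  H <- stats::fft(c(h, numeric(L - length(h))))
  sCm <- radialGrid(geometry) / 10
  ## pixel centre world coordinates, cm
  xw <- (origin[1] + (seq_len(nx) - 1) * spacing[1]) / 10
  yw <- (origin[2] + (seq_len(ny) - 1) * spacing[2]) / 10
  X <- matrix(xw, nx, ny)
  Y <- matrix(yw, nx, ny, byrow = TRUE)
  f <- matrix(0, nx, ny)
  for (a in seq_along(geometry@angles)) {
    pa <- p[a, ]
    q <- Re(stats::fft(stats::fft(c(pa, numeric(L - nR))) * H,
                       inverse = TRUE))[nR:(2 * nR - 1)] / L * ds
    th <- geometry@angles[a] * pi / 180
    tq <- X * cos(th) + Y * sin(th)
    f <- f + stats::approx(sCm, q, xout = tq, yleft = 0, yright = 0)$y
  }
  f * pi / length(geometry@angles)
}
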