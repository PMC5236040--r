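#' Construct a voxel image
#'
#' @param values 3-D numeric array (x, y, z).
#' @param spacing voxel spacing per axis, mm (scalar recycled to 3).
#' @param origin world coordinate of the centre of voxel (1,1,1), mm. The
#'   default places the world origin at the in-plane grid centre and z = 0 at
#'   the bottom face of the first slice.
#' @param semantics value tag: `"HU"`, `"LAC_per_cm"`, `"kBq_per_ml"` or
#'   `"dimensionless"`.
#' @return A [VoxelImage-class].
#' @export
voxelImage <- function(values, spacing = c(1, 1, 1), origin = NULL,
                       semantics = "dimensionless") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(values)
  if (is.null(origin))
    origin <- c(-(d[1] - 1) / 2 * spacing[1], -(d[2] - 1) / 2 * spacing[2],
                spacing[3] / 2)
  new("VoxelImage", values = values, spacing = spacing, origin = origin,
      semantics = semantics)
}

#' @describeIn voxelImage Voxel value array accessor.
#' @param image a [VoxelImage-class].
#' @export
imageValues <- function(image) image@values

#' @describeIn voxelImage Voxel spacing accessor (mm).
#' @export
voxelSpacing <- function(image) image@spacing

#' @describeIn voxelImage Semantics tag accessor.
#' @export
imageSemantics <- function(image) image@semantics

setMethod("dim", "VoxelImage", function(x) dim(x@values))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@values)
  cat(sprintf(paste0("VoxelImage [%s]: %d x %d x %d voxels,",
                     " spacing %g x %g x %g mm\n  range [%.4g, %.4g]\n"),
              object@semantics, d[1], d[2], d[3], object@spacing[1],
              object@spacing[2], object@spacing[3],
              min(object@values), max(object@values)))
})

#' Read and write voxel images as NIfTI with a JSON sidecar
#'
#' The array and geometry go into a NIfTI-1 file; the value-semantics tag
#' (and the exact spacing/origin) go into a small JSON sidecar next to it,
#' since NIfTI has no standard slot for value semantics.
#'
#' @param image a [VoxelImage-class].
#' @param path NIfTI file path (`.nii` or `.nii.gz`); the sidecar is written
#'   at the same path with a `.json` extension appended.
#' @return `writeVoxelImage` returns `path` invisibly; `readVoxelImage`
#'   returns a [VoxelImage-class].
#' @export
writeVoxelImage <- function(image, path) {
  stopifnot(is(image, "VoxelImage"))
  nii <- RNifti::asNifti(image@values,
                         pixdim = image@spacing)
  RNifti::writeNifti(nii, path)
  jsonlite::write_json(
    list(semantics = image@semantics, spacing_mm = image@spacing,
         origin_mm = image@origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write sinograms as CSV with a JSON sidecar
#'
#' Long-format CSV (`angle_deg`, `radial_bin`, `slice`, `value`) plus a JSON
#' sidecar carrying the semantics tag and radial spacing, so projection data
#' can be inspected or exchanged as plain text.
#'
#' @param sinogram a [Sinogram-class].
#' @param path CSV file path; the sidecar is written at the same path with a
#'   `.json` extension appended.
#' @return `writeSinogram` returns `path` invisibly; `readSinogram` returns
#'   a [Sinogram-class].
#' @export
writeSinogram <- function(sinogram, path) {
  stopifnot(is(sinogram, "Sinogram"))
  d <- dim(sinogram@values)
  df <- data.frame(
    angle_deg = rep(sinogram@angles, times = d[2] * d[3]),
    radial_bin = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    slice = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(sinogram@values))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(semantics = sinogram@semantics,
         radial_spacing_mm = sinogram@radialSpacing,
         n_angles = d[1], n_radial = d[2], n_slices = d[3]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  vals <- array(df$value[order(df$slice, df$radial_bin)],
                c(meta$n_angles, meta$n_radial, meta$n_slices))
  new("Sinogram", values = vals,
      angles = unique(df$angle_deg)[seq_len(meta$n_angles)],
      radialSpacing = meta$radial_spacing_mm, semantics = meta$semantics)
}

#' @rdname writeVoxelImage
#' @export
readVoxelImage <- function(path) {
  nii <- RNifti::readNifti(path)
  vals <- array(as.vector(nii), dim = dim(nii))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  voxelImage(vals, spacing = meta$spacing_mm, origin = meta$origin_mm,
             semantics = meta$semantics)
}
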