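#' Construct a 4D BOLD image container
#'
#' A `bold_image` bundles a 4D intensity array (x, y, z, time) with its
#' voxel size, repetition time and an affine mapping grid indices to
#' reference-space millimetres. All pipeline stages operate on this
#' container so that spatial metadata travels with the data.
#'
#' @param data 4D numeric array, dimensions (nx, ny, nz, nt).
#' @param voxel_size_mm Positive scalar, isotropic voxel edge length in mm.
#' @param tr_s Positive scalar, repetition time (sampling interval) in
#'   seconds.
#' @param affine Optional 4x4 matrix mapping 0-based voxel indices to mm.
#'   Defaults to a diagonal scaling by `voxel_size_mm` with the origin at
#'   the volume centre.
#' @param meta Named list of free-form metadata (e.g. the subject id or a
#'   record of any positivity shift applied by the simulator).
#' @return An object of class `bold_image`.
#' @seealso [generate_subject_bold()], [peraf_map()]
#' @export
bold_image <- function(data, voxel_size_mm, tr_s, affine = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, time)")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be positive")
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop("`tr_s` must be positive")
  if (is.null(affine))
    affine <- centered_affine(dim(data)[1:3], voxel_size_mm)
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         affine = affine, meta = meta),
    class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %d x %d x %d voxels, %d timepoints (TR %.3g s, voxel %.3g mm)\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$voxel_size_mm))
  invisible(x)
}

#' @export
dim.bold_image <- function(x) dim(x$data)

#' Construct a 3D amplitude/statistic map container
#'
#' An `amplitude_map` is a 3D scalar field (PerAF percent, ALFF, or a
#' t-statistic) defined on a binary mask, sharing the grid and affine of
#' the 4D image it was computed from. Values outside the mask are held at
#' 0 and are not meaningful.
#'
#' @param values 3D numeric array.
#' @param metric Character scalar, one of `"PerAF"`, `"mPerAF"`, `"ALFF"`,
#'   `"fALFF"`, `"t"`.
#' @param mask Logical 3D array of the same dimensions; the voxels on
#'   which `values` is defined.
#' @param voxel_size_mm Positive scalar, voxel edge length in mm.
#' @param affine Optional 4x4 affine (defaults to centred diagonal).
#' @param meta Named list of metadata (e.g. dropped-voxel counts).
#' @return An object of class `amplitude_map`.
#' @export
amplitude_map <- function(values, metric, mask, voxel_size_mm,
                          affine = NULL, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  metric <- match.arg(metric, c("PerAF", "mPerAF", "ALFF", "fALFF", "t"))
  mask <- as_mask(mask, dim(values))
  if (any(!is.finite(values[mask])))
    stop("non-finite map values inside the mask")
  values[!mask] <- 0
  if (is.null(affine))
    affine <- centered_affine(dim(values), voxel_size_mm)
  structure(
    list(values = values, metric = metric, mask = mask,
         voxel_size_mm = voxel_size_mm, affine = affine, meta = meta),
    class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$mask]
  cat(sprintf("<amplitude_map> metric %s, %d x %d x %d grid, %d mask voxels, range [%.4g, %.4g]\n",
              x$metric, d[1], d[2], d[3], sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' @export
dim.amplitude_map <- function(x) dim(x$values)

# Diagonal affine with the mm origin at the grid centre, 0-based indices.
centered_affine <- function(grid_shape, voxel_size_mm) {
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  aff
}

# Map 1-based voxel index triples (rows of a matrix) to mm via the affine.
voxel_to_mm <- function(ijk, affine) {
  ijk <- rbind(ijk)  # ensure matrix
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# Coerce numeric/logical input to a logical 3D mask and check shape.
as_mask <- function(mask, expect_dim = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!is.null(expect_dim) && !identical(dim(mask), as.integer(expect_dim)))
    stop(sprintf("mask dimensions (%s) do not match data (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(expect_dim, collapse = "x")))
  storage.mode(mask) <- "logical"
  mask
}

#' Write a 3D or 4D volume to NIfTI-1
#'
#' Serialises a `bold_image`, `amplitude_map`, or plain array to a
#' `.nii`/`.nii.gz` file with the voxel size (and, for 4D, the TR)
#' recorded in the header pixdim.
#'
#' @param x A `bold_image`, `amplitude_map`, or numeric/logical array.
#' @param path Output file path, ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm Voxel size for plain arrays (ignored for the two
#'   container classes, which carry their own).
#' @param tr_s TR in seconds for plain 4D arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = 1, tr_s = 1) {
  if (inherits(x, "bold_image")) {
    arr <- x$data; vs <- x$voxel_size_mm; tr <- x$tr_s
  } else if (inherits(x, "amplitude_map")) {
    arr <- x$values; vs <- x$voxel_size_mm; tr <- 1
  } else {
    arr <- x
    if (is.logical(arr)) { arr <- arr + 0L }
    vs <- voxel_size_mm; tr <- tr_s
  }
  nim <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4L) c(vs, vs, vs, tr) else rep(vs, length(dim(arr)))
  RNifti::pixdim(nim) <- pd
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A list with `data` (array), `voxel_size_mm` (first pixdim) and
#'   `tr_s` (fourth pixdim, `NA` for 3D images).
#' @export
read_volume <- function(path) {
  nim <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(nim)
  list(data = as.array(nim),
       voxel_size_mm = pd[1],
       tr_s = if (length(pd) >= 4) pd[4] else NA_real_)
}
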