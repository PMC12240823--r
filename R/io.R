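#' @useDynLib petnorm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

grid_from_nifti <- function(img) {
  dims <- dim(img)
  if (length(dims) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dims), " dimensions")
  aff <- unclass(RNifti::xform(img))
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  voxel_grid(dims, voxel_size = vs, affine = aff)
}

#' Read a set of parametric maps into a masked matrix
#'
#' Reads one scalar NIfTI volume per subject, checks that all volumes share
#' the mask's grid (dimensions and affine within `tol` mm), and samples the
#' in-mask voxels in fixed x-fastest flattening order.
#'
#' @param paths Character vector of NIfTI file paths, one per subject.
#' @param mask A [brain_mask()] defining grid and voxel selection.
#' @param subject_ids Row identifiers; defaults to file base names.
#' @param tracer Tracer tag stored on the result.
#' @return A [map_set()] with `length(paths)` rows.
#' @export
read_map_set <- function(paths, mask, subject_ids = NULL, tracer = "") {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(paths) < 1L) stop("no files to read")
  idx <- mask_index(mask)
  values <- matrix(NA_real_, length(paths), length(idx))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    g <- grid_from_nifti(img)
    if (!same_grid(g, mask$grid, tol = 1e-4))
      stop("grid mismatch in file: ", paths[i])
    v <- as.numeric(img)[idx]
    if (!all(is.finite(v)))
      stop("non-finite voxel values inside the mask in file: ", paths[i])
    values[i, ] <- v
  }
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  map_set(values, mask, subject_ids = subject_ids, tracer = tracer)
}

#' Write a scalar field or masked vector as a NIfTI volume
#'
#' Writes 32-bit float NIfTI-1 preserving the grid affine. A masked vector
#' (length `mask$n_voxels`) is scattered back onto the grid with
#' out-of-mask voxels set to 0.
#'
#' @param x Numeric array with grid dimensions, or a masked vector.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param mask A [brain_mask()]; required for the masked-vector form and
#'   for the grid geometry.
#' @return `path`, invisibly.
#' @export
write_map <- function(x, path, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  grid <- mask$grid
  if (is.null(dim(x))) {
    if (length(x) != mask$n_voxels)
      stop("masked vector length (", length(x),
           ") must equal mask$n_voxels (", mask$n_voxels, ")")
    field <- array(0, dim = grid$dims)
    field[mask_index(mask)] <- x
  } else {
    if (!all(dim(x) == grid$dims))
      stop("array dimensions must match the grid")
    field <- array(as.numeric(x), dim = grid$dims)
  }
  img <- RNifti::asNifti(field)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write every subject map of a map set as NIfTI files
#'
#' @param maps A [map_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_map_set <- function(maps, dir, prefix = "map") {
  stopifnot(inherits(maps, "map_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, "_", maps$subject_ids, ".nii.gz"))
  for (i in seq_along(paths))
    write_map(maps$values[i, ], paths[i], maps$mask)
  invisible(paths)
}
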