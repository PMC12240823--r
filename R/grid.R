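#' Voxel grid geometry
#'
#' A `voxel_grid` records the 3-D array dimensions, the voxel size in mm
#' and the 4x4 voxel-to-world affine (0-based voxel indices, mm world
#' coordinates) shared by every map in an analysis.
#'
#' @param dims Integer vector of length 3, array dimensions (all >= 1).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm
#'   (strictly positive).
#' @param affine Optional 4x4 voxel-to-world matrix. Defaults to a diagonal
#'   affine scaled by `voxel_size` with the world origin at the grid centre.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size = c(2, 2, 2), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three strictly positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -(dims - 1) / 2 * voxel_size
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %s voxels, %s mm\n",
              paste(x$dims, collapse = " x "),
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-4) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) <= tol
}

#' Brain analysis mask
#'
#' A boolean scalar field over a [voxel_grid()] selecting the voxels that
#' enter the analysis. Masked vectors are flattened in fixed x-fastest,
#' then y, then z order (R column-major order, 0-based voxel indices).
#'
#' @param grid A [voxel_grid()].
#' @param flags Logical array with dimensions `grid$dims` (or a logical
#'   vector of matching length).
#' @return An object of class `brain_mask` with elements `grid`, `flags`
#'   and `n_voxels`.
#' @export
brain_mask <- function(grid, flags) {
  stopifnot(inherits(grid, "voxel_grid"))
  flags <- array(as.logical(flags), dim = grid$dims)
  if (anyNA(flags)) stop("mask flags must not contain NA")
  n <- sum(flags)
  if (n < 1L) stop("mask is empty: no analyzable voxels")
  structure(list(grid = grid, flags = flags, n_voxels = as.integer(n)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: %d of %d voxels\n", x$n_voxels,
              prod(x$grid$dims)))
  invisible(x)
}

# linear (column-major, x fastest) indices of in-mask voxels
mask_index <- function(mask) which(mask$flags)

#' Threshold a probability map into a brain mask
#'
#' Binarizes a probabilistic tissue map (e.g. grey matter probability) at
#' `prob >= threshold`, the inclusive reading of an "at least p%
#' probability" criterion.
#'
#' @param prob Numeric array of probabilities in \[0, 1\] (dimensions must
#'   match `grid$dims`), or a path to a NIfTI file.
#' @param threshold Probability cutoff in \[0, 1\]; default 0.30.
#' @param grid A [voxel_grid()]; required when `prob` is an array, derived
#'   from the file header when `prob` is a path.
#' @return A [brain_mask()].
#' @export
make_probability_mask <- function(prob, threshold = 0.30, grid = NULL) {
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]")
  if (is.character(prob)) {
    img <- RNifti::readNifti(prob)
    grid <- grid_from_nifti(img)
    prob <- as.array(img)
  }
  if (is.null(grid)) stop("'grid' is required when 'prob' is an array")
  prob <- array(as.numeric(prob), dim = grid$dims)
  if (anyNA(prob) || min(prob) < 0 || max(prob) > 1)
    stop("'prob' must be finite and lie in [0, 1]")
  flags <- prob >= threshold
  if (!any(flags))
    stop("probability mask is empty at threshold ", threshold)
  brain_mask(grid, flags)
}

#' Atlas parcellation
#'
#' Integer-labelled parcellation over a grid; label 0 is background and
#' every non-zero label must be named.
#'
#' @param grid A [voxel_grid()].
#' @param labels Non-negative integer array over `grid`.
#' @param names Named character vector or list mapping label (as character)
#'   to region name, e.g. `c("1" = "striatum")`.
#' @return An object of class `atlas_parcellation`.
#' @export
atlas_parcellation <- function(grid, labels, names) {
  stopifnot(inherits(grid, "voxel_grid"))
  labels <- array(as.integer(labels), dim = grid$dims)
  if (anyNA(labels) || min(labels) < 0L)
    stop("labels must be non-negative integers")
  present <- sort(unique(labels[labels > 0L]))
  names <- unlist(names)
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("unnamed atlas labels: ", paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = labels, names = names),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  lab <- sort(unique(x$labels[x$labels > 0L]))
  cat("atlas_parcellation:\n")
  for (l in lab)
    cat(sprintf("  %d %-12s %d voxels\n", l, x$names[[as.character(l)]],
                sum(x$labels == l)))
  invisible(x)
}

#' Parametric map set
#'
#' The in-memory carrier for a cohort of parametric maps: a subjects x
#' masked-voxels matrix plus the mask that defines the flattening.
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   in-mask voxel (x-fastest flattening order). All values must be finite.
#' @param mask A [brain_mask()].
#' @param subject_ids Character vector of row identifiers.
#' @param tracer Free-text tag for the tracer/parameter (e.g. "Ki", "BPND").
#' @return An object of class `map_set`.
#' @export
map_set <- function(values, mask, subject_ids = rownames(values),
                    tracer = "") {
  stopifnot(inherits(mask, "brain_mask"))
  values <- as.matrix(values)
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (nrow(values) != length(subject_ids))
    stop("rows of 'values' must match 'subject_ids'")
  if (ncol(values) != mask$n_voxels)
    stop("columns of 'values' (", ncol(values),
         ") must equal mask$n_voxels (", mask$n_voxels, ")")
  if (!all(is.finite(values)))
    stop("non-finite parametric values inside the mask")
  rownames(values) <- subject_ids
  structure(list(values = values, mask = mask, subject_ids = subject_ids,
                 tracer = tracer),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("map_set%s: %d subjects x %d voxels\n",
              if (nzchar(x$tracer)) paste0(" [", x$tracer, "]") else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
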