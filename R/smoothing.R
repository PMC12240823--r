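#' Convert Gaussian kernel FWHM to sigma
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2))`; the ratio FWHM/sigma is 2.35 to
#' three significant figures.
#'
#' @param fwhm Full width at half maximum in mm (> 0).
#' @return Kernel sigma in mm.
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (!is.numeric(fwhm) || any(fwhm <= 0)) stop("'fwhm' must be > 0")
  fwhm / (2 * sqrt(2 * log(2)))
}

# discrete 1-D Gaussian kernel, sigma in voxels, truncated at 4 sigma
gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D zero-padded convolution along the rows of a matrix
conv_rows <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    keep <- which(src >= 1L & src <= n)
    if (!length(keep)) next
    out[keep, ] <- out[keep, ] + k[j] * m[src[keep], , drop = FALSE]
  }
  out
}

# separable zero-padded 3-D convolution of an array
conv3d_separable <- function(field, sigmas_vox) {
  d <- dim(field)
  for (ax in 1:3) {
    if (sigmas_vox[ax] <= 0) next
    k <- gauss_kernel_1d(sigmas_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(field, perm)
    dp <- dim(a)
    a <- conv_rows(matrix(a, dp[1]), k)
    field <- aperm(array(a, dp), order(perm))
  }
  field
}

#' Gaussian-smooth every map of a map set
#'
#' Convolves each subject's 3-D field with an isotropic Gaussian of the
#' given FWHM (converted to sigma via [fwhm_to_sigma()] and to voxels via
#' the grid's voxel size). Out-of-mask voxels are treated as absent: the
#' kernel is renormalized over the mask (`smooth(f*m)/smooth(m)`), and the
#' result is re-masked. `fwhm = 0` is the identity.
#'
#' @param maps A [map_set()].
#' @param fwhm Kernel FWHM in mm (>= 0).
#' @return A smoothed [map_set()].
#' @export
gaussian_smooth <- function(maps, fwhm) {
  stopifnot(inherits(maps, "map_set"))
  if (fwhm < 0) stop("'fwhm' must be >= 0")
  if (fwhm == 0) return(maps)
  grid <- maps$mask$grid
  sig_vox <- fwhm_to_sigma(fwhm) / grid$voxel_size
  idx <- mask_index(maps$mask)
  w <- array(0, grid$dims); w[idx] <- 1
  den <- conv3d_separable(w, sig_vox)
  out <- maps$values
  for (s in seq_len(nrow(out))) {
    f <- array(0, grid$dims)
    f[idx] <- maps$values[s, ]
    num <- conv3d_separable(f, sig_vox)
    out[s, ] <- num[idx] / den[idx]
  }
  map_set(out, maps$mask, subject_ids = maps$subject_ids,
          tracer = maps$tracer)
}

#' Select a smoothing kernel that matches a reference distribution
#'
#' For each candidate FWHM, smooths the target set and measures the
#' absolute difference between the pooled-value SD of the smoothed target
#' and that of the reference. Returns the candidate minimizing the
#' criterion; ties break toward the smaller kernel. (Alternative
#' criterion: Kolmogorov-Smirnov distance between pooled distributions.)
#'
#' @param target,reference [map_set()] objects on the same mask.
#' @param candidates Numeric vector of candidate FWHM values in mm (>= 0).
#' @param criterion `"sd"` (default) or `"ks"`.
#' @return A list of class `smoothing_choice` with `fwhm`, `candidates`
#'   and per-candidate `criterion` values.
#' @export
select_smoothing_kernel <- function(target, reference, candidates,
                                    criterion = c("sd", "ks")) {
  criterion <- match.arg(criterion)
  if (length(candidates) < 1L || any(candidates < 0))
    stop("'candidates' must be non-negative FWHM values")
  ref <- as.numeric(reference$values)
  crit <- vapply(candidates, function(f) {
    sm <- as.numeric(gaussian_smooth(target, f)$values)
    if (criterion == "sd") abs(stats::sd(sm) - stats::sd(ref))
    else as.numeric(stats::ks.test(sm, ref)$statistic)
  }, numeric(1))
  ord <- order(crit, candidates)  # ties toward smaller fwhm
  structure(list(fwhm = candidates[ord[1]], candidates = candidates,
                 criterion = crit, criterion_name = criterion),
            class = "smoothing_choice")
}

#' @export
print.smoothing_choice <- function(x, ...) {
  cat(sprintf("smoothing_choice: fwhm = %g mm (criterion: %s)\n",
              x$fwhm, x$criterion_name))
  invisible(x)
}
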