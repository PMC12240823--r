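# scatter masked-vector values onto the full grid (0 elsewhere)
masked_to_field <- function(x, mask, fill = 0) {
  f <- array(fill, mask$grid$dims)
  f[mask_index(mask)] <- x
  f
}

#' Threshold-free cluster enhancement of a statistic field
#'
#' `TFCE(v) = sum_h extent(v, h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ...` up to the voxel's statistic, where extent is the
#' size of the connected component containing v at threshold h. The
#' statistic must be non-negative (enhance `|stat|` per sign separately
#' for two-sided use). Defaults are the standard published values
#' (E = 0.5, H = 2, dh = max/100, 26-connectivity).
#'
#' @param stat Non-negative statistic values: a 3-D array, or a masked
#'   vector with `mask` supplied.
#' @param E,H Extent and height exponents.
#' @param dh Threshold step; default `max(stat)/100`.
#' @param connectivity 6 or 26.
#' @param mask [brain_mask()] when `stat` is a masked vector.
#' @return Enhanced field, same shape as the input.
#' @export
tfce_enhance <- function(stat, E = 0.5, H = 2, dh = NULL,
                         connectivity = 26, mask = NULL) {
  vec_in <- is.null(dim(stat))
  if (vec_in) {
    if (is.null(mask)) stop("'mask' required for masked-vector input")
    field <- masked_to_field(stat, mask)
  } else field <- stat
  if (anyNA(field)) field[is.na(field)] <- 0
  if (min(field) < 0) stop("'stat' must be non-negative")
  if (is.null(dh)) dh <- max(field) / 100
  if (max(field) == 0) return(if (vec_in) stat else field)
  out <- .tfce_cpp(as.numeric(field), as.integer(dim(field)),
                   E, H, dh, as.integer(connectivity))
  out <- array(out, dim(field))
  if (vec_in) out[mask_index(mask)] else out
}

# voxel-wise F statistics for effect columns given precomputed projectors
glm_fstat <- function(Y, Mfull, Mnuis, df1, df2) {
  ssr_full <- colSums((Mfull %*% Y)^2)
  ssr_red <- colSums((Mnuis %*% Y)^2)
  f <- ((ssr_red - ssr_full) / df1) / (ssr_full / df2)
  f[!is.finite(f)] <- 0
  pmax(f, 0)
}

#' Voxel-wise permutation GLM with max-statistic FWE correction
#'
#' Fits `Z ~ nuisance + effect` per voxel and tests the effect term with
#' an F statistic. The null distribution is built by Freedman-Lane
#' residual permutation: residuals from the nuisance-only model are
#' row-permuted, the nuisance fit added back, and the statistic map
#' recomputed. Family-wise-corrected p-values use the permutation
#' distribution of the image-wise maximum of the (optionally
#' TFCE-enhanced) statistic:
#' `p_FWE(v) = (1 + #\{perm max >= observed(v)\}) / (1 + n_perm)`.
#' Uncorrected p-values use each voxel's own permutation distribution.
#' Deterministic under a fixed seed.
#'
#' @param dev A `deviation_maps` (or subjects x voxels matrix with `mask`).
#' @param design Data frame of per-subject factors/covariates.
#' @param effect One-sided formula (or character term label) for the
#'   tested term, e.g. `~ group` or `"group:dataset"`.
#' @param nuisance One-sided formula for nuisance terms (default
#'   intercept only; the interaction test permutes residuals under the
#'   main-effects model).
#' @param n_perm Number of permutations (>= 1; 5000 in full-scale use).
#' @param seed Integer seed.
#' @param enhancement `"none"` or `"tfce"`.
#' @param tfce List of TFCE parameters (`E`, `H`, `dh`, `connectivity`).
#' @param mask [brain_mask()] when `dev` is a matrix.
#' @return Object of class `stat_map`: per-voxel `stat` (F),
#'   `enhanced`, `p_uncorrected`, `p_fwe`, `max_null` distribution and
#'   metadata.
#' @export
permutation_glm <- function(dev, design, effect, nuisance = ~ 1,
                            n_perm = 1000, seed = 1L,
                            enhancement = c("none", "tfce"),
                            tfce = list(), mask = NULL) {
  enhancement <- match.arg(enhancement)
  if (inherits(dev, "deviation_maps")) {
    mask <- dev$mask
    cols <- which(dev$converged)
    Y <- dev$Z[, cols, drop = FALSE]
  } else {
    if (is.null(mask)) stop("'mask' required for matrix input")
    Y <- as.matrix(dev)
    cols <- seq_len(ncol(Y))
  }
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  design <- as.data.frame(design)
  n <- nrow(Y)
  if (nrow(design) != n) stop("design rows must match subjects")

  eff_form <- if (inherits(effect, "formula")) effect
  else stats::reformulate(effect)
  eff_label <- attr(stats::terms(eff_form), "term.labels")
  # full-model matrix = nuisance terms + tested term; locate tested
  # columns through the model matrix 'assign' attribute
  tt <- stats::terms(stats::update(
    nuisance,
    stats::as.formula(paste("~ . +", paste(eff_label, collapse = " + ")))))
  Xfull <- stats::model.matrix(tt, design)
  labels <- attr(tt, "term.labels")
  eff_idx <- which(attr(Xfull, "assign") %in% match(eff_label, labels))
  if (!length(eff_idx)) stop("effect term not found in the design")
  Xnuis <- Xfull[, -eff_idx, drop = FALSE]
  if (qr(Xfull)$rank < ncol(Xfull)) stop("design matrix is rank deficient")

  pfull <- ncol(Xfull)
  df1 <- length(eff_idx); df2 <- n - pfull
  if (df2 < 1) stop("no residual degrees of freedom")
  Hn <- Xnuis %*% solve(crossprod(Xnuis), t(Xnuis))
  Mn <- diag(n) - Hn
  Hf <- Xfull %*% solve(crossprod(Xfull), t(Xfull))
  Mf <- diag(n) - Hf

  obs <- glm_fstat(Y, Mf, Mn, df1, df2)
  use_tfce <- enhancement == "tfce"
  tf <- utils::modifyList(list(E = 0.5, H = 2, dh = NULL,
                               connectivity = 26), tfce)
  enh_fun <- function(fvec) {
    if (!use_tfce) return(fvec)
    full <- rep(0, mask$n_voxels); full[cols] <- fvec
    tfce_enhance(full, E = tf$E, H = tf$H, dh = tf$dh,
                 connectivity = tf$connectivity, mask = mask)[cols]
  }
  obs_enh <- enh_fun(obs)

  set.seed(seed)
  Rn <- Mn %*% Y          # nuisance residuals
  Fit_n <- Hn %*% Y
  exceed <- numeric(length(obs))
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    Yp <- Fit_n + Rn[pm, , drop = FALSE]
    fp <- enh_fun(glm_fstat(Yp, Mf, Mn, df1, df2))
    exceed <- exceed + (fp >= obs_enh)
    max_null[b] <- max(fp)
  }
  p_unc <- (1 + exceed) / (1 + n_perm)
  p_fwe <- vapply(obs_enh, function(o)
    (1 + sum(max_null >= o)) / (1 + n_perm), numeric(1))

  full_stat <- full_enh <- full_punc <- full_pfwe <-
    rep(NA_real_, mask$n_voxels)
  full_stat[cols] <- obs; full_enh[cols] <- obs_enh
  full_punc[cols] <- p_unc; full_pfwe[cols] <- p_fwe
  structure(list(stat = full_stat, enhanced = full_enh,
                 p_uncorrected = full_punc, p_fwe = full_pfwe,
                 max_null = max_null, n_perm = n_perm,
                 effect = eff_label, df1 = df1, df2 = df2,
                 enhancement = enhancement, tfce = tf, seed = seed,
                 mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "stat_map: F test of %s (df = %d, %d), %d permutations, %s\n",
    paste(x$effect, collapse = " + "), x$df1, x$df2, x$n_perm,
    if (x$enhancement == "tfce") "TFCE-enhanced" else "max-stat"))
  cat(sprintf("  min p_FWE = %.4g; voxels with p_FWE < 0.05: %d\n",
              min(x$p_fwe, na.rm = TRUE),
              sum(x$p_fwe < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Extract significant clusters from a permutation stat map
#'
#' Connected components of `{p_FWE < alpha}`; components smaller than
#' `min_size` voxels are discarded (50-voxel reporting convention). When
#' deviation maps are supplied, each cluster carries the per-subject mean
#' Z within it, for post-hoc tests.
#'
#' @param stat_map A [permutation_glm()] result.
#' @param alpha Significance level on `p_FWE`.
#' @param min_size Minimum cluster extent in voxels.
#' @param dev Optional `deviation_maps` for per-subject cluster means.
#' @param connectivity 6 or 26.
#' @return Object of class `cluster_set`: a list with a `clusters` table
#'   (id, size, peak stat, peak i/j/k 0-based) and per-cluster voxel
#'   indices and subject means.
#' @export
extract_clusters <- function(stat_map, alpha = 0.05, min_size = 50,
                             dev = NULL, connectivity = 26) {
  stopifnot(inherits(stat_map, "stat_map"))
  mask <- stat_map$mask
  sig <- masked_to_field(!is.na(stat_map$p_fwe) & stat_map$p_fwe < alpha,
                         mask, fill = FALSE)
  labels <- array(.label_components_cpp(as.logical(sig),
                                        as.integer(dim(sig)),
                                        as.integer(connectivity)),
                  dim(sig))
  ids <- setdiff(unique(as.integer(labels)), 0L)
  keep <- ids[vapply(ids, function(l) sum(labels == l), numeric(1)) >= min_size]
  stat_field <- masked_to_field(stat_map$stat, mask, fill = NA)
  rows <- list(); members <- list(); means <- list()
  midx <- mask_index(mask)
  for (j in seq_along(keep)) {
    l <- keep[j]
    vox <- which(labels == l)
    pk <- vox[which.max(stat_field[vox])]
    pk_ijk <- arrayInd(pk, dim(sig)) - 1L
    cols <- match(vox, midx)
    rows[[j]] <- data.frame(id = j, size = length(vox),
                            peak_stat = max(stat_field[vox], na.rm = TRUE),
                            peak_i = pk_ijk[1], peak_j = pk_ijk[2],
                            peak_k = pk_ijk[3])
    members[[j]] <- cols
    if (!is.null(dev))
      means[[j]] <- rowMeans(dev$Z[, cols, drop = FALSE], na.rm = TRUE)
  }
  structure(list(clusters = if (length(rows)) do.call(rbind, rows)
                 else data.frame(id = integer(), size = integer(),
                                 peak_stat = numeric(), peak_i = integer(),
                                 peak_j = integer(), peak_k = integer()),
                 members = members,
                 subject_means = if (is.null(dev)) NULL else means,
                 alpha = alpha, min_size = min_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) at p_FWE < %g, min size %d\n",
              nrow(x$clusters), x$alpha, x$min_size))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
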