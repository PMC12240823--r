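# columns of a deviation_maps restricted to a sub-mask, excluding
# non-converged sentinel voxels
dev_columns <- function(dev, mask = NULL) {
  cols <- which(dev$converged)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "brain_mask"))
    keep <- mask$flags[mask_index(dev$mask)]
    cols <- intersect(cols, which(keep))
  }
  if (!length(cols)) stop("no analyzable voxels in the requested mask")
  cols
}

#' Per-subject deviation summary measures
#'
#' For each subject: the mean Z-score over analyzed voxels and the
#' percentages of voxels with extreme deviations (`Z > z`, `Z < -z`,
#' `|Z| > z`; strict inequalities). Non-converged voxels are excluded
#' from numerator and denominator; `pct_tot = pct_pos + pct_neg` holds
#' exactly.
#'
#' @param dev A `deviation_maps`.
#' @param mask Optional sub-[brain_mask()] (e.g. an EXPV mask) to restrict
#'   the analyzed voxels.
#' @param z_threshold Extreme-deviation threshold (default 2).
#' @param scope Label recorded in the output's `scope` column.
#' @return Data frame with columns subject_id, mean_z, pct_pos, pct_neg,
#'   pct_tot, n_voxels, scope.
#' @export
summary_measures <- function(dev, mask = NULL, z_threshold = 2,
                             scope = "mask") {
  stopifnot(inherits(dev, "deviation_maps"), z_threshold > 0)
  cols <- dev_columns(dev, mask)
  Z <- dev$Z[, cols, drop = FALSE]
  nv <- length(cols)
  data.frame(subject_id = dev$subject_ids,
             mean_z = rowMeans(Z),
             pct_pos = 100 * rowSums(Z > z_threshold) / nv,
             pct_neg = 100 * rowSums(Z < -z_threshold) / nv,
             pct_tot = 100 * rowSums(abs(Z) > z_threshold) / nv,
             n_voxels = nv, scope = scope,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Voxel-wise overlap of extreme deviations within a group
#'
#' For each voxel, the percentage of the group's subjects with an extreme
#' deviation of the requested sign. Stored values are unthresholded;
#' display thresholding at the chance level (2.5% for pos/neg, 5% for
#' tot) is a rendering choice.
#'
#' @param dev A `deviation_maps`.
#' @param subjects Subject ids or row indices defining the group
#'   (defaults to all).
#' @param sign One of `"pos"`, `"neg"`, `"tot"`.
#' @param z_threshold Extreme-deviation threshold.
#' @return An object of class `overlap_map`: per-voxel percentages (NA at
#'   non-converged voxels) with the mask, sign and chance level attached.
#' @export
overlap_map <- function(dev, subjects = NULL, sign = c("pos", "neg", "tot"),
                        z_threshold = 2) {
  sign <- match.arg(sign)
  stopifnot(inherits(dev, "deviation_maps"))
  rows <- if (is.null(subjects)) seq_len(nrow(dev$Z))
  else if (is.character(subjects)) match(subjects, dev$subject_ids)
  else subjects
  if (!length(rows) || anyNA(rows)) stop("empty or unknown subject subset")
  Z <- dev$Z[rows, , drop = FALSE]
  ex <- switch(sign,
               pos = Z > z_threshold,
               neg = Z < -z_threshold,
               tot = abs(Z) > z_threshold)
  pct <- 100 * colMeans(ex)
  pct[!dev$converged] <- NA_real_
  structure(list(pct = pct, mask = dev$mask, sign = sign,
                 n_subjects = length(rows),
                 chance = if (sign == "tot") 5 else 2.5),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf(
    "overlap_map (%s, n = %d): max %.1f%%, chance level %.1f%%\n",
    x$sign, x$n_subjects, max(x$pct, na.rm = TRUE), x$chance))
  invisible(x)
}

#' Risk ratio of extreme deviations, patients vs controls
#'
#' Pools voxel-subject pairs per group into one 2x2 table: `a` = extreme
#' and `b` = non-extreme pairs among patients, `c`/`d` likewise for
#' controls. `RR = [a/(a+b)] / [c/(c+d)]` with the Wald 95% CI
#' `exp(log RR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Zero
#' extreme counts trigger a +0.5 continuity correction on every cell
#' (flagged in the result). A per-subject counting variant (mean of
#' per-subject rates) is also reported for reference.
#'
#' @param dev_patients,dev_hc `deviation_maps` on the same voxel set.
#' @param sign `"pos"`, `"neg"` or `"tot"`.
#' @param z_threshold Extreme-deviation threshold.
#' @param mask Optional sub-mask restricting the analyzed voxels.
#' @return Object of class `risk_ratio`: counts, `rr`, `ci_low`,
#'   `ci_high`, `corrected` flag, and `rr_subject` (averaged per-subject
#'   rates variant).
#' @export
risk_ratio <- function(dev_patients, dev_hc, sign = c("tot", "pos", "neg"),
                       z_threshold = 2, mask = NULL) {
  sign <- match.arg(sign)
  cols <- intersect(dev_columns(dev_patients, mask),
                    dev_columns(dev_hc, mask))
  if (!length(cols)) stop("no shared analyzable voxels")
  ex <- function(Z) switch(sign,
                           pos = Z > z_threshold,
                           neg = Z < -z_threshold,
                           tot = abs(Z) > z_threshold)
  Ep <- ex(dev_patients$Z[, cols, drop = FALSE])
  Eh <- ex(dev_hc$Z[, cols, drop = FALSE])
  a <- sum(Ep); b <- length(Ep) - a
  cc <- sum(Eh); d <- length(Eh) - cc
  corrected <- a == 0 || cc == 0
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  rr <- (a / (a + b)) / (cc / (cc + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  rr_subj <- mean(rowMeans(Ep)) / mean(rowMeans(Eh))
  structure(list(a = a, b = b, c = cc, d = d, sign = sign, rr = rr,
                 ci_low = rr * exp(-1.96 * se), ci_high = rr * exp(1.96 * se),
                 corrected = corrected, rr_subject = rr_subj),
            class = "risk_ratio")
}

#' @export
print.risk_ratio <- function(x, ...) {
  cat(sprintf("risk_ratio (%s): RR = %.3f, 95%% CI [%.3f, %.3f]%s\n",
              x$sign, x$rr, x$ci_low, x$ci_high,
              if (x$corrected) " (continuity-corrected)" else ""))
  invisible(x)
}

#' Regional deviation summaries over an atlas parcellation
#'
#' Restricts [summary_measures()] to the voxels of one atlas region (or
#' every region when `region` is NULL).
#'
#' @param dev A `deviation_maps`.
#' @param atlas An [atlas_parcellation()] on the same grid.
#' @param region Region name or label; NULL for all regions.
#' @param z_threshold Extreme-deviation threshold.
#' @param mask Optional additional sub-mask (e.g. an EXPV mask).
#' @return Data frame of per-subject summaries with `scope` = region name.
#' @export
regional_summary <- function(dev, atlas, region = NULL, z_threshold = 2,
                             mask = NULL) {
  stopifnot(inherits(atlas, "atlas_parcellation"))
  if (!same_grid(atlas$grid, dev$mask$grid))
    stop("atlas grid does not match the deviation maps")
  labs <- sort(unique(atlas$labels[atlas$labels > 0L]))
  if (!is.null(region)) {
    if (is.character(region)) {
      l <- as.integer(names(atlas$names)[atlas$names == region])
      if (!length(l)) stop("unknown region: ", region)
    } else l <- as.integer(region)
    if (!l %in% labs) stop("region label not present in atlas")
    labs <- l
  }
  out <- lapply(labs, function(l) {
    flags <- array(FALSE, atlas$grid$dims)
    flags[atlas$labels == l] <- TRUE
    if (!is.null(mask)) flags <- flags & mask$flags
    if (!any(flags & dev$mask$flags))
      stop("region '", atlas$names[[as.character(l)]],
           "' does not intersect the analysis mask")
    summary_measures(dev, mask = brain_mask(atlas$grid, flags),
                     z_threshold = z_threshold,
                     scope = atlas$names[[as.character(l)]])
  })
  do.call(rbind, out)
}
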