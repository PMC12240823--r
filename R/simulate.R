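#' Specification of a synthetic multi-scanner cohort
#'
#' Defines the generative model used to emulate multi-site PET cohorts:
#' per-voxel baseline and covariate effects, per-scanner additive/
#' multiplicative batch effects, spatially structured deviation fields in
#' patient groups, and response labels coupled to striatal deviation.
#'
#' The observation model for subject s at voxel v is
#' \deqn{y_{sv} = \mu_v + a_v (age_s - 40) + s_v sex_s + b_v (bmi_s - 25)
#'   + g_{i(s),v} + \theta_s D_{g(s),v} + d_{i(s)} \sigma_v \epsilon_{sv}}
#' with standard-normal noise. Healthy controls have \eqn{\theta_s = 0};
#' patient deviation magnitudes are drawn \eqn{\theta_s \sim
#' N(\bar\theta_g, \tau_g^2)}. Defaults emulate a dopamine-synthesis (Ki,
#' 1/min) tracer: striatal baseline elevation, mild negative age slope,
#' small sex offset, reference cohort of 50 controls split over two
#' scanners (at least 10 per scanner), FEP-like positive striatal
#' deviations, chronic-SCZ-like negative cortical deviations, and
#' responder labels tied to striatal deviation magnitude.
#'
#' @param dims Grid dimensions (default 16^3, desk scale).
#' @param voxel_size Voxel size in mm.
#' @param n_hc Named integer vector: healthy controls per scanner.
#' @param hc_dataset Optional named character vector mapping scanner to
#'   the dataset id its controls belong to (defaults to the scanner
#'   name); lets controls share a dataset with matched patients.
#' @param n_patients Data frame with columns `scanner`, `group`
#'   (`"FEP"`/`"SCZ"`), `dataset`, `n`; NULL for a control-only cohort.
#'   A patient dataset without controls of its own emulates a
#'   patient-only cohort scored against the stored reference.
#' @param mu0,mu_striatum Baseline intensity outside/inside the striatal
#'   ellipsoid (tracer units).
#' @param age_slope Per-year covariate slope `a_v` applied in the grey
#'   matter (tracer units per year).
#' @param sex_offset Additive offset for sex = 1 (tracer units).
#' @param bmi_slope Per-unit-BMI slope; 0 disables BMI generation.
#' @param sigma Voxel noise SD (tracer units).
#' @param batch_shift Named numeric: additive scanner shift `g_i` (applied
#'   uniformly over voxels).
#' @param batch_scale Named numeric: multiplicative noise scale `d_i > 0`.
#' @param theta_mean,theta_sd Named numeric vectors (per patient group):
#'   mean and SD of the subject deviation magnitude \eqn{\theta_s}.
#' @param response_cutoff Threshold on \eqn{\theta_s} above which a patient
#'   is labelled responder (before label noise).
#' @param label_noise Probability of flipping a response label
#'   (`0 <= label_noise < 0.5`).
#' @param panss_scale Tracer-to-PANSS coupling: expected PANSS points above
#'   the scale minimum per unit \eqn{\theta_s / \tau}.
#' @param age_range,bmi_mean,bmi_sd Demographic sampling parameters.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   bitwise.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(dims = c(16, 16, 16),
                        voxel_size = c(2, 2, 2),
                        n_hc = c(scannerA = 25, scannerB = 25),
                        hc_dataset = NULL,
                        n_patients = NULL,
                        mu0 = 0.008,
                        mu_striatum = 0.012,
                        age_slope = -4e-5,
                        sex_offset = 5e-4,
                        bmi_slope = 0,
                        sigma = 1.5e-3,
                        batch_shift = NULL,
                        batch_scale = NULL,
                        theta_mean = c(FEP = 2.5e-3, SCZ = 2.0e-3),
                        theta_sd = c(FEP = 1.0e-3, SCZ = 1.0e-3),
                        response_cutoff = 2.5e-3,
                        label_noise = 0.05,
                        panss_scale = 12,
                        age_range = c(20, 60),
                        bmi_mean = 25, bmi_sd = 3.5,
                        seed = 1L) {
  scanners <- names(n_hc)
  if (is.null(scanners) || any(!nzchar(scanners)))
    stop("'n_hc' must be a named vector (one entry per scanner)")
  if (any(n_hc < 1))
    stop("every scanner needs at least one healthy control")
  if (!is.null(n_patients)) {
    n_patients <- as.data.frame(n_patients)
    stopifnot(all(c("scanner", "group", "n") %in% names(n_patients)))
    if (is.null(n_patients$dataset))
      n_patients$dataset <- paste0("DS", seq_len(nrow(n_patients)))
    bad <- setdiff(unique(n_patients$scanner), scanners)
    if (length(bad))
      stop("patient scanner(s) without any healthy control: ",
           paste(bad, collapse = ", "))
  }
  if (is.null(hc_dataset))
    hc_dataset <- stats::setNames(scanners, scanners)
  if (!all(scanners %in% names(hc_dataset)))
    stop("'hc_dataset' must name every scanner")
  if (is.null(batch_shift))
    batch_shift <- stats::setNames(rep(0, length(scanners)), scanners)
  if (is.null(batch_scale))
    batch_scale <- stats::setNames(rep(1, length(scanners)), scanners)
  if (any(batch_scale <= 0)) stop("batch scales must be > 0")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("'label_noise' must lie in [0, 0.5)")
  structure(list(dims = dims, voxel_size = voxel_size, n_hc = n_hc,
                 hc_dataset = hc_dataset,
                 n_patients = n_patients, mu0 = mu0,
                 mu_striatum = mu_striatum, age_slope = age_slope,
                 sex_offset = sex_offset, bmi_slope = bmi_slope,
                 sigma = sigma, batch_shift = batch_shift,
                 batch_scale = batch_scale, theta_mean = theta_mean,
                 theta_sd = theta_sd, response_cutoff = response_cutoff,
                 label_noise = label_noise, panss_scale = panss_scale,
                 age_range = age_range, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Toy atlas with striatal and cortical parcels
#'
#' Builds a two-region parcellation on a grid: label 1 ("striatum") is a
#' central ellipsoid of at least 50 voxels, label 2 ("cortex") a
#' surrounding shell; the regions are disjoint.
#'
#' @param grid A [voxel_grid()] with all dimensions >= 8.
#' @return An [atlas_parcellation()].
#' @export
make_toy_atlas <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- grid$dims
  if (any(d < 8L)) stop("grid too small for a toy atlas (need >= 8 per axis)")
  centre <- (d + 1) / 2
  ix <- slice.index(array(0, d), 1); iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  # radii scale with grid size so striatum stays >= 50 voxels at 8^3
  r1 <- pmax(d / 5, 2.4)
  e1 <- ((ix - centre[1]) / r1[1])^2 + ((iy - centre[2]) / r1[2])^2 +
    ((iz - centre[3]) / r1[3])^2
  striatum <- e1 <= 1
  r2a <- d / 2.6; r2b <- d / 2.05
  e2a <- ((ix - centre[1]) / r2a[1])^2 + ((iy - centre[2]) / r2a[2])^2 +
    ((iz - centre[3]) / r2a[3])^2
  e2b <- ((ix - centre[1]) / r2b[1])^2 + ((iy - centre[2]) / r2b[2])^2 +
    ((iz - centre[3]) / r2b[3])^2
  cortex <- e2a > 1 & e2b <= 1 & !striatum
  if (sum(striatum) < 50L) stop("striatal parcel smaller than 50 voxels")
  labels <- array(0L, d)
  labels[striatum] <- 1L
  labels[cortex] <- 2L
  atlas_parcellation(grid, labels, c("1" = "striatum", "2" = "cortex"))
}

# deviation template fields in data units: +1 on striatum (FEP-like),
# -1 on cortex (chronic-SCZ-like), smoothed lightly for spatial structure
deviation_templates <- function(atlas, mask) {
  fep <- array(0, atlas$grid$dims); fep[atlas$labels == 1L] <- 1
  scz <- array(0, atlas$grid$dims); scz[atlas$labels == 2L] <- -1
  list(FEP = as.numeric(fep)[mask_index(mask)],
       SCZ = as.numeric(scz)[mask_index(mask)])
}

#' Generate a synthetic multi-scanner cohort
#'
#' Draws demographics, applies the generative observation model of
#' [cohort_spec()], and returns the parametric maps together with the
#' covariate table. Identical spec and seed give bitwise-identical output.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `maps` (a [map_set()]), `cohort` (a data
#'   frame with subject_id, age, sex, optional bmi, scanner_id, dataset_id,
#'   group, response, PANSS columns, and the latent `theta`), `mask`,
#'   `atlas` and `grid`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  grid <- voxel_grid(spec$dims, spec$voxel_size)
  mask <- brain_mask(grid, array(TRUE, grid$dims))
  atlas <- make_toy_atlas(grid)
  idx <- mask_index(mask)
  V <- length(idx)

  mu <- rep(spec$mu0, V)
  mu[atlas$labels[idx] == 1L] <- spec$mu_striatum
  templ <- deviation_templates(atlas, mask)

  rows <- data.frame(scanner = rep(names(spec$n_hc), spec$n_hc),
                     group = "HC",
                     dataset = rep(unname(spec$hc_dataset[names(spec$n_hc)]),
                                   spec$n_hc),
                     stringsAsFactors = FALSE)
  if (!is.null(spec$n_patients)) {
    p <- spec$n_patients
    rows <- rbind(rows,
                  data.frame(scanner = rep(p$scanner, p$n),
                             group = rep(as.character(p$group), p$n),
                             dataset = rep(as.character(p$dataset), p$n),
                             stringsAsFactors = FALSE))
  }
  n <- nrow(rows)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  bmi <- if (spec$bmi_slope != 0)
    stats::rnorm(n, spec$bmi_mean, spec$bmi_sd) else rep(NA_real_, n)

  theta <- numeric(n)
  pat <- rows$group != "HC"
  if (any(pat)) {
    g <- rows$group[pat]
    theta[pat] <- stats::rnorm(sum(pat), spec$theta_mean[g],
                               spec$theta_sd[g])
  }

  values <- matrix(stats::rnorm(n * V), n, V)
  for (s in seq_len(n)) {
    sc <- rows$scanner[s]
    y <- mu + spec$age_slope * (age[s] - 40) + spec$sex_offset * sex[s] +
      spec$batch_shift[[sc]]
    if (spec$bmi_slope != 0) y <- y + spec$bmi_slope * (bmi[s] - 25)
    if (theta[s] != 0) y <- y + theta[s] * templ[[rows$group[s]]]
    values[s, ] <- y + spec$batch_scale[[sc]] * spec$sigma * values[s, ]
  }

  # response: threshold rule on theta, then label-noise flips
  response <- rep("unknown", n)
  if (any(pat)) {
    resp <- theta[pat] > spec$response_cutoff
    if (spec$label_noise > 0) {
      flip <- stats::runif(sum(pat)) < spec$label_noise
      resp <- xor(resp, flip)
    }
    response[pat] <- ifelse(resp, "responder", "nonresponder")
  }

  # PANSS: minimum 30 (positive 7 + negative 7 + general 16), severity
  # increasing in theta; split roughly 30/25/45% across subscales
  panss <- matrix(NA_integer_, n, 4,
                  dimnames = list(NULL, c("panss_pos", "panss_neg",
                                          "panss_gen", "panss_tot")))
  if (any(pat)) {
    tau <- mean(spec$theta_sd)
    extra <- pmax(0, round(spec$panss_scale * theta[pat] / tau +
                             stats::rnorm(sum(pat), 0, 4)))
    pos <- 7L + as.integer(round(0.30 * extra))
    neg <- 7L + as.integer(round(0.25 * extra))
    gen <- 16L + as.integer(extra) - (pos - 7L) - (neg - 7L)
    panss[pat, ] <- cbind(pos, neg, gen, pos + neg + gen)
  }

  cohort <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                       age = age, sex = sex, bmi = bmi,
                       scanner_id = rows$scanner,
                       dataset_id = rows$dataset,
                       group = rows$group,
                       response = response,
                       panss, theta = theta,
                       stringsAsFactors = FALSE)
  maps <- map_set(values, mask, subject_ids = cohort$subject_id,
                  tracer = "Ki")
  list(maps = maps, cohort = cohort, mask = mask, atlas = atlas,
       grid = grid)
}
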