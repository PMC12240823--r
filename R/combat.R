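#' Fit an empirical-Bayes (ComBat) harmonization model
#'
#' Implements the parametric empirical-Bayes location/scale batch
#' adjustment from genomics, fitted so it can later be applied to new
#' subjects from the same scanners (e.g. fit on healthy controls, apply to
#' patients). Steps: (1) voxel-wise least squares for per-batch means and
#' covariate effects, pooled residual SD; (2) standardization; (3)
#' moment-matched normal / inverse-gamma priors per batch; (4) iterated
#' conditional posterior means for the batch location gamma* and scale
#' delta*^2 (convergence `max |rel change| < 1e-4`, at most 100
#' iterations).
#'
#' With a single batch the model is a no-op (gamma* = 0, delta*^2 = 1).
#'
#' @param maps A [map_set()] (or a subjects x voxels matrix).
#' @param batch Factor/character of batch (scanner) labels, one per row.
#' @param covariates Optional numeric matrix or data frame of covariates
#'   to preserve (no intercept column; factors must be pre-coded).
#' @param eps Convergence tolerance for the EB iterations.
#' @param max_iter Maximum EB iterations.
#' @return An object of class `combat_model`.
#' @export
fit_combat <- function(maps, batch, covariates = NULL, eps = 1e-4,
                       max_iter = 100L) {
  Y <- if (inherits(maps, "map_set")) maps$values else as.matrix(maps)
  batch <- factor(batch)
  if (nrow(Y) != length(batch)) stop("'batch' must have one label per row")
  if (any(table(batch) < 2L)) stop("every batch needs >= 2 subjects")
  nb <- nlevels(batch)
  n <- nrow(Y); V <- ncol(Y)
  B <- outer(batch, levels(batch), `==`) * 1     # n x nb indicators
  colnames(B) <- levels(batch)
  X <- if (is.null(covariates)) NULL else {
    X <- as.matrix(as.data.frame(covariates))
    storage.mode(X) <- "double"
    X
  }
  design <- if (is.null(X)) B else cbind(B, X)
  if (qr(design)$rank < ncol(design))
    stop("design matrix [batch | covariates] is rank deficient")

  # (1) least squares; grand mean = size-weighted mean of batch means
  beta_hat <- solve(crossprod(design), crossprod(design, Y))  # p x V
  n_b <- as.numeric(table(batch))
  grand_mean <- drop(crossprod(n_b / n, beta_hat[seq_len(nb), , drop = FALSE]))
  resid <- Y - design %*% beta_hat
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled <= 0))
    stop("zero pooled variance at ", sum(var_pooled <= 0), " voxel(s)")
  beta_cov <- if (is.null(X)) NULL else
    beta_hat[-seq_len(nb), , drop = FALSE]

  model <- list(batches = levels(batch), n_per_batch = n_b,
                grand_mean = grand_mean, beta_cov = beta_cov,
                covariate_names = colnames(X),
                var_pooled = var_pooled)

  if (nb == 1L) {
    model$gamma_star <- matrix(0, 1, V)
    model$delta_star2 <- matrix(1, 1, V)
    model$hyper <- NULL
    model$n_iter <- 0L
    class(model) <- "combat_model"
    return(model)
  }

  # (2) standardize
  stand_mean <- matrix(grand_mean, n, V, byrow = TRUE)
  if (!is.null(X)) stand_mean <- stand_mean + X %*% beta_cov
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, V, byrow = TRUE)

  # (3) per-batch moments and parametric priors
  gamma_hat <- rowsum(Z, batch) / n_b                       # nb x V
  delta_hat <- matrix(NA_real_, nb, V)
  for (i in seq_len(nb)) {
    zi <- Z[batch == levels(batch)[i], , drop = FALSE]
    delta_hat[i, ] <- apply(zi, 2, stats::var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta_hat); s2_d <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  # (4) iterate conditional posterior means
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  n_iter <- integer(nb)
  for (i in seq_len(nb)) {
    zi <- Z[batch == levels(batch)[i], , drop = FALSE]
    ni <- n_b[i]
    g_new <- gamma_hat[i, ]; d_new <- delta_hat[i, ]
    change <- 1; it <- 0L
    while (change > eps && it < max_iter) {
      g_old <- g_new; d_old <- d_new
      g_new <- (tau2[i] * ni * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (tau2[i] * ni + d_old)
      sum2 <- colSums((zi - matrix(g_new, ni, V, byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      it <- it + 1L
    }
    gamma_star[i, ] <- g_new
    delta_star[i, ] <- d_new
    n_iter[i] <- it
  }

  model$gamma_star <- gamma_star
  model$delta_star2 <- delta_star
  model$hyper <- list(gamma_bar = gamma_bar, tau2 = tau2,
                      a_prior = a_prior, b_prior = b_prior)
  model$n_iter <- n_iter
  class(model) <- "combat_model"
  model
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("combat_model: %d batch(es) [%s], %d voxels, covariates: %s\n",
              length(x$batches), paste(x$batches, collapse = ", "),
              length(x$grand_mean),
              if (is.null(x$beta_cov)) "none"
              else paste(x$covariate_names, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Adjusts maps from scanners seen at fit time:
#' `y* = (sigma_v / delta*_i) (z - gamma*_iv) + alpha_v + x' beta_v`.
#' Batch location/scale estimates come from the fitted model only, so a
#' model fitted on controls can harmonize patient cohorts without the
#' patients influencing the batch estimates.
#'
#' @param model A [fit_combat()] model.
#' @param maps A [map_set()] or matrix with the same voxel columns.
#' @param batch Batch labels (must be a subset of `model$batches`).
#' @param covariates Covariates matching those used at fit time.
#' @return Object of the same type as `maps` with adjusted values.
#' @export
apply_combat <- function(model, maps, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  is_ms <- inherits(maps, "map_set")
  Y <- if (is_ms) maps$values else as.matrix(maps)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen))
    stop("batch(es) not seen at fit time: ", paste(unseen, collapse = ", "))
  if (xor(is.null(covariates), is.null(model$beta_cov)))
    stop("covariates must match those used at fit time")
  n <- nrow(Y); V <- ncol(Y)
  if (V != length(model$grand_mean)) stop("voxel count mismatch")
  stand_mean <- matrix(model$grand_mean, n, V, byrow = TRUE)
  if (!is.null(covariates)) {
    X <- as.matrix(as.data.frame(covariates))
    storage.mode(X) <- "double"
    if (ncol(X) != nrow(model$beta_cov))
      stop("covariate count mismatch with fitted model")
    stand_mean <- stand_mean + X %*% model$beta_cov
  }
  sd_pooled <- matrix(sqrt(model$var_pooled), n, V, byrow = TRUE)
  Z <- (Y - stand_mean) / sd_pooled
  bi <- match(batch, model$batches)
  adj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star2[bi, , drop = FALSE])
  out <- adj * sd_pooled + stand_mean
  if (is_ms)
    map_set(out, maps$mask, subject_ids = maps$subject_ids,
            tracer = maps$tracer)
  else out
}

#' Residual scanner effects on per-subject distribution moments
#'
#' Summarizes each subject's value distribution by its mean and SD over
#' voxels and compares these across batches: Mann-Whitney U with rank
#' effect size r for two batches, Kruskal-Wallis H with eta-squared for
#' more. Used to quantify how much scanner signal survives harmonization.
#'
#' @param x A [map_set()], deviation-map object, or subjects x voxels
#'   matrix.
#' @param batch Batch labels, one per subject.
#' @return Data frame with one row per moment (`mean`, `sd`): test name,
#'   statistic, p value and effect size.
#' @export
residual_scanner_effect <- function(x, batch) {
  Y <- if (inherits(x, "map_set")) x$values
  else if (inherits(x, "deviation_maps")) x$Z
  else as.matrix(x)
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  moments <- list(mean = rowMeans(Y, na.rm = TRUE),
                  sd = apply(Y, 1, stats::sd, na.rm = TRUE))
  out <- lapply(names(moments), function(m) {
    v <- moments[[m]]
    if (nlevels(batch) == 2L) {
      r <- mann_whitney_effect(v[batch == levels(batch)[1]],
                               v[batch == levels(batch)[2]], n_boot = 0)
      data.frame(moment = m, test = "mann-whitney", statistic = r$statistic,
                 p = r$p, effect = r$effect, stringsAsFactors = FALSE)
    } else {
      r <- kruskal_eta2(v, batch, n_boot = 0)
      data.frame(moment = m, test = "kruskal-wallis", statistic = r$statistic,
                 p = r$p, effect = r$effect, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
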