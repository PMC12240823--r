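#' Build a normative-model design matrix
#'
#' Column order is fixed as intercept, then covariates in the order given.
#' Continuous covariates (`age`, `bmi`) are standardized by the reference
#' cohort's mean and SD; when scoring new subjects the *reference*
#' statistics must be reused, so they are returned (and stored on fitted
#' models). `sex` is passed through as 0/1.
#'
#' @param cohort Data frame with the covariate columns.
#' @param covariates Character vector, subset of `c("age", "sex", "bmi")`.
#' @param std Optional list of reference standardization constants
#'   (`list(age = c(mean, sd), ...)`); computed from `cohort` when NULL.
#' @return List with `X` (n x (1 + p) matrix, first column ones) and
#'   `std`.
#' @export
build_design <- function(cohort, covariates = c("age", "sex"),
                         std = NULL) {
  bad <- setdiff(covariates, c("age", "sex", "bmi"))
  if (length(bad)) stop("unsupported covariates: ", paste(bad, collapse = ", "))
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("covariates missing from cohort: ",
                         paste(miss, collapse = ", "))
  n <- nrow(cohort)
  X <- matrix(1, n, 1 + length(covariates),
              dimnames = list(cohort$subject_id,
                              c("(Intercept)", covariates)))
  compute_std <- is.null(std)
  if (compute_std) std <- list()
  for (j in seq_along(covariates)) {
    cv <- covariates[j]
    v <- cohort[[cv]]
    if (anyNA(v))
      stop("missing '", cv, "' for subject(s): ",
           paste(cohort$subject_id[is.na(v)], collapse = ", "))
    if (cv %in% c("age", "bmi")) {
      if (compute_std) std[[cv]] <- c(mean = mean(v), sd = stats::sd(v))
      v <- (v - std[[cv]][["mean"]]) / std[[cv]][["sd"]]
    }
    X[, j + 1] <- v
  }
  list(X = X, std = std)
}

# shared sufficient-statistics context for a fixed design
blr_context <- function(X) {
  XtX <- crossprod(X)
  e <- eigen(XtX, symmetric = TRUE)
  list(X = X, U = e$vectors, lam = pmax(e$values, 0), n = nrow(X),
       p = ncol(X))
}

# negative log marginal likelihood in rotated coordinates
blr_negml <- function(u, ctx, cc, yty) {
  a <- exp(u[1]); b <- exp(u[2])
  denom <- a + b * ctx$lam
  mt <- b * cc / denom                       # rotated posterior mean
  ess <- yty - 2 * sum(mt * cc) + sum(ctx$lam * mt^2)
  E <- b / 2 * ess + a / 2 * sum(mt^2)
  -(0.5 * (ctx$p * u[1] + ctx$n * u[2] - ctx$n * log(2 * pi)) -
      E - 0.5 * sum(log(denom)))
}

blr_fit_one <- function(ctx, cc, yty, vy) {
  if (!is.finite(vy) || vy <= 0)
    return(list(alpha = NA_real_, beta = NA_real_, converged = FALSE,
                logml = NA_real_))
  init <- c(0, log(1 / vy))
  opt <- stats::optim(init, blr_negml, ctx = ctx, cc = cc, yty = yty,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(alpha = exp(opt$par[1]), beta = exp(opt$par[2]),
       converged = opt$convergence == 0 && is.finite(opt$value),
       logml = -opt$value)
}

#' Fit one Bayesian linear regression by evidence maximization
#'
#' Model: `y = X w + e`, `e ~ N(0, 1/beta)`, `w ~ N(0, I/alpha)`
#' (isotropic weight prior with evidence-optimized precision, the standard
#' normative-model construction). `(alpha, beta)` maximize the log
#' marginal likelihood via derivative-free Nelder-Mead over
#' `(log alpha, log beta)`, initialized at `(0, log(1/var(y)))`. A
#' zero-variance response is flagged non-converged rather than raising an
#' error.
#'
#' @param y Response vector (length n > ncol(X) + 2).
#' @param X Design matrix (intercept included).
#' @return List with `alpha`, `beta`, posterior mean `m`, posterior
#'   precision matrix `A = alpha I + beta X'X`, `converged` and `logml`.
#' @export
fit_blr_voxel <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) <= ncol(X) + 2)
    stop("need n > ncol(X) + 2 observations")
  ctx <- blr_context(X)
  cc <- drop(crossprod(ctx$U, crossprod(X, y)))
  fit <- blr_fit_one(ctx, cc, sum(y^2), stats::var(y))
  if (!fit$converged)
    return(c(fit, list(m = rep(NA_real_, ctx$p), A = NULL)))
  denom <- fit$alpha + fit$beta * ctx$lam
  m <- drop(ctx$U %*% (fit$beta * cc / denom))
  A <- ctx$U %*% (denom * t(ctx$U))
  names(m) <- colnames(X)
  c(fit, list(m = m, A = A))
}

# fit all voxels of a response matrix sharing one design
blr_fit_matrix <- function(Y, X) {
  ctx <- blr_context(X)
  V <- ncol(Y)
  Ct <- crossprod(ctx$U, crossprod(X, Y))   # p x V rotated projections
  yty <- colSums(Y^2)
  vy <- apply(Y, 2, stats::var)
  alpha <- beta <- logml <- rep(NA_real_, V)
  converged <- logical(V)
  for (v in seq_len(V)) {
    f <- blr_fit_one(ctx, Ct[, v], yty[v], vy[v])
    alpha[v] <- f$alpha; beta[v] <- f$beta
    converged[v] <- f$converged; logml[v] <- f$logml
  }
  Mt <- matrix(NA_real_, ctx$p, V)
  ok <- which(converged)
  for (v in ok) {
    denom <- alpha[v] + beta[v] * ctx$lam
    Mt[, v] <- ctx$U %*% (beta[v] * Ct[, v] / denom)
  }
  list(ctx = ctx, alpha = alpha, beta = beta, M = Mt,
       converged = converged, logml = logml)
}

# predictive mean and SD for new design rows given a matrix fit
blr_predict <- function(fit, Xnew) {
  Tn <- crossprod(fit$ctx$U, t(Xnew))        # p x nnew
  mu <- Xnew %*% ifelse(is.na(fit$M), 0, fit$M)  # nnew x V
  sd <- matrix(NA_real_, nrow(Xnew), ncol(fit$M))
  ok <- which(fit$converged)
  for (v in ok) {
    denom <- fit$alpha[v] + fit$beta[v] * fit$ctx$lam
    sd[, v] <- sqrt(1 / fit$beta[v] + colSums(Tn^2 / denom))
  }
  mu[, !fit$converged] <- NA_real_
  list(mean = mu, sd = sd)
}

#' Compute deviation Z-scores against fitted voxel models
#'
#' `Z = (y - x'm) / sqrt(1/beta + x' A^{-1} x)`: the denominator is the
#' posterior-predictive SD, so parameter uncertainty is propagated.
#' Non-converged voxels return the NA sentinel.
#'
#' @param fit A single-voxel fit from [fit_blr_voxel()].
#' @param Xnew Design rows for the scored subjects.
#' @param ynew Observed values.
#' @return Numeric vector of Z-scores.
#' @export
predict_z <- function(fit, Xnew, ynew) {
  Xnew <- rbind(Xnew)
  if (!isTRUE(fit$converged)) return(rep(NA_real_, nrow(Xnew)))
  Ainv <- solve(fit$A)
  pv <- 1 / fit$beta + rowSums((Xnew %*% Ainv) * Xnew)
  drop((ynew - Xnew %*% fit$m) / sqrt(pv))
}

#' Out-of-sample explained variance
#'
#' `EXPV = 1 - Var(y - yhat) / Var(y)` with population (divisor n)
#' variances; negative values flag models that predict worse than the
#' mean, the operational non-convergence criterion for normative maps.
#'
#' @param y Observed values (length >= 3).
#' @param yhat Predictions.
#' @return Scalar EXPV (<= 1), or NA when `Var(y) = 0`.
#' @export
explained_variance <- function(y, yhat) {
  if (length(y) < 3) stop("need at least 3 observations")
  vy <- mean((y - mean(y))^2)
  if (vy == 0) return(NA_real_)
  1 - mean((y - yhat - mean(y - yhat))^2) / vy
}

#' Fit voxel-wise normative models on a reference cohort
#'
#' Fits one Bayesian linear regression per masked voxel (see
#' [fit_blr_voxel()]) on the reference cohort, and estimates
#' cross-validated deviation Z-scores and explained variance (EXPV) by
#' seeded k-fold cross-validation. Patients or other target subjects are
#' scored against the full reference fit via [predict()].
#'
#' @param formula One-sided formula naming covariates, e.g. `~ age + sex`
#'   (supported covariates: age, sex, bmi).
#' @param data Reference cohort data frame.
#' @param maps A [map_set()] with one row per reference subject.
#' @param k Number of cross-validation folds (default 5); use `k = n` for
#'   leave-one-out. `k = 0` skips cross-validation.
#' @param seed Seed for the fold shuffle.
#' @return An object of class `normod` with per-voxel `alpha`, `beta`,
#'   posterior weight means (`coef()`), convergence flags, `expv`, and
#'   cross-validated deviations in `$cv` (a `deviation_maps`).
#' @seealso [predict.normod()], [expv_mask()], [summary_measures()]
#' @export
normod <- function(formula, data, maps, k = 5, seed = 1L) {
  stopifnot(inherits(maps, "map_set"))
  covariates <- all.vars(formula)
  if (nrow(data) != nrow(maps$values))
    stop("cohort rows must match map rows")
  des <- build_design(data, covariates)
  n <- nrow(des$X)
  fit <- blr_fit_matrix(maps$values, des$X)

  res <- maps$values - des$X %*% ifelse(is.na(fit$M), 0, fit$M)
  res[, !fit$converged] <- NA_real_
  rownames(res) <- maps$subject_ids

  obj <- structure(
    list(call = match.call(), formula = formula, covariates = covariates,
         std = des$std, X = des$X, alpha = fit$alpha, beta = fit$beta,
         M = fit$M, ctx = fit$ctx, converged = fit$converged,
         logml = fit$logml, residuals = res, mask = maps$mask,
         tracer = maps$tracer, subject_ids = maps$subject_ids, n = n,
         k = k, seed = seed, expv = NULL, cv = NULL),
    class = "normod")

  if (k >= 2) {
    cv <- crossval_deviations(maps, data, covariates, k = k, seed = seed)
    obj$expv <- cv$expv
    obj$cv <- cv$dev
  }
  obj
}

#' Cross-validated deviation maps and explained variance
#'
#' Subjects are shuffled (seeded) into k folds; each fold is scored with
#' models fit on the remaining folds (each fold's models use their own
#' training-fold standardization). EXPV per voxel is computed on the
#' concatenated out-of-fold predictive means.
#'
#' @param maps A [map_set()].
#' @param cohort Covariate table.
#' @param covariates Character vector of covariate names.
#' @param k Number of folds (>= 2, n >= k).
#' @param seed Seed for the fold shuffle.
#' @return List with `dev` (a `deviation_maps`, provenance
#'   "cross-validated") and `expv` (per-voxel vector).
#' @export
crossval_deviations <- function(maps, cohort, covariates = c("age", "sex"),
                                k = 5, seed = 1L) {
  n <- nrow(maps$values)
  if (k < 2) stop("'k' must be >= 2")
  if (n < k) stop("more folds than subjects")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  p <- 1 + length(covariates)
  if (any((n - table(fold)) <= p + 2))
    stop("a training fold has too few subjects for the design")
  Z <- matrix(NA_real_, n, ncol(maps$values))
  Yhat <- matrix(NA_real_, n, ncol(maps$values))
  ok_all <- rep(TRUE, ncol(maps$values))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    des <- build_design(cohort[tr, , drop = FALSE], covariates)
    fit <- blr_fit_matrix(maps$values[tr, , drop = FALSE], des$X)
    Xte <- build_design(cohort[te, , drop = FALSE], covariates,
                        std = des$std)$X
    pr <- blr_predict(fit, Xte)
    Z[te, ] <- (maps$values[te, , drop = FALSE] - pr$mean) / pr$sd
    Yhat[te, ] <- pr$mean
    ok_all <- ok_all & fit$converged
  }
  expv <- rep(NA_real_, ncol(maps$values))
  for (v in which(ok_all))
    expv[v] <- explained_variance(maps$values[, v], Yhat[, v])
  Z[, !ok_all] <- NA_real_
  dev <- deviation_maps(Z, maps$mask, subject_ids = maps$subject_ids,
                        provenance = "cross-validated",
                        converged = ok_all)
  list(dev = dev, expv = expv)
}

#' Deviation (Z-score) maps
#'
#' Container for per-subject voxel-wise standard scores; non-converged
#' voxels carry the NA sentinel and are excluded by downstream analytics.
#'
#' @param Z Subjects x voxels matrix of Z-scores.
#' @param mask The [brain_mask()] defining the voxel columns.
#' @param subject_ids Row identifiers.
#' @param provenance `"cross-validated"` or `"out-of-sample"`.
#' @param converged Per-voxel logical; defaults to columns without NA.
#' @return An object of class `deviation_maps`.
#' @export
deviation_maps <- function(Z, mask, subject_ids = rownames(Z),
                           provenance = "out-of-sample",
                           converged = NULL) {
  Z <- as.matrix(Z)
  stopifnot(inherits(mask, "brain_mask"), ncol(Z) == mask$n_voxels)
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_len(nrow(Z)))
  if (is.null(converged)) converged <- colSums(is.na(Z)) == 0
  rownames(Z) <- subject_ids
  structure(list(Z = Z, mask = mask, subject_ids = as.character(subject_ids),
                 provenance = provenance, converged = converged),
            class = "deviation_maps")
}

#' @export
print.deviation_maps <- function(x, ...) {
  cat(sprintf("deviation_maps (%s): %d subjects x %d voxels (%d converged)\n",
              x$provenance, nrow(x$Z), ncol(x$Z), sum(x$converged)))
  invisible(x)
}

#' @export
print.normod <- function(x, ...) {
  cat("Voxel-wise Bayesian linear regression normative model\n")
  cat(sprintf("  covariates: %s\n", paste(x$covariates, collapse = ", ")))
  cat(sprintf("  reference subjects: %d; voxels: %d (%.1f%% converged)\n",
              x$n, length(x$alpha), 100 * mean(x$converged)))
  if (!is.null(x$expv))
    cat(sprintf("  EXPV (cross-validated, k = %d): median %.3f, max %.3f\n",
                x$k, stats::median(x$expv, na.rm = TRUE),
                max(x$expv, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.normod <- function(object, ...) {
  out <- list(
    n = object$n, n_voxels = length(object$alpha),
    covariates = object$covariates,
    pct_converged = 100 * mean(object$converged),
    alpha = stats::quantile(object$alpha, c(.05, .5, .95), na.rm = TRUE),
    beta = stats::quantile(object$beta, c(.05, .5, .95), na.rm = TRUE),
    expv = if (is.null(object$expv)) NULL else
      stats::quantile(object$expv, c(.05, .5, .95), na.rm = TRUE),
    n_expv_pos = if (is.null(object$expv)) NA_integer_ else
      sum(object$expv > 0, na.rm = TRUE))
  class(out) <- "summary.normod"
  out
}

#' @export
print.summary.normod <- function(x, ...) {
  cat(sprintf("normod: %d subjects, %d voxels, %.1f%% converged\n",
              x$n, x$n_voxels, x$pct_converged))
  cat("  prior precision alpha  [5/50/95%]:",
      paste(signif(x$alpha, 3), collapse = " / "), "\n")
  cat("  noise precision beta   [5/50/95%]:",
      paste(signif(x$beta, 3), collapse = " / "), "\n")
  if (!is.null(x$expv)) {
    cat("  EXPV                   [5/50/95%]:",
        paste(signif(x$expv, 3), collapse = " / "), "\n")
    cat(sprintf("  voxels with EXPV > 0: %d\n", x$n_expv_pos))
  }
  invisible(x)
}

#' @export
coef.normod <- function(object, ...) object$M

#' @export
residuals.normod <- function(object, ...) object$residuals

#' @export
fitted.normod <- function(object, ...) {
  f <- object$X %*% ifelse(is.na(object$M), 0, object$M)
  f[, !object$converged] <- NA_real_
  rownames(f) <- object$subject_ids
  f
}

#' Score subjects against a fitted normative model
#'
#' Builds the design for `newdata` using the reference standardization
#' constants stored in the model and returns, per subject and voxel, the
#' predictive mean, predictive SD, or the deviation Z-score
#' `(y - mean)/sd` when `maps` are supplied.
#'
#' @param object A fitted [normod()].
#' @param newdata Covariate table for the scored subjects.
#' @param maps Optional [map_set()] of observed values (required for
#'   `type = "z"`).
#' @param type `"z"` (default, needs `maps`), `"mean"` or `"sd"`.
#' @param ... Unused.
#' @return A `deviation_maps` for `type = "z"`, otherwise a subjects x
#'   voxels matrix.
#' @export
predict.normod <- function(object, newdata, maps = NULL,
                           type = c("z", "mean", "sd"), ...) {
  type <- match.arg(type)
  X <- build_design(newdata, object$covariates, std = object$std)$X
  fit <- list(ctx = object$ctx, alpha = object$alpha, beta = object$beta,
              M = object$M, converged = object$converged)
  pr <- blr_predict(fit, X)
  if (type == "mean") return(pr$mean)
  if (type == "sd") return(pr$sd)
  if (is.null(maps)) stop("'maps' required for type = \"z\"")
  stopifnot(nrow(maps$values) == nrow(X))
  Z <- (maps$values - pr$mean) / pr$sd
  deviation_maps(Z, object$mask, subject_ids = maps$subject_ids,
                 provenance = "out-of-sample",
                 converged = object$converged)
}

#' Simulate reference-like subjects from the posterior predictive
#'
#' @param object A fitted [normod()].
#' @param nsim Number of simulated cohorts.
#' @param seed Optional seed.
#' @param newdata Covariate table (defaults to the reference cohort).
#' @param ... Unused.
#' @return A list of subjects x voxels matrices (NA at non-converged
#'   voxels).
#' @export
simulate.normod <- function(object, nsim = 1, seed = NULL,
                            newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- if (is.null(newdata)) object$X else
    build_design(newdata, object$covariates, std = object$std)$X
  fit <- list(ctx = object$ctx, alpha = object$alpha, beta = object$beta,
              M = object$M, converged = object$converged)
  pr <- blr_predict(fit, X)
  lapply(seq_len(nsim), function(i)
    pr$mean + pr$sd * matrix(stats::rnorm(length(pr$mean)),
                             nrow(pr$mean), ncol(pr$mean)))
}

#' @export
plot.normod <- function(x, ...) {
  if (is.null(x$expv)) {
    graphics::hist(x$beta, breaks = 40, main = "Noise precision",
                   xlab = expression(beta))
    return(invisible(x))
  }
  graphics::hist(x$expv, breaks = 40,
                 main = "Cross-validated explained variance",
                 xlab = "EXPV", col = "grey85")
  graphics::abline(v = c(0, 0.03, 0.10), lty = c(1, 2, 3), col = "red3")
  invisible(x)
}

#' Analysis mask from explained-variance thresholds
#'
#' Restricts the model mask to converged voxels whose EXPV clears the
#' threshold. The comparison is strict (`>`) for the 0 and 3% thresholds
#' and inclusive (`>=`) for the conservative 10% threshold, following the
#' operator conventions these cutoffs are quoted with; any other
#' threshold uses `>`.
#'
#' @param model A fitted [normod()] with cross-validated EXPV.
#' @param threshold EXPV cutoff (canonical values 0, 0.03, 0.10).
#' @return A [brain_mask()] selecting the retained voxels.
#' @export
expv_mask <- function(model, threshold = 0.03) {
  if (is.null(model$expv)) stop("model has no cross-validated EXPV")
  inclusive <- isTRUE(all.equal(threshold, 0.10))
  sel <- model$converged & !is.na(model$expv) &
    (if (inclusive) model$expv >= threshold else model$expv > threshold)
  if (!any(sel)) stop("no voxels survive EXPV threshold ", threshold)
  flags <- array(FALSE, model$mask$grid$dims)
  flags[mask_index(model$mask)[sel]] <- TRUE
  brain_mask(model$mask$grid, flags)
}
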