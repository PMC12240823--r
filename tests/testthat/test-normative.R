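test_that("design construction standardizes by reference statistics", {
  co <- data.frame(subject_id = c("a", "b", "c"),
                   age = c(20, 40, 60), sex = c(0, 1, 0))
  d <- build_design(co, c("age", "sex"))
  expect_equal(dim(d$X), c(3L, 3L))
  expect_true(all(d$X[, 1] == 1))
  expect_equal(mean(d$X[, "age"]), 0)
  expect_equal(stats::sd(d$X[, "age"]), 1)
  expect_equal(d$X[, "sex"], c(a = 0, b = 1, c = 0))

  # patient design reuses reference statistics -> nonzero mean in general
  pat <- data.frame(subject_id = "p", age = 75, sex = 1)
  Xp <- build_design(pat, c("age", "sex"), std = d$std)$X
  expect_equal(unname(Xp[, "age"]), (75 - 40) / 20)

  co$age[2] <- NA
  expect_error(build_design(co, c("age", "sex")), "b")
})

test_that("single-voxel BLR recovers constants and improves the evidence", {
  set.seed(51)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- 5 + rnorm(n, 0, 1e-6)
  fit <- fit_blr_voxel(y, X)
  expect_true(fit$converged)
  expect_equal(unname(fit$m[1]), 5, tolerance = 1e-3)
  expect_lt(max(abs(fit$m[-1])), 1e-3)

  # optimizer contract: the optimum beats the initialization
  y2 <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n, 0, 0.5)
  f2 <- fit_blr_voxel(y2, X)
  ctx <- petnorm:::blr_context(X)
  cc <- drop(crossprod(ctx$U, crossprod(X, y2)))
  init_val <- -petnorm:::blr_negml(c(0, log(1 / var(y2))), ctx, cc,
                                   sum(y2^2))
  expect_gte(f2$logml, init_val)

  # degenerate voxel flagged, not thrown
  f0 <- fit_blr_voxel(rep(2, n), X)
  expect_false(f0$converged)
  expect_error(fit_blr_voxel(1:3, X), "n >")
})

test_that("BLR recovers planted weights at n = 200", {
  hits <- vapply(1:40, function(s) {
    set.seed(600 + s)
    n <- 200
    X <- cbind(1, rnorm(n), rnorm(n))   # standardized covariates
    w <- c(0.3, 0.5, -0.4)
    y <- drop(X %*% w) + rnorm(n, 0, 0.5)
    fit <- fit_blr_voxel(y, X)
    max(abs(fit$m - w)) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Z-scores follow the posterior-predictive definition", {
  set.seed(52)
  n <- 100
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, 0.7)) + rnorm(n, 0, 0.3)
  fit <- fit_blr_voxel(y, X)
  xstar <- rbind(c(1, 0.5))
  mu <- drop(xstar %*% fit$m)
  s <- sqrt(1 / fit$beta + drop(xstar %*% solve(fit$A) %*% t(xstar)))
  expect_equal(predict_z(fit, xstar, mu), 0)
  expect_equal(predict_z(fit, xstar, mu + 2 * s), 2)
  fit$converged <- FALSE
  expect_true(is.na(predict_z(fit, xstar, mu)))
})

test_that("held-out null subjects are calibrated per voxel", {
  set.seed(53)
  n_tr <- 150; n_te <- 200; V <- 40
  age <- rnorm(n_tr + n_te, 40, 12); sex <- rbinom(n_tr + n_te, 1, 0.5)
  co <- data.frame(subject_id = sprintf("s%03d", seq_along(age)),
                   age = age, sex = sex)
  slopes <- runif(V, -0.02, 0.02)
  Y <- outer(age, slopes) + outer(sex, runif(V, -0.3, 0.3)) +
    matrix(rnorm((n_tr + n_te) * V, 0, 0.5), n_tr + n_te, V)
  tr <- seq_len(n_tr)
  g <- voxel_grid(c(V, 1, 1))
  msk <- full_mask(g)
  m <- normod(~ age + sex, co[tr, ], map_set(Y[tr, ], msk), k = 0)
  dev <- predict(m, co[-tr, ], maps = map_set(Y[-tr, ], msk))
  # per-voxel means combine test-sample noise (SE 1/sqrt(200)) with the
  # shared training-estimation error (SE ~ 1/sqrt(150)), total SD ~ 0.11
  cm <- colMeans(dev$Z)
  expect_lt(abs(mean(cm)), 0.06)
  expect_gte(mean(abs(cm) < 0.25), 0.9)
  zsd <- apply(dev$Z, 2, sd)
  expect_lt(abs(mean(zsd) - 1), 0.05)
  expect_gte(mean(zsd > 0.85 & zsd < 1.15), 0.9)
})

test_that("cross-validation is seeded, exhaustive and produces sane EXPV", {
  set.seed(54)
  sim <- generate_cohort(small_hc_spec(seed = 54, n_per_scanner = 6,
                                       dims = c(8, 8, 8)))
  co <- sim$cohort
  # leave-one-out at n = 12 runs and returns one row per subject
  cv <- crossval_deviations(sim$maps, co, c("age", "sex"), k = 12,
                            seed = 1)
  expect_equal(nrow(cv$dev$Z), 12L)
  cv2 <- crossval_deviations(sim$maps, co, c("age", "sex"), k = 12,
                             seed = 1)
  expect_identical(cv$dev$Z, cv2$dev$Z)
  expect_error(crossval_deviations(sim$maps, co, c("age", "sex"), k = 1),
               ">= 2")
})

test_that("cross-validated EXPV tracks a planted signal fraction", {
  # R^2 = 0.15 voxels and pure-noise voxels, n = 150
  expvs <- sapply(1:6, function(s) {
    set.seed(700 + s)
    n <- 150
    age <- rnorm(n, 40, 12)
    co <- data.frame(subject_id = sprintf("s%d", 1:n), age = age,
                     sex = rbinom(n, 1, 0.5))
    b <- sqrt(0.15 / (1 - 0.15)) / 12   # signal/noise for R^2 = 0.15
    Y <- cbind(age * b + rnorm(n), rnorm(n))
    g <- voxel_grid(c(2, 1, 1))
    cv <- crossval_deviations(map_set(Y, full_mask(g)), co,
                              c("age", "sex"), k = 5, seed = s)
    cv$expv
  })
  expect_lt(abs(mean(expvs[1, ]) - 0.15), 0.07)
  # null voxels are excluded by the 3% mask most of the time
  expect_gte(mean(expvs[2, ] <= 0.03), 0.8)
})

test_that("explained variance follows its definition including negatives", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(mean(y), 5)), 0)
  expect_lt(explained_variance(y, -2 * y), 0)
  expect_true(is.na(explained_variance(rep(1, 5), rep(1, 5))))
})

test_that("EXPV masks are nested and use the stated operators", {
  sim <- generate_cohort(small_hc_spec(seed = 55, n_per_scanner = 25,
                                       dims = c(8, 8, 8)))
  m <- normod(~ age + sex, sim$cohort, sim$maps, k = 5, seed = 2)
  m0 <- expv_mask(m, 0); m3 <- expv_mask(m, 0.03)
  expect_true(all(m3$flags[m3$flags] & m0$flags[m3$flags]))
  expect_lte(m3$n_voxels, m0$n_voxels)
  # threshold semantics: > for 0/0.03, >= for 0.10
  m$expv <- rep(c(0.05, 0.10), length.out = length(m$expv))
  m$converged <- rep(TRUE, length(m$converged))
  expect_equal(expv_mask(m, 0.10)$n_voxels, sum(m$expv >= 0.10))
  expect_equal(expv_mask(m, 0.03)$n_voxels, length(m$expv))
  m$expv <- rep(0.03, length(m$expv))
  expect_error(expv_mask(m, 0.03), "no voxels")
})

test_that("model object supports the standard S3 verbs", {
  sim <- generate_cohort(small_hc_spec(seed = 56, n_per_scanner = 20,
                                       dims = c(8, 8, 8)))
  m <- normod(~ age + sex, sim$cohort, sim$maps, k = 2, seed = 3)
  expect_s3_class(m, "normod")
  expect_output(print(m), "normative model")
  expect_output(print(summary(m)), "EXPV")
  expect_equal(dim(coef(m)), c(3L, 512L))
  expect_equal(dim(residuals(m)), c(40L, 512L))
  expect_equal(dim(fitted(m)), c(40L, 512L))
  expect_equal(unname(fitted(m) + residuals(m)), unname(sim$maps$values))
  sims <- simulate(m, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(m$residuals))
  # average predictive SD shrinks as training n grows
  sim2 <- generate_cohort(small_hc_spec(seed = 57, n_per_scanner = 100,
                                        dims = c(8, 8, 8)))
  m2 <- normod(~ age + sex, sim2$cohort, sim2$maps, k = 0)
  newco <- data.frame(subject_id = "x", age = 45, sex = 1)
  expect_lt(mean(predict(m2, newco, type = "sd")),
            mean(predict(m, newco, type = "sd")))
})
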