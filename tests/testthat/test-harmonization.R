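test_that("fwhm/sigma conversion matches the closed form", {
  expect_equal(fwhm_to_sigma(2 * sqrt(2 * log(2))), 1)
  expect_equal(fwhm_to_sigma(2.3548), 1, tolerance = 1e-4)
  expect_equal(signif(2.3548 / fwhm_to_sigma(2.3548), 3), 2.35)
  expect_error(fwhm_to_sigma(0), "> 0")
})

test_that("gaussian smoothing matches the analytic kernel and conserves mass", {
  g <- voxel_grid(c(21, 21, 21), c(2, 2, 2))
  msk <- full_mask(g)

  # constant field is unchanged (mask-normalized kernel)
  const <- map_set(matrix(3.7, 1, 21^3), msk)
  expect_lt(max(abs(gaussian_smooth(const, 5)$values - 3.7)), 1e-10)

  # unit impulse at the centre reproduces the analytic 3-D Gaussian
  # (sigma = 1 voxel = 2 mm)
  imp <- matrix(0, 1, 21^3); imp[1, (21^3 + 1) / 2] <- 1
  sm <- gaussian_smooth(map_set(imp, msk), fwhm = 2 * sqrt(2 * log(2)) * 2)
  f <- array(sm$values[1, ], g$dims)
  analytic <- function(d2) exp(-d2 / 2) / (2 * pi)^1.5
  expect_equal(f[11, 11, 11], analytic(0), tolerance = 1e-3)
  expect_equal(f[12, 11, 11], analytic(1), tolerance = 1e-3)
  expect_equal(f[12, 12, 11], analytic(2), tolerance = 1e-3)

  # total mass preserved for a compactly supported field
  expect_equal(sum(f), 1, tolerance = 1e-6)

  expect_identical(gaussian_smooth(const, 0), const)
})

test_that("kernel selection recovers the generating kernel", {
  sim <- generate_cohort(small_hc_spec(seed = 31, n_per_scanner = 10,
                                       dims = c(12, 12, 12)))
  target <- sim$maps
  # identical distributions -> no smoothing wins
  ch0 <- select_smoothing_kernel(target, target, c(0, 3, 6))
  expect_equal(ch0$fwhm, 0)
  # reference built by smoothing the target at 3 mm -> 3 mm wins
  ref <- gaussian_smooth(target, 3)
  ch3 <- select_smoothing_kernel(target, ref, c(0, 1.5, 3, 4.5))
  expect_equal(ch3$fwhm, 3)
})

test_that("single-batch ComBat is the identity", {
  set.seed(41)
  Y <- matrix(rnorm(200, 10), 20, 10)
  fit <- fit_combat(Y, rep("A", 20))
  expect_lt(max(abs(apply_combat(fit, Y, rep("A", 20)) - Y)), 1e-8)
})

test_that("ComBat recovers a pure additive shift on near-noiseless data", {
  set.seed(42)
  mu <- runif(30, 5, 15)
  Y <- matrix(mu, 24, 30, byrow = TRUE) +
    matrix(rnorm(24 * 30, 0, 1e-8), 24, 30)
  batch <- rep(c("A", "B"), each = 12)
  delta <- 0.6
  Y[batch == "B", ] <- Y[batch == "B", ] + delta
  fit <- fit_combat(Y, batch)
  rec <- (fit$gamma_star[2, ] - fit$gamma_star[1, ]) * sqrt(fit$var_pooled)
  expect_lt(max(abs(rec - delta)), 1e-6)
  adj <- apply_combat(fit, Y, batch)
  expect_lt(max(abs(colMeans(adj[batch == "A", ]) -
                      colMeans(adj[batch == "B", ]))), 1e-6)
})

test_that("ComBat matches the reference EB implementation", {
  skip_if_not_installed("sva")
  set.seed(43)
  n <- 40; V <- 100
  batch <- rep(c("A", "B"), each = 20)
  age <- rnorm(n, 40, 10)
  Y <- matrix(rnorm(n * V, 10), n, V) + outer(age, rnorm(V, 0.05, 0.01)) +
    ifelse(batch == "B", 0.8, 0)
  fit <- fit_combat(Y, batch, covariates = cbind(age = age))
  adj <- apply_combat(fit, Y, batch, covariates = cbind(age = age))
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(Y), batch = batch,
                mod = stats::model.matrix(~age))))
  expect_lt(max(abs(adj - ref)), 1e-5)
})

test_that("ComBat is idempotent and preserves planted structure", {
  set.seed(44)
  sp <- small_hc_spec(seed = 44, n_per_scanner = 25, dims = c(8, 8, 8),
                      batch_shift = c(scannerA = 0, scannerB = 1e-3),
                      batch_scale = c(scannerA = 1, scannerB = 1.3))
  sim <- generate_cohort(sp)
  covs <- build_design(sim$cohort, c("age", "sex"))$X[, -1, drop = FALSE]
  fit <- fit_combat(sim$maps, sim$cohort$scanner_id, covariates = covs)
  adj <- apply_combat(fit, sim$maps, sim$cohort$scanner_id,
                      covariates = covs)
  # refit on adjusted data: the residual batch locations collapse to a
  # small fraction of the original estimates (empirical-Bayes shrinkage
  # leaves sampling noise of order 1/sqrt(n) per voxel)
  fit2 <- fit_combat(adj, sim$cohort$scanner_id, covariates = covs)
  expect_lt(max(abs(fit2$gamma_star)), 0.25 * max(abs(fit$gamma_star)))
  # unseen scanner is refused
  expect_error(apply_combat(fit, sim$maps, rep("scannerX", 50),
                            covariates = covs), "not seen")
})

test_that("HC-fitted ComBat preserves patient deviations and age slopes", {
  ps <- data.frame(scanner = c("scannerA", "scannerB"), group = "FEP",
                   dataset = c("DS01", "DS02"), n = c(15, 15))
  sp <- cohort_spec(dims = c(10, 10, 10),
                    n_hc = c(scannerA = 25, scannerB = 25),
                    n_patients = ps,
                    batch_shift = c(scannerA = 0, scannerB = 1e-3),
                    seed = 45)
  sim <- generate_cohort(sp)
  hc <- sim$cohort$group == "HC"
  covs <- build_design(sim$cohort, c("age", "sex"))$X[, -1, drop = FALSE]
  fit <- fit_combat(map_set(sim$maps$values[hc, ], sim$mask),
                    sim$cohort$scanner_id[hc],
                    covariates = covs[hc, , drop = FALSE])
  adj <- apply_combat(fit, sim$maps, sim$cohort$scanner_id,
                      covariates = covs)
  stri <- sim$atlas$labels[mask_index(sim$mask)] == 1L
  pat <- !hc
  planted <- mean(sim$cohort$theta[pat])
  raw_shift <- mean(sim$maps$values[pat, stri]) -
    mean(sim$maps$values[hc, stri])
  adj_shift <- mean(adj$values[pat, stri]) - mean(adj$values[hc, stri])
  # the planted striatal deviation survives harmonization (< 5% relative)
  expect_lt(abs(adj_shift - raw_shift) / planted, 0.05)

  # planted age slope recovered by OLS on adjusted controls
  slopes <- vapply(seq_len(ncol(adj$values)), function(v)
    stats::coef(stats::lm(adj$values[hc, v] ~ age + sex,
                          data = sim$cohort[hc, ]))[["age"]], numeric(1))
  expect_lt(abs(mean(slopes) - sp$age_slope), 0.1 * abs(sp$age_slope))
})

test_that("ComBat removes planted between-batch mean variance", {
  # covariate effects off: the between-batch variance is the planted
  # shift plus sampling noise, both of which ComBat should absorb
  reduction <- vapply(1:5, function(s) {
    sp <- cohort_spec(dims = c(8, 8, 8),
                      n_hc = c(scannerA = 20, scannerB = 20),
                      age_slope = 0, sex_offset = 0,
                      batch_shift = c(scannerA = 0, scannerB = 1.5e-3),
                      seed = 100 + s)
    sim <- generate_cohort(sp)
    covs <- build_design(sim$cohort, c("age", "sex"))$X[, -1, drop = FALSE]
    fit <- fit_combat(sim$maps, sim$cohort$scanner_id, covariates = covs)
    adj <- apply_combat(fit, sim$maps, sim$cohort$scanner_id,
                        covariates = covs)
    bv <- function(M) mean((colMeans(M[sim$cohort$scanner_id == "scannerA", ]) -
                              colMeans(M[sim$cohort$scanner_id == "scannerB", ]))^2)
    1 - bv(adj$values) / bv(sim$maps$values)
  }, numeric(1))
  expect_true(all(reduction >= 0.90))
})

test_that("smoothing cannot remove an additive batch shift", {
  # constant-plus-shift phantom: smoothing leaves the between-batch mean
  # difference untouched while ComBat removes it
  g <- tiny_grid(c(8, 8, 8))
  msk <- full_mask(g)
  Y <- matrix(10, 20, 512)
  batch <- rep(c("A", "B"), each = 10)
  Y[batch == "B", ] <- Y[batch == "B", ] + 1
  ms <- map_set(Y, msk)
  dmean <- function(M) mean(M[batch == "B", ]) - mean(M[batch == "A", ])
  sm <- gaussian_smooth(ms, 6)
  expect_equal(dmean(sm$values), dmean(Y), tolerance = 1e-10)
  # ComBat on the same phantom (tiny jitter for estimability) removes it
  set.seed(46)
  Yj <- Y + matrix(rnorm(20 * 512, 0, 0.05), 20, 512)
  msj <- map_set(Yj, msk)
  cb <- apply_combat(fit_combat(msj, batch), msj, batch)
  expect_lt(abs(dmean(cb$values)), 0.05 * abs(dmean(Yj)))
})

test_that("residual scanner reports detect planted shifts and pass nulls", {
  set.seed(47)
  Y <- matrix(rnorm(40 * 100), 40, 100)
  batch <- rep(c("A", "B"), each = 20)
  rep0 <- residual_scanner_effect(Y, batch)
  expect_true(all(rep0$p > 0.05))
  Y2 <- Y; Y2[batch == "B", ] <- Y2[batch == "B", ] + 1
  rep1 <- residual_scanner_effect(Y2, batch)
  expect_lt(rep1$p[rep1$moment == "mean"], 0.01)
  # three batches route through Kruskal-Wallis
  rep3 <- residual_scanner_effect(rbind(Y, Y[1:20, ]),
                                  c(batch, rep("C", 20)))
  expect_true(all(rep3$test == "kruskal-wallis"))
})
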