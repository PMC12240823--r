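test_that("Scheirer-Ray-Hare degenerates and reduces correctly", {
  # all values identical: every H = 0, p = 1
  r0 <- scheirer_ray_hare(rep(2, 12), rep(c("a", "b"), 6),
                          rep(c("x", "y"), each = 6))
  expect_equal(r0$a$statistic, 0); expect_equal(r0$a$p, 1)
  expect_equal(r0$interaction$p, 1)

  # single-level second factor: A main effect equals Kruskal-Wallis H
  set.seed(71)
  v <- rnorm(30); gr <- rep(letters[1:3], 10)
  srh <- scheirer_ray_hare(v, gr, rep("only", 30))
  kw <- stats::kruskal.test(v, factor(gr))
  expect_equal(srh$a$statistic, unname(kw$statistic), tolerance = 1e-10)
  expect_equal(srh$a$p, kw$p.value, tolerance = 1e-10)

  expect_error(scheirer_ray_hare(rnorm(6), c("a", "a", "a", "b", "b", "b"),
                                 c("x", "x", "x", "x", "x", "y")),
               "nonempty")
})

test_that("Scheirer-Ray-Hare p agrees with a permutation null", {
  set.seed(72)
  a <- rep(c("a1", "a2", "a3"), each = 16)
  b <- rep(rep(c("b1", "b2"), each = 8), 3)
  v <- rnorm(48) + (a == "a2") * 0.8
  obs <- scheirer_ray_hare(v, a, b)
  perm <- vapply(1:2000, function(i)
    scheirer_ray_hare(sample(v), a, b)$a$statistic, numeric(1))
  p_perm <- mean(perm >= obs$a$statistic)
  expect_lt(abs(obs$a$p - p_perm), 0.02)
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(73)
  v <- rexp(36); gr <- rep(c("g1", "g2", "g3"), 12)
  t1 <- kruskal_eta2(v, gr, n_boot = 0)
  t2 <- kruskal_eta2(log(v + 1), gr, n_boot = 0)
  expect_equal(t1$statistic, t2$statistic)
  m1 <- mann_whitney_effect(v[1:18], v[19:36], n_boot = 0)
  m2 <- mann_whitney_effect(exp(v[1:18]), exp(v[19:36]), n_boot = 0)
  expect_equal(m1$statistic, m2$statistic)
})

test_that("Kruskal-Wallis eta-squared behaves at k = 2 and near the null", {
  set.seed(74)
  x <- rnorm(25); y <- rnorm(30, 0.8)
  kw <- kruskal_eta2(c(x, y), rep(c("x", "y"), c(25, 30)), n_boot = 200)
  mw <- mann_whitney_effect(x, y, n_boot = 0)
  expect_equal(kw$p, mw$p, tolerance = 1e-6)
  expect_true(kw$ci_low <= kw$effect && kw$effect <= kw$ci_high)

  # eta^2 may be slightly negative under the null (allowed by contract)
  etas <- vapply(1:50, function(i) {
    v <- rnorm(40)
    kruskal_eta2(v, rep(c("p", "q"), 20), n_boot = 0)$effect
  }, numeric(1))
  expect_true(any(etas < 0))
  expect_lt(abs(mean(etas)), 0.05)
})

test_that("Mann-Whitney U matches enumeration and nulls out", {
  r <- mann_whitney_effect(c(1, 2), c(3, 4), n_boot = 0)
  expect_equal(r$statistic, 0)   # every y exceeds every x

  # continuity-corrected normal approximation tracks the exact
  # enumeration p at n = 6/6
  set.seed(75)
  diffs <- vapply(1:20, function(i) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    r2 <- mann_whitney_effect(x, y, n_boot = 0, correct = TRUE)
    abs(r2$p - stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }, numeric(1))
  expect_lt(median(diffs), 0.02)

  rnull <- vapply(1:50, function(i)
    mann_whitney_effect(rnorm(30), rnorm(30), n_boot = 0)$effect,
    numeric(1))
  expect_lt(mean(rnull), 0.15)
})

test_that("Spearman correlations recover exact and planted couplings", {
  sc <- spearman_clinical(data.frame(m = 1:10),
                          data.frame(panss = (1:10)^2))
  expect_equal(sc$rho, 1)
  sc2 <- spearman_clinical(data.frame(m = 1:10),
                           data.frame(panss = -(1:10)))
  expect_equal(sc2$rho, -1)

  # theta-coupled PANSS: pct_tot correlates with panss_tot
  ps <- data.frame(scanner = "scannerA", group = "FEP", dataset = "DS01",
                   n = 36)
  hits <- vapply(1:6, function(s) {
    sim <- generate_cohort(cohort_spec(dims = c(10, 10, 10),
                                       n_hc = c(scannerA = 30),
                                       n_patients = ps, seed = 900 + s))
    hc <- sim$cohort$group == "HC"
    m <- normod(~ age + sex, sim$cohort[hc, ],
                map_set(sim$maps$values[hc, ], sim$mask), k = 0)
    dev <- predict(m, sim$cohort[!hc, ],
                   maps = map_set(sim$maps$values[!hc, ], sim$mask))
    sm <- summary_measures(dev)
    out <- spearman_clinical(sm["pct_tot"],
                             sim$cohort[!hc, "panss_tot", drop = FALSE])
    out$rho > 0 && out$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("TFCE matches closed forms and is monotone", {
  g <- voxel_grid(c(12, 12, 12))
  # all-zero field stays zero
  expect_true(all(tfce_enhance(array(0, g$dims)) == 0))

  # uniform cluster of extent e and height h: integral -> e^0.5 h^3 / 3
  arr <- array(0, g$dims); arr[5:8, 5:8, 5:8] <- 2
  e1 <- max(tfce_enhance(arr, dh = 2 / 200))
  expect_equal(e1, 64^0.5 * 2^3 / 3, tolerance = 0.02)

  # doubling the extent multiplies TFCE by sqrt(2)
  big <- array(0, c(12, 12, 24)); big[5:8, 5:8, 5:12] <- 2
  e_single <- max(tfce_enhance(arr, dh = 2 / 200))
  e_double <- max(tfce_enhance(big, dh = 2 / 200))
  expect_equal(e_double / e_single, sqrt(2), tolerance = 0.02)

  # monotonicity: pointwise-larger fields enhance pointwise larger
  set.seed(76)
  f1 <- array(abs(rnorm(12^3)), g$dims)
  f2 <- f1 + 0.5
  dh <- max(f2) / 100
  expect_true(all(tfce_enhance(f2, dh = dh) >=
                    tfce_enhance(f1, dh = dh) - 1e-12))
})

test_that("permutation GLM is seeded, bounded and detects planted blobs", {
  set.seed(77)
  g <- voxel_grid(c(10, 10, 10))
  msk <- full_mask(g)
  n <- 60
  Z <- matrix(rnorm(n * 1000), n, 1000)
  blob <- array(FALSE, g$dims); blob[4:7, 4:7, 4:7] <- TRUE
  bi <- which(as.vector(blob))
  grp <- rep(c("HC", "PAT"), each = 30)
  Z[grp == "PAT", bi] <- Z[grp == "PAT", bi] + 1.0
  dev <- deviation_maps(Z, msk)

  r <- permutation_glm(dev, data.frame(group = grp), ~ group,
                       n_perm = 300, seed = 3, enhancement = "tfce")
  expect_gte(mean(r$p_fwe[bi] < 0.05), 0.5)
  expect_lte(mean(r$p_fwe[-bi] < 0.05), 0.01)
  # identical seed reproduces the p fields bitwise
  r2 <- permutation_glm(dev, data.frame(group = grp), ~ group,
                        n_perm = 300, seed = 3, enhancement = "tfce")
  expect_identical(r$p_fwe, r2$p_fwe)
  # p is monotone in the observed statistic and respects the 1/(1+B) floor
  ok <- !is.na(r$p_fwe)
  ord <- order(r$enhanced[ok])
  expect_true(all(diff(r$p_fwe[ok][ord]) <= 1e-12))
  expect_gte(min(r$p_fwe, na.rm = TRUE), 1 / 301)

  # single-permutation boundary: p = 1/(1+1) at best, no division error
  r1 <- permutation_glm(dev, data.frame(group = grp), ~ group,
                        n_perm = 1, seed = 4)
  expect_true(all(r1$p_fwe >= 0.5, na.rm = TRUE))

  expect_error(permutation_glm(dev, data.frame(group = rep("HC", n)),
                               ~ group, n_perm = 10), "rank|contrast")
})

test_that("cluster extraction enforces the size threshold", {
  g <- voxel_grid(c(12, 12, 12))
  msk <- full_mask(g)
  p <- rep(1, prod(g$dims))
  big <- array(FALSE, g$dims); big[2:5, 2:5, 2:5] <- TRUE      # 64 voxels
  small <- array(FALSE, g$dims); small[8:11, 8:11, 9:11] <- TRUE  # 48
  p[as.vector(big) | as.vector(small)] <- 0.01
  sm <- structure(list(stat = rep(1, length(p)), enhanced = rep(1, length(p)),
                       p_uncorrected = p, p_fwe = p, mask = msk,
                       n_perm = 100, effect = "group", df1 = 1, df2 = 10,
                       enhancement = "none"),
                  class = "stat_map")
  cs <- extract_clusters(sm, min_size = 50)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$size, 64L)

  # no significant voxels: empty set allowed
  sm$p_fwe <- rep(1, length(p))
  expect_equal(nrow(extract_clusters(sm)$clusters), 0L)

  # per-subject cluster means equal hand-computed means
  sm$p_fwe <- p
  Z <- matrix(seq_len(4 * prod(g$dims)) %% 7, 4, prod(g$dims))
  dev <- deviation_maps(Z, msk)
  cs2 <- extract_clusters(sm, min_size = 50, dev = dev)
  expect_equal(unname(cs2$subject_means[[1]]),
               unname(rowMeans(Z[, cs2$members[[1]]])))
})

test_that("permutation GLM keeps nominal FWE under the null", {
  # reduced-scale calibration: fewer replicates than the acceptance run
  set.seed(78)
  g <- voxel_grid(c(10, 10, 10)); msk <- full_mask(g)
  grp <- rep(c("A", "B"), each = 12)
  fp <- vapply(1:30, function(i) {
    Z <- matrix(rnorm(24 * 1000), 24, 1000)
    r <- permutation_glm(deviation_maps(Z, msk), data.frame(group = grp),
                         ~ group, n_perm = 250, seed = i)
    any(r$p_fwe < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(fp), 0.0)
  expect_lte(mean(fp), 0.2)
})
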