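# Group statistics and quantification: Kruskal/Dunn, Levene,
# Theil-Sen / Kd, molecule counting, cycle-effect summaries.

test_that("kruskal_dunn matches hand computation and kruskal.test", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_dunn(g)
  expect_equal(res$statistic, 7.2)
  expect_equal(res$statistic,
               unname(kruskal.test(g)$statistic))
  expect_equal(res$p.value, kruskal.test(g)$p.value)
  # identical groups: H = 0, no significant pairs
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- kruskal_dunn(same)
  expect_equal(r0$statistic, 0)
  expect_false(any(r0$pairs$significant))
  # permutation of values within groups leaves the result unchanged
  g2 <- list(a = c(3, 1, 2), b = c(6, 4, 5), c = c(9, 7, 8))
  expect_equal(kruskal_dunn(g2)$statistic, res$statistic)
  expect_equal(kruskal_dunn(g2)$pairs$z, res$pairs$z)
  expect_error(kruskal_dunn(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("kruskal_dunn agrees with brute-force oracles on random
           fixtures with ties", {
  set.seed(31)
  for (rep in 1:8) {
    k <- sample(2:4, 1)
    g <- lapply(seq_len(k), function(i)
      sample(1:6, sample(2:5, 1), replace = TRUE))
    names(g) <- letters[seq_len(k)]
    res <- kruskal_dunn(g)
    expect_equal(res$statistic, oracle_kruskal_H(g), tolerance = 1e-12)
    expect_equal(res$statistic,
                 unname(kruskal.test(g)$statistic),
                 tolerance = 1e-12)
    expect_equal(res$pairs$z[1], unname(oracle_dunn_z(g, 1, 2)),
                 tolerance = 1e-12)
  }
})

test_that("levene_test is exact on constructed fixtures", {
  # identical spreads: deviations coincide, W = 0
  r <- levene_test(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # location shifts leave W unchanged
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30, sd = 2)
  r1 <- levene_test(list(x = x, y = y))
  r2 <- levene_test(list(x = x + 100, y = y - 50))
  expect_equal(r1$statistic, r2$statistic)
  expect_lt(abs(r1$p.value - r2$p.value), 1e-12)
})

test_that("levene_test agrees with car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(9)
  x <- rnorm(25); y <- rnorm(30, sd = 1.6); z <- rnorm(20, sd = 0.7)
  mine <- levene_test(list(x = x, y = y, z = z))
  vals <- c(x, y, z)
  grp <- factor(rep(c("x", "y", "z"), c(25, 30, 20)))
  ref <- car::leveneTest(vals, grp, center = mean)
  expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("levene_test detects a threefold spread difference", {
  hits <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    levene_test(list(a = rnorm(100), b = rnorm(100, sd = 3)))$p.value
  }, numeric(1))
  expect_gte(sum(hits < 0.01), 95)
})

test_that("theil_sen_slope matches enumeration and resists outliers", {
  expect_equal(theil_sen_slope(c(0, 1, 2), c(0, 2, 4))$slope, 2)
  expect_equal(theil_sen_slope(c(0, 2), c(0, 6))$slope, 3)
  # one wild point among colinear data does not move the median slope
  expect_equal(
    theil_sen_slope(0:4, c(0, 2, 4, 6, 100))$slope, 2)
  x <- 0:10; y <- 3 * x + 1
  y[6] <- 500
  expect_equal(theil_sen_slope(x, y)$slope, 3)
  expect_error(theil_sen_slope(c(1, 1, 1), c(1, 2, 3)), "equal")
  # full pairwise enumeration oracle on random small fixtures
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(3:12, 1)
    x <- sample(1:15, n, replace = TRUE)
    y <- rnorm(n)
    if (length(unique(x)) < 2) next
    expect_equal(theil_sen_slope(x, y)$slope, oracle_theil_sen(x, y),
                 tolerance = 1e-12)
  }
})

test_that("estimate_kd recovers construction exactly and scales", {
  tri <- generate_fccs_set(true_kd_nM = 12, n = 20, noise_sd = 0,
                           seed = 3)
  expect_equal(tri$freeA_nM * tri$freeB_nM / tri$complex_nM,
               rep(12, 20), tolerance = 1e-12, ignore_attr = TRUE)
  kd <- estimate_kd(tri)
  expect_equal(kd$kd_nM, 12, tolerance = 1e-12)
  expect_true(kd$ci_nM[1] <= kd$kd_nM && kd$kd_nM <= kd$ci_nM[2])
  # scale equivariance: concentrations in different units
  tri2 <- tri
  tri2[c("freeA_nM", "freeB_nM", "complex_nM")] <-
    tri[c("freeA_nM", "freeB_nM", "complex_nM")] * 0.001
  expect_equal(estimate_kd(tri2)$kd_nM, 0.012, tolerance = 1e-12)
  expect_equal(coef(kd)[["kd_nM"]], kd$kd_nM)
})

test_that("estimate_kd tolerates noise at the study's sample size", {
  tri <- generate_fccs_set(true_kd_nM = 12, n = 46, noise_sd = 0.1,
                           seed = 1)
  kd <- estimate_kd(tri)
  expect_lt(abs(kd$kd_nM - 12) / 12, 0.15)
})

test_that("molecules_per_cell applies the volume scaling formula", {
  expect_equal(molecules_per_cell(list(n_nuc = 0, n_cyt = 0,
    v_conf_fL = 0.59, v_nuc_fL = 1420, v_cyt_fL = 6110)), 0)
  expect_equal(molecules_per_cell(list(n_nuc = 1, n_cyt = 0,
    v_conf_fL = 2, v_nuc_fL = 2, v_cyt_fL = 5)), 1)
  # printed volumes: 10 nuclear particles in 1420 fL vs 0.59 fL
  expect_equal(molecules_per_cell(list(n_nuc = 10, n_cyt = 0,
    v_conf_fL = 0.59, v_nuc_fL = 1420, v_cyt_fL = 6110)),
    10 * 1420 / 0.59)
  expect_error(molecules_per_cell(list(n_nuc = -1, n_cyt = 0,
    v_conf_fL = 0.59, v_nuc_fL = 1420, v_cyt_fL = 6110)),
    "non-negative")
})

test_that("cycle_effect_summary reports exact effects on fixtures", {
  set.seed(2)
  same <- rnorm(40, 20, 2)
  eff <- cycle_effect_summary(same, same, n_boot = 200)
  expect_equal(eff$mean_diff_h, 0)
  expect_equal(eff$sd_ratio, 1)
  eff2 <- cycle_effect_summary(c(18, 20, 22), c(20, 22, 24),
                               n_boot = 200)
  expect_equal(eff2$mean_diff_h, 2)
  expect_output(print(eff2), "mean difference")
})

test_that("cycle-effect bootstrap CIs cover the programmed effects", {
  # scaled-down coverage check on duration-only populations
  programmed <- 0.40 * 1.8 + 0.10 * 9 + 0.15 * 1.8
  hit_mean <- hit_sd <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    u <- duration_population(60, seed = 3000 + i, dose = 0)
    t <- duration_population(60, seed = 6000 + i, dose = 1)
    du <- cycle_durations(u); du <- du[!duplicated(du$cell_id), ]
    dt <- cycle_durations(t, spanning_time_min = 30 * 60)
    set.seed(9000 + i)
    eff <- cycle_effect_summary(du$duration_h, dt$duration_h,
                                n_boot = 400)
    hit_mean <- hit_mean + (eff$mean_diff_ci[1] <= programmed &&
                            programmed <= eff$mean_diff_ci[2])
    hit_sd <- hit_sd + (eff$sd_ratio_ci[1] <= 2 &&
                        2 <= eff$sd_ratio_ci[2])
  }
  expect_gte(hit_mean / n_rep, 0.9)
  expect_gte(hit_sd / n_rep, 0.9)
})
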