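test_that("subsampling a full-map square reproduces the whole-map TI and is reproducible", {
  rec <- texture_recipe(c_dispersion = 8, a_model = a_dispersed(8),
                        unindexed_fraction = 0.2)
  map <- generate_map(rec, 36, 36, seed = 3)
  full <- subsample_squares(map, sizes = 36, n_per_size = 1, seed = 1,
                            metrics = "ti")
  whole <- texture_index(build_odf(map))
  expect_equal(full$ti, whole, tolerance = 1e-9)
  expect_equal(full$n_indexed, sum(map$phase > 0))

  a <- subsample_squares(map, c(12, 16), n_per_size = 3, seed = 7,
                         min_indexed = 60, metrics = "ti")
  b <- subsample_squares(map, c(12, 16), n_per_size = 3, seed = 7,
                         min_indexed = 60, metrics = "ti")
  expect_identical(a, b)
  expect_true(all(a$n_indexed >= 60))
  expect_error(subsample_squares(map, sizes = 100, n_per_size = 1), "larger")
})

test_that("finite-sample inflation makes small squares score higher TI on homogeneous maps", {
  rec <- texture_recipe(c_dispersion = 8, a_model = a_dispersed(8),
                        unindexed_fraction = 0.2)
  map <- generate_map(rec, 96, 96, seed = 5)
  ss <- subsample_squares(map, sizes = c(12, 60), n_per_size = 15, seed = 6,
                          metrics = "ti")
  m_small <- mean(ss$ti[ss$size_um == 12])
  m_large <- mean(ss$ti[ss$size_um == 60])
  expect_gt(m_small, m_large)
})

test_that("TI-area correlation handles the toy, degenerate and error cases", {
  toy <- data.frame(area_um2 = c(1, 2, 3), ti = c(10, 5, 0))
  ct <- ti_area_correlation(toy)
  expect_equal(ct$rho, -1, tolerance = 1e-12)
  const <- data.frame(area_um2 = c(1, 2, 3), ti = c(2, 2, 2))
  expect_error(ti_area_correlation(const), "variance")
})

test_that("Kruskal-Wallis matches the explicit rank formula, with and without ties", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)  # 3.857142857...
  expect_equal(kw$H, kw_hand(list(c(1, 2, 3), c(4, 5, 6))), tolerance = 1e-12)
  expect_equal(kw$df, 1)

  set.seed(8)
  g <- list(a = sample(1:8, 10, TRUE), b = sample(2:9, 12, TRUE),
            c = sample(1:9, 9, TRUE))   # heavy ties
  kw2 <- kruskal_wallis(g)
  expect_equal(kw2$H, kw_hand(g), tolerance = 1e-12)
  expect_equal(kw2$df, 2)
  expect_lte(kw2$H, sum(lengths(g)) - 1)

  # identical groups: H ~ 0, p ~ 1
  kw3 <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(kw3$H, 1e-12)
  expect_gt(kw3$p_value, 0.99)
  expect_error(kruskal_wallis(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(9)
  rej <- mean(replicate(2000, {
    g <- split(rnorm(24), rep(1:3, each = 8))
    kruskal_wallis(g)$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("pairwise Wilcoxon applies the published Bonferroni arithmetic", {
  set.seed(10)
  g <- list(a = rnorm(12), b = rnorm(12) + 3, c = rnorm(12))
  pw <- pairwise_wilcoxon_bonferroni(g)
  expect_equal(pw$adjusted_alpha, 0.05 / 6)
  expect_equal(100 * pw$adjusted_alpha, 0.8333, tolerance = 1e-4)
  expect_equal(100 * pw$conf_level, 99.1667, tolerance = 1e-4)
  expect_equal(nrow(pw$pairs), 3)
  expect_true(pw$pairs$significant[pw$pairs$group1 == "a" &
                                     pw$pairs$group2 == "b"])

  # identical groups: maximal p, CI straddles zero
  same <- pairwise_wilcoxon_bonferroni(list(x = 1:10, y = 1:10))
  expect_equal(same$pairs$p_value, 1)
  expect_lt(same$pairs$ci_lower, 0)
  expect_gt(same$pairs$ci_upper, 0)
})

test_that("exact Wilcoxon p-values equal exhaustive rank-sum enumeration", {
  x <- c(1, 3, 5, 7, 9, 11)
  y <- c(2.5, 4.5, 8.5, 10.5, 12.5, 14.5)
  pw <- pairwise_wilcoxon_bonferroni(list(x = x, y = y))
  expect_equal(pw$pairs$p_value, wilcox_exact_enum(x, y), tolerance = 1e-12)

  set.seed(11)
  x2 <- rnorm(6); y2 <- rnorm(6) + 1
  pw2 <- pairwise_wilcoxon_bonferroni(list(x = x2, y = y2))
  expect_equal(pw2$pairs$p_value, wilcox_exact_enum(x2, y2), tolerance = 1e-12)
})

test_that("the M-index responds less to area than TI on the same map", {
  rec <- texture_recipe(c_dispersion = 8, a_model = a_dispersed(8),
                        unindexed_fraction = 0.2)
  map <- generate_map(rec, 96, 96, seed = 12)
  ss <- subsample_squares(map, sizes = c(12, 20, 34, 56), n_per_size = 8,
                          seed = 13)
  sens <- area_sensitivity(ss)
  expect_lt(abs(sens$rel_slope[sens$metric == "m_index"]),
            abs(sens$rel_slope[sens$metric == "ti"]))
})
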