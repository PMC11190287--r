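test_that("kernel shape parameter solves the half-maximum equation", {
  expect_equal(kernel_kappa(4), log(0.5) / (2 * log(cos(2 * pi / 180))),
               tolerance = 1e-12)
  # the kernel really falls to half its peak at the halfwidth
  for (hw in c(4, 10, 25)) {
    odf <- build_odf(matrix(c(1, 0, 0, 0), 1), crystal_symmetry("1"),
                     halfwidth = hw)
    at_peak <- odf_eval(odf, matrix(c(1, 0, 0, 0), 1))
    at_hw <- odf_eval(odf, axis_angle_quat(c(1, 0, 0), hw))
    expect_equal(at_hw / at_peak, 0.5, tolerance = 1e-6)
  }
})

test_that("a single-component ODF peaks at the normalization constant and has unit mass", {
  sym <- crystal_symmetry()
  odf <- build_odf(matrix(c(1, 0, 0, 0), 1), sym, halfwidth = 4)
  # symmetrized peak = C(kappa) / |622|; C by the closed form checked against
  # 1-d numeric quadrature of the kernel mass
  kap <- odf$kappa
  w <- seq(0, pi, length.out = 200001)
  mass_num <- sum(cos(w / 2)^(2 * kap) * (2 / pi) * sin(w / 2)^2) * (pi / 200000)
  C_num <- 1 / mass_num
  expect_equal(conotex:::kernel_peak(kap), C_num, tolerance = 1e-6)
  expect_equal(odf_eval(odf, matrix(c(1, 0, 0, 0), 1)),
               conotex:::kernel_peak(kap) / 12, tolerance = 1e-4)
})

test_that("quadrature mass is unity within 0.5% across halfwidths and mixtures", {
  sym <- crystal_symmetry()
  for (hw in c(4, 10, 25)) {
    q <- random_orientations(20, seed = hw)
    expect_equal(conotex:::odf_mass(build_odf(q, sym, hw)), 1,
                 tolerance = 0.005)
  }
  expect_equal(conotex:::odf_mass(build_odf(matrix(c(1, 0, 0, 0), 1), sym, 4)),
               1, tolerance = 0.005)
})

test_that("TI of a uniform texture approaches 1 with the expected finite-sample inflation", {
  sym <- crystal_symmetry()
  q <- random_orientations(3000, seed = 11)
  odf <- build_odf(q, sym, 4)
  ti <- texture_index(odf)
  ti1 <- texture_index(build_odf(matrix(c(1, 0, 0, 0), 1), sym, 4))
  # E[TI] = 1 + (TI_single - 1)/n for Haar data; allow 3 sd of slack
  expect_gt(ti, 0.995)
  expect_lt(ti, 1 + 2.5 * ti1 / 3000)
})

test_that("the three TI routes agree: quadrature vs series vs Monte Carlo", {
  sym <- crystal_symmetry()
  # sharp single kernel against an importance-sampled MC oracle
  odf1 <- build_odf(matrix(c(1, 0, 0, 0), 1), sym, 4)
  ti_series <- texture_index(odf1, "series")
  ti_grid <- texture_index(odf1, "grid")
  ti_mc <- texture_index(odf1, "mc", n_mc = 2e5, importance = TRUE, seed = 1)
  expect_equal(ti_grid / ti_series, 1, tolerance = 0.02)
  expect_equal(ti_mc / ti_series, 1, tolerance = 0.02)
  # random mixtures, plain Haar MC
  set.seed(21)
  for (k in 1:4) {
    hw <- runif(1, 8, 30)
    q <- random_orientations(sample(3:10, 1))
    odf <- build_odf(q, sym, hw)
    tg <- texture_index(odf, "grid")
    ts <- texture_index(odf, "series")
    tm <- texture_index(odf, "mc", n_mc = 2e5, seed = k)
    expect_equal(ts / tg, 1, tolerance = 0.02)
    expect_equal(tm / tg, 1, tolerance = 0.02)
  }
})

test_that("two well-separated sharp components halve the single-component TI", {
  sym <- crystal_symmetry()
  q2 <- rbind(c(1, 0, 0, 0), axis_angle_quat(c(1, 0, 0), 90))
  ti2 <- texture_index(build_odf(q2, sym, 4))
  ti1 <- texture_index(build_odf(matrix(c(1, 0, 0, 0), 1), sym, 4))
  expect_equal(ti2 / (ti1 / 2), 1, tolerance = 0.02)
})

test_that("TI is invariant under a global rotation of the specimen frame", {
  sym <- crystal_symmetry()
  q <- random_orientations(80, seed = 31)
  odf <- build_odf(q, sym, 6)
  r <- random_orientations(1, seed = 32)
  qr <- quat_multiply(q, r[rep(1, nrow(q)), ])
  odfr <- build_odf(qr, sym, 6)
  expect_equal(texture_index(odfr) / texture_index(odf), 1, tolerance = 0.01)
})

test_that("TI decreases monotonically with kernel halfwidth", {
  sym <- crystal_symmetry()
  q <- random_orientations(150, seed = 41)
  tis <- vapply(c(4, 10, 20), function(hw)
    texture_index(build_odf(q, sym, hw)), numeric(1))
  expect_true(all(diff(tis) < 0))
})

test_that("sharper synthetic textures rank higher in TI, pfJ and peak MUD", {
  sym <- crystal_symmetry()
  mk <- function(spread, seed) {
    base <- conotex:::orientation_from_c_axis(matrix(c(1, 0, 0), 1), 0)
    pert <- conotex:::random_perturbation(400, spread)
    with_seed_local(seed, quat_multiply(pert, base[rep(1, 400), ]))
  }
  set.seed(51)
  q_list <- lapply(c(25, 10, 4), function(s) mk(s, s))
  ti <- vapply(q_list, function(q) texture_index(build_odf(q, sym, 4)),
               numeric(1))
  pf <- vapply(q_list, function(q)
    pfj(pole_density(q, c(0, 0, 0, 1), sym)), numeric(1))
  mm <- vapply(q_list, function(q)
    max_mud(pole_density(q, c(0, 0, 0, 1), sym)), numeric(1))
  expect_true(all(diff(ti) > 0))
  expect_true(all(diff(pf) > 0))
  expect_true(all(diff(mm) > 0))
})

test_that("pole densities are normalized MUD: uniform limit, unit mass, identity peak", {
  sym <- crystal_symmetry()
  q <- random_orientations(5000, seed = 61)
  pd <- pole_density(q, c(0, 0, 0, 1), sym)
  expect_equal(mean(pd$mud), 1, tolerance = 0.01)        # total mass
  expect_equal(pfj(pd), 1, tolerance = 0.05)
  expect_gte(max_mud(pd), 1)

  # all orientations identity: the c-axis maps to specimen z
  qi <- matrix(rep(c(1, 0, 0, 0), 60), ncol = 4, byrow = TRUE)
  pdz <- pole_density(qi, c(0, 0, 0, 1), sym)
  peak_node <- pdz$nodes[which.max(pdz$mud), ]
  expect_gt(abs(peak_node[3]), 0.999)
  expect_equal(mean(pdz$mud), 1, tolerance = 0.01)
})

test_that("pfJ matches a Monte-Carlo spherical quadrature and is at least 1", {
  sym <- crystal_symmetry()
  base <- conotex:::orientation_from_c_axis(matrix(c(0, 0, 1), 1), 0)
  q <- quat_multiply(conotex:::random_perturbation(200, 6),
                     base[rep(1, 200), ])
  pd <- pole_density(q, c(0, 0, 0, 1), sym)
  # same density evaluated at random uniform sphere nodes instead of the
  # deterministic lattice
  set.seed(71)
  rnd <- matrix(rnorm(3 * 3e4), ncol = 3)
  rnd <- rnd / sqrt(rowSums(rnd^2))
  qc <- quat_conjugate(q)
  fam <- miller_family(c(0, 0, 0, 1), sym)
  dirs <- do.call(rbind, lapply(seq_len(nrow(fam)), function(j)
    conotex:::quat_rotate(qc, matrix(fam[j, ], nrow(q), 3, byrow = TRUE))))
  kap <- kernel_kappa(4)
  mud_rnd <- conotex:::sphere_density_cpp(rnd, dirs,
                                          rep(1 / nrow(dirs), nrow(dirs)),
                                          kap, kap + 1,
                                          conotex:::kernel_cutd2(kap))
  expect_equal(pfj(pd), mean(mud_rnd^2), tolerance = 0.02)

  pa <- pole_density(q, c(1, 1, -2, 0), sym)
  expect_gte(pfj(pa), 1 - 0.005)
  expect_gte(pfj(pd), 1 - 0.005)
})
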