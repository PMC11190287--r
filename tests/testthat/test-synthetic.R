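test_that("generated maps are pure functions of recipe and seed, with ground truth attached", {
  rec <- texture_recipe(c_dispersion = 6, a_model = a_clustered(),
                        unindexed_fraction = 0.3)
  m1 <- generate_map(rec, 40, 40, seed = 2)
  m2 <- generate_map(rec, 40, 40, seed = 2)
  expect_identical(m1$quat, m2$quat)
  expect_identical(m1$phase, m2$phase)
  tr <- attr(m1, "truth")
  expect_length(tr$patch_id, 40 * 40)
  expect_equal(nrow(tr$patches), nrow(tr$patch_orientation))

  # the masked fraction is hit exactly (up to rounding)
  expect_equal(indexed_fraction(m1), 1 - 0.3, tolerance = 1e-3)
})

test_that("a degenerate single-orientation recipe reproduces the single-kernel TI", {
  rec <- texture_recipe(c_dispersion = 0, a_model = a_dispersed(0),
                        patch_noise = 0, unindexed_fraction = 0)
  map <- generate_map(rec, 24, 24, seed = 3)
  # all pixels carry one orientation
  ti_map <- texture_index(build_odf(map))
  ti_one <- texture_index(build_odf(map$quat[1, , drop = FALSE],
                                    crystal_symmetry(), 4))
  expect_equal(ti_map / ti_one, 1, tolerance = 0.03)
})

test_that("a girdle recipe produces a ring in the a-axis pole figure", {
  # small patches so the girdle is sampled densely enough for a smooth ring
  rec <- texture_recipe(c_dispersion = 2, a_model = a_girdle(),
                        patch_length = 2, patch_width = 1,
                        patch_noise = 1, unindexed_fraction = 0)
  map <- generate_map(rec, 60, 60, seed = 4)
  pa <- pole_density(map, c(1, 1, -2, 0))
  # c along specimen X: the a-axes sweep the plane x = 0.  Evaluate the same
  # kernel density exactly on the girdle and well off it.
  q <- map_orientations(map)
  fam <- miller_family(c(1, 1, -2, 0))
  dirs <- do.call(rbind, lapply(seq_len(nrow(fam)), function(j)
    conotex:::quat_rotate(quat_conjugate(q),
                          matrix(fam[j, ], nrow(q), 3, byrow = TRUE))))
  kap <- kernel_kappa(4)
  eval_at <- function(nodes)
    conotex:::sphere_density_cpp(nodes, dirs,
                                 rep(1 / nrow(dirs), nrow(dirs)),
                                 kap, kap + 1, conotex:::kernel_cutd2(kap))
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  ring <- eval_at(cbind(0, cos(phi), sin(phi)))
  off <- eval_at(cbind(cos(phi) * 0.9,
                       sin(phi) * sqrt(1 - 0.81), 0))
  expect_gt(min(ring) / max(ring), 0.5)
  expect_lt(max(off), 0.5)
  # the lattice-based pole figure sees the same ring: its peak sits on it
  peak <- pa$nodes[which.max(pa$mud), ]
  expect_lt(abs(peak[1]), 0.15)
})

test_that("generated CTF files round-trip through the reader", {
  rec <- texture_recipe(unindexed_fraction = 0.25)
  map <- generate_map(rec, 20, 20, seed = 5)
  f <- tempfile(fileext = ".ctf")
  write_ctf(map, f)
  back <- read_ctf(f)
  expect_identical(back$phase, map$phase)
  idx <- map$phase > 0
  expect_lt(max(rot_angle_between(back$quat[idx, ], map$quat[idx, ])), 1e-6)
  unlink(f)
})

test_that("the taxon series enforces its monotone-control precondition", {
  sched <- default_taxon_schedule()
  expect_length(taxon_series(n_taxa = 2, seed = 1), 2)
  bad <- sched
  bad[[1]]$c_dispersion <- 1   # weakest taxon suddenly tightest
  expect_error(taxon_series(schedule = bad, seed = 1), "non-increasing")
  # reproducibility of the whole series
  s1 <- taxon_series(n_taxa = 3, seed = 9, width = 24, height = 24)
  s2 <- taxon_series(n_taxa = 3, seed = 9, width = 24, height = 24)
  expect_identical(lapply(s1, `[[`, "quat"), lapply(s2, `[[`, "quat"))
})

test_that("synthetic Raman spectra carry their stated band and noise level", {
  sp <- generate_raman(964.1, 5.0, 0.5, snr = Inf, n_points = 2000)
  base <- attr(sp, "truth")$baseline
  net <- sp$intensity - base[1] - base[2] * sp$wavenumber
  expect_equal(sp$wavenumber[which.max(net)], 964.1, tolerance = 0.05)
  # half-maximum crossings span the FWHM within the grid resolution
  above <- sp$wavenumber[net >= max(net) / 2]
  expect_equal(diff(range(above)), 5.0, tolerance = 2 * diff(sp$wavenumber[1:2]))
  # seeded noise is reproducible and at the right scale
  n1 <- generate_raman(964, 4.5, 0.5, snr = 50, seed = 6)
  n2 <- generate_raman(964, 4.5, 0.5, snr = 50, seed = 6)
  expect_identical(n1$intensity, n2$intensity)
  noise <- n1$intensity - generate_raman(964, 4.5, 0.5, snr = Inf)$intensity
  expect_equal(sd(noise), 1000 / 50, tolerance = 0.2)
})
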