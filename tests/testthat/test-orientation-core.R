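test_that("Euler round trip reproduces the same rotation, including gimbal cases", {
  set.seed(42)
  eu <- rbind(cbind(runif(50, 0, 360), runif(50, 0, 180), runif(50, 0, 360)),
              c(123.4, 0, 0),        # Phi = 0 (phi1/phi2 merge)
              c(10, 180, 250),       # Phi = 180
              c(0, 0, 0),
              c(359.99, 179.99, 0.01))
  q <- euler_to_quat(eu)
  expect_true(all(abs(quat_norm(q) - 1) < 1e-10))
  q2 <- euler_to_quat(quat_to_euler(q))
  expect_lt(max(rot_angle_between(q, q2)), 1e-8)
  # radians path
  q3 <- euler_to_quat(quat_to_euler(q, degrees = FALSE), degrees = FALSE)
  expect_lt(max(rot_angle_between(q, q3)), 1e-8)
})

test_that("the hexagonal symmetry group has 12 proper rotations, contains the identity and is closed", {
  sym <- crystal_symmetry()
  expect_equal(nrow(sym$rotations), 12)
  expect_true(any(abs(abs(sym$rotations %*% c(1, 0, 0, 0)) - 1) < 1e-12))
  expect_true(conotex:::sym_is_group(sym))
  expect_true(all(abs(quat_norm(sym$rotations) - 1) < 1e-12))
})

test_that("Miller-Bravais families expand to the right unit vectors", {
  sym <- crystal_symmetry()
  cax <- miller_family(c(0, 0, 0, 1), sym)
  expect_equal(nrow(cax), 2)              # +c and -c under the two-folds
  expect_true(all(abs(abs(cax[, 3]) - 1) < 1e-9))
  aax <- miller_family(c(1, 1, -2, 0), sym)
  expect_equal(nrow(aax), 6)
  expect_true(all(abs(aax[, 3]) < 1e-9))  # basal plane
  expect_true(all(abs(sqrt(rowSums(aax^2)) - 1) < 1e-9))
  m10 <- miller_family(c(1, 0, -1, 0), sym)
  expect_equal(nrow(m10), 6)
  # <10-10> bisects neighboring <11-20> directions: 30 degrees apart
  ang <- acos(pmin(1, abs(aax %*% m10[1, ]))) * 180 / pi
  expect_equal(min(ang), 30, tolerance = 1e-6)
  expect_error(miller_family(c(1, 1, 1, 0), sym), "u \\+ v \\+ t")
})

test_that("misorientation angle: identity, c-axis rotation folding and unit-norm guard", {
  sym <- crystal_symmetry()
  id <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(misorientation_angle(id, id, sym), 0)
  q70 <- axis_angle_quat(c(0, 0, 1), 70)
  expect_equal(misorientation_angle(id, q70, sym), 10, tolerance = 1e-9)
  expect_error(misorientation_angle(id, 2 * q70, sym), "non-unit")
})

test_that("misorientation agrees with the exhaustive 12x12 brute-force oracle", {
  sym <- crystal_symmetry()
  q1 <- random_orientations(300, seed = 1)
  q2 <- random_orientations(300, seed = 2)
  fast <- misorientation_angle(q1, q2, sym)
  slow <- vapply(seq_len(300), function(i)
    brute_misorientation(q1[i, , drop = FALSE], q2[i, , drop = FALSE], sym),
    numeric(1))
  expect_lt(max(abs(fast - slow)), 1e-9)
})

test_that("misorientation is symmetric, vanishes only on symmetry equivalents, and obeys the triangle bound", {
  sym <- crystal_symmetry()
  q1 <- random_orientations(200, seed = 3)
  q2 <- random_orientations(200, seed = 4)
  expect_equal(misorientation_angle(q1, q2, sym),
               misorientation_angle(q2, q1, sym), tolerance = 1e-9)
  # zero iff symmetry-equivalent
  s <- sym$rotations[sample.int(12, 200, replace = TRUE), ]
  equiv <- quat_multiply(s, q1)
  expect_lt(max(misorientation_angle(q1, equiv, sym)), 1e-8)
  expect_gt(min(misorientation_angle(q1, q2, sym)), 1e-8)  # a.s. distinct
  # triangle-style bound on random triples
  q3 <- random_orientations(200, seed = 5)
  a13 <- misorientation_angle(q1, q3, sym)
  a12 <- misorientation_angle(q1, q2, sym)
  a23 <- misorientation_angle(q2, q3, sym)
  expect_true(all(a13 <= a12 + a23 + 1e-9))
})

test_that("the maximum hexagonal misorientation approaches 93.84 degrees", {
  sym <- crystal_symmetry()
  q1 <- random_orientations(2e5, seed = 6)
  q2 <- random_orientations(2e5, seed = 7)
  ang <- misorientation_angle(q1, q2, sym)
  expect_lt(max(ang), 93.85)
  expect_gt(max(ang), 93.0)   # the supremum is approached
})

test_that("fundamental-zone projection picks the minimal-angle representative and is idempotent", {
  sym <- crystal_symmetry()
  id <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(fz_project(id, sym), id)
  q70 <- axis_angle_quat(c(0, 0, 1), 70)
  expect_equal(quat_angle(fz_project(q70, sym)), 10, tolerance = 1e-9)
  q <- random_orientations(100, seed = 8)
  p1 <- fz_project(q, sym)
  expect_equal(fz_project(p1, sym), p1, tolerance = 1e-12)
  # projection never changes the orientation class
  expect_lt(max(misorientation_angle(q, p1, sym)), 1e-8)
  # representative angle equals the misorientation from the identity
  idm <- matrix(c(1, 0, 0, 0), 100, 4, byrow = TRUE)
  expect_equal(quat_angle(p1), misorientation_angle(q, idm, sym),
               tolerance = 1e-6)
})

test_that("random orientations are Haar-uniform and reproducible", {
  q <- random_orientations(1e5, seed = 9)
  expect_identical(q, random_orientations(1e5, seed = 9))
  expect_true(all(abs(quat_norm(q) - 1) < 1e-10))
  # rotation-angle law: F(w) = (w - sin w) / pi
  ang <- sort(quat_angle(q)) * pi / 180
  ks <- max(abs(seq_along(ang) / length(ang) - (ang - sin(ang)) / pi))
  expect_lt(ks, 0.01)
})
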