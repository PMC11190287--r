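# Quaternion arithmetic on n x 4 matrices (scalar first).  These are the
# vectorized R counterparts of the compiled kernels; they also serve as
# independent oracles in the test suite.

as_quat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  storage.mode(q) <- "double"
  if (ncol(q) != 4) stop("quaternions must have 4 columns (w, x, y, z)")
  q
}

quat_norm <- function(q) sqrt(rowSums(as_quat(q)^2))

check_unit_quat <- function(q, tol = 1e-6) {
  q <- as_quat(q)
  nn <- quat_norm(q)
  if (any(abs(nn - 1) > tol))
    stop("non-unit quaternion input (norm deviates from 1 by more than ",
         format(tol), ")")
  q / nn
}

#' Quaternion product
#'
#' Componentwise Hamilton product of two sets of rotation quaternions
#' (scalar-first rows).  Rows are recycled if one input has a single row.
#'
#' @param a,b numeric matrices with 4 columns (or length-4 vectors).
#' @return a matrix of products with 4 columns.
#' @export
quat_multiply <- function(a, b) {
  a <- as_quat(a); b <- as_quat(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) {
  a <- as_quat(a)
  cbind(a[, 1], -a[, 2], -a[, 3], -a[, 4])
}

# canonical representative of {q, -q}: scalar part >= 0 (first non-zero
# component positive when w == 0)
quat_canonical <- function(q) {
  q <- as_quat(q)
  sgn <- sign(q[, 1])
  zero <- sgn == 0
  if (any(zero)) {
    for (j in 2:4) {
      s2 <- sign(q[, j])
      sgn[zero & sgn == 0] <- s2[zero & sgn == 0]
    }
    sgn[sgn == 0] <- 1
  }
  q * sgn
}

#' Rotation angle of a quaternion
#'
#' @param q quaternion matrix.
#' @return rotation angles in degrees, in `[0, 180]`.
#' @export
quat_angle <- function(q) {
  q <- as_quat(q)
  2 * acos(pmin(1, abs(q[, 1]))) * 180 / pi
}

# apply the rotation q to the rows of v (n x 3); q recycled as needed
quat_rotate <- function(q, v) {
  q <- as_quat(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1) q <- q[rep(1, n), , drop = FALSE]
  if (nrow(v) == 1) v <- v[rep(1, n), , drop = FALSE]
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # v' = v + 2 q_vec x (q_vec x v + w v)
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + (y * tz - z * ty),
        vy + w * ty + (z * tx - x * tz),
        vz + w * tz + (x * ty - y * tx))
}

#' Axis-angle rotation quaternion
#'
#' @param axis rotation axis (length-3 vector or n x 3 matrix), need not be
#'   normalized.
#' @param angle rotation angle(s) in degrees.
#' @return quaternion matrix.
#' @export
axis_angle_quat <- function(axis, angle) {
  if (is.null(dim(axis))) axis <- matrix(axis, ncol = 3)
  n <- max(nrow(axis), length(angle))
  if (nrow(axis) == 1) axis <- axis[rep(1, n), , drop = FALSE]
  angle <- rep_len(angle, n) * pi / 180
  axis <- axis / sqrt(rowSums(axis^2))
  cbind(cos(angle / 2), axis * sin(angle / 2))
}

#' Convert Bunge Euler angles to quaternions
#'
#' Z-X-Z intrinsic convention (phi1 about Z, Phi about the rotated X, phi2
#' about the rotated Z), the convention of the CTF and ANG vendor formats.
#'
#' @param phi1,Phi,phi2 Euler angles; a three-column matrix may be passed as
#'   `phi1` instead.
#' @param degrees logical; angles in degrees (default) or radians.
#' @return quaternion matrix (scalar first).
#' @export
euler_to_quat <- function(phi1, Phi = NULL, phi2 = NULL, degrees = TRUE) {
  if (is.null(Phi)) {
    m <- as.matrix(phi1)
    phi1 <- m[, 1]; Phi <- m[, 2]; phi2 <- m[, 3]
  }
  if (degrees) {
    phi1 <- phi1 * pi / 180; Phi <- Phi * pi / 180; phi2 <- phi2 * pi / 180
  }
  cp <- cos(Phi / 2); sp <- sin(Phi / 2)
  sum2 <- (phi1 + phi2) / 2; dif2 <- (phi1 - phi2) / 2
  quat_canonical(cbind(cp * cos(sum2), sp * cos(dif2),
                       sp * sin(dif2), cp * sin(sum2)))
}

#' Convert quaternions to Bunge Euler angles
#'
#' Inverse of [euler_to_quat()]; in the degenerate (gimbal) cases `Phi = 0`
#' or `Phi = 180` the convention `phi2 = 0` is used.
#'
#' @param q quaternion matrix.
#' @param degrees logical; return degrees (default) or radians.
#' @return matrix with columns `phi1`, `Phi`, `phi2`.
#' @export
quat_to_euler <- function(q, degrees = TRUE) {
  q <- as_quat(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  r03 <- sqrt(w^2 + z^2)
  r12 <- sqrt(x^2 + y^2)
  Phi <- 2 * atan2(r12, r03)
  sum2 <- atan2(z, w)     # (phi1 + phi2)/2
  dif2 <- atan2(y, x)     # (phi1 - phi2)/2
  phi1 <- sum2 + dif2
  phi2 <- sum2 - dif2
  # gimbal cases: the two z-rotations merge; put everything into phi1
  top <- r12 < 1e-9
  if (any(top)) {
    phi1[top] <- 2 * atan2(z[top], w[top]); phi2[top] <- 0
  }
  bot <- r03 < 1e-9
  if (any(bot)) {
    phi1[bot] <- 2 * atan2(y[bot], x[bot]); phi2[bot] <- 0
  }
  out <- cbind(phi1 %% (2 * pi), Phi, phi2 %% (2 * pi))
  colnames(out) <- c("phi1", "Phi", "phi2")
  if (degrees) out * 180 / pi else out
}

#' Uniformly random orientations
#'
#' Draws orientations from the Haar (uniform) measure on the rotation space
#' by normalizing standard 4-d Gaussian vectors.
#'
#' @param n number of orientations.
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG stream is left untouched.
#' @return an `n x 4` quaternion matrix.
#' @export
random_orientations <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    q <- matrix(rnorm(4 * n), ncol = 4)
    quat_canonical(q / sqrt(rowSums(q^2)))
  })
}
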