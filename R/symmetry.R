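# Crystal symmetry groups as sets of proper rotation quaternions, plus
# Miller-Bravais direction families for hexagonal lattices.

#' Crystal symmetry
#'
#' Builds a proper-rotation symmetry group for use in misorientation and
#' texture computations.  The default is the hexagonal Laue class of apatite,
#' represented by the 12 proper rotations of point group 622: improper
#' operations are omitted because diffraction cannot distinguish
#' inversion-related orientations.
#'
#' @param name `"622"` (hexagonal, default) or `"1"` (triclinic / no
#'   symmetry).
#' @param a,c lattice parameters in Angstrom.  Defaults are fluorapatite
#'   (a = 9.37, c = 6.88); override them when a refinement provides other
#'   values.
#' @return an object of class `crystal_symmetry` with elements `name`,
#'   `rotations` (an m x 4 quaternion matrix), `a` and `c`.
#' @examples
#' sym <- crystal_symmetry()
#' nrow(sym$rotations)  # 12
#' @export
crystal_symmetry <- function(name = "622", a = 9.37, c = 6.88) {
  rot <- switch(name,
    "622" = {
      kz <- 0:5 * 60
      sixfold <- axis_angle_quat(c(0, 0, 1), kz)
      ka <- 0:5 * 30
      twofold <- cbind(0, cos(ka * pi / 180), sin(ka * pi / 180), 0)
      rbind(sixfold, twofold)
    },
    "1" = matrix(c(1, 0, 0, 0), nrow = 1),
    stop("unsupported symmetry group: ", name)
  )
  structure(list(name = name, rotations = quat_canonical(rot), a = a, c = c),
            class = "crystal_symmetry")
}

#' @export
print.crystal_symmetry <- function(x, ...) {
  cat("<crystal_symmetry>", x$name, "-", nrow(x$rotations),
      "proper rotations; a =", x$a, "A, c =", x$c, "A\n")
  invisible(x)
}

sym_rotations <- function(sym) {
  if (!inherits(sym, "crystal_symmetry")) stop("`sym` must be a crystal_symmetry")
  sym$rotations
}

# group-closure check used by the test suite: every pairwise product must be
# (up to sign) a member of the group
sym_is_group <- function(sym, tol = 1e-9) {
  r <- sym_rotations(sym)
  m <- nrow(r)
  for (i in seq_len(m)) {
    prod <- quat_canonical(quat_multiply(r[rep(i, m), , drop = FALSE], r))
    d <- abs(tcrossprod(prod, r))  # |<p, r_k>| = 1 iff same rotation
    if (any(apply(d, 1, max) < 1 - tol)) return(FALSE)
  }
  TRUE
}

#' Symmetry-equivalent direction family
#'
#' Expands a four-index Miller-Bravais direction `[u v t w]` into the set of
#' symmetry-equivalent unit vectors in the Cartesian crystal frame
#' (a1 along x, c along z), using the lattice parameters stored in `sym`.
#'
#' @param indices integer vector of length 4, e.g. `c(0, 0, 0, 1)` for the
#'   c-axis `<0001>` or `c(1, 1, -2, 0)` for the a-axes `<11-20>`.
#' @param sym a [crystal_symmetry()].
#' @return a k x 3 matrix of unit vectors with attribute `indices`.
#' @export
miller_family <- function(indices, sym = crystal_symmetry()) {
  stopifnot(length(indices) == 4)
  u <- indices[1]; v <- indices[2]; t <- indices[3]; w <- indices[4]
  if (abs(u + v + t) > 1e-9) stop("Miller-Bravais indices need u + v + t = 0")
  cart <- c(sym$a * (u - v / 2 - t / 2),
            sym$a * sqrt(3) / 2 * (v - t),
            sym$c * w)
  nn <- sqrt(sum(cart^2))
  if (nn == 0) stop("zero direction")
  cart <- cart / nn
  rots <- sym_rotations(sym)
  vecs <- quat_rotate(rots, matrix(cart, nrow = nrow(rots), ncol = 3,
                                   byrow = TRUE))
  vecs <- unique(round(vecs, 9))
  vecs <- vecs / sqrt(rowSums(vecs^2))
  structure(vecs, indices = indices)
}
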