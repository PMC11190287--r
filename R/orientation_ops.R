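# Symmetry-reduced misorientation and fundamental-zone projection.

#' Misorientation angle under crystal symmetry
#'
#' The smallest rotation angle relating two orientations after applying the
#' crystal symmetry group on both sides, i.e.
#' `min over s1, s2 of angle(s1 o1^-1 o2 s2)`.  By conjugation invariance of
#' the rotation angle this equals a single-sided minimum over the group,
#' which is what is evaluated.  Vectorized over rows; single rows recycle.
#'
#' @param q1,q2 orientation quaternion matrices (rows paired).
#' @param sym a [crystal_symmetry()].
#' @return misorientation angles in degrees.  For the hexagonal Laue class
#'   the maximum attainable value is about 93.84 degrees.
#' @export
misorientation_angle <- function(q1, q2, sym = crystal_symmetry()) {
  q1 <- check_unit_quat(q1); q2 <- check_unit_quat(q2)
  if (nrow(q1) == 1 && nrow(q2) > 1) q1 <- q1[rep(1, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1 && nrow(q1) > 1) q2 <- q2[rep(1, nrow(q1)), , drop = FALSE]
  misori_angles_cpp(q1, q2, sym_rotations(sym))
}

#' Project orientations into the fundamental zone
#'
#' Returns, for each orientation, the symmetry-equivalent representative with
#' the smallest rotation angle (disorientation representative).  The
#' operation is idempotent.
#'
#' @inheritParams misorientation_angle
#' @param q orientation quaternion matrix.
#' @return quaternion matrix of the same shape.
#' @export
fz_project <- function(q, sym = crystal_symmetry()) {
  q <- check_unit_quat(q)
  fz_project_cpp(q, sym_rotations(sym))
}
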