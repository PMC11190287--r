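# Uncorrelated misorientation-angle distributions, the random (Mackenzie-
# type) reference for a crystal symmetry, and the M-index.
#
# "Uncorrelated" pairs are drawn from pixels, not reconstructed grains: the
# texture maps this package targets are analyzed without grain
# reconstruction.  The random reference is estimated once per symmetry by
# seeded Monte Carlo and cached, one implementation path for any symmetry.

# maximum disorientation angle of the hexagonal Laue class, degrees
HEX_THETA_MAX <- 93.84

mis_hist_edges <- function(bin_width) seq(0, 180, by = bin_width)

new_mis_hist <- function(angles, bin_width, kind, n_pairs) {
  edges <- mis_hist_edges(bin_width)
  h <- hist(angles, breaks = edges, plot = FALSE)
  structure(list(bin_edges = edges, density = h$counts / length(angles),
                 n_pairs = n_pairs, bin_width = bin_width, kind = kind),
            class = "misorientation_hist")
}

#' @importFrom graphics hist
NULL

#' Uncorrelated misorientation-angle histogram
#'
#' Draws `n_pairs` random distinct index pairs from a set of orientations,
#' computes their symmetry-reduced misorientation angles and bins them.
#'
#' @param q orientation quaternions or an [ebsd_map()].
#' @param sym a [crystal_symmetry()].
#' @param n_pairs number of random pairs (capped for tractability; the
#'   default follows the misorientation literature).
#' @param bin_width histogram bin width in degrees (1 degree convention).
#' @param seed optional seed.
#' @return a `misorientation_hist`: bin edges, per-bin probability mass
#'   (summing to 1), pair count and kind.
#' @export
misorientation_hist <- function(q, sym = crystal_symmetry(), n_pairs = 1e5,
                                bin_width = 1, seed = NULL) {
  if (inherits(q, "ebsd_map")) q <- map_orientations(q)
  q <- check_unit_quat(q)
  n <- nrow(q)
  if (n < 2) stop("at least two orientations are required")
  with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)   # distinct pairs, uniform
    ang <- misori_angles_cpp(q[i, , drop = FALSE], q[j, , drop = FALSE],
                             sym_rotations(sym))
    new_mis_hist(ang, bin_width, "observed-uncorrelated", n_pairs)
  })
}

#' Random-pair (Mackenzie-type) misorientation reference
#'
#' The misorientation-angle distribution of two independent uniformly random
#' orientations under the crystal symmetry, estimated by seeded Monte Carlo
#' and cached per symmetry and binning.  For the hexagonal Laue class the
#' support ends near 93.84 degrees.
#'
#' @param sym a [crystal_symmetry()].
#' @param bin_width bin width in degrees.
#' @param n_mc Monte-Carlo sample size.
#' @param seed seed of the cached estimate.
#' @return a `misorientation_hist` of kind `"theoretical-random"`.
#' @export
mackenzie_reference <- function(sym = crystal_symmetry(), bin_width = 1,
                                n_mc = 1e6, seed = 1) {
  key <- sprintf("mack_%s_%g_%g_%d", sym$name, bin_width, n_mc, seed)
  hit <- .conotex_cache[[key]]
  if (!is.null(hit)) return(hit)
  # the misorientation of two Haar orientations equals one Haar orientation
  # against the identity
  q <- random_orientations(n_mc, seed = seed)
  idq <- matrix(c(1, 0, 0, 0), n_mc, 4, byrow = TRUE)
  ang <- misori_angles_cpp(q, idq, sym_rotations(sym))
  out <- new_mis_hist(ang, bin_width, "theoretical-random", n_mc)
  .conotex_cache[[key]] <- out
  out
}

#' M-index
#'
#' Half the integrated absolute difference between the observed uncorrelated
#' misorientation-angle distribution and the random reference (the discrete
#' total-variation form): 0 for a random texture, approaching 1 for a single
#' crystal.
#'
#' @param observed,reference `misorientation_hist` objects with identical
#'   binning.
#' @return the M-index, in `[0, 1]`.
#' @export
m_index <- function(observed, reference) {
  if (!identical(observed$bin_edges, reference$bin_edges))
    stop("binning mismatch between observed and reference histograms")
  0.5 * sum(abs(reference$density - observed$density))
}
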