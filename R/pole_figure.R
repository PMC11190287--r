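# Pole-figure densities in multiples of uniform density (MUD) and the
# pole-figure texture index pfJ.
#
# The pole density of a crystal-direction family is the spherical kernel
# density of all symmetry-equivalent specimen-frame directions, antipodally
# symmetrized (diffraction cannot sign a direction) and normalized so that a
# uniform distribution evaluates to 1 everywhere.  Only crystal symmetry is
# applied; specimen symmetry is triclinic (none), so pole figures may be
# asymmetric.

# near-equal-area spherical quadrature lattice
sphere_grid <- function(n = 10000) {
  key <- sprintf("s2_%d", n)
  hit <- .conotex_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- fibonacci_sphere(n)
  .conotex_cache[[key]] <- g
  g
}

#' Pole-figure density (MUD)
#'
#' @param q orientation quaternions (or an [ebsd_map()]).
#' @param family a Miller-Bravais index vector (length 4) or a matrix of
#'   crystal-frame unit vectors from [miller_family()].
#' @param sym a [crystal_symmetry()].
#' @param halfwidth spherical kernel halfwidth in degrees (half width at
#'   half maximum), default 4 as for the ODF kernel.
#' @param grid_n number of quadrature nodes on the sphere (default 10000,
#'   about 2 degree spacing).
#' @return an object of class `pole_density` holding the nodes and the MUD
#'   value at each node.
#' @export
pole_density <- function(q, family = c(0, 0, 0, 1), sym = crystal_symmetry(),
                         halfwidth = 4, grid_n = 10000) {
  if (inherits(q, "ebsd_map")) q <- map_orientations(q)
  q <- check_unit_quat(q)
  if (is.null(dim(family))) family <- miller_family(family, sym)
  k <- nrow(family)
  qc <- quat_conjugate(q)   # orientations map specimen -> crystal (Bunge)
  dirs <- do.call(rbind, lapply(seq_len(k), function(j) {
    quat_rotate(qc, matrix(family[j, ], nrow(q), 3, byrow = TRUE))
  }))
  wts <- rep(1 / nrow(dirs), nrow(dirs))
  kappa <- kernel_kappa(halfwidth)
  nodes <- sphere_grid(grid_n)
  mud <- sphere_density_cpp(nodes, dirs, wts, kappa, kappa + 1,
                            kernel_cutd2(kappa))
  structure(list(nodes = nodes, mud = mud, family = family,
                 halfwidth = halfwidth, n_orientations = nrow(q)),
            class = "pole_density")
}

#' @export
print.pole_density <- function(x, ...) {
  cat(sprintf("<pole_density> %d nodes, %d poles, max MUD %.2f\n",
              nrow(x$nodes), nrow(x$family) * x$n_orientations, max(x$mud)))
  invisible(x)
}

#' Pole-figure texture index
#'
#' The surface integral of the squared MUD over the sphere with normalized
#' measure, the pole-figure analogue of the Texture Index: 1 for a uniform
#' distribution, larger for sharper pole figures; by the Cauchy-Schwarz
#' inequality it can never fall below 1 (up to quadrature slack).
#'
#' @param pd a [pole_density()] object.
#' @return pfJ (dimensionless).
#' @export
pfj <- function(pd) {
  stopifnot(inherits(pd, "pole_density"))
  mean(pd$mud^2)
}

#' Peak MUD of a pole density
#' @param pd a [pole_density()] object.
#' @export
max_mud <- function(pd) max(pd$mud)

#' Upper-hemisphere stereographic table of a pole density
#'
#' @param x a [pole_density()] object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with azimuth and polar angle (degrees),
#'   equal-angle stereographic coordinates (sx, sy) and MUD, restricted to
#'   the upper hemisphere.
#' @export
as.data.frame.pole_density <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  up <- x$nodes[, 3] >= 0
  v <- x$nodes[up, , drop = FALSE]
  pol <- acos(pmin(1, v[, 3]))
  az <- atan2(v[, 2], v[, 1])
  r <- tan(pol / 2)
  data.frame(azimuth = az * 180 / pi, polar = pol * 180 / pi,
             sx = r * cos(az), sy = r * sin(az), mud = x$mud[up])
}

#' Plot a pole figure
#'
#' Upper-hemisphere equal-angle stereographic projection, points colored by
#' MUD.
#'
#' @param x a [pole_density()] object.
#' @param ... passed to [graphics::plot()].
#' @export
#' @importFrom graphics points symbols
#' @importFrom grDevices hcl.colors
plot.pole_density <- function(x, ...) {
  df <- as.data.frame(x)
  pal <- grDevices::hcl.colors(64, "Inferno")
  col <- pal[cut(df$mud, breaks = 64, labels = FALSE)]
  plot(df$sx, df$sy, col = col, pch = 16, cex = 0.5, asp = 1,
       xlab = "", ylab = "", axes = FALSE,
       main = sprintf("max MUD %.1f", max(x$mud)), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  invisible(x)
}

#' @importFrom graphics lines
NULL

#' Scalar texture summary of a set of orientations
#'
#' Computes the Texture Index, the M-index, the pole-figure texture indices
#' of the c-axis `<0001>` and a-axis `<11-20>` families, and the peak MUD,
#' for one region.
#'
#' @param q orientation quaternions or an [ebsd_map()].
#' @param sym a [crystal_symmetry()].
#' @param halfwidth kernel halfwidth in degrees.
#' @param area_um2 optional region area to record.
#' @param n_pairs number of uncorrelated pairs for the M-index.
#' @param seed optional seed (M-index pair sampling).
#' @param metrics character vector choosing which indices to compute
#'   (subset of `"ti"`, `"m_index"`, `"pfj"`).
#' @return a one-row data frame with columns `n`, `area_um2`, `ti`,
#'   `m_index`, `pfj_c`, `pfj_a`, `max_mud`.
#' @export
texture_summary <- function(q, sym = crystal_symmetry(), halfwidth = 4,
                            area_um2 = NA_real_, n_pairs = 2e4, seed = NULL,
                            metrics = c("ti", "m_index", "pfj")) {
  if (inherits(q, "ebsd_map")) {
    if (is.na(area_um2)) area_um2 <- map_area(q)
    q <- map_orientations(q)
  }
  q <- check_unit_quat(q)
  out <- data.frame(n = nrow(q), area_um2 = area_um2, ti = NA_real_,
                    m_index = NA_real_, pfj_c = NA_real_, pfj_a = NA_real_,
                    max_mud = NA_real_)
  if ("ti" %in% metrics)
    out$ti <- texture_index(build_odf(q, sym, halfwidth))
  if ("m_index" %in% metrics) {
    obs <- misorientation_hist(q, sym, n_pairs = n_pairs, seed = seed)
    out$m_index <- m_index(obs, mackenzie_reference(sym))
  }
  if ("pfj" %in% metrics) {
    pc <- pole_density(q, c(0, 0, 0, 1), sym, halfwidth)
    pa <- pole_density(q, c(1, 1, -2, 0), sym, halfwidth)
    out$pfj_c <- pfj(pc)
    out$pfj_a <- pfj(pa)
    out$max_mud <- max(max_mud(pc), max_mud(pa))
  }
  out
}
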