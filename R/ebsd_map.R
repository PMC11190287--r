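# The EBSDMap container: a regular square-grid raster of orientations with a
# phase id per pixel (0 = non-indexed), band contrast, step size and the
# specimen frame.  Pixels are stored in file order: x fastest (left to
# right), then y (top to bottom); index = (y - 1) * width + x.

default_frame <- c(
  X = "denticle long axis (occlusal direction)",
  Y = "map north",
  Z = "into the viewing plane"
)

#' Construct an EBSD map
#'
#' @param width,height raster size in pixels.
#' @param step pixel size in micrometres.
#' @param quat per-pixel orientation quaternions (`width*height x 4`); rows of
#'   non-indexed pixels may be `NA`.
#' @param phase integer phase id per pixel; 0 marks non-indexed pixels.
#' @param band_contrast numeric per-pixel band contrast (image quality).
#' @param phases data frame describing the phases (`id`, `name`, `a`, `c`).
#' @param frame named character vector documenting the specimen axes.  The
#'   frame is metadata: analyses that need specimen directions receive it,
#'   the raster itself is never remapped.
#' @return an object of class `ebsd_map`.
#' @export
ebsd_map <- function(width, height, step = 1, quat = NULL,
                     phase = integer(width * height), band_contrast = NULL,
                     phases = data.frame(id = 1L, name = "Apatite",
                                         a = 9.37, c = 6.88),
                     frame = default_frame) {
  n <- width * height
  if (is.null(quat)) quat <- matrix(NA_real_, n, 4)
  quat <- as_quat(quat)
  stopifnot(nrow(quat) == n, length(phase) == n)
  if (is.null(band_contrast)) band_contrast <- rep(NA_real_, n)
  phase <- as.integer(phase)
  if (any(phase > 0 & !is.finite(quat[, 1])))
    stop("every indexed pixel must carry a valid orientation")
  structure(list(width = as.integer(width), height = as.integer(height),
                 step = step, quat = quat, phase = phase,
                 band_contrast = band_contrast, phases = phases,
                 frame = frame),
            class = "ebsd_map")
}

#' @export
print.ebsd_map <- function(x, ...) {
  cat(sprintf("<ebsd_map> %d x %d px, step %g um, indexed %.1f%% (%d phase%s)\n",
              x$width, x$height, x$step, 100 * indexed_fraction(x),
              nrow(x$phases), if (nrow(x$phases) == 1) "" else "s"))
  invisible(x)
}

#' Fraction of indexed pixels
#' @param map an [ebsd_map()].
#' @return a number in `[0, 1]`.
#' @export
indexed_fraction <- function(map) mean(map$phase > 0)

#' Orientations of the indexed pixels
#' @param map an [ebsd_map()].
#' @return quaternion matrix with one row per indexed pixel (raster order).
#' @export
map_orientations <- function(map) map$quat[map$phase > 0, , drop = FALSE]

#' Map area in square micrometres
#' @param map an [ebsd_map()].
#' @export
map_area <- function(map) map$width * map$height * map$step^2

#' Crop an EBSD map
#'
#' Extracts the `w x h` pixel rectangle with top-left corner `(x0, y0)`
#' (1-based).  No resampling, filtering or smoothing is applied; step size
#' and frame are preserved.
#'
#' @param map an [ebsd_map()].
#' @param x0,y0 top-left pixel of the rectangle (1-based).
#' @param w,h rectangle size in pixels.
#' @export
crop_map <- function(map, x0, y0, w, h) {
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > map$width || y0 + h - 1 > map$height)
    stop("crop rectangle out of bounds")
  xs <- x0:(x0 + w - 1)
  ys <- y0:(y0 + h - 1)
  idx <- as.vector(outer(xs, (ys - 1) * map$width, `+`))
  ebsd_map(w, h, step = map$step, quat = map$quat[idx, , drop = FALSE],
           phase = map$phase[idx], band_contrast = map$band_contrast[idx],
           phases = map$phases, frame = map$frame)
}

#' Merge one phase into another
#'
#' Reassigns all pixels of phase `from_id` to phase `to_id`, leaving
#' orientations untouched.  Used e.g. to fold a hydroxyapatite admixture into
#' the apatite phase before texture analysis.  Both phases must share the
#' hexagonal lattice (compatible symmetry); merging an absent phase is the
#' identity.
#'
#' @param map an [ebsd_map()].
#' @param from_id,to_id integer phase ids.
#' @export
merge_phases <- function(map, from_id, to_id) {
  ph <- map$phases
  if (!to_id %in% ph$id) stop("unknown target phase id: ", to_id)
  if (from_id %in% ph$id) {
    pf <- ph[ph$id == from_id, ]
    pt <- ph[ph$id == to_id, ]
    if (abs(pf$a - pt$a) / pt$a > 0.05 || abs(pf$c - pt$c) / pt$c > 0.05)
      stop("phases ", from_id, " and ", to_id,
           " have incompatible lattices; refusing to merge")
  }
  map$phase[map$phase == from_id] <- as.integer(to_id)
  map$phases <- ph[ph$id != from_id, , drop = FALSE]
  map
}

#' Per-pixel table of an EBSD map
#'
#' @param x an [ebsd_map()].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with x, y (pixels), phase, Euler angles (degrees) and
#'   band contrast; Euler angles are `NA` for non-indexed pixels.
#' @export
as.data.frame.ebsd_map <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- x$width * x$height
  eu <- matrix(NA_real_, n, 3)
  idx <- x$phase > 0
  if (any(idx)) eu[idx, ] <- quat_to_euler(x$quat[idx, , drop = FALSE])
  data.frame(x = rep(seq_len(x$width), x$height),
             y = rep(seq_len(x$height), each = x$width),
             phase = x$phase,
             phi1 = eu[, 1], Phi = eu[, 2], phi2 = eu[, 3],
             band_contrast = x$band_contrast)
}
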