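# EDAX/TSL ANG reader and writer (square grids only).  ANG numbers phases
# from 0 in single-phase files and flags non-indexed points with a negative
# confidence index; internally phases are shifted to start at 1 so that 0
# can keep its meaning of "non-indexed".

#' Read an EDAX/TSL ANG file
#'
#' Header lines start with `#`; data rows are
#' `phi1 PHI phi2 x y IQ CI phase ...` with Euler angles in radians (Bunge).
#' Only square grids are supported: a `# GRID: HexGrid` header raises an
#' error.  Rows with a negative confidence index are treated as non-indexed.
#'
#' @param path path to a `.ang` file.
#' @return an [ebsd_map()].
#' @export
read_ang <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  header <- lines[is_hdr]

  grid_ln <- grep("GRID:", header, value = TRUE)
  if (length(grid_ln) && grepl("Hex", grid_ln[1], ignore.case = TRUE))
    stop("unsupported grid: hexagonal ANG grids are not supported, ",
         "only SqrGrid")
  get_key <- function(key) {
    ln <- grep(paste0(key, ":"), header, value = TRUE)
    if (!length(ln)) stop("ANG format error: missing header key '", key, "'")
    as.numeric(sub(paste0(".*", key, ":\\s*"), "", ln[1]))
  }
  xstep <- get_key("XSTEP")
  ncols <- as.integer(get_key("NCOLS_ODD"))
  nrows <- as.integer(get_key("NROWS"))

  mat_ln <- grep("MaterialName", header, value = TRUE)
  name <- if (length(mat_ln)) trimws(sub(".*MaterialName\\s*", "", mat_ln[1]))
          else "Apatite"
  lat_ln <- grep("LatticeConstants", header, value = TRUE)
  a <- 9.37; cc <- 6.88
  if (length(lat_ln)) {
    lat <- as.numeric(strsplit(trimws(
      sub(".*LatticeConstants\\s*", "", lat_ln[1])), "\\s+")[[1]])
    if (length(lat) >= 3 && all(is.finite(lat[1:3]))) {
      a <- lat[1]; cc <- lat[3]
    }
  }

  dat <- utils::read.table(text = lines[!is_hdr], header = FALSE)
  if (nrow(dat) != ncols * nrows)
    stop(sprintf("ANG truncation error: %d data rows but NCOLS x NROWS = %d",
                 nrow(dat), ncols * nrows))
  colnames(dat)[1:8] <- c("phi1", "PHI", "phi2", "x", "y", "iq", "ci", "phase")
  dat <- dat[order(dat$y, dat$x), ]

  indexed <- dat$ci >= 0
  phase <- ifelse(indexed, as.integer(dat$phase) + 1L, 0L)
  quat <- matrix(NA_real_, nrow(dat), 4)
  if (any(indexed))
    quat[indexed, ] <- euler_to_quat(dat$phi1[indexed], dat$PHI[indexed],
                                     dat$phi2[indexed], degrees = FALSE)
  ebsd_map(ncols, nrows, step = xstep, quat = quat, phase = phase,
           band_contrast = dat$iq,
           phases = data.frame(id = 1L, name = name, a = a, c = cc))
}

#' Write an EBSD map as an ANG file
#'
#' Inverse of [read_ang()]; Euler angles are written in radians and
#' non-indexed pixels get a confidence index of -1.
#'
#' @param map an [ebsd_map()].
#' @param path output path.
#' @export
write_ang <- function(map, path) {
  p1 <- map$phases[1, ]
  hdr <- c(
    "# TEM_PIXperUM          1.000000",
    "# WorkingDistance       10.000000",
    "# Phase 1",
    paste0("# MaterialName  \t", p1$name),
    "# Formula     \tCa5(PO4)3F",
    sprintf("# LatticeConstants\t%.4f %.4f %.4f 90.000 90.000 120.000",
            p1$a, p1$a, p1$c),
    "# GRID: SqrGrid",
    sprintf("# XSTEP: %.6f", map$step),
    sprintf("# YSTEP: %.6f", map$step),
    sprintf("# NCOLS_ODD: %d", map$width),
    sprintf("# NCOLS_EVEN: %d", map$width),
    sprintf("# NROWS: %d", map$height)
  )
  n <- map$width * map$height
  eu <- matrix(0, n, 3)
  idx <- map$phase > 0
  if (any(idx))
    eu[idx, ] <- quat_to_euler(map$quat[idx, , drop = FALSE], degrees = FALSE)
  x <- rep(seq_len(map$width) - 1, map$height) * map$step
  y <- rep(seq_len(map$height) - 1, each = map$width) * map$step
  iq <- ifelse(is.finite(map$band_contrast), map$band_contrast, 0)
  ci <- ifelse(idx, 0.9, -1)
  ph <- ifelse(idx, map$phase - 1L, 0L)
  rows <- sprintf("  %.10f  %.10f  %.10f  %.5f  %.5f  %.1f  %.3f  %d  1  1.0",
                  eu[, 1], eu[, 2], eu[, 3], x, y, iq, ci, ph)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
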