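# Oxford/HKL Channel Text File (CTF) reader and writer.  The reader is
# bit-faithful to file content: no filtering, smoothing or interpolation is
# ever applied; non-indexed rows (phase 0) are carried as a mask.

#' Read an Oxford/HKL Channel Text File
#'
#' Parses the header (phase list, `XCells`, `YCells`, `XStep`) and the data
#' block with columns `Phase X Y Bands Error Euler1 Euler2 Euler3 MAD BC BS`.
#' Euler angles are interpreted as Bunge Z-X-Z in degrees; phase-0 rows
#' become non-indexed pixels.
#'
#' @param path path to a `.ctf` file.
#' @return an [ebsd_map()].
#' @export
read_ctf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_end <- grep("^Phase\\s", lines)[1]
  if (is.na(hdr_end)) stop("CTF format error: no 'Phase ...' column header line")
  header <- lines[seq_len(hdr_end - 1)]

  get_key <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), header, value = TRUE)
    if (!length(ln)) stop("CTF format error: missing header key '", key, "'")
    as.numeric(strsplit(ln[1], "\\s+")[[1]][2])
  }
  xcells <- get_key("XCells")
  ycells <- get_key("YCells")
  xstep <- get_key("XStep")

  nph_line <- grep("^Phases\\b", header)
  if (!length(nph_line)) stop("CTF format error: missing header key 'Phases'")
  nph <- as.integer(strsplit(header[nph_line[1]], "\\s+")[[1]][2])
  phases <- data.frame(id = integer(), name = character(),
                       a = numeric(), c = numeric())
  for (i in seq_len(nph)) {
    fl <- strsplit(header[nph_line[1] + i], "\t")[[1]]
    abc <- as.numeric(strsplit(fl[1], ";")[[1]])
    phases <- rbind(phases, data.frame(id = i, name = fl[3],
                                       a = abc[1], c = abc[3]))
  }

  dat <- utils::read.table(text = lines[(hdr_end + 1):length(lines)],
                           header = FALSE)
  if (nrow(dat) != xcells * ycells)
    stop(sprintf(
      "CTF truncation error: %d data rows but XCells x YCells = %d",
      nrow(dat), xcells * ycells))
  colnames(dat)[1:11] <- c("Phase", "X", "Y", "Bands", "Error",
                           "Euler1", "Euler2", "Euler3", "MAD", "BC", "BS")
  # rows are stored x-fastest; order by (Y, X) to be safe
  dat <- dat[order(dat$Y, dat$X), ]

  phase <- as.integer(dat$Phase)
  quat <- matrix(NA_real_, nrow(dat), 4)
  idx <- phase > 0
  if (any(idx))
    quat[idx, ] <- euler_to_quat(dat$Euler1[idx], dat$Euler2[idx],
                                 dat$Euler3[idx])
  ebsd_map(xcells, ycells, step = xstep, quat = quat, phase = phase,
           band_contrast = dat$BC, phases = phases)
}

#' Write an EBSD map as a Channel Text File
#'
#' Inverse of [read_ctf()]; a round trip reproduces the map (orientations to
#' the printed precision of 10 decimal digits in the Euler angles).
#'
#' @param map an [ebsd_map()].
#' @param path output path.
#' @export
write_ctf <- function(map, path) {
  n <- map$width * map$height
  df <- as.data.frame(map)
  df$phi1[map$phase == 0] <- 0
  df$Phi[map$phase == 0] <- 0
  df$phi2[map$phase == 0] <- 0
  bc <- ifelse(is.finite(map$band_contrast), map$band_contrast, 0)
  hdr <- c(
    "Channel Text File",
    "Prj conotex synthetic export",
    "Author\tconotex",
    "JobMode\tGrid",
    paste0("XCells\t", map$width),
    paste0("YCells\t", map$height),
    paste0("XStep\t", format(map$step, digits = 10)),
    paste0("YStep\t", format(map$step, digits = 10)),
    "AcqE1\t0", "AcqE2\t0", "AcqE3\t0",
    "Euler angles refer to Sample Coordinate system (CS0)!",
    paste0("Phases\t", nrow(map$phases))
  )
  for (i in seq_len(nrow(map$phases))) {
    p <- map$phases[i, ]
    hdr <- c(hdr, sprintf("%.4f;%.4f;%.4f\t90;90;120\t%s\t9\t194",
                          p$a, p$a, p$c, p$name))
  }
  hdr <- c(hdr, paste("Phase", "X", "Y", "Bands", "Error", "Euler1", "Euler2",
                      "Euler3", "MAD", "BC", "BS", sep = "\t"))
  rows <- sprintf("%d\t%.4f\t%.4f\t%d\t%d\t%.10f\t%.10f\t%.10f\t%.4f\t%d\t%d",
                  map$phase,
                  (df$x - 1) * map$step, (df$y - 1) * map$step,
                  ifelse(map$phase > 0, 8L, 0L), 0L,
                  df$phi1, df$Phi, df$phi2,
                  ifelse(map$phase > 0, 0.5, 0),
                  as.integer(round(bc)), 255L)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
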