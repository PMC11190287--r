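# Synthetic EBSD maps and Raman spectra with known ground truth.
#
# The generator emulates the texture archetypes of conodont crown tissue:
# c-axes concentrated near the functional (X) axis with taxon-dependent
# dispersion; rotation about the c-axis ranging from a uniform girdle,
# through a dispersed unimodal spread, to tight clusters (including the
# three-cluster case); spatially coherent elongated orientation patches
# whose long axes need not follow the c-axis; and a non-indexed pixel
# fraction in the range observed for beam-sensitive bioapatite (13-43%).
# Every generator is a pure function of (recipe, seed).

#' Rotation-about-c models for the synthetic generator
#'
#' `a_girdle()` draws the rotation angle about the c-axis uniformly over the
#' 60 degree hexagonal period (a complete girdle of a-axes);
#' `a_dispersed()` draws it from a wrapped normal with the given standard
#' deviation; `a_clustered()` from a mixture of wrapped normals (default
#' three clusters).
#'
#' @param sd standard deviation of the rotation angle, degrees.
#' @param centers cluster centers within the 60 degree period, degrees.
#' @param weights mixture weights (normalized to sum to 1).
#' @return a model description used by [texture_recipe()].
#' @export
a_girdle <- function() list(type = "girdle")

#' @rdname a_girdle
#' @export
a_dispersed <- function(sd) list(type = "dispersed", sd = sd)

#' @rdname a_girdle
#' @export
a_clustered <- function(centers = c(0, 20, 40), sd = 5,
                        weights = rep(1, length(centers))) {
  stopifnot(length(weights) == length(centers), all(sd >= 0))
  list(type = "clustered", centers = centers, sd = sd,
       weights = weights / sum(weights))
}

#' Texture recipe for the synthetic EBSD generator
#'
#' @param c_axis specimen-frame direction the crystal c-axes concentrate
#'   around (default X, the occlusal/denticle long axis).
#' @param c_dispersion angular standard deviation of the c-axis about that
#'   direction, degrees.
#' @param a_model rotation-about-c model: [a_girdle()], [a_dispersed()] or
#'   [a_clustered()].
#' @param patch_length,patch_width mean patch dimensions in pixels
#'   (elongated orientation patches; anisotropic Voronoi tessellation).
#' @param patch_axis patch elongation direction, degrees from the map +x
#'   axis (default 90: patches elongated along map y).
#' @param patch_noise within-patch orientation noise (angular sd, degrees).
#' @param unindexed_fraction fraction of pixels masked as non-indexed, in
#'   `[0, 1)`.
#' @param unindexed_mode `"random"` or `"patch-border"` placement of the
#'   masked pixels.
#' @return an object of class `texture_recipe`.
#' @export
texture_recipe <- function(c_axis = c(1, 0, 0), c_dispersion = 10,
                           a_model = a_girdle(), patch_length = 12,
                           patch_width = 4, patch_axis = 90,
                           patch_noise = 3, unindexed_fraction = 0.25,
                           unindexed_mode = c("random", "patch-border")) {
  stopifnot(c_dispersion >= 0, patch_noise >= 0,
            unindexed_fraction >= 0, unindexed_fraction < 1)
  unindexed_mode <- match.arg(unindexed_mode)
  c_axis <- c_axis / sqrt(sum(c_axis^2))
  structure(list(c_axis = c_axis, c_dispersion = c_dispersion,
                 a_model = a_model, patch_length = patch_length,
                 patch_width = patch_width, patch_axis = patch_axis,
                 patch_noise = patch_noise,
                 unindexed_fraction = unindexed_fraction,
                 unindexed_mode = unindexed_mode),
            class = "texture_recipe")
}

# small random rotation with half-normal angle (angular sd in degrees) about
# a uniform random axis
random_perturbation <- function(n, sd_deg) {
  if (sd_deg <= 0) return(matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE))
  ax <- matrix(rnorm(3 * n), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  ang <- abs(rnorm(n, 0, sd_deg))
  axis_angle_quat(ax, ang)
}

sample_a_angle <- function(model, n) {
  period <- 60
  ang <- switch(model$type,
    girdle = runif(n, 0, period),
    dispersed = rnorm(n, 0, model$sd) %% period,
    clustered = {
      k <- sample.int(length(model$centers), n, replace = TRUE,
                      prob = model$weights)
      (model$centers[k] + rnorm(n, 0, model$sd)) %% period
    },
    stop("unknown a-rotation model: ", model$type))
  ang
}

# orientation (Bunge, specimen->crystal) whose crystal c-axis maps to the
# specimen direction v with spin rho (degrees) about c
orientation_from_c_axis <- function(v, rho) {
  q_c2s <- quat_multiply(quat_align_z(v),
                         axis_angle_quat(c(0, 0, 1), rho))
  quat_canonical(quat_conjugate(q_c2s))
}

#' Generate a synthetic EBSD map
#'
#' Tessellates the raster into elongated patches (anisotropic Voronoi with a
#' stretched metric), draws one orientation per patch from the recipe's
#' c-axis and rotation-about-c models, adds within-patch orientation noise
#' per pixel, and masks the requested fraction of pixels as non-indexed.
#' Ground truth (per-pixel patch id, per-patch orientations) is attached as
#' attribute `truth`.
#'
#' @param recipe a [texture_recipe()].
#' @param width,height raster size in pixels.
#' @param step pixel size in micrometres.
#' @param seed optional seed; the map is a pure function of (recipe, seed).
#' @return an [ebsd_map()] with a `truth` attribute.
#' @export
generate_map <- function(recipe, width = 72, height = 72, step = 1,
                         seed = NULL) {
  stopifnot(inherits(recipe, "texture_recipe"))
  with_seed(seed, {
    n <- width * height
    npatch <- max(1, round(n / (recipe$patch_length * recipe$patch_width)))
    px <- runif(npatch, 0.5, width + 0.5)
    py <- runif(npatch, 0.5, height + 0.5)
    x <- rep(seq_len(width), height)
    y <- rep(seq_len(height), each = width)
    th <- recipe$patch_axis * pi / 180
    elong <- recipe$patch_length / recipe$patch_width
    # rotate into the patch frame and shrink the along-axis coordinate
    u <- (cos(th) * x + sin(th) * y) / elong
    v <- -sin(th) * x + cos(th) * y
    pu <- (cos(th) * px + sin(th) * py) / elong
    pv <- -sin(th) * px + cos(th) * py
    d2 <- outer(u, pu, function(a, b) (a - b)^2) +
          outer(v, pv, function(a, b) (a - b)^2)
    patch_id <- max.col(-d2)

    cdirs <- quat_rotate(random_perturbation(npatch, recipe$c_dispersion),
                         matrix(recipe$c_axis, npatch, 3, byrow = TRUE))
    rho <- sample_a_angle(recipe$a_model, npatch)
    qpatch <- orientation_from_c_axis(cdirs, rho)

    quat <- qpatch[patch_id, , drop = FALSE]
    if (recipe$patch_noise > 0) {
      # wobble applied on the crystal->specimen side: q_pix = q (x) conj(r)
      r <- random_perturbation(n, recipe$patch_noise)
      quat <- quat_canonical(quat_multiply(quat, quat_conjugate(r)))
    }

    n_mask <- round(recipe$unindexed_fraction * n)
    mask <- integer(0)
    if (n_mask > 0) {
      if (recipe$unindexed_mode == "patch-border") {
        pid <- matrix(patch_id, nrow = width)
        border <- matrix(FALSE, width, height)
        border[-width, ] <- border[-width, ] | (pid[-width, ] != pid[-1, ])
        border[-1, ] <- border[-1, ] | (pid[-width, ] != pid[-1, ])
        border[, -height] <- border[, -height] | (pid[, -height] != pid[, -1])
        border[, -1] <- border[, -1] | (pid[, -height] != pid[, -1])
        bidx <- which(as.vector(border))
        if (length(bidx) >= n_mask) {
          mask <- sample(bidx, n_mask)
        } else {
          extra <- sample(setdiff(seq_len(n), bidx), n_mask - length(bidx))
          mask <- c(bidx, extra)
        }
      } else {
        mask <- sample.int(n, n_mask)
      }
    }
    phase <- rep(1L, n)
    phase[mask] <- 0L
    qout <- quat
    qout[mask, ] <- NA_real_
    bc <- numeric(n)
    bc[phase > 0] <- round(runif(sum(phase > 0), 120, 200))
    bc[phase == 0] <- round(runif(sum(phase == 0), 20, 80))

    map <- ebsd_map(width, height, step = step, quat = qout, phase = phase,
                    band_contrast = bc)
    attr(map, "truth") <- list(
      patch_id = patch_id,
      patches = data.frame(x = px, y = py, rho = rho,
                           cx = cdirs[, 1], cy = cdirs[, 2], cz = cdirs[, 3]),
      patch_orientation = qpatch,
      pixel_orientation = quat,
      recipe = recipe)
    map
  })
}

#' Default control schedule for the six-taxon synthetic series
#'
#' Dispersions decrease (control increases) along the series, spanning the
#' archetypes girdle, three-cluster and progressively tighter dispersed
#' rotation about c.
#'
#' @return a list of [texture_recipe()]s, weakest control first.
#' @export
default_taxon_schedule <- function() {
  list(
    taxon1 = texture_recipe(c_dispersion = 24, a_model = a_girdle(),
                            patch_noise = 6, unindexed_fraction = 0.35),
    taxon2 = texture_recipe(c_dispersion = 12, a_model = a_girdle(),
                            patch_noise = 5, unindexed_fraction = 0.30),
    taxon3 = texture_recipe(c_dispersion = 9,
                            a_model = a_clustered(c(0, 20, 40), sd = 6),
                            patch_noise = 4, unindexed_fraction = 0.25),
    taxon4 = texture_recipe(c_dispersion = 7, a_model = a_dispersed(10),
                            patch_noise = 4, unindexed_fraction = 0.25),
    taxon5 = texture_recipe(c_dispersion = 5, a_model = a_dispersed(6),
                            patch_noise = 3, unindexed_fraction = 0.20),
    taxon6 = texture_recipe(c_dispersion = 3, a_model = a_dispersed(3),
                            patch_noise = 2, unindexed_fraction = 0.15)
  )
}

#' Generate the six-taxon synthetic series
#'
#' One map per taxon with monotonically decreasing orientation dispersion
#' (increasing biomineralization control) along the series.
#'
#' @param n_taxa number of maps (prefix of the schedule).
#' @param schedule list of [texture_recipe()]s, weakest control first; the
#'   c-axis dispersions must be non-increasing.
#' @param width,height,step map geometry.
#' @param seed optional seed.
#' @return a named list of [generate_map()] results.
#' @export
taxon_series <- function(n_taxa = 6, schedule = default_taxon_schedule(),
                         width = 72, height = 72, step = 1, seed = NULL) {
  stopifnot(n_taxa >= 1, n_taxa <= length(schedule))
  schedule <- schedule[seq_len(n_taxa)]
  disp <- vapply(schedule, function(r) r$c_dispersion, numeric(1))
  if (any(diff(disp) > 0))
    stop("schedule must have non-increasing c-axis dispersion")
  with_seed(seed, {
    out <- lapply(schedule, function(r)
      generate_map(r, width, height, step,
                   seed = sample.int(.Machine$integer.max, 1)))
    out
  })
}

#' Generate a synthetic Raman spectrum
#'
#' Pseudo-Voigt band over a linear baseline with seeded additive Gaussian
#' noise at the stated signal-to-noise ratio (amplitude / noise sd).
#'
#' @param pcmi band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1.
#' @param eta pseudo-Voigt mixing fraction in `[0, 1]`.
#' @param snr signal-to-noise ratio; `Inf` for a noiseless spectrum.
#' @param n_points number of samples across the window.
#' @param window wavenumber window, cm^-1.
#' @param amplitude band amplitude (arbitrary units).
#' @param baseline linear baseline coefficients `c(b0, b1)` evaluated as
#'   `b0 + b1 * wavenumber`.
#' @param seed optional seed.
#' @return data frame with `wavenumber` and `intensity`; the generating
#'   parameters are attached as attribute `truth`.
#' @export
generate_raman <- function(pcmi = 964, fwhm = 4.5, eta = 0.5, snr = 50,
                           n_points = 300, window = c(940, 985),
                           amplitude = 1000, baseline = c(50, -0.02),
                           seed = NULL) {
  stopifnot(eta >= 0, eta <= 1, fwhm > 0, n_points >= 50,
            pcmi > window[1], pcmi < window[2])
  with_seed(seed, {
    x <- seq(window[1], window[2], length.out = n_points)
    y <- baseline[1] + baseline[2] * x +
      pseudo_voigt(x, pcmi, fwhm, eta, amplitude)
    if (is.finite(snr)) y <- y + rnorm(n_points, 0, amplitude / snr)
    out <- data.frame(wavenumber = x, intensity = y)
    attr(out, "truth") <- list(pcmi = pcmi, fwhm = fwhm, eta = eta,
                               snr = snr, amplitude = amplitude,
                               baseline = baseline)
    out
  })
}
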