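# The area-subsampling experiment (robustness of texture indices to the
# measured area) and the between-group non-parametric statistics.

#' Subsample square regions and compute texture indices
#'
#' Draws axis-aligned squares of the given side lengths at seeded uniform
#' random positions (squares may overlap) and computes the requested texture
#' indices for each.  Squares with fewer indexed pixels than `min_indexed`
#' are rejected and redrawn.
#'
#' @param map an [ebsd_map()].
#' @param sizes square side lengths in micrometres.
#' @param n_per_size number of squares per size.
#' @param seed optional seed making the whole draw reproducible.
#' @param min_indexed minimum indexed pixels per square (default 100).
#' @param halfwidth ODF kernel halfwidth in degrees.
#' @param metrics which indices to compute per square (subset of `"ti"`,
#'   `"m_index"`, `"pfj"`).
#' @param n_pairs uncorrelated pairs per square for the M-index.
#' @param max_tries redraw attempts per square before giving up.
#' @return a data frame, one row per square: `size_um`, `area_um2`, `x0`,
#'   `y0`, `n_indexed` and the requested indices.
#' @export
subsample_squares <- function(map, sizes, n_per_size = 50, seed = NULL,
                              min_indexed = 100, halfwidth = 4,
                              metrics = c("ti", "m_index"), n_pairs = 2e4,
                              max_tries = 100) {
  sizes_px <- pmax(1L, as.integer(round(sizes / map$step)))
  if (any(sizes_px > map$width) || any(sizes_px > map$height))
    stop("subsample size larger than the map")
  sym <- sym_of_map(map)
  with_seed(seed, {
    rows <- list()
    for (k in seq_along(sizes_px)) {
      s <- sizes_px[k]
      for (r in seq_len(n_per_size)) {
        for (try in seq_len(max_tries)) {
          x0 <- sample.int(map$width - s + 1L, 1)
          y0 <- sample.int(map$height - s + 1L, 1)
          sub <- crop_map(map, x0, y0, s, s)
          q <- map_orientations(sub)
          if (nrow(q) >= min_indexed) break
          if (try == max_tries)
            stop("could not place a square with >= ", min_indexed,
                 " indexed pixels at size ", sizes[k], " um")
        }
        ts <- texture_summary(q, sym, halfwidth, area_um2 = map_area(sub),
                              n_pairs = n_pairs, metrics = metrics)
        names(ts)[names(ts) == "n"] <- "n_indexed"
        rows[[length(rows) + 1]] <-
          cbind(data.frame(size_um = sizes[k], x0 = x0, y0 = y0), ts)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Pearson correlation between Texture Index and area
#'
#' Tests the null of no relationship between TI and the subsampled area with
#' Pearson's correlation coefficient and its two-sided t-test.  In
#' heterogeneous materials the correlation is negative: the larger the
#' examined area, the lower the TI.
#'
#' @param results a [subsample_squares()] data frame (needs `area_um2` and
#'   `ti`), or any data frame with those columns.
#' @return a list with `rho`, `p_value` and `n`.
#' @export
ti_area_correlation <- function(results) {
  stopifnot(nrow(results) >= 3)
  if (sd(results$ti) == 0 || sd(results$area_um2) == 0)
    stop("zero variance in TI or area; correlation undefined")
  ct <- cor.test(results$area_um2, results$ti, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(results))
}

#' Area sensitivity of texture indices
#'
#' Relative slope of each index against log(area): the per-decade change as
#' a fraction of the index mean.  Used to compare how stable the M-index is
#' against area relative to TI.
#'
#' @param results a [subsample_squares()] data frame.
#' @param metrics columns to assess.
#' @return data frame with `metric`, `slope` and `rel_slope`.
#' @export
area_sensitivity <- function(results, metrics = c("ti", "m_index")) {
  do.call(rbind, lapply(metrics, function(mt) {
    y <- results[[mt]]
    fit <- lm(y ~ log(results$area_um2))
    sl <- unname(coef(fit)[2])
    data.frame(metric = mt, slope = sl, rel_slope = sl / mean(y))
  }))
}

#' Kruskal-Wallis test across groups
#'
#' The non-parametric test of the null hypothesis that index values for all
#' groups originate from the same distribution; H is tie-corrected and the
#' p-value uses the chi-squared approximation with `k - 1` degrees of
#' freedom.
#'
#' @param groups a named list of numeric vectors (one per taxon/group).
#' @return a list with `H`, `df`, `p_value` and group sizes `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!lengths(groups))) stop("every group needs at least one value")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1)
    stop("degenerate input: all values identical across all groups")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = lengths(groups))
}

#' Pairwise Wilcoxon tests with Bonferroni correction
#'
#' Rank-sum tests for every unordered pair of groups at the
#' Bonferroni-adjusted significance level `alpha / divisor`, with a
#' Hodges-Lehmann location-shift confidence interval at the corresponding
#' corrected confidence level.  The default divisor of 6 reproduces the
#' published convention of dividing by the number of samples (for
#' `alpha = 0.05`: a per-comparison level of 0.83% and a 99.17% confidence
#' interval); it is exposed as an argument because dividing by the number of
#' pairs is an equally defensible choice.
#'
#' @param groups a named list of numeric vectors.
#' @param alpha family significance level (default 0.05).
#' @param divisor Bonferroni divisor (default 6).
#' @return a list with `adjusted_alpha`, `conf_level`, and a data frame
#'   `pairs` with raw p-values, significance at the corrected level, the
#'   Hodges-Lehmann shift estimate and its confidence interval.
#' @export
pairwise_wilcoxon_bonferroni <- function(groups, alpha = 0.05, divisor = 6) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!lengths(groups))) stop("every group needs at least one value")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  adj <- alpha / divisor
  conf <- 1 - adj
  cmb <- utils::combn(names(groups), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    g1 <- cmb[1, k]; g2 <- cmb[2, k]
    wt <- suppressWarnings(wilcox.test(groups[[g1]], groups[[g2]],
                                       conf.int = TRUE, conf.level = conf))
    data.frame(group1 = g1, group2 = g2, p_value = wt$p.value,
               significant = wt$p.value < adj,
               shift = unname(wt$estimate),
               ci_lower = wt$conf.int[1], ci_upper = wt$conf.int[2])
  }))
  list(adjusted_alpha = adj, conf_level = conf, pairs = pairs)
}

#' @importFrom utils combn
NULL
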