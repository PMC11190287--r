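# Independent oracles used across the suite.  These deliberately avoid the
# package's compiled code paths: plain R quaternion algebra, exhaustive
# enumeration and union-find.

# accurate rotation angle (degrees) between two unit quaternions; the
# asin form keeps full precision near zero where acos loses it
rot_angle_between <- function(q1, q2) {
  if (is.null(dim(q1))) q1 <- matrix(q1, ncol = 4)
  if (is.null(dim(q2))) q2 <- matrix(q2, ncol = 4)
  d1 <- sqrt(rowSums((q1 - q2)^2))
  d2 <- sqrt(rowSums((q1 + q2)^2))
  4 * asin(pmin(1, pmin(d1, d2) / 2)) * 90 / pi  # 2*asin(d/2) in degrees
}

# brute-force both-sided symmetry reduction: replace each orientation by
# every symmetry-equivalent representative (crystal symmetry composing on
# the crystal side, s (x) q) and take the smallest relative rotation angle
brute_misorientation <- function(q1, q2, sym) {
  rots <- sym$rotations
  best_ang <- 360
  for (i in seq_len(nrow(rots))) {
    r1 <- conotex::quat_multiply(rots[i, , drop = FALSE], q1)
    for (j in seq_len(nrow(rots))) {
      r2 <- conotex::quat_multiply(rots[j, , drop = FALSE], q2)
      p <- conotex::quat_multiply(conotex::quat_conjugate(r1), r2)
      ang <- 2 * atan2(sqrt(sum(p[1, 2:4]^2)), abs(p[1, 1])) * 180 / pi
      best_ang <- min(best_ang, ang)
    }
  }
  best_ang
}

# union-find grain segmentation oracle mirroring the published procedure:
# join 4-adjacent indexed pixels below the threshold, drop grains smaller
# than min_px, run again on the survivors
union_find_grains <- function(map, threshold, min_px = 2) {
  W <- map$width; H <- map$height
  n <- W * H
  sym <- conotex::crystal_symmetry("622", map$phases$a[1], map$phases$c[1])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pass <- function(alive) {
    parent <<- seq_len(n)
    join <- function(a, b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
    for (y in seq_len(H)) for (x in seq_len(W)) {
      i <- (y - 1) * W + x
      if (!alive[i]) next
      for (d in list(c(1, 0), c(0, 1))) {
        x2 <- x + d[1]; y2 <- y + d[2]
        if (x2 > W || y2 > H) next
        j <- (y2 - 1) * W + x2
        if (!alive[j]) next
        ang <- conotex::misorientation_angle(map$quat[i, , drop = FALSE],
                                             map$quat[j, , drop = FALSE], sym)
        if (ang < threshold) join(i, j)
      }
    }
    roots <- rep(0L, n)
    roots[alive] <- vapply(which(alive), function(i) as.integer(find(i)),
                           integer(1))
    roots
  }
  alive <- map$phase > 0
  roots <- pass(alive)
  sizes <- table(roots[roots > 0])
  small <- as.integer(names(sizes)[sizes < min_px])
  alive[roots %in% small] <- FALSE
  roots <- pass(alive)
  roots
}

# canonical form of a label partition: map each label to its first pixel index
partition_signature <- function(labels) {
  sig <- integer(length(labels))
  first <- tapply(seq_along(labels), labels, min)
  sig[labels > 0] <- first[as.character(labels[labels > 0])]
  sig
}

# exact two-sided rank-sum p-value by exhaustive enumeration (no ties)
wilcox_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# tie-corrected Kruskal-Wallis H by the explicit rank formula
kw_hand <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  splits <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, splits, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

hex_sym <- conotex::crystal_symmetry()
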