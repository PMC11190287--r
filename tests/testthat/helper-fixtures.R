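# Shared fixture builders; everything is generated in code at test time.

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_test_map <- function(w = 7, h = 5, unindexed = 0.3, seed = 1) {
  with_seed_local(seed, {
    n <- w * h
    q <- conotex::random_orientations(n)
    phase <- rep(1L, n)
    if (unindexed > 0) phase[sample.int(n, round(unindexed * n))] <- 0L
    q[phase == 0, ] <- NA
    conotex::ebsd_map(w, h, step = 0.5, quat = q, phase = phase,
                      band_contrast = round(runif(n, 50, 200)))
  })
}

# uniform-orientation map (no spatial structure), fully parameterized
constant_map <- function(w, h, q1 = c(1, 0, 0, 0)) {
  conotex::ebsd_map(w, h, quat = matrix(q1, w * h, 4, byrow = TRUE),
                    phase = rep(1L, w * h))
}
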