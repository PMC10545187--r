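# Independent oracles. These are deliberately naive re-derivations of the
# quantities under test and must stay independent of the package internals.

# Exhaustive pairwise minimum Euclidean distance with the smaller-x tie rule.
brute_min_dist <- function(P1, P2) {
  vapply(seq_len(nrow(P1)), function(i) {
    d <- sqrt((P2[, 1] - P1[i, 1])^2 + (P2[, 2] - P1[i, 2])^2)
    min(d)
  }, numeric(1))
}

# Plain 1D discrete convolution with a unit-sum Gaussian kernel truncated at
# 4 sigma and symmetric-reflection ("reflect", edge repeated) padding,
# written as an explicit loop.
conv1_sym <- function(v, sigma, truncate = 4) {
  if (sigma <= 0) return(v)
  r <- ceiling(truncate * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(v)
  reflect <- function(i) {
    j <- (i - 1) %% (2 * n)
    if (j < n) j + 1 else 2 * n - j
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -r:r) acc <- acc + w[k + r + 1] * v[reflect(i + k)]
    out[i] <- acc
  }
  out
}

# Random smooth interface-curve pair (knots in OPL um) for oracle sweeps:
# i1 is a wavy line, i2 sits 60-140 um below it.
random_curve_points <- function(seed) {
  withr::with_seed(seed, {
    x <- sort(runif(8, 0, 600))
    while (min(diff(x)) < 10) x <- sort(runif(8, 0, 600))
    z1 <- 150 + 30 * sin(x / runif(1, 40, 120)) + rnorm(8, 0, 5)
    z2 <- z1 + runif(1, 60, 140) + rnorm(8, 0, 5)
    rbind(
      sampling_points(0L, "i1", x, z1),
      sampling_points(0L, "i2", x, z2)
    )
  })
}
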