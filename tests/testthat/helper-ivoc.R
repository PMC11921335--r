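# Shared fixtures and independent oracles, built in code at test time.

# Small VOC panel so cohort generation stays fast in unit tests.
small_panel <- function() {
  data.frame(
    voc = c("ethanol", "limonene", "benzene", "toluene", "ethylbenzene",
            "xylene", "1,2,4-trimethylbenzene"),
    class = c("oxygenate", "monoterpene", "btex", "btex", "btex", "btex",
              "tmb"),
    indoor_median = c(320, 15, 0.5, 1.5, 0.4, 1.2, 0.4),
    indoor_gsd = c(3, 2.8, 1.8, 2.2, 2.2, 2.2, 2.2),
    outdoor_median = c(5, 0.3, 0.18, 0.3, 0.1, 0.2, 0.05),
    outdoor_gsd = rep(1.8, 7))
}

small_spec <- function(n_homes = 50, seed = 11, ...) {
  cohort_spec(n_homes = n_homes, seed = seed, voc_panel = small_panel(),
              ...)
}

# Independent Brunner-Munzel studentised statistic, written from the
# defining formulas (midranks, within-group rank variances); used as the
# brute-force oracle against the package implementation.
oracle_bm_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y), ties.method = "average")
  rx <- r[1:n1]; ry <- r[(n1 + 1):N]
  s2x <- stats::var(rx - rank(x, ties.method = "average"))
  s2y <- stats::var(ry - rank(y, ties.method = "average"))
  denom <- N * sqrt(n1 * s2x + n2 * s2y)
  if (denom == 0) {
    if (mean(ry) == mean(rx)) 0 else sign(mean(ry) - mean(rx)) * Inf
  } else n1 * n2 * (mean(ry) - mean(rx)) / denom
}

# Exhaustive two-sided permutation p-value of the statistic above.
oracle_bm_perm_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  obs <- abs(oracle_bm_stat(x, y))
  splits <- utils::combn(N, n1)
  perm <- apply(splits, 2L, function(idx)
    oracle_bm_stat(pool[idx], pool[-idx]))
  mean(abs(perm) >= obs - 1e-12)
}
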