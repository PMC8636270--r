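# Shared oracles for the test suite.

# at% <-> ratio helpers kept independent of the package implementation.
at_to_ratio <- function(at) at / (100 - at)

# Theoretical standard error (in at%) of the mean-of-pixel-ratios estimator
# for Poisson ion counts: per pixel, n15 ~ Pois(lam * p), n14 ~ Pois(lam * (1 - p)),
# r = n15/n14, var(r) ~ r^2 (1/lam15 + 1/lam14); delta method for at% = 100 r/(1+r).
se_atpct_ratio_mean <- function(p, lam, n_px) {
  r <- p / (1 - p)
  sd_r <- r * sqrt(1 / (lam * p) + 1 / (lam * (1 - p)))
  sd_r / sqrt(n_px) * 100 / (1 + r)^2
}

# A deterministic textured matrix for registration tests (fixed seed).
textured_matrix <- function(nr, nc, seed = 99) {
  set.seed(seed)
  matrix(stats::runif(nr * nc), nr, nc)
}
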