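# shared builders for the test suite; fixtures are always generated in code

# Gaussian posterior draws around given log10-scale parameter means
make_posterior <- function(log_g0 = 2, log_ginf = 4.4, log_ec50 = 2,
                           n = 1.5, sd = c(0.05, 0.03, 0.06, 0.08),
                           draws = 50L, seed = 1L) {
  set.seed(seed)
  hill_posterior(cbind(
    log_g0 = rnorm(draws, log_g0, sd[1]),
    log_ginf = rnorm(draws, log_ginf, sd[2]),
    log_ec50 = rnorm(draws, log_ec50, sd[3]),
    n = pmax(rnorm(draws, n, sd[4]), 0.05)))
}

# random valid Hill parameter sets (optionally including inverted ones)
random_hill_params <- function(seed) {
  set.seed(seed)
  hill_params(g0 = 10^runif(1, 1, 4), ginf = 10^runif(1, 1, 5),
              ec50 = 10^runif(1, -1, 3), n = runif(1, 0.3, 4))
}

# a tiny landscape with prescribed posterior medians on the EC50 axis
make_tiny_landscape <- function(ec50s, seed = 1L) {
  recs <- lapply(seq_along(ec50s), function(i)
    variant_record(genotype(sprintf("A%dV", i + 1)),
                   make_posterior(log_ec50 = log10(ec50s[i]),
                                  seed = seed + i),
                   id = sprintf("v%05d", i)))
  landscape(recs)
}

expect_deep_equal_num <- function(a, b, tol = 1e-8) {
  expect_equal(a, b, tolerance = tol)
}
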