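# Independent oracles used across tests.

# Brute-force Benjamini-Hochberg: for each p_i, q_i is the smallest
# min(1, p_j * m / rank_j) over all p_j >= p_i, computed by explicit
# enumeration (O(n^2)), independent of stats::p.adjust.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) min(1, p[j] * m / ranks[j]) else Inf
    }, 0)
    min(cand)
  }, 0)
}

# doubling time by numeric root-finding on the logistic kernel itself
doubling_time_numeric <- function(K, r, G0) {
  f <- function(t) logistic_growth(t, K, r, G0) - 2 * G0
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}

# a small, fast screen-pair configuration for unit tests
tiny_config <- function(...) {
  defaults <- list(n_genes = 30, n_replicates = 3,
                   timepoints = seq(0, 5, length.out = 10),
                   dead_fraction = 0, noise_sigma = 0.02,
                   planted_fraction_sup = 0, planted_fraction_enh = 0,
                   seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# random valid logistic parameter sets mirroring colony-intensity scales
random_params <- function(n, seed = 1) {
  set.seed(seed)
  K <- rlnorm(n, log(0.2), 0.3)
  r <- rlnorm(n, log(3), 0.4)
  G0 <- pmin(rlnorm(n, log(0.003), 0.4), K / 4)
  data.frame(K = K, r = r, G0 = G0)
}
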