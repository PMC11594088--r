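# Independent numerical oracles used across the suite.

# Inverse Langevin by bisection on coth(b) - 1/b (independent of the
# closed-form approximation under test).
bisect_inverse_langevin <- function(y, tol = 1e-12) {
  vapply(y, function(yy) {
    if (yy == 0) return(0)
    lo <- 1e-12
    hi <- 1
    Lfun <- function(b) 1 / tanh(b) - 1 / b
    while (Lfun(hi) < yy) hi <- hi * 2
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      if (Lfun(mid) < yy) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Convenience: a noiseless single-cycle table from a pure elastic backbone.
elastic_cycle <- function(G, N = Inf, max_strain = 0.2, n = 100,
                          specimen_id = "S1", time_h = 0) {
  generate_compression(
    ground_truth(G = G, N = if (is.finite(N)) N else Inf, eta_eff = 0),
    max_strain = max_strain, n_cycles = 1, n_points = n,
    noise_sd = 0, specimen_id = specimen_id, time_h = time_h
  )
}
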