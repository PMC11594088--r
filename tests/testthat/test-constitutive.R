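test_that("strain/stretch conversion is the elementwise map 1 - strain", {
  expect_equal(strain_to_stretch(0), 1)
  expect_equal(strain_to_stretch(0.20), 0.80)
  expect_equal(strain_to_stretch(c(0, 0.1, 0.2)), c(1.0, 0.9, 0.8))
  expect_error(strain_to_stretch(c(0.1, 1.0)), "index: 2")
  expect_error(strain_to_stretch(-0.01), "index: 1")
})

test_that("Neo-Hookean nominal stress follows G*(lambda - lambda^-2)", {
  expect_equal(nh_stress(1, 12345), 0)
  expect_equal(nh_stress(0.8, 1000), 1000 * (0.8 - 0.8^-2)) # -762.5 Pa
  expect_equal(nh_stress(1.25, 1000), 1000 * (1.25 - 1.25^-2)) # 610 Pa
  expect_error(nh_stress(0, 1000), "stretch")
  expect_error(nh_stress(0.8, -1), "G")
})

test_that("Langevin function: limit at zero, saturation, oddness", {
  expect_equal(langevin(0), 0)
  expect_equal(langevin(1), 1 / tanh(1) - 1, tolerance = 1e-12)
  expect_gte(langevin(50), 0.98)
  b <- seq(-5, 5, length.out = 41)
  expect_equal(langevin(-b), -langevin(b), tolerance = 1e-12)
  # series branch agrees with the leading-order behaviour beta/3
  expect_equal(langevin(9.9e-5), 9.9e-5 / 3, tolerance = 1e-9)
})

test_that("Petrosyan inverse Langevin matches the bisection oracle", {
  expect_equal(inverse_langevin(0), 0)
  y1 <- 1 / tanh(1) - 1 # = langevin(1)
  expect_equal(inverse_langevin(y1), 1, tolerance = 3e-3)
  expect_equal(inverse_langevin(0.9), bisect_inverse_langevin(0.9),
               tolerance = 3e-3)
  expect_error(inverse_langevin(-0.1), "index")
  expect_error(inverse_langevin(1), "index")
})

test_that("inverse_langevin o langevin is identity within 3e-3 over [0.01, 0.95]", {
  y <- seq(0.01, 0.95, length.out = 1000)
  beta_oracle <- bisect_inverse_langevin(y)
  rel_err <- abs(inverse_langevin(y) - beta_oracle) / beta_oracle
  expect_lt(max(rel_err), 3e-3)
  # strictly increasing
  expect_true(all(diff(inverse_langevin(y)) > 0))
})

test_that("eight-chain stress: zero at unity, Gaussian limit, strain stiffening", {
  expect_equal(ab_stress(1, 1000, 10), 0)
  expect_equal(ab_stress(1, 1000, 1e6), 0)
  # Gaussian limit: N -> infinity recovers 3G(lambda - lambda^-2)
  expect_equal(ab_stress(0.8, 1000, 1e6), 3 * 1000 * (0.8 - 0.8^-2),
               tolerance = 1e-3)
  lam <- seq(0.8, 1.25, length.out = 50)
  gauss <- 3 * 1000 * (lam - lam^-2)
  ab <- vapply(lam, ab_stress, numeric(1), G = 1000, N = 1e6)
  expect_equal(ab, gauss, tolerance = 1e-3)
  # finite extensibility stiffens the response
  expect_gt(abs(ab_stress(0.8, 1000, 2)), abs(ab_stress(0.8, 1000, 1e6)))
  # locking
  expect_error(ab_stress(0.3, 1000, 2), "locking|extensibility")
  expect_error(ab_stress(0.8, 1000, 0.5), "N")
})

test_that("both models vanish at lambda = 1 and increase monotonically in stretch", {
  lam <- seq(0.7, 1.3, length.out = 200)
  s_nh <- nh_stress(lam, 800)
  s_ab <- vapply(lam, ab_stress, numeric(1), G = 800, N = 6)
  expect_true(all(diff(s_nh) > 0))
  expect_true(all(diff(s_ab) > 0))
  expect_equal(nh_stress(1, 800), 0)
  expect_equal(ab_stress(1, 800, 6), 0)
})

test_that("Drucker screen quantifies decreasing-slope increments", {
  eps <- seq(0, 0.2, length.out = 10)
  mono <- data.frame(strain = eps, stress = 1000 * eps)
  rep <- drucker_check(mono)
  expect_equal(rep$fraction_violating, 0)
  expect_true(rep$pass)
  # one decreasing increment among 9
  s <- 1000 * eps
  s[6] <- s[5] - 50
  s[7:10] <- s[7:10] + 100
  rep2 <- drucker_check(data.frame(strain = eps, stress = s))
  expect_equal(rep2$fraction_violating, 1 / 9)
  expect_false(rep2$pass)
  # constant stress is non-decreasing: allowed
  flat <- data.frame(strain = eps, stress = rep(100, 10))
  expect_equal(drucker_check(flat)$fraction_violating, 0)
  expect_error(drucker_check(mono[1:2, ]), "3 points")
})

test_that("noiseless Neo-Hookean self-recovery is exact", {
  cyc <- elastic_cycle(G = 2000)
  fit <- fit_nh(cyc)
  expect_true(fit$converged)
  expect_equal(fit$G, 2000, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12 * 2000^2)
  expect_equal(fit$nu, 2000 / (1.380649e-23 * 293.15), tolerance = 1e-10)
})

test_that("noiseless eight-chain self-recovery is exact", {
  cyc <- elastic_cycle(G = 500, N = 4)
  fit <- fit_ab(cyc)
  expect_true(fit$converged)
  expect_false(fit$at_bound)
  expect_equal(fit$G, 500, tolerance = 1e-6)
  expect_equal(fit$N, 4, tolerance = 1e-4)
  expect_equal(fit$lambda_lock, sqrt(fit$N))
  expect_equal(fit$nu, 3 * fit$G / (1.380649e-23 * 293.15), tolerance = 1e-10)
})

test_that("NH modulus is recovered within 5% at 2% noise (Monte Carlo)", {
  set.seed(42)
  n_rep <- 200
  hit <- logical(n_rep)
  tr <- ground_truth(G = 2000, N = Inf, eta_eff = 0)
  for (i in seq_len(n_rep)) {
    cyc <- generate_compression(tr, n_cycles = 1, n_points = 50,
                                noise_sd = 0.02)
    hit[i] <- abs(fit_nh(cyc)$G - 2000) / 2000 < 0.05
  }
  expect_gte(mean(hit), 0.95)
})

test_that("AB parameters are recovered (G 10%, N 25%) at 2% noise (Monte Carlo)", {
  set.seed(43)
  n_rep <- 200
  hitG <- logical(n_rep); hitN <- logical(n_rep)
  # a strongly strain-stiffening specimen measured with the full 5-cycle
  # protocol: at 20% strain the chain stretch reaches ~72% of locking, the
  # regime where N is identifiable (see the methods vignette)
  tr <- ground_truth(G = 500, N = 2, eta_eff = 0)
  for (i in seq_len(n_rep)) {
    cyc <- generate_compression(tr, n_cycles = 5, n_points = 100,
                                noise_sd = 0.02)
    f <- fit_ab(cyc)
    hitG[i] <- abs(f$G - 500) / 500 < 0.10
    hitN[i] <- abs(f$N - 2) / 2 < 0.25
  }
  expect_gte(mean(hitG), 0.90)
  expect_gte(mean(hitN), 0.90)
})

test_that("fitted G_NH exceeds fitted G_AB on strain-stiffening data", {
  set.seed(44)
  for (N_true in c(2, 4, 10)) {
    cyc <- elastic_cycle(G = 800, N = N_true)
    g_nh <- fit_nh(cyc)$G
    g_ab <- fit_ab(cyc)$G
    expect_gt(g_nh, g_ab)
  }
})

test_that("with N fixed at 1e6 the AB fit equals the NH fit divided by 3", {
  set.seed(45)
  cyc <- generate_compression(ground_truth(G = 2000, N = Inf, eta_eff = 0),
                              n_cycles = 1, n_points = 60, noise_sd = 0.01)
  g_nh <- fit_nh(cyc)$G
  f_ab <- fit_ab(cyc, fix_N = 1e6)
  expect_equal(f_ab$G, g_nh / 3, tolerance = 2e-3)
})

test_that("loading-arm reduction averages cycles and honours the policy", {
  tr <- ground_truth(G = 1000, N = Inf, eta_eff = 500)
  cyc <- generate_compression(tr, n_cycles = 3, n_points = 40, noise_sd = 0)
  avg <- loading_arm(cyc, "average", n_grid = 50)
  fst <- loading_arm(cyc, "first", n_grid = 50)
  expect_equal(nrow(avg), 50)
  # noiseless cycles are identical, so average == first
  expect_equal(avg$stress, fst$stress, tolerance = 1e-12)
  expect_error(loading_arm(dplyr::filter(cyc, arm == "unloading")),
               "loading")
})

test_that("cycle validation catches malformed tables", {
  cyc <- elastic_cycle(G = 1000)
  expect_s3_class(check_cycle_data(cyc), "tbl_df")
  bad <- cyc
  bad$strain[1] <- 0.05 # first loading sample deformed
  expect_error(check_cycle_data(bad), "undeformed|non-decreasing")
  expect_error(check_cycle_data(dplyr::select(cyc, -stress)), "missing")
})
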