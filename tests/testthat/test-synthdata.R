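test_that("pure elastic limit: arms coincide and hysteresis vanishes", {
  cyc <- generate_compression(ground_truth(G = 2000, N = 4, eta_eff = 0),
                              n_cycles = 1, n_points = 50, noise_sd = 0)
  lo <- dplyr::filter(cyc, arm == "loading")
  un <- dplyr::filter(cyc, arm == "unloading")
  expect_equal(lo$stress, rev(un$stress), tolerance = 1e-12)
  expect_equal(cycle_hysteresis(cyc)$w_diss, 0, tolerance = 1e-10)
  expect_equal(attr(cyc, "injected_dissipation"), 0)
})

test_that("viscous overstress injects the book-kept dissipation", {
  tr <- ground_truth(G = 2000, N = 4, eta_eff = 3000)
  cyc <- generate_compression(tr, n_cycles = 1, n_points = 120, noise_sd = 0)
  # rectangle area of the symmetric overstress: 2 * eta * rate * strain range
  rate <- attr(cyc, "strain_rate")
  expect_equal(rate, 0.05)
  w_inj <- attr(cyc, "injected_dissipation")
  expect_equal(w_inj, 2 * 3000 * rate * 0.2)
  expect_equal(cycle_hysteresis(cyc, n_grid = 200)$w_diss, w_inj,
               tolerance = 0.02)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_compression(seed = 99)
  b <- generate_compression(seed = 99)
  expect_identical(a$stress, b$stress)
  s1 <- generate_swelling(seed = 99)
  s2 <- generate_swelling(seed = 99)
  expect_identical(s1$records, s2$records)
  st1 <- generate_study(n_replicates = 1, n_cycles = 1, n_points = 20,
                        seed = 5)
  st2 <- generate_study(n_replicates = 1, n_cycles = 1, n_points = 20,
                        seed = 5)
  expect_identical(st1$mechanics$stress, st2$mechanics$stress)
  expect_identical(st1$swelling$mass_g, st2$swelling$mass_g)
})

test_that("swelling series honours the initial condition and asymptote", {
  tr <- ground_truth(Qv_eq = 235, tau = 8)
  sw <- generate_swelling(tr, times = c(0, 24, 48, 72, 1e5),
                          noise_sd_mass = 0, noise_sd_volume = 0,
                          V0 = 0.5)
  rec <- sw$records
  q <- swelling_ratios(rec$mass_g[1], rec$mass_g, rec$volume_cm3[1],
                       rec$volume_cm3)
  expect_equal(q$Qv[1], 100)
  expect_equal(q$Qv[length(q$Qv)], 235, tolerance = 1e-8)
  # density obeys the mixing rule with the truth's phases
  phi <- phi_evolution(tr$phi_p0, q$Qv)
  expect_equal(rec$density_g_cm3,
               tr$rho_p * phi + tr$rho_s * (1 - phi), tolerance = 1e-12)
})

test_that("noiseless swelling output round-trips through the analysis", {
  tr <- ground_truth(Qv_eq = 235, tau = 8, phi_p0 = 0.15,
                     rho_p = 1.40, rho_s = 1.002)
  sw <- generate_swelling(tr, noise_sd_mass = 0, noise_sd_volume = 0)
  rec <- sw$records
  q <- swelling_ratios(rec$mass_g[1], rec$mass_g, rec$volume_cm3[1],
                       rec$volume_cm3)
  kin <- fit_kinetics(rec$time_h, q$Qv, scale = "Qv")
  expect_equal(kin$Q_eq, 235, tolerance = 1e-6)
  expect_equal(kin$tau, 8, tolerance = 1e-4)
  omega_p <- sw$dry$dry_mass_g / rec$mass_g
  cmp <- composition_from_drying(rec$density_g_cm3, sw$dry$rho_p_g_cm3,
                                 omega_p)
  expect_equal(cmp$rho_s, rep(1.002, 4), tolerance = 1e-10)
  phi_p0_hat <- (sw$dry$dry_mass_g / sw$dry$rho_p_g_cm3) / rec$volume_cm3[1]
  expect_equal(phi_p0_hat, 0.15, tolerance = 1e-10)
})

test_that("study bundle has the declared cardinality and embedded seed", {
  st <- generate_study(n_replicates = 3, times = c(0, 24, 48, 72),
                       n_cycles = 2, n_points = 10, seed = 3)
  expect_equal(length(unique(st$mechanics$specimen_id)), 8 * 3)
  expect_equal(nrow(st$swelling), 8 * 3 * 4)
  expect_equal(nrow(st$dry), 8 * 3)
  expect_equal(nrow(st$mechanics), 8 * 3 * 4 * 2 * 2 * 10)
  expect_equal(nrow(st$truth), 8)
  expect_true(all(st$truth$seed == 3))
  expect_equal(attr(st$swelling, "seed"), 3)
  # one de-swelling scenario is part of the design
  expect_true(any(st$truth$Qv_eq < 100))
  # scenarios with prescribed chi lie in the near-theta band
  expect_true(all(st$truth$chi_true > 0.5 & st$truth$chi_true < 0.60))
})

test_that("study files round-trip through the CSV writers/readers", {
  st <- generate_study(n_replicates = 1, times = c(0, 24, 48),
                       n_cycles = 1, n_points = 10, seed = 4)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  mech <- read_cycles_csv(file.path(dir, "mechanics.csv"))
  expect_equal(nrow(mech), nrow(st$mechanics))
  expect_equal(mech$stress, st$mechanics$stress)
  expect_true(all(mech$seed == 4))
})
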