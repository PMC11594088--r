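#' Default ground truth for a synthetic specimen
#'
#' Parameters of one synthetic hydrogel specimen: the eight-chain elastic
#' backbone `(G, N)` (with `N = Inf` meaning a Gaussian/Neo-Hookean
#' backbone with modulus `G`), an effective dashpot viscosity `eta_eff`
#' producing rate-proportional hysteresis, the swelling-kinetics truth
#' `(Qv_eq, tau)`, and the composition truth
#' `(phi_p0, rho_p, rho_s)`.
#'
#' @param G Shear modulus of the elastic backbone, Pa (eight-chain
#'   convention when `N` is finite).
#' @param N Segments per strand; `Inf` for a Gaussian backbone.
#' @param eta_eff Effective dashpot viscosity, Pa s.
#' @param Qv_eq Equilibrium volumetric swelling ratio, %.
#' @param tau Swelling time constant, h.
#' @param phi_p0 Initial polymer volume fraction.
#' @param rho_p Dry polymer density, g cm^-3.
#' @param rho_s Viscous-phase density, g cm^-3.
#' @return A named list.
#' @export
ground_truth <- function(G = 4000, N = 4, eta_eff = 3000,
                         Qv_eq = 235, tau = 24,
                         phi_p0 = 0.15, rho_p = 1.40, rho_s = 1.002) {
  stopifnot(G > 0, N > 1, eta_eff >= 0, Qv_eq > 0, tau > 0,
            phi_p0 > 0, phi_p0 < 1, rho_p > 0, rho_s > 0)
  list(G = G, N = N, eta_eff = eta_eff, Qv_eq = Qv_eq, tau = tau,
       phi_p0 = phi_p0, rho_p = rho_p, rho_s = rho_s)
}

#' Generate cyclic-compression data with hysteresis
#'
#' Emulates unconfined constant-rate cyclic compression: a crosshead moving
#' at `rate_um_s` against a specimen of height `height_mm` produces a
#' constant strain rate; each cycle loads to `max_strain` and unloads to
#' zero. The stress is an elastic backbone (eight-chain with the truth's
#' `G`, `N`; Neo-Hookean when `N = Inf`) plus a rate-proportional viscous
#' overstress \eqn{+\eta_{eff}\dot\epsilon} on loading and
#' \eqn{-\eta_{eff}\dot\epsilon} on unloading -- the minimal mechanism that
#' produces a loop of analytically known area
#' \eqn{2 \eta_{eff} \dot\epsilon \, \epsilon_{max}} per cycle (recorded in
#' the `injected_dissipation` attribute) -- plus multiplicative Gaussian
#' noise on stress.
#'
#' @param truth A [ground_truth()] list.
#' @param rate_um_s Crosshead speed, micrometres per second.
#' @param max_strain Peak engineering compressive strain.
#' @param n_cycles Number of loading-unloading cycles.
#' @param height_mm Initial specimen height, mm.
#' @param n_points Samples per arm.
#' @param noise_sd Relative (multiplicative Gaussian) stress noise.
#' @param specimen_id,time_h Metadata stamped on every row.
#' @param seed Optional integer; when given, the RNG is seeded so output is
#'   bit-identical across calls.
#' @return A tidy cycle tibble (see [check_cycle_data()]) with attributes
#'   `injected_dissipation` (J m^-3 per cycle), `strain_rate` (1/s) and
#'   `seed`.
#' @export
generate_compression <- function(truth = ground_truth(),
                                 rate_um_s = 300, max_strain = 0.2,
                                 n_cycles = 5, height_mm = 6,
                                 n_points = 80, noise_sd = 0.02,
                                 specimen_id = "S1", time_h = 0,
                                 seed = NULL) {
  stopifnot(max_strain > 0, max_strain < 0.5, n_cycles >= 1, n_points >= 3)
  if (!is.null(seed)) set.seed(seed)
  rate <- rate_um_s * 1e-6 / (height_mm * 1e-3) # strain rate, 1/s
  eps <- seq(0, max_strain, length.out = n_points)
  lam <- strain_to_stretch(eps)
  backbone <- if (is.infinite(truth$N)) {
    -nh_stress(lam, truth$G)
  } else {
    -ab_stress(lam, truth$G, truth$N) # errors beyond locking
  }
  over <- truth$eta_eff * rate
  one_cycle <- function(k) {
    tibble(
      specimen_id = specimen_id, time_h = time_h, cycle = k,
      arm = rep(c("loading", "unloading"), each = n_points),
      strain = c(eps, rev(eps)),
      stress_clean = c(backbone + over, rev(backbone) - over)
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_cycles), one_cycle))
  out$stress <- out$stress_clean *
    (1 + noise_sd * stats::rnorm(nrow(out)))
  out$stress_clean <- NULL
  attr(out, "injected_dissipation") <- 2 * over * max_strain
  attr(out, "strain_rate") <- rate
  attr(out, "seed") <- seed
  out
}

#' Generate a pycnometry-style swelling series
#'
#' The specimen volume follows first-order kinetics,
#' \eqn{V_t = V_0 (100 + (Q_{v,eq} - 100)(1 - e^{-t/\tau}))/100}; the
#' polymer volume is conserved (\eqn{\phi_p = \phi_{p,0} V_0 / V_t}) and
#' the mass follows from the density mixing rule with the viscous-phase
#' density held at its truth value. Independent multiplicative Gaussian
#' noise is applied to mass and volume (defaults reflect pycnometer-grade
#' repeatability); the recorded density is the noisy mass over the noisy
#' volume. A dry-state sidecar carries the dried polymer mass and density.
#'
#' @inheritParams generate_compression
#' @param times Measurement time points in hours (must include 0).
#' @param V0 Initial specimen volume, cm^3.
#' @param noise_sd_mass,noise_sd_volume Relative measurement noise.
#' @return A list with `records` (columns `specimen_id`, `time_h`,
#'   `mass_g`, `volume_cm3`, `density_g_cm3`) and `dry` (columns
#'   `specimen_id`, `dry_mass_g`, `rho_p_g_cm3`); the seed is attached as
#'   an attribute of each tibble.
#' @export
generate_swelling <- function(truth = ground_truth(),
                              times = c(0, 24, 48, 72), V0 = 0.5,
                              noise_sd_mass = 0.005,
                              noise_sd_volume = 0.005,
                              specimen_id = "S1", seed = NULL) {
  if (!any(times == 0)) abort("`times` must include 0")
  if (!is.null(seed)) set.seed(seed)
  Qv <- 100 + (truth$Qv_eq - 100) * (1 - exp(-times / truth$tau))
  Vt <- V0 * Qv / 100
  phi_p <- truth$phi_p0 * V0 / Vt
  rho_h <- truth$rho_p * phi_p + truth$rho_s * (1 - phi_p)
  mass <- rho_h * Vt
  mass_obs <- mass * (1 + noise_sd_mass * stats::rnorm(length(mass)))
  vol_obs <- Vt * (1 + noise_sd_volume * stats::rnorm(length(Vt)))
  records <- tibble(
    specimen_id = specimen_id, time_h = times,
    mass_g = mass_obs, volume_cm3 = vol_obs,
    density_g_cm3 = mass_obs / vol_obs
  )
  dry_mass <- truth$phi_p0 * V0 * truth$rho_p
  dry <- tibble(
    specimen_id = specimen_id,
    dry_mass_g = dry_mass * (1 + noise_sd_mass * stats::rnorm(1)),
    rho_p_g_cm3 = truth$rho_p
  )
  attr(records, "seed") <- seed
  attr(dry, "seed") <- seed
  list(records = records, dry = dry)
}

#' Default study design for the synthetic generator
#'
#' Eight cross-linking scenarios emulating a swelling study: equilibrium
#' swelling ratios spanning two orders of magnitude (loose physical blends
#' near 2000% down to strongly cross-linked networks near 100%), moduli of
#' a few kPa, and one de-swelling scenario (`Qv_eq = 85%`, emulating ionic
#' cross-linking densifying the network in the swelling medium). The
#' interaction parameter `chi_true` of every scenario is derived from its
#' equilibrium state by [chi_from_equilibrium()] with the truth's
#' \eqn{\nu_0 = 3G/(k_B T)} and \eqn{V_1 = M_m/\rho_s}, so the analysis
#' pipeline can be checked against it end to end; the swelling scenarios
#' land in the near-theta band by construction.
#'
#' @param temperature Absolute temperature, K.
#' @return A tibble with one row per scenario and all truth columns.
#' @export
study_design <- function(temperature = 293.15) {
  des <- tibble(
    group = sprintf("gel%02d", 1:8),
    Qv_eq = c(1800, 235, 2400, 220, 776, 105, 417, 85),
    G = c(2500, 3000, 3500, 4000, 4500, 5000, 5500, 6000),
    N = 4,
    eta_eff = c(2000, 2500, 3000, 3500, 4000, 4500, 5000, 5500),
    tau = c(14, 16, 18, 20, 22, 24, 26, 28),
    phi_p0 = c(0.18, 0.16, 0.15, 0.14, 0.14, 0.135, 0.13, 0.15),
    rho_p = 1.40,
    rho_s = c(1.000, 1.001, 1.002, 1.003, 1.004, 1.005, 1.006, 1.008)
  )
  # The Neo-Hookean strand density the analysis sees is the least-squares
  # projection of the eight-chain backbone onto the NH stress over the
  # protocol's strain range (finite extensibility inflates it above
  # 3 G_AB), so the truth ledger records exactly that.
  lam <- strain_to_stretch(seq(0, 0.2, length.out = 100))
  f_nh <- lam^-2 - lam
  des$G_NH <- vapply(seq_len(nrow(des)), function(i) {
    s <- -ab_stress(lam, des$G[i], des$N[i])
    sum(s * f_nh) / sum(f_nh^2)
  }, numeric(1))
  des$nu0 <- des$G_NH / (.kB * temperature)
  des$V1 <- 18.015 / des$rho_s
  st <- equilibrium_state(
    phi_p0 = des$phi_p0,
    phi_peq = phi_evolution(des$phi_p0, des$Qv_eq),
    nu0 = des$nu0, V1 = des$V1,
    specimen_id = des$group, temperature = temperature
  )
  des$chi_true <- chi_from_equilibrium(st)$chi
  des
}

#' Generate a full synthetic study
#'
#' Generates mechanics, swelling and dry-state tables for a grid of
#' cross-linking scenarios ([study_design()]) with `n_replicates` specimens
#' each, measured at `times`. The compression modulus at each time point is
#' scaled as \eqn{G_t = G (Q_v(t)/100)^{-1/3}}, injecting the
#' normalised-modulus scaling so that downstream recovery of the exponent
#' can be tested. All randomness derives from `seed`; regeneration with the
#' same arguments is bit-identical.
#'
#' @param design A scenario tibble as from [study_design()].
#' @param n_replicates Specimens per scenario.
#' @param times Swelling/testing time points, h.
#' @param n_cycles,n_points,noise_sd Compression protocol, see
#'   [generate_compression()].
#' @param noise_sd_mass,noise_sd_volume See [generate_swelling()].
#' @param seed Integer seed, recorded in every output table.
#' @return A list of tibbles: `mechanics`, `swelling`, `dry`, `truth`
#'   (per-scenario ground truth incl. the injected per-cycle dissipation
#'   `w_diss` and `seed`).
#' @export
generate_study <- function(design = study_design(), n_replicates = 3,
                           times = c(0, 24, 48, 72),
                           n_cycles = 5, n_points = 80, noise_sd = 0.02,
                           noise_sd_mass = 0.005, noise_sd_volume = 0.005,
                           seed = 1) {
  set.seed(seed)
  rate <- 300 * 1e-6 / 6e-3
  mech <- list(); swell <- list(); dry <- list()
  for (i in seq_len(nrow(design))) {
    tr_row <- design[i, ]
    for (r in seq_len(n_replicates)) {
      id <- sprintf("%s_r%d", tr_row$group, r)
      tr <- ground_truth(
        G = tr_row$G, N = tr_row$N, eta_eff = tr_row$eta_eff,
        Qv_eq = tr_row$Qv_eq, tau = tr_row$tau,
        phi_p0 = tr_row$phi_p0, rho_p = tr_row$rho_p, rho_s = tr_row$rho_s
      )
      sw <- generate_swelling(tr, times = times,
                              noise_sd_mass = noise_sd_mass,
                              noise_sd_volume = noise_sd_volume,
                              specimen_id = id)
      swell[[id]] <- sw$records
      dry[[id]] <- sw$dry
      Qv_t <- 100 + (tr$Qv_eq - 100) * (1 - exp(-times / tr$tau))
      mech[[id]] <- dplyr::bind_rows(lapply(seq_along(times), function(j) {
        tr_t <- tr
        tr_t$G <- tr$G * (Qv_t[j] / 100)^(-1 / 3)
        generate_compression(tr_t, n_cycles = n_cycles,
                             n_points = n_points, noise_sd = noise_sd,
                             specimen_id = id, time_h = times[j])
      }))
    }
  }
  truth <- design
  truth$w_diss <- 2 * truth$eta_eff * rate * 0.2
  truth$seed <- seed
  out <- list(
    mechanics = dplyr::bind_rows(mech),
    swelling = dplyr::bind_rows(swell),
    dry = dplyr::bind_rows(dry),
    truth = truth
  )
  out$mechanics$group <- sub("_r\\d+$", "", out$mechanics$specimen_id)
  out$swelling$group <- sub("_r\\d+$", "", out$swelling$specimen_id)
  out$dry$group <- sub("_r\\d+$", "", out$dry$specimen_id)
  for (nm in names(out)) attr(out[[nm]], "seed") <- seed
  out
}

#' Write a synthetic study to disk
#'
#' Emits the CSV dialects the analysis functions consume plus a
#' ground-truth JSON ledger; the seed is embedded in every file.
#'
#' @param study A list from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("mechanics", "swelling", "dry")) {
    df <- study[[nm]]
    df$seed <- attr(study[[nm]], "seed")
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
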