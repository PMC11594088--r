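#' Run the full hydrogel assay
#'
#' Orchestrates the complete analysis for every specimen present in the
#' swelling table: swelling ratios and first-order kinetics (both scales),
#' composition algebra from the dry-state sidecar, hyperelastic fits (NH
#' and AB) per time point with Drucker pre-screening, per-cycle hysteresis,
#' network structural parameters, the normalised-modulus scaling exponent,
#' and the equilibrium-swelling solution for \eqn{\chi} (equilibrium
#' composition extrapolated from the kinetic fits, not taken from the last
#' measured time point). Per-specimen failures are isolated: the specimen
#' is reported with `NA`s and an entry in `warnings`, and the run
#' continues.
#'
#' @param mechanics Tidy cycle table (see [check_cycle_data()]).
#' @param swelling Tibble with columns `specimen_id`, `time_h`, `mass_g`,
#'   `volume_cm3`, `density_g_cm3`.
#' @param dry Tibble with columns `specimen_id`, `dry_mass_g`,
#'   `rho_p_g_cm3`.
#' @param temperature Absolute temperature, K.
#' @param Mm Solvent molar mass, g mol^-1 (saline media are treated as
#'   water).
#' @param nu_source Which model's strand density feeds the equilibrium
#'   solver, `"NH"` (default) or `"AB"`.
#' @param cycle_policy,n_grid Loading-arm reduction, see [loading_arm()].
#' @param density_tol Relative tolerance of the `density_g_cm3` vs
#'   `mass_g/volume_cm3` cross-check (warning, not error).
#' @return An object of class `assay_report`: a list of tibbles `summary`
#'   (one row per specimen, reporting-scale units: `nu0` in 10^6 um^-3,
#'   mesh size in nm), `fits` (per specimen/time/model), `kinetics`,
#'   `composition` (per specimen/time), `hysteresis` (per
#'   specimen/time/cycle) and `warnings`.
#' @export
run_assay <- function(mechanics, swelling, dry,
                      temperature = 293.15, Mm = 18.015,
                      nu_source = c("NH", "AB"),
                      cycle_policy = "average", n_grid = 100,
                      density_tol = 0.02) {
  nu_source <- match.arg(nu_source)
  check_cycle_data(mechanics)
  warnings <- list()
  note <- function(id, stage, msg) {
    warnings[[length(warnings) + 1]] <<-
      tibble(specimen_id = id, stage = stage, message = msg)
  }
  fits <- list(); kin <- list(); comp <- list(); summ <- list()
  hyst <- tryCatch(cycle_hysteresis(mechanics),
                   error = function(e) {
                     note(NA_character_, "hysteresis", conditionMessage(e))
                     tibble()
                   })
  for (id in unique(swelling$specimen_id)) {
    sw <- dplyr::arrange(dplyr::filter(swelling, .data$specimen_id == id),
                         .data$time_h)
    dr <- dplyr::filter(dry, .data$specimen_id == id)
    me <- dplyr::filter(mechanics, .data$specimen_id == id)
    row <- tryCatch(
      assay_one(id, sw, dr, me, temperature, Mm, nu_source, cycle_policy,
                n_grid, density_tol, note),
      error = function(e) {
        note(id, "assay", conditionMessage(e))
        NULL
      }
    )
    if (is.null(row)) next
    fits[[id]] <- row$fits; kin[[id]] <- row$kinetics
    comp[[id]] <- row$composition; summ[[id]] <- row$summary
  }
  structure(
    list(
      summary = dplyr::bind_rows(summ),
      fits = dplyr::bind_rows(fits),
      kinetics = dplyr::bind_rows(kin),
      composition = dplyr::bind_rows(comp),
      hysteresis = hyst,
      warnings = dplyr::bind_rows(warnings)
    ),
    class = "assay_report"
  )
}

# full analysis of one specimen; errors propagate to run_assay's isolation
assay_one <- function(id, sw, dr, me, temperature, Mm, nu_source,
                      cycle_policy, n_grid, density_tol, note) {
  if (nrow(sw) < 3) abort("need at least 3 swelling time points")
  if (nrow(dr) != 1) abort("need exactly one dry-state row")
  if (sw$time_h[1] != 0) abort("swelling series must start at t = 0")
  bad_rho <- abs(sw$density_g_cm3 - sw$mass_g / sw$volume_cm3) >
    density_tol * sw$density_g_cm3
  if (any(bad_rho)) {
    note(id, "swelling",
         sprintf("density inconsistent with mass/volume at t = %s h",
                 paste(sw$time_h[bad_rho], collapse = ", ")))
  }
  m0 <- sw$mass_g[1]; V0 <- sw$volume_cm3[1]
  q <- swelling_ratios(m0, sw$mass_g, V0, sw$volume_cm3)
  kin_qv <- fit_kinetics(sw$time_h, q$Qv, scale = "Qv")
  kin_qm <- fit_kinetics(sw$time_h, q$Qm, scale = "Qm")
  if (!kin_qv$converged) note(id, "kinetics", "Qv kinetics fit flagged")

  phi_p0 <- (dr$dry_mass_g / dr$rho_p_g_cm3) / V0
  omega_p <- dr$dry_mass_g / sw$mass_g
  cmp <- composition_from_drying(sw$density_g_cm3, dr$rho_p_g_cm3, omega_p)
  mol <- molar_properties(cmp$rho_s, Mm)
  composition <- dplyr::bind_cols(
    tibble(specimen_id = id, time_h = sw$time_h, Qm = q$Qm, Qv = q$Qv),
    cmp, mol
  )

  # hyperelastic fits per time point (Drucker failures excluded)
  fit_rows <- list()
  for (t in sort(unique(me$time_h))) {
    mt <- dplyr::filter(me, .data$time_h == t)
    for (model in c("NH", "AB")) {
      f <- tryCatch(
        if (model == "NH") {
          fit_nh(mt, temperature = temperature,
                 cycle_policy = cycle_policy, n_grid = n_grid)
        } else {
          fit_ab(mt, temperature = temperature,
                 cycle_policy = cycle_policy, n_grid = n_grid)
        },
        error = function(e) {
          note(id, paste0("fit_", tolower(model)),
               sprintf("t = %g h: %s", t, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(f)) next
      if (!f$drucker$pass) {
        note(id, "drucker",
             sprintf("t = %g h: loading arm fails stability screen (%.1f%% increments), excluded from fits",
                     t, 100 * f$drucker$fraction_violating))
        next
      }
      fit_rows[[paste(t, model)]] <-
        dplyr::bind_cols(tibble(specimen_id = id, time_h = t), glance(f))
    }
  }
  fits <- dplyr::bind_rows(fit_rows)

  # equilibrium extrapolation and chi
  Qv_eq <- kin_qv$Q_eq
  tau_h <- kin_qv$tau
  chi <- NA_real_; phi_peq <- NA_real_; V1_eq <- NA_real_
  nu0_nh <- NA_real_; nu0_ab <- NA_real_
  xi_nm <- NA_real_; friction <- NA_real_; scaling <- NA_real_
  if (nrow(fits) > 0) {
    t0 <- min(fits$time_h)
    g0 <- dplyr::filter(fits, .data$time_h == t0)
    nu0_nh <- g0$nu[g0$model == "NH"][1]
    nu0_ab <- g0$nu[g0$model == "AB"][1]
    nh_series <- dplyr::filter(fits, .data$model == "NH", .data$converged)
    if (nrow(nh_series) >= 3) {
      qv_at <- approx(sw$time_h, q$Qv, xout = nh_series$time_h, rule = 2)$y
      scaling <- tryCatch(
        modulus_scaling_exponent(nh_series$G, qv_at),
        error = function(e) NA_real_
      )
    }
  }
  if (Qv_eq > 0 && is.finite(Qv_eq)) {
    phi_peq <- phi_evolution(phi_p0, Qv_eq)
    m_eq <- m0 * (1 + kin_qm$Q_eq / 100)
    V_eq <- V0 * Qv_eq / 100
    eq_comp <- tryCatch(
      composition_from_drying(m_eq / V_eq, dr$rho_p_g_cm3,
                              dr$dry_mass_g / m_eq),
      error = function(e) {
        note(id, "equilibrium", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(eq_comp)) {
      V1_eq <- molar_properties(eq_comp$rho_s, Mm)$V1
      nu0 <- if (nu_source == "NH") nu0_nh else nu0_ab
      if (is.finite(nu0) && phi_peq < 1) {
        st <- equilibrium_state(phi_p0, phi_peq, nu0, V1_eq,
                                specimen_id = id, nu_source = nu_source,
                                temperature = temperature)
        sol <- chi_from_equilibrium(st)
        chi <- sol$chi
        if (!is.na(sol$warning)) note(id, "chi", sol$warning)
      } else {
        note(id, "chi", "no usable strand density or phi_peq = 1; chi not computed")
      }
      if (is.finite(nu0_nh)) {
        ns <- network_structure(nu0_nh, cmp$rho_s[1], "NH")
        xi_nm <- ns$xi_nm; friction <- ns$friction_proxy
      }
    }
  }
  list(
    fits = fits,
    kinetics = dplyr::mutate(
      dplyr::bind_rows(glance(kin_qv), glance(kin_qm)),
      specimen_id = id, .before = 1
    ),
    composition = composition,
    summary = tibble(
      specimen_id = id,
      Qv_eq = Qv_eq, tau_h = tau_h,
      phi_p0 = phi_p0, phi_peq = phi_peq,
      nu0_NH_um3e6 = nu0_nh / 1e24, nu0_AB_um3e6 = nu0_ab / 1e24,
      V1_eq = V1_eq, chi = chi, xi_nm = xi_nm,
      friction_proxy = friction, scaling_exponent = scaling
    )
  )
}

#' @export
print.assay_report <- function(x, ...) {
  cat("<assay_report>\n")
  cat(sprintf("  %d specimen(s); %d fit(s); %d warning(s)\n",
              nrow(x$summary), nrow(x$fits), nrow(x$warnings)))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Reference structural parameters for eight alginate/ADA-gelatin gels
#'
#' Published average structural parameters of eight alginate-gelatin and
#' oxidised-alginate (ADA) gelatin hydrogel formulations spanning physical
#' blends, ionically, enzymatically and covalently (Schiff-base)
#' cross-linked networks, measured by gas pycnometry and unconfined cyclic
#' compression: equilibrium volumetric swelling ratio (%), initial and
#' equilibrium polymer volume fractions, initial strand number densities
#' fitted with the Neo-Hookean and eight-chain models (10^6 um^-3 scale),
#' equilibrium solvent molar volume (cm^3 mol^-1) and the reported
#' polymer-solvent interaction parameter.
#'
#' @return A tibble with one row per formulation.
#' @examples
#' gels <- reference_gels()
#' st <- equilibrium_state(gels$phi_p0, gels$phi_peq,
#'                         gels$nu0_NH_um3e6 * 1e24, gels$V1_eq)
#' chi_from_equilibrium(st)
#' @export
reference_gels <- function() {
  path <- system.file("extdata", "reference_gels.csv", package = "gelassay",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}

#' Read mechanics / swelling / dry-state CSV files
#'
#' Thin readers mapping the on-disk column dialect (`stress_pa`) onto the
#' package's tidy formats.
#'
#' @param path CSV file path.
#' @return A tibble in the corresponding tidy format.
#' @export
read_cycles_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("stress_pa" %in% names(df)) df <- dplyr::rename(df, stress = "stress_pa")
  check_cycle_data(df)
}

#' @rdname read_cycles_csv
#' @export
read_swelling_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
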