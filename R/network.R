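#' Strand number density from a fitted shear modulus
#'
#' Rubber elasticity ties the shear modulus to the number density of
#' elastically active network strands: \eqn{G_{NH} = \nu k_B T} for the
#' affine Gaussian network and \eqn{G_{AB} = \nu k_B T / 3} for the
#' eight-chain model, hence \eqn{\nu = G/(k_B T)} (NH) or
#' \eqn{\nu = 3G/(k_B T)} (AB).
#'
#' @param G Shear modulus in Pa.
#' @param temperature Absolute temperature in K.
#' @param model `"NH"` or `"AB"`.
#' @return Strand number density in m^-3.
#' @export
nu_from_G <- function(G, temperature = 293.15, model = c("NH", "AB")) {
  model <- match.arg(model)
  if (any(G <= 0)) abort("`G` must be > 0")
  if (temperature <= 0) abort("`temperature` must be > 0")
  fac <- if (model == "NH") 1 else 3
  fac * G / (.kB * temperature)
}

#' Polymer-network structural parameters from strand density
#'
#' In the ideal homogeneous cubic-lattice picture each cross-link joins two
#' strands, \eqn{c = \nu/2}, and the mesh size is the side of the
#' representative cube, \eqn{\xi = c^{-1/3}}. The polymer-solvent friction
#' proxy follows the blob-scale relation \eqn{f \propto \rho_s \xi^{-2}}
#' and is reported as \eqn{\rho_s \xi^{-2}} in SI units (kg m^-5) without
#' a viscosity calibration, hence "proxy".
#'
#' @param nu Strand number density in m^-3.
#' @param rho_s Viscous-phase (interstitial fluid) density in g cm^-3.
#' @param model_source `"NH"` or `"AB"`, recorded in the output.
#' @return A tibble with `nu` (m^-3), `c` (m^-3), `xi` (m), `xi_nm`,
#'   `friction_proxy` (kg m^-5) and `model_source`; one row per input.
#' @export
network_structure <- function(nu, rho_s, model_source = c("NH", "AB")) {
  model_source <- match.arg(model_source)
  if (any(nu <= 0)) abort("`nu` must be > 0")
  if (any(rho_s <= 0)) abort("`rho_s` must be > 0")
  c_dens <- nu / 2
  xi <- c_dens^(-1 / 3)
  tibble(
    nu = nu, c = c_dens, xi = xi, xi_nm = xi * 1e9,
    friction_proxy = rho_s * 1000 / xi^2, # g/cm^3 -> kg/m^3
    model_source = model_source
  )
}

#' Hysteresis: dissipated energy density of a loading-unloading cycle
#'
#' The area enclosed between the loading and unloading nominal stress-strain
#' curves over their common strain interval, i.e. the energy dissipated per
#' unit volume per cycle (\eqn{W_{diss} = \Delta U + \Delta Q}; the two
#' contributions are not separable from the loop area alone). Both arms are
#' linearly interpolated onto `n_grid` evenly spaced strains and integrated
#' by the trapezoidal rule. For physically ordered arms (loading above
#' unloading) the result is non-negative; crossing arms yield a signed sum
#' and a warning when negative.
#'
#' @param loading,unloading Data frames with columns `strain` and `stress`
#'   (compression magnitudes, Pa), at least 3 points each, overlapping in
#'   strain.
#' @param n_grid Number of integration grid points.
#' @return Dissipated energy density in J m^-3 (Pa per unit strain).
#' @examples
#' eps <- seq(0, 1, length.out = 50)
#' hysteresis(data.frame(strain = eps, stress = eps),
#'            data.frame(strain = eps, stress = eps^2)) # ~1/6
#' @export
hysteresis <- function(loading, unloading, n_grid = 200) {
  if (nrow(loading) < 3 || nrow(unloading) < 3) {
    abort("each arm needs at least 3 points")
  }
  lo <- max(min(loading$strain), min(unloading$strain))
  hi <- min(max(loading$strain), max(unloading$strain))
  if (hi <= lo) abort("loading and unloading arms do not overlap in strain")
  grid <- seq(lo, hi, length.out = n_grid)
  sl <- approx(loading$strain, loading$stress, xout = grid, ties = mean)$y
  su <- approx(unloading$strain, unloading$stress, xout = grid, ties = mean)$y
  area <- pracma::trapz(grid, sl - su)
  if (area < 0) {
    warn(sprintf("crossing arms: signed loop area is negative (%g J/m^3)", area))
  }
  area
}

#' Per-cycle hysteresis of a tidy cycle table
#'
#' Applies [hysteresis()] to every specimen/time point/cycle of a tidy
#' cycle table.
#'
#' @inheritParams check_cycle_data
#' @inheritParams hysteresis
#' @return A tibble with one row per specimen/time point/cycle and column
#'   `w_diss` (J m^-3).
#' @export
cycle_hysteresis <- function(data, n_grid = 200) {
  grp <- dplyr::group_by(data, .data$specimen_id, .data$time_h, .data$cycle)
  dplyr::summarise(
    grp,
    w_diss = hysteresis(
      data.frame(strain = .data$strain[.data$arm == "loading"],
                 stress = .data$stress[.data$arm == "loading"]),
      data.frame(strain = .data$strain[.data$arm == "unloading"],
                 stress = .data$stress[.data$arm == "unloading"]),
      n_grid = n_grid
    ),
    .groups = "drop"
  )
}

#' Scaling exponent of the normalised modulus against swelling
#'
#' Hydrogels obeying the isotropic-swelling scaling of Gaussian rubber
#' elasticity display \eqn{G/G_0 \approx Q_v^{-1/3}}. Given aligned series
#' of moduli and volumetric swelling ratios over time (with \eqn{G_0} the
#' modulus in the as-prepared state, \eqn{Q_v = 100\%} at \eqn{t_0}), the
#' exponent is estimated by least squares on
#' \eqn{\log(G/G_0) = a \log(Q_v/100)}.
#'
#' @param G Numeric vector of shear moduli (Pa), first element at
#'   \eqn{t_0}.
#' @param Qv Numeric vector of volumetric swelling ratios (%), aligned
#'   with `G`, first element 100.
#' @return The fitted exponent `a` (a single number; ~ -1/3 for data
#'   following the scaling).
#' @export
modulus_scaling_exponent <- function(G, Qv) {
  if (length(G) != length(Qv)) abort("`G` and `Qv` must be aligned")
  if (length(G) < 3) abort("need at least 3 time points")
  if (any(G <= 0) || any(Qv <= 0)) abort("`G` and `Qv` must be > 0")
  y <- log(G / G[1])
  x <- log(Qv / 100)
  keep <- abs(x) > 0 # the t0 point carries no information about the slope
  unname(coef(lm(y[keep] ~ 0 + x[keep]))[1])
}
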