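#' Mass and volumetric swelling ratios
#'
#' \eqn{Q_m = 100 (m_t - m_0)/m_0} and \eqn{Q_v = 100 \, V_t/V_0}: the two
#' conventional (deliberately asymmetric) definitions, so \eqn{Q_m = 0} and
#' \eqn{Q_v = 100\%} for the as-prepared state.
#'
#' @param m0,V0 Initial mass (g) and volume (cm^3), strictly positive.
#' @param mt,Vt Mass and volume during swelling.
#' @return A tibble with columns `Qm` and `Qv` (both in %).
#' @examples
#' swelling_ratios(1.0, 1.25, 0.50, 0.60) # Qm 25%, Qv 120%
#' @export
swelling_ratios <- function(m0, mt, V0, Vt) {
  if (any(m0 <= 0) || any(V0 <= 0)) abort("`m0` and `V0` must be > 0")
  if (any(mt <= 0) || any(Vt <= 0)) abort("`mt` and `Vt` must be > 0")
  tibble(Qm = 100 * (mt - m0) / m0, Qv = 100 * Vt / V0)
}

#' Fit first-order swelling kinetics
#'
#' Fits the saturating first-order law \eqn{Q(t) = Q_{eq}(1 - e^{-t/\tau})}
#' to a swelling series in order to predict equilibrium swelling (neglecting
#' degradation and fracture). The raw law vanishes at \eqn{t = 0}, which
#' matches the \eqn{Q_m} scale; on the \eqn{Q_v} scale (100% at \eqn{t_0})
#' the increment is fitted instead,
#' \eqn{Q(t) = 100 + (Q_{eq} - 100)(1 - e^{-t/\tau})}, so that
#' \eqn{Q(0) = 100} and \eqn{Q(\infty) = Q_{eq}}. De-swelling series
#' (decreasing \eqn{Q_v}, \eqn{Q_{eq} < 100}) are permitted. A constant
#' series leaves \eqn{\tau} unidentifiable and is returned flagged
#' (`converged = FALSE`, `tau = NA`).
#'
#' @param times Time points in hours (must include 0, at least 3 points).
#' @param Q Swelling ratios (%) aligned with `times`.
#' @param scale `"Qv"` or `"Qm"` (selects the baseline convention above).
#' @return An object of class `swelling_kinetics` with elements `Q_eq`,
#'   `tau` (h), `scale`, `rss`, `converged`, `n` and the input series.
#' @examples
#' t <- c(0, 24, 48, 72)
#' k <- fit_kinetics(t, 100 + 135 * (1 - exp(-t / 8)), scale = "Qv")
#' glance(k)
#' @export
fit_kinetics <- function(times, Q, scale = c("Qv", "Qm")) {
  scale <- match.arg(scale)
  if (length(times) != length(Q)) abort("`times` and `Q` must be aligned")
  if (length(times) < 3) abort("need at least 3 time points")
  if (!any(times == 0)) abort("`times` must include t = 0")
  base <- if (scale == "Qv") 100 else 0
  y <- Q - base
  new_kin <- function(Q_eq, tau, rss, converged) {
    structure(
      list(Q_eq = Q_eq, tau = tau, scale = scale, rss = rss,
           converged = converged, n = length(times),
           data = tibble(time_h = times, Q = Q)),
      class = "swelling_kinetics"
    )
  }
  amp <- mean(y[times == max(times)])
  if (sd(y) < 1e-12 || abs(amp) < 1e-12) {
    # flat series: Q_eq is the mean level, tau unidentifiable
    return(new_kin(mean(Q), NA_real_, sum((y - mean(y))^2), FALSE))
  }
  # initial tau from the earliest point with an appreciable increment
  fr <- pmin(pmax(y / amp, 0.05), 0.95)
  idx <- which(times > 0)[1]
  tau0 <- -times[idx] / log(1 - fr[idx])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(times) / 3
  res <- minpack.lm::nls.lm(
    par = c(A = amp, tau = tau0),
    lower = c(-Inf, 1e-9),
    fn = function(p) y - p[1] * (1 - exp(-times / p[2])),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 500)
  )
  new_kin(base + unname(res$par[1]), unname(res$par[2]),
          res$deviance, res$info %in% 1:4)
}

#' @export
print.swelling_kinetics <- function(x, ...) {
  cat(sprintf("<swelling_kinetics> %s scale\n", x$scale))
  cat(sprintf("  Q_eq = %.4g %%, tau = %.4g h (rss %.4g, n = %d)%s\n",
              x$Q_eq, x$tau, x$rss, x$n,
              if (!x$converged) " [flagged: not converged]" else ""))
  invisible(x)
}

#' @rdname fit_kinetics
#' @param x,object A `swelling_kinetics` object.
#' @param ... Unused.
#' @export
tidy.swelling_kinetics <- function(x, ...) {
  tibble(term = c("Q_eq", "tau"), estimate = c(x$Q_eq, x$tau),
         unit = c("%", "h"))
}

#' @rdname fit_kinetics
#' @export
glance.swelling_kinetics <- function(x, ...) {
  tibble(Q_eq = x$Q_eq, tau = x$tau, scale = x$scale, rss = x$rss,
         converged = x$converged, n = x$n)
}

#' @rdname fit_kinetics
#' @export
autoplot.swelling_kinetics <- function(object, ...) {
  base <- if (object$scale == "Qv") 100 else 0
  tau <- if (is.na(object$tau)) Inf else object$tau
  tt <- seq(0, max(object$data$time_h), length.out = 200)
  curve <- tibble(
    time_h = tt,
    Q = base + (object$Q_eq - base) * (1 - exp(-tt / tau))
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$Q)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, linetype = 2, colour = "#b2182b") +
    ggplot2::labs(x = "time [h]", y = sprintf("%s [%%]", object$scale),
                  title = sprintf("Q_eq = %.3g %%, tau = %.3g h",
                                  object$Q_eq, object$tau))
}

#' Hydrogel composition from drying measurements
#'
#' Given the hydrogel density \eqn{\rho_h}, the dry-polymer density
#' \eqn{\rho_p} and the polymer mass fraction \eqn{\omega_p} (dry mass over
#' hydrogel mass), the two-phase mixing rules
#' \eqn{\rho_h = \sum_i \rho_i \phi_i} and
#' \eqn{1/\rho_h = \sum_i \omega_i/\rho_i} determine the polymer volume
#' fraction \eqn{\phi_p = \omega_p \rho_h / \rho_p}, the viscous-phase
#' volume fraction \eqn{\phi_s = 1 - \phi_p} and the viscous-phase density
#' \eqn{\rho_s = (\rho_h - \rho_p \phi_p)/\phi_s}. Both mixing rules hold
#' on the output by construction.
#'
#' @param rho_h Hydrogel density, g cm^-3.
#' @param rho_p Dry polymer density, g cm^-3.
#' @param omega_p Polymer mass fraction in `[0, 1)`.
#' @return A tibble with `phi_p`, `phi_s`, `omega_p`, `rho_p`, `rho_s`;
#'   one row per input.
#' @export
composition_from_drying <- function(rho_h, rho_p, omega_p) {
  if (any(rho_h <= 0) || any(rho_p <= 0)) abort("densities must be > 0")
  if (any(omega_p < 0) || any(omega_p >= 1)) {
    abort("`omega_p` must lie in [0, 1): a hydrogel needs a viscous phase")
  }
  phi_p <- omega_p * rho_h / rho_p
  if (any(phi_p >= 1)) {
    abort("inconsistent measurement: polymer volume fraction >= 1")
  }
  phi_s <- 1 - phi_p
  rho_s <- (rho_h - rho_p * phi_p) / phi_s
  if (any(rho_s <= 0)) {
    abort("inconsistent measurement: non-positive viscous-phase density")
  }
  tibble(phi_p = phi_p, phi_s = phi_s, omega_p = omega_p,
         rho_p = rho_p, rho_s = rho_s)
}

#' Polymer volume fraction during swelling
#'
#' With degradation neglected the polymer volume is conserved while the
#' total volume scales by \eqn{Q_v/100} (isotropic swelling,
#' \eqn{\lambda = (Q_v/100)^{1/3} = (\phi_{p,0}/\phi_p)^{1/3}}), so
#' \eqn{\phi_p = \phi_{p,0} \cdot 100 / Q_v}, capped at 1.
#'
#' @param phi_p0 Initial polymer volume fraction in (0, 1).
#' @param Qv Volumetric swelling ratio in % (> 0).
#' @return Polymer volume fraction at the given swelling state.
#' @export
phi_evolution <- function(phi_p0, Qv) {
  if (any(phi_p0 <= 0) || any(phi_p0 >= 1)) abort("`phi_p0` must be in (0, 1)")
  if (any(Qv <= 0)) abort("`Qv` must be > 0")
  pmin(1, phi_p0 * 100 / Qv)
}

#' Molar properties of the interstitial fluid
#'
#' Average solvent molar volume \eqn{V_1 = M_m/\rho_s} and molecular number
#' density \eqn{n_M = N_A \rho_s / M_m = N_A / V_1}. For free water
#' (\eqn{\rho_s = 0.9982} g cm^-3, \eqn{M_m = 18.015} g mol^-1) this gives
#' \eqn{n_M \approx 3.337 \times 10^{22}} cm^-3. Bound water, being denser,
#' raises \eqn{n_M} and lowers \eqn{V_1}.
#'
#' @param rho_s Viscous-phase density, g cm^-3.
#' @param Mm Solvent molar mass, g mol^-1 (default: water).
#' @return A tibble with `V1` (cm^3 mol^-1) and `nM` (cm^-3).
#' @examples
#' molar_properties(0.9982)
#' @export
molar_properties <- function(rho_s, Mm = 18.015) {
  if (any(rho_s <= 0) || any(Mm <= 0)) abort("inputs must be > 0")
  tibble(V1 = Mm / rho_s, nM = .NAv * rho_s / Mm)
}
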