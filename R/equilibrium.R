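#' Mixing chemical potential bracket
#'
#' The Flory-Huggins mixing contribution to the solvent chemical potential,
#' in units of \eqn{k_B T N_A / V_1} factored out:
#' \eqn{\phi_p + \ln(1 - \phi_p) + \chi \phi_p^2}. For
#' \eqn{\phi_p < 10^{-4}} the \eqn{\chi}-independent part is evaluated by
#' its series \eqn{-\phi^2/2 - \phi^3/3 - \phi^4/4} to avoid catastrophic
#' cancellation in \eqn{\phi + \ln(1 - \phi)}.
#'
#' @param phi_p Polymer volume fraction in `[0, 1)`.
#' @param chi Polymer-solvent interaction parameter.
#' @return Dimensionless mixing potential, 0 in the pure-solvent limit.
#' @export
mu_mix <- function(phi_p, chi) {
  if (any(phi_p < 0) || any(phi_p >= 1)) abort("`phi_p` must lie in [0, 1)")
  base <- ifelse(
    phi_p < 1e-4,
    -phi_p^2 / 2 - phi_p^3 / 3 - phi_p^4 / 4,
    phi_p + log1p(-phi_p)
  )
  base + chi * phi_p^2
}

#' Elastic chemical potential bracket of an affine network
#'
#' Elastic contribution of an affine network, in the same normalisation as
#' [mu_mix()]:
#' \deqn{\mu_{el} = \frac{\nu V_1 \times 10^{-6}}{N_A}
#'   \left[\left(\frac{\phi_p}{\phi_{p,0}}\right)^{1/3}
#'   - \frac{1}{2}\frac{\phi_p}{\phi_{p,0}}\right],}
#' from the isotropic swelling stretch
#' \eqn{\lambda = (\phi_{p,0}/\phi_p)^{1/3}} relative to the as-prepared
#' reference state. `nu` in m^-3 and `V1` in cm^3 mol^-1 combine into a
#' dimensionless prefactor through the factor \eqn{10^{-6}/N_A}.
#'
#' @param phi_p Current polymer volume fraction in (0, 1].
#' @param phi_p0 Reference (as-prepared) polymer volume fraction in (0, 1].
#' @param nu Strand number density to use, m^-3 (see
#'   [chi_from_equilibrium()] for the density convention at equilibrium).
#' @param V1 Solvent molar volume, cm^3 mol^-1.
#' @return Dimensionless elastic potential; equals
#'   \eqn{\nu V_1 10^{-6} / (2 N_A)} in the unswollen state and vanishes
#'   for an uncross-linked network.
#' @export
mu_el <- function(phi_p, phi_p0, nu, V1) {
  if (any(phi_p <= 0) || any(phi_p0 <= 0) || any(phi_p > 1) || any(phi_p0 > 1)) {
    abort("`phi_p` and `phi_p0` must lie in (0, 1]")
  }
  if (any(nu < 0) || any(V1 <= 0)) abort("`nu` must be >= 0 and `V1` > 0")
  r <- phi_p / phi_p0
  (nu * V1 * 1e-6 / .NAv) * (r^(1 / 3) - r / 2)
}

#' Construct an equilibrium-swelling state table
#'
#' Light validating constructor for the input of [chi_from_equilibrium()].
#'
#' @param phi_p0 Initial polymer volume fraction(s), (0, 1].
#' @param phi_peq Equilibrium polymer volume fraction(s), (0, 1).
#' @param nu0 Initial strand number density, m^-3 (as fitted in the
#'   as-prepared state).
#' @param V1 Equilibrium solvent molar volume, cm^3 mol^-1.
#' @param specimen_id Optional labels.
#' @param nu_source `"NH"` (default; the affine equilibrium-swelling
#'   relation is a Gaussian-network construct) or `"AB"`.
#' @param temperature Absolute temperature in K (metadata only: the
#'   normalised brackets are temperature-free).
#' @return A tibble with one row per state.
#' @export
equilibrium_state <- function(phi_p0, phi_peq, nu0, V1,
                              specimen_id = NULL,
                              nu_source = c("NH", "AB"),
                              temperature = 293.15) {
  nu_source <- match.arg(nu_source)
  if (any(phi_p0 <= 0) || any(phi_p0 > 1)) abort("`phi_p0` must be in (0, 1]")
  if (any(phi_peq <= 0) || any(phi_peq >= 1)) abort("`phi_peq` must be in (0, 1)")
  if (any(nu0 <= 0)) abort("`nu0` must be > 0")
  if (any(V1 <= 0)) abort("`V1` must be > 0")
  tibble(
    specimen_id = specimen_id %||% paste0("state_", seq_along(phi_p0)),
    phi_p0 = phi_p0, phi_peq = phi_peq, nu0 = nu0, V1 = V1,
    nu_source = nu_source, temperature = temperature
  )
}

# Elastic bracket at equilibrium under the package's density convention:
# the strand density entering the per-solvent-molecule potential is the
# density in the swollen state, nu0 * phi/phi0 (nu0 is measured per
# as-prepared volume; strands dilute as the gel swells). See the methods
# vignette for why this convention, not the undiluted one, reproduces
# published reference tables.
elastic_at_equilibrium <- function(phi_p, phi_p0, nu0, V1) {
  mu_el(phi_p, phi_p0, nu0 * phi_p / phi_p0, V1)
}

#' Polymer-solvent interaction parameter from an equilibrium state
#'
#' Solves the affine-network equilibrium-swelling balance for \eqn{\chi}.
#' At swelling equilibrium the mixing and elastic brackets balance,
#' \eqn{\mu_{mix}(\phi_{p,eq}, \chi) = \mu_{el,eq}(\phi_{p,eq})}, and since
#' the balance is linear in \eqn{\chi} the solution is closed-form:
#' \deqn{\chi = \frac{-(\phi_{p,eq} + \ln(1-\phi_{p,eq})) +
#'   \mu_{el,eq}}{\phi_{p,eq}^2}.}
#' The elastic bracket uses the swollen-state strand density
#' \eqn{\nu_0 \phi_{p,eq}/\phi_{p,0}} (see [mu_el()]); under this
#' convention the elastic correction is non-negative for swollen gels, so
#' \eqn{\chi} is the mixing-only (theta-balance) value plus a cross-linking
#' correction. A cancellation warning is attached for
#' \eqn{\phi_{p,eq} < 10^{-4}}.
#'
#' @param state A data frame as returned by [equilibrium_state()] (columns
#'   `phi_p0`, `phi_peq`, `nu0`, `V1`, optionally `specimen_id`).
#' @return A tibble with one row per state: `chi`, `mixing_term` (the
#'   chi-independent mixing bracket magnitude), `elastic_term`,
#'   `elastic_fraction` (share of `chi` contributed by the elastic
#'   correction), `residual` (balance residual at the returned `chi`,
#'   checked `< 1e-12`), and `warning` (`NA` or a message).
#' @examples
#' st <- equilibrium_state(phi_p0 = 0.135, phi_peq = 0.133,
#'                         nu0 = 3.943e24, V1 = 17.737)
#' chi_from_equilibrium(st)
#' @export
chi_from_equilibrium <- function(state) {
  need <- c("phi_p0", "phi_peq", "nu0", "V1")
  miss <- setdiff(need, names(state))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  phi <- state$phi_peq
  if (any(phi >= 1)) abort("`phi_peq` must be < 1")
  mix0 <- mu_mix(phi, 0)                 # phi + ln(1 - phi), < 0
  el <- elastic_at_equilibrium(phi, state$phi_p0, state$nu0, state$V1)
  chi <- (-mix0 + el) / phi^2
  residual <- abs(mu_mix(phi, chi) - el)
  if (any(residual >= 1e-12)) {
    abort("internal error: equilibrium balance residual exceeds 1e-12")
  }
  tibble(
    specimen_id = state$specimen_id %||% paste0("state_", seq_along(phi)),
    chi = chi,
    mixing_term = -mix0,
    elastic_term = el,
    elastic_fraction = (el / phi^2) / chi,
    residual = residual,
    warning = ifelse(
      phi < 1e-4,
      "phi_peq < 1e-4: chi dominated by cancellation-prone mixing bracket",
      NA_character_
    )
  )
}

#' Equilibrium polymer fraction from a given interaction parameter
#'
#' Inverts the equilibrium-swelling balance: finds the polymer volume
#' fraction \eqn{\phi_p} at which
#' \eqn{\mu_{mix}(\phi_p, \chi) - \mu_{el,eq}(\phi_p) = 0}, using the same
#' swollen-state density convention as [chi_from_equilibrium()] so the two
#' functions are mutual inverses. Roots are bracketed on a dense grid over
#' \eqn{(10^{-8}, \min(1.5\,\phi_{p,0}, 1 - 10^{-8}))}, refined by
#' [stats::uniroot()] and polished by Newton steps; when several roots
#' exist the one closest to \eqn{\phi_{p,0}} is returned and the
#' multiplicity is reported.
#'
#' @param chi Interaction parameter (finite).
#' @param phi_p0 Initial polymer volume fraction in (0, 1].
#' @param nu0 Initial strand number density, m^-3.
#' @param V1 Solvent molar volume, cm^3 mol^-1.
#' @return A one-row tibble with `phi_peq`, `Qv_eq` (the implied
#'   equilibrium volumetric swelling ratio, %), `n_roots` and `residual`.
#' @export
phi_eq_from_chi <- function(chi, phi_p0, nu0, V1) {
  stopifnot(length(chi) == 1, length(phi_p0) == 1, length(nu0) == 1,
            length(V1) == 1)
  if (!is.finite(chi)) abort("`chi` must be finite")
  if (phi_p0 <= 0 || phi_p0 > 1) abort("`phi_p0` must be in (0, 1]")
  if (nu0 < 0 || V1 <= 0) abort("`nu0` must be >= 0 and `V1` > 0")
  E <- nu0 * V1 * 1e-6 / .NAv
  f <- function(phi) {
    r <- phi / phi_p0
    mu_mix(phi, chi) - E * (r^(4 / 3) - r^2 / 2)
  }
  fprime <- function(phi) {
    r <- phi / phi_p0
    1 - 1 / (1 - phi) + 2 * chi * phi - (E / phi_p0) * (4 / 3 * r^(1 / 3) - r)
  }
  upper <- min(1.5 * phi_p0, 1 - 1e-8)
  grid <- exp(seq(log(1e-8), log(upper), length.out = 600))
  fg <- f(grid)
  flips <- which(fg[-1] * fg[-length(fg)] < 0)
  exact <- which(fg == 0)
  roots <- grid[exact]
  for (i in flips) {
    rt <- uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-14)$root
    roots <- c(roots, rt)
  }
  if (length(roots) == 0) {
    abort(sprintf(
      "no swelling equilibrium in (%.1e, %.4g): end-point residuals %.3e and %.3e",
      1e-8, upper, fg[1], fg[length(fg)]
    ))
  }
  # Newton polish to machine precision
  roots <- vapply(roots, function(rt) {
    for (k in 1:5) {
      step <- f(rt) / fprime(rt)
      if (!is.finite(step)) break
      rt_new <- rt - step
      if (rt_new <= 0 || rt_new >= 1) break
      rt <- rt_new
      if (abs(step) < 1e-16) break
    }
    rt
  }, numeric(1))
  best <- roots[which.min(abs(roots - phi_p0))]
  tibble(
    phi_peq = best,
    Qv_eq = 100 * phi_p0 / best,
    n_roots = length(roots),
    residual = abs(f(best))
  )
}
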