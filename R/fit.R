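#' Fit the Neo-Hookean model to compression cycles
#'
#' Identifies the shear modulus `G` by least squares on the (resampled,
#' cycle-reduced) loading arm returned by [loading_arm()]. Because the
#' Neo-Hookean nominal stress is linear in `G`, the least-squares minimiser
#' of \eqn{\sum_i (\sigma_i - G x_i)^2} with
#' \eqn{x_i = \lambda_i^{-2} - \lambda_i} is available in closed form and is
#' used directly. The strand number density \eqn{\nu = G/(k_B T)} is
#' reported alongside.
#'
#' @param data Tidy cycle table for a single specimen/time point (see
#'   [check_cycle_data()]); stress as compression magnitude in Pa.
#' @param temperature Absolute temperature in K (tests at 20 degC by
#'   default).
#' @param cycle_policy,n_grid Passed to [loading_arm()].
#' @param drucker_tolerance,drucker_threshold Passed to [drucker_check()].
#' @param drucker_points Resolution of the stability screen: the reduced
#'   loading arm is resampled to this many evenly spaced strains before
#'   incremental slopes are formed (coarser increments estimate the
#'   underlying slope rather than point noise; see the methods vignette).
#' @return An object of class `hyperelastic_fit`. Use [glance()] for a
#'   one-row summary, [tidy()] for parameters, [autoplot()] for a fit plot.
#' @seealso [fit_ab()]
#' @export
fit_nh <- function(data, temperature = 293.15,
                   cycle_policy = c("average", "first", "last"),
                   n_grid = 100,
                   drucker_tolerance = NULL, drucker_threshold = 0.05,
                   drucker_points = 11) {
  arm <- loading_arm(data, cycle_policy = cycle_policy, n_grid = n_grid)
  drucker <- drucker_check(coarsen_arm(arm, drucker_points),
                           tolerance = drucker_tolerance,
                           threshold = drucker_threshold)
  lam <- strain_to_stretch(arm$strain)
  x <- lam^-2 - lam                       # magnitude regressor, >= 0
  G <- sum(arm$stress * x) / sum(x^2)
  converged <- is.finite(G) && G > 0
  rss <- sum((arm$stress - G * x)^2)
  new_hyperelastic_fit(
    model = "NH", G = G, N = NA_real_, temperature = temperature,
    rss = rss, n_points = nrow(arm), converged = converged,
    at_bound = FALSE, drucker = drucker, arm = arm
  )
}

#' Fit the Arruda-Boyce (eight-chain) model to compression cycles
#'
#' Identifies `(G, N)` by trust-region (Levenberg-Marquardt) nonlinear least
#' squares on the reduced loading arm. `G` is initialised from the
#' Neo-Hookean fit divided by 3 (the Gaussian-limit correspondence) and `N`
#' from twice the squared maximum chain stretch; `N` is bounded below by the
#' squared maximum chain stretch so the inverse Langevin argument stays in
#' domain. A solution sitting on that bound is flagged via `at_bound`.
#' Supplying `fix_N` fits `G` alone (closed form, the model then being
#' linear in `G`).
#'
#' @inheritParams fit_nh
#' @param fix_N Optional fixed segment number; `Inf` fits the Gaussian
#'   limit.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults to
#'   `ftol = 1e-10`, `maxiter = 500`.
#' @return An object of class `hyperelastic_fit` with `lambda_lock =
#'   sqrt(N)` and \eqn{\nu = 3G/(k_B T)}.
#' @export
fit_ab <- function(data, temperature = 293.15,
                   cycle_policy = c("average", "first", "last"),
                   n_grid = 100, fix_N = NULL,
                   drucker_tolerance = NULL, drucker_threshold = 0.05,
                   drucker_points = 11,
                   control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)) {
  arm <- loading_arm(data, cycle_policy = cycle_policy, n_grid = n_grid)
  drucker <- drucker_check(coarsen_arm(arm, drucker_points),
                           tolerance = drucker_tolerance,
                           threshold = drucker_threshold)
  lam <- strain_to_stretch(arm$strain)
  lam_c <- chain_stretch(lam)
  ab_mag <- function(G, N) -ab_stress_vec(lam, G, N)
  if (!is.null(fix_N)) {
    f <- ab_mag(1, fix_N)
    G <- sum(arm$stress * f) / sum(f^2)
    rss <- sum((arm$stress - G * f)^2)
    return(new_hyperelastic_fit(
      model = "AB", G = G, N = fix_N, temperature = temperature,
      rss = rss, n_points = nrow(arm), converged = is.finite(G) && G > 0,
      at_bound = FALSE, drucker = drucker, arm = arm
    ))
  }
  N_min <- max(lam_c)^2 * (1 + 1e-8)
  x_nh <- lam^-2 - lam
  G0 <- sum(arm$stress * x_nh) / sum(x_nh^2) / 3
  start <- c(G = G0, N = max(2 * max(lam_c)^2, N_min * 1.5))
  res <- minpack.lm::nls.lm(
    par = start,
    lower = c(1e-12, N_min), upper = c(Inf, Inf),
    fn = function(p) arm$stress - ab_mag(p[1], p[2]),
    control = control
  )
  G <- unname(res$par[1]); N <- unname(res$par[2])
  new_hyperelastic_fit(
    model = "AB", G = G, N = N, temperature = temperature,
    rss = res$deviance, n_points = nrow(arm),
    converged = res$info %in% 1:4 && is.finite(G) && G > 0,
    at_bound = (N - N_min) < 1e-6 * N_min,
    drucker = drucker, arm = arm
  )
}

# ab_stress() for a stretch vector, tolerating near-locking by evaluating
# only in-domain points during optimisation (out-of-domain -> large residual)
ab_stress_vec <- function(stretch, G, N) {
  lam_c <- chain_stretch(stretch)
  if (is.infinite(N)) return(3 * G * (stretch - stretch^-2))
  y <- lam_c / sqrt(N)
  out <- rep(-1e12 * G, length(stretch)) # penalty outside locking domain
  ok <- y < 1
  out[ok] <- G * (sqrt(N) / lam_c[ok]) * inverse_langevin(y[ok]) *
    (stretch[ok] - stretch[ok]^-2)
  out
}

new_hyperelastic_fit <- function(model, G, N, temperature, rss, n_points,
                                 converged, at_bound, drucker, arm) {
  structure(
    list(
      model = model, G = G, N = N,
      nu = nu_from_G(G, temperature, model),
      lambda_lock = if (model == "AB") sqrt(N) else NA_real_,
      rss = rss, n_points = n_points, converged = converged,
      at_bound = at_bound, temperature = temperature,
      drucker = drucker, arm = arm
    ),
    class = "hyperelastic_fit"
  )
}

#' @export
print.hyperelastic_fit <- function(x, ...) {
  cat(sprintf("<hyperelastic_fit> %s model\n", x$model))
  cat(sprintf("  G      = %.4g Pa\n", x$G))
  if (x$model == "AB") {
    cat(sprintf("  N      = %.4g segments (locking stretch %.4g)\n",
                x$N, x$lambda_lock))
  }
  cat(sprintf("  nu     = %.4g m^-3 (%.4g x 10^6 um^-3)\n", x$nu, x$nu / 1e24))
  cat(sprintf("  rss    = %.4g Pa^2 on %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  cat(sprintf("  Drucker screen: %s (%.1f%% increments violating)\n",
              if (x$drucker$pass) "pass" else "FAIL",
              100 * x$drucker$fraction_violating))
  invisible(x)
}

#' @rdname fit_nh
#' @param x A `hyperelastic_fit` object.
#' @param ... Unused.
#' @export
tidy.hyperelastic_fit <- function(x, ...) {
  tibble(
    term = c("G", "N")[c(TRUE, x$model == "AB")],
    estimate = c(x$G, x$N)[c(TRUE, x$model == "AB")],
    unit = c("Pa", "segments")[c(TRUE, x$model == "AB")]
  )
}

#' @rdname fit_nh
#' @export
glance.hyperelastic_fit <- function(x, ...) {
  tibble(
    model = x$model, G = x$G, N = x$N, nu = x$nu,
    lambda_lock = x$lambda_lock, rss = x$rss, n_points = x$n_points,
    converged = x$converged, at_bound = x$at_bound,
    drucker_pass = x$drucker$pass
  )
}

#' @rdname fit_nh
#' @param object A `hyperelastic_fit` object.
#' @export
autoplot.hyperelastic_fit <- function(object, ...) {
  arm <- object$arm
  lam <- strain_to_stretch(arm$strain)
  fitted <- if (object$model == "NH") {
    -nh_stress(lam, object$G)
  } else {
    -ab_stress_vec(lam, object$G, object$N)
  }
  df <- tibble(strain = arm$strain, observed = arm$stress, fitted = fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::labs(
      x = "compressive strain [-]", y = "nominal stress [Pa]",
      title = sprintf("%s fit: G = %.3g Pa%s", object$model, object$G,
                      if (object$model == "AB") sprintf(", N = %.3g", object$N) else "")
    )
}
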