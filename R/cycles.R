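#' Validate a tidy table of compression cycles
#'
#' The package's canonical mechanics format is one row per sample point with
#' columns `specimen_id`, `time_h`, `cycle`, `arm` (`"loading"` or
#' `"unloading"`), `strain` (engineering compressive strain, dimensionless)
#' and `stress` (nominal compressive stress magnitude, Pa). Checks performed
#' per specimen/time point/cycle/arm:
#' * strain and stress present, equal length, at least 3 points;
#' * strain in `[0, 1)` (stretch \eqn{\lambda = 1-\epsilon \in (0,1]});
#' * first loading sample at \eqn{\lambda = 1} within `tol`;
#' * loading arms have non-decreasing strain, unloading arms non-increasing
#'   (i.e. \eqn{\lambda} monotone the other way).
#'
#' @param data Data frame of cycles in the format above.
#' @param tol Tolerance on the undeformed first loading sample.
#' @return `data` as a tibble, invisibly validated (errors on violation).
#' @export
check_cycle_data <- function(data, tol = 1e-6) {
  need <- c("specimen_id", "time_h", "cycle", "arm", "strain", "stress")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(data$arm %in% c("loading", "unloading"))) {
    abort("`arm` must be 'loading' or 'unloading'")
  }
  strain_to_stretch(data$strain) # domain check with index reporting
  grp <- dplyr::group_by(data, .data$specimen_id, .data$time_h, .data$cycle, .data$arm)
  chk <- dplyr::summarise(
    grp,
    n = dplyr::n(),
    first_ok = .data$arm[1] != "loading" | abs(.data$strain[1]) <= tol,
    mono_ok = if (.data$arm[1] == "loading") {
      all(diff(.data$strain) >= -tol)
    } else {
      all(diff(.data$strain) <= tol)
    },
    .groups = "drop"
  )
  if (any(chk$n < 3)) abort("each cycle arm needs at least 3 points")
  if (!all(chk$first_ok)) abort("first loading sample must be undeformed (strain 0)")
  if (!all(chk$mono_ok)) {
    abort("loading arms must have non-decreasing strain; unloading arms non-increasing")
  }
  as_tibble(data)
}

#' Extract a single loading arm for fitting
#'
#' Resamples the loading arm(s) of a set of cycles onto a common grid of
#' evenly spaced strains (linear interpolation) and reduces them according
#' to `cycle_policy`: the default `"average"` averages the stress of all
#' cycles point-wise, mirroring fits of average stress-strain responses;
#' `"first"`/`"last"` select a single cycle.
#'
#' @inheritParams check_cycle_data
#' @param cycle_policy One of `"average"`, `"first"`, `"last"`.
#' @param n_grid Number of strain grid points.
#' @return A tibble with columns `strain` and `stress` (compression
#'   magnitudes) of `n_grid` rows.
#' @export
loading_arm <- function(data, cycle_policy = c("average", "first", "last"),
                        n_grid = 100) {
  cycle_policy <- match.arg(cycle_policy)
  load <- dplyr::filter(data, .data$arm == "loading")
  if (nrow(load) == 0) abort("no loading-arm data")
  cycles <- sort(unique(load$cycle))
  if (cycle_policy == "first") cycles <- cycles[1]
  if (cycle_policy == "last") cycles <- cycles[length(cycles)]
  load <- dplyr::filter(load, .data$cycle %in% cycles)
  lo <- max(tapply(load$strain, load$cycle, min))
  hi <- min(tapply(load$strain, load$cycle, max))
  if (hi <= lo) abort("loading arms do not share a common strain range")
  grid <- seq(lo, hi, length.out = n_grid)
  per_cycle <- lapply(split(load, load$cycle), function(d) {
    approx(d$strain, d$stress, xout = grid, ties = mean)$y
  })
  tibble(strain = grid, stress = rowMeans(do.call(cbind, per_cycle)))
}

#' Drucker stability pre-screen of a loading arm
#'
#' A stable material response requires a non-negative incremental slope
#' \eqn{\Delta\sigma/\Delta\epsilon \ge 0} along the loading arm (stress and
#' strain taken as compression magnitudes). The check reports the fraction
#' of increments whose slope falls below `-tolerance` and passes when that
#' fraction does not exceed `threshold`. The defaults (tolerance 1% of the
#' maximum observed slope, threshold 5% of increments) make the screen
#' robust to instrument noise.
#'
#' @param arm Data frame with columns `strain` and `stress` for one loading
#'   arm (at least 3 points), e.g. from [loading_arm()].
#' @param tolerance Slope tolerance in Pa per unit strain; `NULL` (default)
#'   uses 1% of the maximum incremental slope.
#' @param threshold Maximum tolerated fraction of violating increments.
#' @return A one-row tibble with `fraction_violating`, `pass`, `tolerance`,
#'   and `n_increments`.
#' @export
drucker_check <- function(arm, tolerance = NULL, threshold = 0.05) {
  if (nrow(arm) < 3) abort("Drucker screen needs at least 3 points")
  slopes <- diff(arm$stress) / diff(arm$strain)
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) < 2) abort("Drucker screen needs at least 2 finite increments")
  if (is.null(tolerance)) tolerance <- 0.01 * max(abs(slopes))
  frac <- mean(slopes < -tolerance)
  tibble(
    fraction_violating = frac,
    pass = frac <= threshold,
    tolerance = tolerance,
    n_increments = length(slopes)
  )
}

# Resample an arm to a small number of evenly spaced rows so incremental
# slopes estimate the underlying derivative instead of point noise.
coarsen_arm <- function(arm, n_points) {
  if (nrow(arm) <= n_points) return(arm)
  arm[round(seq(1, nrow(arm), length.out = n_points)), ]
}
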