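#' Covered search area over time
#'
#' Partitions the periodic plane into quadratic patches of linear size
#' `delta_L` and marks, per step, the patch containing the immune-cell
#' center. The covered area is \eqn{A(t) = n_{vis}(t)\,\delta L^2} with
#' \eqn{n_{vis}(t)} the number of distinct patches visited up to time `t`.
#' With `delta_L` equal to the cell radius, marking only the center patch
#' (rather than the full disk footprint) is a sub-dominant simplification.
#'
#' @param trajectory data frame with folded coordinates `x`, `y` (e.g. the
#'   `immune_trajectory` of a `run_result`), or a two-column matrix.
#' @param delta_L patch size, \eqn{\mu m}.
#' @param L_sys linear system size, \eqn{\mu m}.
#' @return data frame with `step` (0-based), `n_vis` and `A`
#'   (\eqn{\mu m^2}), both non-decreasing.
#' @export
covered_area <- function(trajectory, delta_L = 10, L_sys = 1000) {
  xy <- if (is.data.frame(trajectory)) cbind(trajectory$x, trajectory$y)
        else matrix(trajectory, ncol = 2)
  stopifnot(all(xy >= 0), all(xy < L_sys))
  n_side <- ceiling(L_sys / delta_L)
  patch <- floor(xy[, 1] / delta_L) + n_side * floor(xy[, 2] / delta_L)
  n_vis <- cumsum(!duplicated(patch))
  data.frame(step = seq_along(n_vis) - 1, n_vis = n_vis,
             A = n_vis * delta_L^2)
}

#' Mean squared displacement over lag time
#'
#' \eqn{\bar{R^2}(\Delta t) = \langle(\vec r(t+\Delta t)-\vec r(t))^2\rangle_t},
#' time-averaged over all overlapping origins, computed on unwrapped
#' coordinates (no periodic folding).
#'
#' @param trajectory data frame with `x_unwrapped`, `y_unwrapped` columns,
#'   or a two-column matrix of unwrapped coordinates.
#' @return data frame with `lag` (steps, 1..T-1) and `R2`
#'   (\eqn{\mu m^2}).
#' @export
msd <- function(trajectory) {
  xy <- if (is.data.frame(trajectory))
    cbind(trajectory$x_unwrapped, trajectory$y_unwrapped)
  else matrix(trajectory, ncol = 2)
  T_len <- nrow(xy)
  if (T_len < 2) stop("trajectory must contain at least 2 positions")
  lags <- seq_len(T_len - 1)
  R2 <- vapply(lags, function(lag) {
    d <- xy[(lag + 1):T_len, , drop = FALSE] -
         xy[seq_len(T_len - lag), , drop = FALSE]
    mean(rowSums(d * d))
  }, numeric(1))
  data.frame(lag = lags, R2 = R2)
}

#' Momentary nearest-target distances along a run
#'
#' For each recorded step, the minimum-image distance from the immune cell
#' to its nearest live target. Steps with no live target are skipped.
#' Under blind search these distances follow the Rayleigh reference of
#' [rayleigh_nn_density()]; chemotactic steering shifts the mass toward
#' zero (localization at targets).
#'
#' @param result a `run_result` recorded with `record = TRUE`.
#' @param L_sys linear system size, \eqn{\mu m}; defaults to the folded
#'   coordinate range implied by the run.
#' @return numeric vector of nearest-target distances (\eqn{\mu m}), one
#'   per step with at least one live target.
#' @export
nearest_target_distances <- function(result, L_sys = 1000) {
  stopifnot(inherits(result, "run_result"), !is.null(result$immune_trajectory))
  it <- result$immune_trajectory
  out <- rep(NA_real_, nrow(it))
  for (i in seq_len(nrow(it))) {
    live <- which(result$alive[i, ])
    if (length(live) == 0) next
    pts <- cbind(result$target_x[i, live], result$target_y[i, live])
    out[i] <- min(min_image_distance(c(it$x[i], it$y[i]), pts, L_sys))
  }
  out[!is.na(out)]
}

#' Rayleigh reference density for nearest-neighbor distances
#'
#' For uncorrelated, uniformly random target positions at areal density
#' `rho_tar`, the nearest-neighbor distance has density
#' \eqn{p(d) = 2\pi\rho\, d\, e^{-\pi\rho d^2}}, with mean
#' \eqn{1/(2\sqrt{\rho})} and mode \eqn{1/\sqrt{2\pi\rho}}.
#'
#' @param rho_tar target density, \eqn{\mu m^{-2}}, positive.
#' @param d distance(s), \eqn{\mu m}, non-negative.
#' @return probability density value(s).
#' @export
rayleigh_nn_density <- function(rho_tar, d) {
  stopifnot(rho_tar > 0, all(d >= 0))
  2 * pi * rho_tar * d * exp(-pi * rho_tar * d^2)
}
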