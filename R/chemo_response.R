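#' Logistic stimulus-response function
#'
#' \eqn{logistic(x) = 1/(1+e^{-x})}, mapping an arbitrary sensor signal to a
#' probability. Used both for the migration-mode choice and for the
#' turn-direction choice.
#'
#' @param x numeric input(s).
#' @return probability value(s) in `(0, 1)`.
#' @export
logistic <- function(x) {
  1 / (1 + exp(-x))
}

#' Immune-cell strategy parameters
#'
#' The seven tunable parameters of the chemotactic response: the speed and
#' persistence of the normal migration mode (`v_N`, `eps_N`) and of the
#' approach mode (`v_A`, `eps_A`), the mode bias `c_A0`, the sensitivity
#' `c_A1` to temporal concentration differences (mode switching), and the
#' sensitivity `c_R1` to spatial left/right concentration differences
#' (turn steering). Per step the approach mode is chosen with probability
#' \eqn{logistic(c_{A0} + c_{A1}\Delta\rho^C)} and a right turn with
#' probability \eqn{logistic(c_{R1}\Delta\rho^{LR})}.
#'
#' The nominal optimization range of `c_A0` is `[-5, 5]`; the large value
#' 500 is accepted as an "always approach" override used by the pure
#' spatial-gradient strategy.
#'
#' @param v_N,v_A mode speeds, \eqn{\mu m}/min, in `[0, 6]`.
#' @param eps_N,eps_A mode persistences in `[0, 1]`.
#' @param c_A0 mode bias (dimensionless).
#' @param c_A1 temporal sensitivity, in `[-500, 500]`.
#' @param c_R1 spatial sensitivity, in `[-500, 500]`.
#' @return an object of class `strategy_params`.
#' @export
strategy_params <- function(v_N, eps_N, v_A, eps_A, c_A0, c_A1, c_R1) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop(sprintf("%s must lie in [%g, %g]", nm, lo, hi))
    as.numeric(x)
  }
  structure(list(
    v_N = chk(v_N, 0, 6, "v_N"), eps_N = chk(eps_N, 0, 1, "eps_N"),
    v_A = chk(v_A, 0, 6, "v_A"), eps_A = chk(eps_A, 0, 1, "eps_A"),
    c_A0 = chk(c_A0, -500, 500, "c_A0"),
    c_A1 = chk(c_A1, -500, 500, "c_A1"),
    c_R1 = chk(c_R1, -500, 500, "c_R1")),
    class = "strategy_params")
}

#' @export
print.strategy_params <- function(x, ...) {
  cat("Immune-cell strategy parameters\n")
  cat(sprintf("  normal mode:   v_N = %g um/min, eps_N = %g\n", x$v_N, x$eps_N))
  cat(sprintf("  approach mode: v_A = %g um/min, eps_A = %g\n", x$v_A, x$eps_A))
  cat(sprintf("  response: c_A0 = %g, c_A1 = %g, c_R1 = %g\n",
              x$c_A0, x$c_A1, x$c_R1))
  invisible(x)
}

#' Sensor memory for temporal gradient sensing
#'
#' Holds the central concentration reading of the previous step. Before the
#' first reading the temporal difference is defined as 0, so the mode prior
#' is \eqn{logistic(c_{A0})}.
#'
#' @return an object of class `sensor_state`.
#' @export
sensor_state <- function() {
  structure(list(rho_prev = NA_real_, initialized = FALSE),
            class = "sensor_state")
}

#' Temporal concentration difference at the cell center
#'
#' \eqn{\Delta\rho^C_n = \rho^C_n - \rho^C_{n-1}}; returns 0 on the first
#' call and updates the sensor memory.
#'
#' @param sensor a `sensor_state`.
#' @param rho_now current central density reading (non-negative).
#' @return list with `delta` (the temporal difference) and `sensor` (the
#'   updated memory).
#' @export
temporal_difference <- function(sensor, rho_now) {
  stopifnot(inherits(sensor, "sensor_state"), rho_now >= 0)
  delta <- if (sensor$initialized) rho_now - sensor$rho_prev else 0
  sensor$rho_prev <- rho_now
  sensor$initialized <- TRUE
  list(delta = delta, sensor = sensor)
}

#' Lateral sensor positions on the cell border
#'
#' The two spatial sensors sit on the left and right border of the cell
#' body, perpendicular to the heading of the previous step: offsets
#' \eqn{r_{imm}(\cos(\phi \pm \pi/2), \sin(\phi \pm \pi/2))}.
#'
#' @param center numeric length-2 cell-center position.
#' @param heading heading of the previous step (radians).
#' @param r_imm immune-cell radius (\eqn{\mu m}), positive.
#' @return list with `left` and `right` sensor positions.
#' @export
lateral_sensor_positions <- function(center, heading, r_imm) {
  if (r_imm <= 0) stop("r_imm must be positive")
  list(left  = center + r_imm * c(cos(heading + pi / 2), sin(heading + pi / 2)),
       right = center + r_imm * c(cos(heading - pi / 2), sin(heading - pi / 2)))
}

#' Spatial concentration difference between the lateral sensors
#'
#' \eqn{\Delta\rho^{LR}_n = \rho^R_n - \rho^L_n}: positive when the right
#' sensor sees the denser field.
#'
#' @param ctx a `field_context`.
#' @param left,right sensor positions from [lateral_sensor_positions()].
#' @return the signed spatial difference.
#' @export
spatial_difference <- function(ctx, left, right) {
  field_at(ctx, right) - field_at(ctx, left)
}

#' Choose the migration mode from the temporal gradient
#'
#' The approach mode `"A"` is drawn with probability
#' \eqn{logistic(c_{A0} + c_{A1}\Delta\rho^C)}, freshly each step
#' (memoryless two-mode switching); otherwise the normal mode `"N"`.
#'
#' @param params a `strategy_params`.
#' @param delta_C temporal concentration difference.
#' @return `"A"` or `"N"`.
#' @export
choose_mode <- function(params, delta_C) {
  q_A <- logistic(params$c_A0 + params$c_A1 * delta_C)
  if (runif(1) < q_A) "A" else "N"
}

#' Choose the turn sign from the spatial gradient
#'
#' A right (clockwise) turn, sign -1, is drawn with probability
#' \eqn{logistic(c_{R1}\Delta\rho^{LR})}; otherwise +1. With positive
#' sensitivity and a denser field on the right, right turns are favored, so
#' the cell steers toward the attractant.
#'
#' @param params a `strategy_params`.
#' @param delta_LR spatial concentration difference (right minus left).
#' @return -1 (right/clockwise) or +1 (left/counter-clockwise).
#' @export
choose_turn_sign <- function(params, delta_LR) {
  q_R <- logistic(params$c_R1 * delta_LR)
  if (runif(1) < q_R) -1 else 1
}
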