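#' Correlated-random-walk parameters
#'
#' A cell's discrete-time walk is governed by three parameters: the mean
#' step speed `v` (step widths are Rayleigh-distributed with mean `v`, and
#' with a 1-minute time step the step width in \eqn{\mu m} equals the speed
#' in \eqn{\mu m}/min), the directional persistence `eps` that bounds the
#' turning-angle magnitude, and the right-turn probability `q_R` (balanced
#' at 1/2 unless chemotactic steering biases it).
#'
#' @param v mean step speed, \eqn{\mu m}/min, non-negative.
#' @param eps persistence in `[-1, 1]`: +1 fully persistent (ballistic),
#'   0 isotropic (diffusive), -1 fully anti-persistent (reversing).
#' @param q_R probability of a right (clockwise, sign -1) turn.
#' @return an object of class `walk_params`.
#' @export
walk_params <- function(v, eps, q_R = 0.5) {
  if (!is.numeric(v) || v < 0) stop("v must be non-negative")
  if (!is.numeric(eps) || abs(eps) > 1) stop("eps must lie in [-1, 1]")
  if (!is.numeric(q_R) || q_R < 0 || q_R > 1) stop("q_R must lie in [0, 1]")
  structure(list(v = v, eps = eps, q_R = q_R), class = "walk_params")
}

#' Agent state on the periodic plane
#'
#' Position is stored twice: folded into `[0, L_sys)^2` for field and
#' contact geometry, and unwrapped (no periodic folding) for mean-squared
#' displacement analysis. The heading is the direction of the last step,
#' normalized to `[-pi, pi)`.
#'
#' @param position numeric length-2 folded position (\eqn{\mu m}).
#' @param heading heading angle in radians.
#' @param unwrapped numeric length-2 unwrapped position; defaults to
#'   `position`.
#' @param alive logical; targets are flagged dead once eliminated.
#' @return an object of class `agent_state`.
#' @export
agent_state <- function(position, heading = 0, unwrapped = position,
                        alive = TRUE) {
  stopifnot(length(position) == 2, length(unwrapped) == 2)
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading),
                 unwrapped = as.numeric(unwrapped),
                 alive = isTRUE(alive)),
            class = "agent_state")
}

#' Normalize an angle to `[-pi, pi)`
#'
#' @param phi angle(s) in radians.
#' @return normalized angle(s).
#' @export
wrap_angle <- function(phi) {
  phi - 2 * pi * floor((phi + pi) / (2 * pi))
}

#' Draw Rayleigh step widths with a given mean
#'
#' Step widths are Rayleigh-distributed with mean `v`, i.e. scale
#' \eqn{\sigma = v\sqrt{2/\pi}}; samples are generated as
#' \eqn{\sigma\sqrt{-2\log U}}. `v = 0` returns exact zeros.
#'
#' @param v mean step width (\eqn{\mu m}), non-negative.
#' @param n number of draws.
#' @return numeric vector of `n` step widths.
#' @export
draw_step_width <- function(v, n = 1) {
  if (v < 0) stop("v must be non-negative")
  v * sqrt(2 / pi) * sqrt(-2 * log(runif(n)))
}

#' Turning-angle bounds for a persistence parameter
#'
#' For `eps >= 0` the turning angle is uniform on
#' \eqn{(-(1-\epsilon)\pi, +(1-\epsilon)\pi)}; for `eps < 0` it is uniform on
#' \eqn{((1-|\epsilon|)\pi, (1+|\epsilon|)\pi)}, so reversals dominate.
#'
#' @param eps persistence in `[-1, 1]`.
#' @return numeric length-2 vector `(dphi_min, dphi_max)` in radians.
#' @export
turning_bounds <- function(eps) {
  if (abs(eps) > 1) stop("eps must lie in [-1, 1]")
  if (eps >= 0) {
    c(-(1 - eps) * pi, (1 - eps) * pi)
  } else {
    c((1 - abs(eps)) * pi, (1 + abs(eps)) * pi)
  }
}

#' Draw raw turning angles for a persistence parameter
#'
#' Uniform draws between the bounds of [turning_bounds()]; only the
#' magnitude of the draw enters the position update, with the sign applied
#' separately.
#'
#' @param eps persistence in `[-1, 1]`.
#' @param n number of draws.
#' @return numeric vector of angles (radians).
#' @export
draw_turning_angle <- function(eps, n = 1) {
  b <- turning_bounds(eps)
  b[1] + runif(n) * (b[2] - b[1])
}

#' Advance an agent by one correlated-random-walk step
#'
#' Draws a Rayleigh step width and a turning-angle magnitude, applies the
#' turn sign (either supplied by a chemotactic steering decision or drawn
#' with right-turn probability `q_R`), updates the heading
#' \eqn{\phi' = \phi + s\,|\Delta\phi|}, and advances both the folded and
#' the unwrapped position by \eqn{w(\cos\phi', \sin\phi')}.
#'
#' Consumes exactly two uniform variates (width, angle) plus one more when
#' the sign is drawn; the compiled simulation engine consumes the identical
#' sequence, so both produce the same trajectories from the same seed.
#'
#' @param state an `agent_state`.
#' @param params a `walk_params`.
#' @param L_sys linear system size (\eqn{\mu m}) for periodic folding.
#' @param sign_override optional turn sign (-1 or +1) chosen by spatial
#'   gradient steering; if `NULL` the sign is drawn from `q_R`.
#' @return the advanced `agent_state`.
#' @export
advance <- function(state, params, L_sys, sign_override = NULL) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "walk_params"))
  w <- draw_step_width(params$v, 1)
  dphi <- draw_turning_angle(params$eps, 1)
  if (is.null(sign_override)) {
    s <- if (runif(1) < params$q_R) -1 else 1
  } else {
    if (!sign_override %in% c(-1, 1)) stop("sign_override must be -1 or +1")
    s <- sign_override
  }
  phi <- wrap_angle(state$heading + s * abs(dphi))
  disp <- w * c(cos(phi), sin(phi))
  pos <- state$position + disp
  pos <- pos - L_sys * floor(pos / L_sys)
  agent_state(position = pos, heading = phi,
              unwrapped = state$unwrapped + disp, alive = state$alive)
}
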