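#' Solve the stationary radial chemoattractant kernel
#'
#' Each target cell emits a chemoattractant that diffuses (diffusivity `D`)
#' and decays at a constant rate `k`. In the fast-diffusion limit the
#' concentration cloud around an emitter is stationary, and its radial
#' profile \eqn{f(r)} outside the emitter radius satisfies the modified
#' Bessel equation of order zero,
#' \deqn{f'' + f'/r = (k/D)\, f,}
#' with boundary conditions \eqn{f(r_{tar}) = 1} (normalization at the cell
#' border) and \eqn{f(r \to \infty) = 0}. The decaying solution is found by a
#' shooting method: the profile is integrated outward with a fourth-order
#' Runge-Kutta scheme on a geometric radial grid, and the initial slope
#' \eqn{f'(r_{tar})} is bisected between trial values that make the solution
#' cross zero and trial values that make it diverge, until the tail at
#' `r_max` lies in `[0, 1e-8]`.
#'
#' The profile decays like \eqn{\exp(-r/L_{dif})} at large \eqn{r}, with
#' diffusion length \eqn{L_{dif} = \sqrt{D/k}}. Beyond the truncation radius
#' `r_max` (default \eqn{10 L_{dif}}) the kernel is defined as exactly zero;
#' the neglected mass is far below Monte-Carlo noise.
#'
#' @param D diffusivity of the attractant (\eqn{\mu m^2}/min).
#' @param k first-order decay rate of the attractant (1/min).
#' @param r_tar emitter (target-cell) radius (\eqn{\mu m}); the kernel is
#'   normalized to 1 at this radius.
#' @param r_max truncation radius (\eqn{\mu m}); must be at least
#'   \eqn{10\sqrt{D/k}}. Default \eqn{10\sqrt{D/k}}.
#' @param n_grid number of radial grid nodes (geometric spacing, denser near
#'   `r_tar`); at least 2000.
#' @param use_cache reuse a previously solved kernel for identical
#'   parameters.
#'
#' @return An object of class `attractant_kernel`: a list with `r_grid`,
#'   `f_values`, `L_dif`, `r_tar`, `r_max`, `D`, `k`.
#' @examples
#' K <- solve_kernel(D = 6000, k = 0.6, r_tar = 10)
#' K$L_dif            # 100 um
#' kernel_value(K, 10)  # 1 at the emitter border
#' @export
solve_kernel <- function(D, k, r_tar, r_max = NULL, n_grid = 2000,
                         use_cache = TRUE) {
  stopifnot(is.numeric(D), is.numeric(k), is.numeric(r_tar))
  if (D <= 0 || k <= 0 || r_tar <= 0)
    stop("D, k and r_tar must be strictly positive")
  L_dif <- sqrt(D / k)
  if (is.null(r_max)) r_max <- 10 * L_dif
  if (r_max < 10 * L_dif)
    stop("r_max must be at least 10*sqrt(D/k) so the profile has decayed")
  if (n_grid < 2000) stop("n_grid must be >= 2000")

  key <- paste(D, k, r_tar, r_max, n_grid, sep = "|")
  if (use_cache && !is.null(.kernel_cache[[key]]))
    return(.kernel_cache[[key]])

  r_grid <- r_tar * (r_max / r_tar)^(seq_len(n_grid) / n_grid)
  r_grid <- c(r_tar, r_grid[-n_grid], r_max)  # pin both endpoints exactly

  deriv <- function(r, y, parms) {
    list(c(y[2], (k / D) * y[1] - y[2] / r))
  }
  integrate_trial <- function(slope) {
    sol <- deSolve::ode(y = c(f = 1, fp = slope), times = r_grid,
                        func = deriv, parms = NULL, method = "rk4")
    sol[, "f"]
  }

  # Bisection on the initial slope: too-negative slopes drive f below zero,
  # too-shallow slopes let the growing Bessel mode dominate at the tail.
  s_lo <- -10  # crossing side
  s_hi <- 0    # diverging side
  f_lo <- integrate_trial(s_lo)
  if (!any(f_lo < 0))
    stop("shooting bracket invalid: lower slope does not cross zero")
  tail_tol <- 1e-8
  solution <- NULL
  for (iter in seq_len(200)) {
    s_mid <- (s_lo + s_hi) / 2
    f_mid <- integrate_trial(s_mid)
    if (any(f_mid < 0)) {
      s_lo <- s_mid
    } else {
      if (f_mid[length(f_mid)] <= tail_tol) {
        solution <- f_mid
        break
      }
      s_hi <- s_mid
    }
    if ((s_hi - s_lo) < 1e-16 * max(1, abs(s_lo))) break
  }
  if (is.null(solution))
    stop("shooting method failed to converge: tail at r_max not within [0, 1e-8]")

  kernel <- structure(
    list(r_grid = r_grid, f_values = solution,
         log_f = log(pmax(solution, 1e-300)),
         L_dif = L_dif, r_tar = r_tar, r_max = r_max, D = D, k = k),
    class = "attractant_kernel")
  if (use_cache) .kernel_cache[[key]] <- kernel
  kernel
}

#' @export
print.attractant_kernel <- function(x, ...) {
  cat("Stationary chemoattractant kernel\n")
  cat(sprintf("  D = %g um^2/min, k = %g /min  ->  L_dif = %g um\n",
              x$D, x$k, x$L_dif))
  cat(sprintf("  normalized f(r_tar = %g um) = 1, truncated at r_max = %g um\n",
              x$r_tar, x$r_max))
  cat(sprintf("  %d radial nodes, f(r_max) = %.3g\n",
              length(x$r_grid), x$f_values[length(x$f_values)]))
  invisible(x)
}

#' Evaluate the attractant kernel at radial distances
#'
#' Interpolates the tabulated stationary profile. Because the immune cell
#' center can never come closer to an emission point than the emitter radius,
#' distances below `r_tar` are clamped to the boundary value 1 (no
#' extrapolation); distances beyond `r_max` return exactly 0. In between the
#' profile is interpolated log-linearly in `f`, which is accurate for the
#' exponential tail.
#'
#' @param kernel an `attractant_kernel` from [solve_kernel()].
#' @param r radial distance(s), \eqn{\mu m}, non-negative.
#' @return dimensionless density value(s) in `[0, 1]`.
#' @export
kernel_value <- function(kernel, r) {
  stopifnot(inherits(kernel, "attractant_kernel"), is.numeric(r), all(r >= 0))
  out <- numeric(length(r))
  out[r < kernel$r_tar] <- 1
  mid <- r >= kernel$r_tar & r < kernel$r_max
  if (any(mid)) {
    out[mid] <- exp(approx(kernel$r_grid, kernel$log_f, xout = r[mid],
                           rule = 2)$y)
  }
  out
}

#' Minimum-image distance on the periodic plane
#'
#' Euclidean distance between two points on the \eqn{L_{sys} \times L_{sys}}
#' torus, measured to the nearest periodic copy. `b` may be a matrix of
#' points (one per row), giving a vector of distances.
#'
#' @param a numeric length-2 point.
#' @param b numeric length-2 point or an `n x 2` matrix.
#' @param L_sys linear system size (\eqn{\mu m}).
#' @return distance(s) in `[0, L_sys/sqrt(2)]`.
#' @export
min_image_distance <- function(a, b, L_sys) {
  b <- matrix(b, ncol = 2)
  dx <- b[, 1] - a[1]
  dy <- b[, 2] - a[2]
  dx <- dx - L_sys * floor(dx / L_sys + 0.5)
  dy <- dy - L_sys * floor(dy / L_sys + 0.5)
  sqrt(dx * dx + dy * dy)
}

#' Field context: live emitters plus kernel on a periodic plane
#'
#' Bundles the positions of the live (not yet eliminated) target cells with
#' the attractant kernel and the system size. Positions are folded into
#' `[0, L_sys)^2`.
#'
#' @param positions `n x 2` matrix of emitter positions (\eqn{\mu m}), or
#'   `NULL`/0-row for an empty field.
#' @param kernel an `attractant_kernel`.
#' @param L_sys linear system size (\eqn{\mu m}).
#' @return an object of class `field_context`.
#' @export
field_context <- function(positions, kernel, L_sys) {
  stopifnot(inherits(kernel, "attractant_kernel"), L_sys > 0)
  if (is.null(positions) || length(positions) == 0) {
    positions <- matrix(numeric(0), ncol = 2)
  } else {
    positions <- matrix(positions, ncol = 2)
    positions <- positions - L_sys * floor(positions / L_sys)
  }
  structure(list(positions = positions, kernel = kernel, L_sys = L_sys),
            class = "field_context")
}

#' Total chemoattractant density at a point
#'
#' The concentration kernels of the individual emitters add up linearly: the
#' total density at `p` is the sum over live targets of the kernel evaluated
#' at the minimum-image distance.
#'
#' @param ctx a `field_context`.
#' @param p numeric length-2 point (\eqn{\mu m}).
#' @return non-negative dimensionless density.
#' @export
field_at <- function(ctx, p) {
  stopifnot(inherits(ctx, "field_context"))
  if (nrow(ctx$positions) == 0) return(0)
  d <- min_image_distance(p, ctx$positions, ctx$L_sys)
  sum(kernel_value(ctx$kernel, d))
}

#' Export an attractant kernel as CSV
#'
#' Two columns (`r`, `f`) preceded by a single JSON header comment line
#' carrying `D`, `k`, `r_tar`, `r_max` and `L_dif` for reproducibility.
#'
#' @param kernel an `attractant_kernel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  header <- jsonlite::toJSON(
    list(D = kernel$D, k = kernel$k, r_tar = kernel$r_tar,
         r_max = kernel$r_max, L_dif = kernel$L_dif),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  write.csv(data.frame(r = kernel$r_grid, f = kernel$f_values),
            con, row.names = FALSE)
  invisible(path)
}

#' Import an attractant kernel written by [write_kernel_csv()]
#'
#' @param path CSV file path.
#' @return an `attractant_kernel`.
#' @export
read_kernel_csv <- function(path) {
  header_line <- readLines(path, n = 1)
  if (!startsWith(header_line, "# "))
    stop("missing JSON header line in kernel CSV")
  meta <- jsonlite::fromJSON(sub("^# ", "", header_line))
  tab <- read.csv(path, comment.char = "#")
  structure(
    list(r_grid = tab$r, f_values = tab$f,
         log_f = log(pmax(tab$f, 1e-300)),
         L_dif = meta$L_dif, r_tar = meta$r_tar, r_max = meta$r_max,
         D = meta$D, k = meta$k),
    class = "attractant_kernel")
}
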