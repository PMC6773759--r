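#' Parameter grid for strategy optimization
#'
#' Defines, for each free strategy parameter, the discrete values scanned
#' by the cyclic coordinate descent. Frozen parameters keep their preset
#' values. `default_parameter_grid()` returns the standard grids within the
#' allowed ranges (speeds in steps of 1 over `[0, 6]`, persistences in
#' steps of 0.1 over `[0, 1]`, mode bias in steps of 1 over `[-5, 5]`,
#' sensitivities over `{0, 5, 50, 500}` and, where negative values are
#' allowed, their sign mirrors) restricted to the free-parameter family of
#' a named strategy.
#'
#' @param ... named numeric vectors, one per free parameter, e.g.
#'   `parameter_grid(v_N = 0:6, eps_N = seq(0, 1, 0.25))`.
#' @return an object of class `parameter_grid` (named list of value
#'   vectors).
#' @export
parameter_grid <- function(...) {
  grids <- list(...)
  if (length(grids) == 0) stop("at least one free parameter is required")
  valid <- c("v_N", "eps_N", "v_A", "eps_A", "c_A0", "c_A1", "c_R1")
  if (is.null(names(grids)) || !all(names(grids) %in% valid))
    stop("grid names must be strategy parameter names")
  ranges <- list(v_N = c(0, 6), eps_N = c(0, 1), v_A = c(0, 6),
                 eps_A = c(0, 1), c_A0 = c(-5, 5),
                 c_A1 = c(-500, 500), c_R1 = c(-500, 500))
  for (nm in names(grids)) {
    v <- grids[[nm]]
    if (any(v < ranges[[nm]][1]) || any(v > ranges[[nm]][2]))
      stop(sprintf("grid for %s exceeds its allowed range", nm))
  }
  structure(grids, class = "parameter_grid")
}

#' @rdname parameter_grid
#' @param strategy strategy family name; selects which of the seven
#'   parameters are free (`"bls"`: v_N, eps_N; `"rms"`: + v_A, eps_A,
#'   c_A0; `"tgs"`: + c_A1 (non-negative); `"sgs"`: v_A, eps_A, c_R1;
#'   `"cgs"`: all seven).
#' @export
default_parameter_grid <- function(strategy = c("bls", "rms", "tgs",
                                                "sgs", "cgs")) {
  strategy <- match.arg(strategy)
  all_grids <- list(
    v_N = 0:6, eps_N = seq(0, 1, 0.1), v_A = 0:6, eps_A = seq(0, 1, 0.1),
    c_A0 = -5:5,
    c_A1 = c(0, 5, 50, 500),                     # non-negative: rising
                                                 # concentration must attract
    c_R1 = c(-500, -50, -5, 0, 5, 50, 500))
  free <- switch(strategy,
    bls = c("v_N", "eps_N"),
    rms = c("v_N", "eps_N", "v_A", "eps_A", "c_A0"),
    tgs = c("v_N", "eps_N", "v_A", "eps_A", "c_A0", "c_A1"),
    sgs = c("v_A", "eps_A", "c_R1"),
    cgs = c("v_N", "eps_N", "v_A", "eps_A", "c_A0", "c_A1", "c_R1"))
  do.call(parameter_grid, all_grids[free])
}

#' Grid-based cyclic coordinate descent on a noisy objective
#'
#' Maximizes `objective` over the discrete parameter grid by scanning one
#' coordinate at a time: within a sweep, each free parameter is scanned
#' over its full grid while the others are held at their incumbent values,
#' and the incumbent is updated to the scan argmax (ties keep the
#' incumbent, otherwise the lowest grid index wins). The method stops when
#' two consecutive sweeps return the identical parameter vector, or at
#' `max_sweeps`.
#'
#' For a Monte-Carlo objective built with [make_Q_objective()], all nodes
#' of a scan share the same run seeds (common random numbers), which makes
#' each scan's argmax deterministic and the incumbent objective
#' non-decreasing across sweeps.
#'
#' @param grid a [parameter_grid()].
#' @param objective function taking a named numeric vector (one entry per
#'   free parameter) and returning the scalar objective to maximize.
#' @param start optional named start values (defaults to each grid's first
#'   value).
#' @param max_sweeps sweep cap; reaching it without convergence flags the
#'   trace as unconverged.
#' @return an object of class `ccd_trace`: list with `best` (named vector),
#'   `best_value`, `converged`, `n_sweeps`, and `sweeps` (per-sweep best
#'   parameters and values).
#' @examples
#' g <- parameter_grid(v_N = 0:6, eps_N = seq(0, 1, 0.25))
#' tr <- ccd_optimize(g, function(p) -(p["v_N"] - 4)^2 - (p["eps_N"] - 0.5)^2)
#' tr$best
#' @export
ccd_optimize <- function(grid, objective, start = NULL, max_sweeps = 20) {
  stopifnot(inherits(grid, "parameter_grid"), is.function(objective))
  params <- vapply(grid, `[`, numeric(1), 1)
  if (!is.null(start)) {
    stopifnot(all(names(start) %in% names(params)))
    params[names(start)] <- start
  }
  incumbent_value <- objective(params)
  sweeps <- list()
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    prev <- params
    for (nm in names(grid)) {
      values <- grid[[nm]]
      scan <- vapply(values, function(v) {
        trial <- params
        trial[nm] <- v
        objective(trial)
      }, numeric(1))
      best_idx <- which.max(scan)
      inc_idx <- match(params[nm], values)
      # keep the incumbent on ties
      if (!is.na(inc_idx) && scan[inc_idx] >= scan[best_idx]) best_idx <- inc_idx
      params[nm] <- values[best_idx]
      incumbent_value <- scan[best_idx]
    }
    sweeps[[sweep]] <- list(params = params, value = incumbent_value)
    # stop when two subsequent sweeps return the same parameter set
    if (sweep >= 2 && identical(params, prev)) {
      converged <- TRUE
      break
    }
  }
  structure(list(best = params, best_value = incumbent_value,
                 converged = converged, n_sweeps = length(sweeps),
                 sweeps = sweeps),
            class = "ccd_trace")
}

#' @export
print.ccd_trace <- function(x, ...) {
  cat(sprintf("CCD trace: %d sweep(s), %s\n", x$n_sweeps,
              if (x$converged) "converged" else "sweep cap reached"))
  cat("  best:", paste(names(x$best), signif(x$best, 4), sep = " = ",
                       collapse = ", "), "\n")
  cat(sprintf("  objective = %.4g\n", x$best_value))
  invisible(x)
}

#' Build a Monte-Carlo search-efficiency objective for the optimizer
#'
#' Returns a closure mapping a named vector of free strategy parameters to
#' the estimated search efficiency Q of the resulting strategy under `cfg`.
#' Every evaluation reuses the same master seed, i.e. the same per-run
#' seeds (common random numbers), so that differences between grid nodes
#' reflect the parameters and not the Monte-Carlo noise.
#'
#' @param cfg a [scenario_config()]; frozen strategy parameters are taken
#'   from `cfg$strategy`.
#' @param N_runs runs per objective evaluation.
#' @param master_seed shared master seed for all evaluations.
#' @param engine simulation engine.
#' @return function(named numeric vector) -> Q estimate.
#' @export
make_Q_objective <- function(cfg, N_runs = 2e3, master_seed = 1,
                             engine = "cpp") {
  force(cfg); force(N_runs); force(master_seed); force(engine)
  function(params) {
    strat <- cfg$strategy
    strat[names(params)] <- as.list(unname(params))
    trial_cfg <- cfg
    trial_cfg$strategy <- do.call(strategy_params, strat[c(
      "v_N", "eps_N", "v_A", "eps_A", "c_A0", "c_A1", "c_R1")])
    estimate_Q(trial_cfg, N_runs = N_runs, master_seed = master_seed,
               engine = engine)$Q
  }
}
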