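#' Target ensemble specification
#'
#' Three ensembles are supported. `"mixed"` draws a fresh speed
#' `v_tar ~ U[0, 6]` and persistence `eps_tar ~ U[0, 1]` for every target in
#' every run, emulating a broad spectrum of target behaviors (the ensemble
#' strategies are optimized against). `"pure"` assigns the same fixed
#' `(v_tar, eps_tar)` to all targets. `"static"` places non-moving targets
#' at prescribed coordinates (a deterministic fixture for unit tests and
#' illustration).
#'
#' @param type one of `"mixed"`, `"pure"`, `"static"`.
#' @param v_tar,eps_tar fixed speed and persistence for the pure ensemble.
#' @param positions `n x 2` matrix of coordinates for the static ensemble.
#' @return an object of class `target_ensemble`.
#' @export
target_ensemble <- function(type = c("mixed", "pure", "static"),
                            v_tar = NULL, eps_tar = NULL, positions = NULL) {
  type <- match.arg(type)
  if (type == "pure") {
    if (is.null(v_tar) || is.null(eps_tar))
      stop("pure ensemble requires v_tar and eps_tar")
    if (v_tar < 0 || v_tar > 6) stop("v_tar must lie in [0, 6]")
    if (eps_tar < 0 || eps_tar > 1) stop("eps_tar must lie in [0, 1]")
  }
  if (type == "static") {
    if (is.null(positions)) stop("static ensemble requires positions")
    positions <- matrix(positions, ncol = 2)
  }
  structure(list(type = type, v_tar = v_tar, eps_tar = eps_tar,
                 positions = positions),
            class = "target_ensemble")
}

#' Scenario configuration
#'
#' Bundles all fixed system parameters with the target ensemble and the
#' immune-cell strategy. Defaults are the standard simulation parameters:
#' a 1000 um periodic box, 1 min time step, 100 min per run, 10 targets of
#' radius 10 um (target density \eqn{10^{-5}\,\mu m^{-2}}), attractant
#' diffusivity 6000 um^2/min and decay 0.6/min (diffusion length 100 um),
#' immune radius 10 um.
#'
#' @param L_sys linear system size, \eqn{\mu m}.
#' @param dt_sim simulation time step, min.
#' @param T_sim total simulated time per run, min.
#' @param N_tar initial number of targets (ignored for static ensembles,
#'   which take their count from the position list).
#' @param r_tar,r_imm target and immune cell radii, \eqn{\mu m}.
#' @param D,k attractant diffusivity (\eqn{\mu m^2}/min) and decay (1/min).
#' @param targets a [target_ensemble()].
#' @param strategy a [strategy_params()].
#' @param immune_start optional list with `position` and `heading` to pin
#'   the immune cell's initial state (otherwise drawn uniformly).
#' @param remove_on_contact if `TRUE` (the elimination scenario used for
#'   all search-efficiency numbers) a contacted target is removed
#'   immediately, together with its attractant cloud. If `FALSE`
#'   (observation scenario for trajectory diagnostics) targets persist
#'   through contact and keep emitting; `Q` then counts distinct targets
#'   contacted at least once.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(L_sys = 1000, dt_sim = 1, T_sim = 100,
                            N_tar = 10, r_tar = 10, r_imm = 10,
                            D = 6000, k = 0.6,
                            targets = target_ensemble("mixed"),
                            strategy = strategy_preset("bls"),
                            immune_start = NULL,
                            remove_on_contact = TRUE) {
  stopifnot(L_sys > 0, dt_sim > 0, T_sim > 0, N_tar >= 0,
            r_tar > 0, r_imm > 0, D > 0, k > 0,
            inherits(targets, "target_ensemble"),
            inherits(strategy, "strategy_params"))
  if (targets$type == "static") N_tar <- nrow(targets$positions)
  structure(list(L_sys = L_sys, dt_sim = dt_sim, T_sim = T_sim,
                 N_tar = N_tar, r_tar = r_tar, r_imm = r_imm,
                 D = D, k = k, targets = targets, strategy = strategy,
                 immune_start = immune_start,
                 remove_on_contact = isTRUE(remove_on_contact)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Pursuit scenario: %g x %g um box, %d targets, %g min (dt = %g)\n",
              x$L_sys, x$L_sys, x$N_tar, x$T_sim, x$dt_sim))
  cat(sprintf("  attractant: D = %g um^2/min, k = %g /min (L_dif = %g um)\n",
              x$D, x$k, sqrt(x$D / x$k)))
  cat(sprintf("  target ensemble: %s\n", x$targets$type))
  print(x$strategy)
  invisible(x)
}

#' Initialize one simulation run
#'
#' Draws, from the current RNG stream: the per-target migration parameters
#' (mixed ensemble), the immune cell's uniform position and heading, then
#' the target positions and headings. Any target initially within contact
#' range of the immune cell is re-placed so runs never start with a
#' zero-effort elimination; static (prescribed) positions are used as given.
#'
#' @param cfg a [scenario_config()].
#' @param max_retries resampling attempts for overlapping placements.
#' @return list with `immune` (an [agent_state()]), `targets` (a list of
#'   `agent_state`s) and `target_params` (a list of [walk_params()]).
#' @export
initialize_run <- function(cfg, max_retries = 1000) {
  stopifnot(inherits(cfg, "scenario_config"))
  N <- cfg$N_tar
  L <- cfg$L_sys
  ens <- cfg$targets

  if (ens$type == "mixed") {
    v_tar <- runif(N, 0, 6)
    eps_tar <- runif(N, 0, 1)
  } else if (ens$type == "pure") {
    v_tar <- rep(ens$v_tar, N)
    eps_tar <- rep(ens$eps_tar, N)
  } else {
    v_tar <- rep(0, N)
    eps_tar <- rep(0, N)
  }

  if (is.null(cfg$immune_start)) {
    imm_pos <- runif(2) * L
    imm_heading <- runif(1, -pi, pi)
  } else {
    imm_pos <- cfg$immune_start$position
    imm_heading <- cfg$immune_start$heading
  }

  contact_dist <- cfg$r_imm + cfg$r_tar
  if (ens$type == "static") {
    tar_pos <- ens$positions
  } else if (N > 0) {
    tar_pos <- cbind(runif(N) * L, runif(N) * L)
    for (i in seq_len(max_retries)) {
      bad <- min_image_distance(imm_pos, tar_pos, L) <= contact_dist
      if (!any(bad)) break
      tar_pos[bad, ] <- cbind(runif(sum(bad)) * L, runif(sum(bad)) * L)
      if (i == max_retries)
        stop("could not place targets outside contact range")
    }
  } else {
    tar_pos <- matrix(numeric(0), ncol = 2)
  }
  tar_heading <- if (N > 0) runif(N, -pi, pi) else numeric(0)

  list(
    immune = agent_state(imm_pos, imm_heading),
    targets = lapply(seq_len(N), function(c)
      agent_state(tar_pos[c, ], tar_heading[c])),
    target_params = lapply(seq_len(N), function(c)
      walk_params(v_tar[c], eps_tar[c], q_R = 0.5))
  )
}

#' Detect immune-target contacts
#'
#' A contact is established when the minimum-image center distance between
#' the immune cell and a live target is at most `r_imm + r_tar` (touching
#' disks; 20 um at the default radii), checked at the post-move
#' configuration of each step.
#'
#' @param immune_pos immune-cell position (length 2).
#' @param target_pos `n x 2` matrix of live-target positions.
#' @param r_imm,r_tar cell radii, \eqn{\mu m}.
#' @param L_sys linear system size, \eqn{\mu m}.
#' @return integer indices (rows of `target_pos`) of contacted targets.
#' @export
detect_contacts <- function(immune_pos, target_pos, r_imm, r_tar, L_sys) {
  if (is.null(target_pos) || length(target_pos) == 0) return(integer(0))
  target_pos <- matrix(target_pos, ncol = 2)
  which(min_image_distance(immune_pos, target_pos, L_sys) <= r_imm + r_tar)
}

#' Run one pursuit simulation
#'
#' Advances the system for `T_sim / dt_sim` steps. Per step, in order:
#' (1) all live targets take a correlated-random-walk step (unbiased turn
#' sign); (2) the immune cell reads the total attractant density at its
#' center, forms the temporal difference and chooses its migration mode;
#' reads its two lateral sensors (placed with the previous heading) and
#' chooses its turn sign from the spatial difference; (3) the immune cell
#' advances with the chosen mode's speed and persistence and the chosen
#' sign; (4) contacts are detected and contacted targets are removed (their
#' attractant cloud vanishes with them, as the field is stationary in the
#' fast-diffusion limit).
#'
#' The compiled engine (`engine = "cpp"`) and the pure-R reference engine
#' (`engine = "r"`) consume the RNG stream identically and produce the same
#' trajectories from the same seed; the compiled engine is used for
#' Monte-Carlo efficiency estimation.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @param record keep full trajectories (set `FALSE` for speed when only
#'   the eliminated-target count is needed).
#' @return an object of class `run_result`: list with `Q` (eliminated
#'   targets), `contact_events` (data frame: step, target, x, y),
#'   `immune_trajectory` (data frame: step, x, y, x_unwrapped, y_unwrapped,
#'   mode), `target_x`/`target_y`/`alive` (step-by-target matrices, `NA`
#'   after elimination) when `record = TRUE`, and `N_tar`.
#' @export
run_simulation <- function(cfg, seed = NULL, engine = c("cpp", "r"),
                           record = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  kernel <- solve_kernel(cfg$D, cfg$k, cfg$r_tar)
  init <- initialize_run(cfg)
  n_steps <- round(cfg$T_sim / cfg$dt_sim)
  if (engine == "cpp") {
    res <- run_engine_cpp(cfg, kernel, init, n_steps, record)
  } else {
    res <- run_engine_r(cfg, kernel, init, n_steps, record)
  }
  res$N_tar <- cfg$N_tar
  class(res) <- "run_result"
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Pursuit run: Q = %d of %d targets eliminated (%d contact events)\n",
              x$Q, x$N_tar, nrow(x$contact_events)))
  invisible(x)
}

run_engine_cpp <- function(cfg, kernel, init, n_steps, record) {
  N <- cfg$N_tar
  tar_pos <- if (N > 0)
    do.call(rbind, lapply(init$targets, `[[`, "position"))
  else matrix(numeric(0), ncol = 2)
  raw <- cpp_run_simulation(
    imm_pos = init$immune$position, imm_heading = init$immune$heading,
    tar_pos = tar_pos,
    tar_heading = vapply(init$targets, `[[`, numeric(1), "heading"),
    tar_v = vapply(init$target_params, `[[`, numeric(1), "v"),
    tar_eps = vapply(init$target_params, `[[`, numeric(1), "eps"),
    strat = unlist(cfg$strategy[c("v_N", "eps_N", "v_A", "eps_A",
                                  "c_A0", "c_A1", "c_R1")]),
    L_sys = cfg$L_sys, n_steps = as.integer(n_steps),
    contact_dist = cfg$r_imm + cfg$r_tar, r_imm = cfg$r_imm,
    kernel_r = kernel$r_grid, kernel_logf = kernel$log_f,
    kernel_rtar = kernel$r_tar, kernel_rmax = kernel$r_max,
    record = record, remove_on_contact = cfg$remove_on_contact)
  out <- list(
    Q = raw$Q,
    contact_events = data.frame(step = raw$contact_step,
                                target = raw$contact_target,
                                x = raw$contact_x, y = raw$contact_y))
  if (record) {
    out$immune_trajectory <- data.frame(
      step = 0:n_steps,
      x = raw$immune_trajectory[, 1], y = raw$immune_trajectory[, 2],
      x_unwrapped = raw$immune_trajectory[, 3],
      y_unwrapped = raw$immune_trajectory[, 4],
      mode = c("N", "A")[raw$mode + 1L])
    out$target_x <- raw$target_x
    out$target_y <- raw$target_y
    out$alive <- raw$alive
  }
  out
}

# Pure-R reference engine built from the exported module operations;
# validates the compiled engine step for step.
run_engine_r <- function(cfg, kernel, init, n_steps, record) {
  N <- cfg$N_tar
  L <- cfg$L_sys
  contact_dist <- cfg$r_imm + cfg$r_tar
  strat <- cfg$strategy
  mode_params <- list(N = walk_params(strat$v_N, strat$eps_N),
                      A = walk_params(strat$v_A, strat$eps_A))

  immune <- init$immune
  targets <- init$targets
  contacted <- rep(FALSE, N)
  sensor <- sensor_state()
  contacts <- data.frame(step = integer(0), target = integer(0),
                         x = numeric(0), y = numeric(0))
  if (record) {
    imm_traj <- matrix(NA_real_, n_steps + 1, 4)
    imm_traj[1, ] <- c(immune$position, immune$unwrapped)
    modes <- rep(NA_character_, n_steps + 1)
    tar_x <- matrix(NA_real_, n_steps + 1, max(N, 1))[, seq_len(N), drop = FALSE]
    tar_y <- tar_x
    alive_rec <- matrix(NA, n_steps + 1, max(N, 1))[, seq_len(N), drop = FALSE]
    for (c in seq_len(N)) {
      tar_x[1, c] <- targets[[c]]$position[1]
      tar_y[1, c] <- targets[[c]]$position[2]
      alive_rec[1, c] <- TRUE
    }
  }

  for (n in seq_len(n_steps)) {
    for (c in seq_len(N)) {
      if (!targets[[c]]$alive) next
      targets[[c]] <- advance(targets[[c]], init$target_params[[c]], L)
    }
    live <- vapply(targets, `[[`, logical(1), "alive")
    live_pos <- do.call(rbind, lapply(targets[live], `[[`, "position"))
    ctx <- field_context(live_pos, kernel, L)

    rho_C <- field_at(ctx, immune$position)
    td <- temporal_difference(sensor, rho_C)
    sensor <- td$sensor
    mode <- choose_mode(strat, td$delta)

    sensors <- lateral_sensor_positions(immune$position, immune$heading,
                                        cfg$r_imm)
    delta_LR <- spatial_difference(ctx, sensors$left, sensors$right)
    s_imm <- choose_turn_sign(strat, delta_LR)

    immune <- advance(immune, mode_params[[mode]], L, sign_override = s_imm)

    fresh <- which(live & !contacted)
    if (length(fresh) > 0) {
      fresh_pos <- do.call(rbind, lapply(targets[fresh], `[[`, "position"))
      hit <- detect_contacts(immune$position, fresh_pos, cfg$r_imm, cfg$r_tar, L)
      for (idx in fresh[hit]) {
        contacted[idx] <- TRUE
        if (cfg$remove_on_contact) targets[[idx]]$alive <- FALSE
        contacts <- rbind(contacts, data.frame(
          step = n, target = idx,
          x = targets[[idx]]$position[1], y = targets[[idx]]$position[2]))
      }
    }

    if (record) {
      imm_traj[n + 1, ] <- c(immune$position, immune$unwrapped)
      modes[n + 1] <- mode
      for (c in seq_len(N)) {
        alive_rec[n + 1, c] <- targets[[c]]$alive
        if (targets[[c]]$alive) {
          tar_x[n + 1, c] <- targets[[c]]$position[1]
          tar_y[n + 1, c] <- targets[[c]]$position[2]
        }
      }
    }
  }

  out <- list(Q = sum(contacted), contact_events = contacts)
  if (record) {
    out$immune_trajectory <- data.frame(
      step = 0:n_steps, x = imm_traj[, 1], y = imm_traj[, 2],
      x_unwrapped = imm_traj[, 3], y_unwrapped = imm_traj[, 4], mode = modes)
    out$target_x <- tar_x
    out$target_y <- tar_y
    out$alive <- alive_rec
  }
  out
}

#' Write run trajectories as tidy CSV
#'
#' One row per step per agent: `run_id, step, agent_id, role, x, y,
#' x_unwrapped, y_unwrapped, mode, alive`. Unwrapped coordinates and the
#' migration mode are recorded for the immune cell only.
#'
#' @param result a `run_result` recorded with `record = TRUE`.
#' @param path output CSV path.
#' @param run_id identifier written into the `run_id` column.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(result, path, run_id = 1) {
  stopifnot(inherits(result, "run_result"),
            !is.null(result$immune_trajectory))
  it <- result$immune_trajectory
  imm <- data.frame(run_id = run_id, step = it$step, agent_id = 0,
                    role = "immune", x = it$x, y = it$y,
                    x_unwrapped = it$x_unwrapped,
                    y_unwrapped = it$y_unwrapped,
                    mode = it$mode, alive = TRUE)
  rows <- list(imm)
  for (c in seq_len(ncol(result$target_x))) {
    rows[[c + 1]] <- data.frame(
      run_id = run_id, step = it$step, agent_id = c, role = "target",
      x = result$target_x[, c], y = result$target_y[, c],
      x_unwrapped = NA_real_, y_unwrapped = NA_real_, mode = NA_character_,
      alive = result$alive[, c])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
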