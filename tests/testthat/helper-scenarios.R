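# Shared fixtures: all built in code, standard parameters unless a test
# needs a deliberately small or degenerate system.

std_kernel <- function() solve_kernel(D = 6000, k = 0.6, r_tar = 10)

# blind-search strategy with chosen normal-mode parameters
bls_variant <- function(v_N, eps_N) {
  s <- strategy_preset("bls")
  strategy_params(v_N = v_N, eps_N = eps_N, v_A = s$v_A, eps_A = s$eps_A,
                  c_A0 = s$c_A0, c_A1 = s$c_A1, c_R1 = s$c_R1)
}

# a preset with its gradient sensitivities zeroed (blinded control)
blinded <- function(name) {
  s <- strategy_preset(name)
  strategy_params(v_N = s$v_N, eps_N = s$eps_N, v_A = s$v_A, eps_A = s$eps_A,
                  c_A0 = s$c_A0, c_A1 = 0, c_R1 = 0)
}

std_cfg <- function(strategy = strategy_preset("bls"), ...) {
  scenario_config(strategy = strategy, ...)
}

# homogeneous correlated random walk driven through advance()
simulate_walk <- function(n_steps, v, eps, L_sys = 1e9) {
  st <- agent_state(c(0, 0), heading = 0)
  p <- walk_params(v, eps)
  out <- matrix(NA_real_, n_steps + 1, 2)
  out[1, ] <- st$unwrapped
  for (i in seq_len(n_steps)) {
    st <- advance(st, p, L_sys)
    out[i + 1, ] <- st$unwrapped
  }
  out
}
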