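test_that("logistic response matches its closed form", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(-5), 1 / (1 + exp(5)))
  expect_equal(round(logistic(-5), 3), 0.007)
  expect_equal(round(logistic(2), 2), 0.88)
  x <- c(-5, -2, 0, 2, 5)
  expect_equal(logistic(x), 1 / (1 + exp(-x)))
  expect_true(all(diff(logistic(seq(-10, 10, 0.5))) > 0))
  expect_equal(logistic(c(-1000, 1000)), c(0, 1))  # saturation is finite
})

test_that("strategy parameter validation enforces the allowed ranges", {
  expect_error(strategy_params(7, 1, 3, 0.5, -5, 0, 0), "v_N")
  expect_error(strategy_params(6, 1.5, 3, 0.5, -5, 0, 0), "eps_N")
  expect_error(strategy_params(6, 1, 3, 0.5, -5, 600, 0), "c_A1")
  # the large always-approach bias used by spatial gradient sensing is legal
  expect_silent(strategy_params(3, 0.5, 6, 0.8, 500, 0, 500))
})

test_that("temporal difference is zero on the first reading, then exact", {
  s <- sensor_state()
  first <- temporal_difference(s, 0.2)
  expect_identical(first$delta, 0)
  second <- temporal_difference(first$sensor, 0.5)
  expect_equal(second$delta, 0.3)
  third <- temporal_difference(second$sensor, 0.1)
  expect_equal(third$delta, -0.4)
})

test_that("eliminating a target drops the field by its kernel contribution", {
  K <- std_kernel()
  pos <- rbind(c(300, 300), c(350, 300))
  p <- c(280, 300)
  with_both <- field_at(field_context(pos, K, 1000), p)
  without_second <- field_at(field_context(pos[1, , drop = FALSE], K, 1000), p)
  s <- sensor_state()
  s <- temporal_difference(s, with_both)$sensor
  after <- temporal_difference(s, without_second)
  expect_equal(after$delta, -kernel_value(K, 70), tolerance = 1e-12)
})

test_that("lateral sensors sit on the cell border perpendicular to heading", {
  sp <- lateral_sensor_positions(c(0, 0), heading = 0, r_imm = 10)
  expect_equal(sp$left, c(0, 10), tolerance = 1e-12)
  expect_equal(sp$right, c(0, -10), tolerance = 1e-12)
  sp2 <- lateral_sensor_positions(c(0, 0), heading = pi / 2, r_imm = 10)
  expect_equal(sp2$left, c(-10, 0), tolerance = 1e-12)
  expect_equal(sp2$right, c(10, 0), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    ctr <- runif(2, 0, 1000)
    h <- runif(1, -pi, pi)
    sp3 <- lateral_sensor_positions(ctr, h, 10)
    expect_equal(sqrt(sum((sp3$left - ctr)^2)), 10)
    expect_equal(sqrt(sum((sp3$right - ctr)^2)), 10)
    expect_equal(sum((sp3$right - sp3$left) * c(cos(h), sin(h))), 0,
                 tolerance = 1e-9)
  }
})

test_that("spatial difference is zero by symmetry and signed toward density", {
  K <- std_kernel()
  empty <- field_context(NULL, K, 1000)
  sp <- lateral_sensor_positions(c(500, 500), 0, 10)
  expect_identical(spatial_difference(empty, sp$left, sp$right), 0)

  ahead <- field_context(rbind(c(560, 500)), K, 1000)  # dead ahead: mirror
  expect_equal(spatial_difference(ahead, sp$left, sp$right), 0,
               tolerance = 1e-12)

  to_right <- field_context(rbind(c(520, 450)), K, 1000)
  expect_gt(spatial_difference(to_right, sp$left, sp$right), 0)
  to_left <- field_context(rbind(c(520, 550)), K, 1000)
  expect_lt(spatial_difference(to_left, sp$left, sp$right), 0)
})

test_that("mode choice follows the logistic of bias plus weighted gradient", {
  blind <- strategy_params(6, 1, 3, 0.5, c_A0 = -5, c_A1 = 0, c_R1 = 0)
  set.seed(61)
  modes <- replicate(2e4, choose_mode(blind, runif(1, -1, 1)))
  expect_lt(abs(mean(modes == "A") - logistic(-5)), 0.002)

  sens <- strategy_params(6, 0, 6, 1, c_A0 = 2, c_A1 = 500, c_R1 = 0)
  expect_true(all(replicate(50, choose_mode(sens, 0.1)) == "A"))
  expect_true(all(replicate(50, choose_mode(sens, -0.1)) == "N"))
})

test_that("turn sign follows the logistic of the lateral difference", {
  neutral <- strategy_params(6, 1, 3, 0.5, -5, 0, c_R1 = 0)
  set.seed(62)
  s <- replicate(2e4, choose_turn_sign(neutral, runif(1, -1, 1)))
  expect_equal(mean(s == -1), 0.5, tolerance = 0.01)

  steer <- strategy_params(3, 0.5, 6, 0.8, 500, 0, c_R1 = 500)
  expect_true(all(replicate(50, choose_turn_sign(steer, 0.05)) == -1))
  expect_true(all(replicate(50, choose_turn_sign(steer, -0.05)) == 1))
  expect_equal(mean(replicate(2e3, choose_turn_sign(steer, 0)) == -1), 0.5,
               tolerance = 0.04)
})

test_that("spatial gradient steering homes in on a single static target", {
  # started 50 um away, a spatial-gradient searcher with c_R1 = 500,
  # v_A = 6, eps_A = 0.8 reaches contact within 100 steps almost always
  sgs <- strategy_params(3, 0.5, 6, 0.8, c_A0 = 500, c_A1 = 0, c_R1 = 500)
  cfg <- scenario_config(
    strategy = sgs,
    targets = target_ensemble("static", positions = rbind(c(550, 500))),
    immune_start = list(position = c(500, 500), heading = pi / 2))
  hits <- vapply(1:100, function(s)
    run_simulation(cfg, seed = s, record = FALSE)$Q, integer(1))
  expect_gt(mean(hits == 1), 0.95)
})
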