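test_that("initialization is deterministic and respects the ensembles", {
  cfg <- std_cfg()
  set.seed(123); a <- initialize_run(cfg)
  set.seed(123); b <- initialize_run(cfg)
  expect_identical(a, b)
  expect_length(a$targets, 10)
  expect_true(all(vapply(a$targets, function(t)
    all(t$position >= 0 & t$position < 1000), logical(1))))
  # no target starts within contact range of the immune cell
  pos <- do.call(rbind, lapply(a$targets, `[[`, "position"))
  expect_true(all(min_image_distance(a$immune$position, pos, 1000) > 20))

  pure <- std_cfg(targets = target_ensemble("pure", v_tar = 2, eps_tar = 0.3))
  set.seed(5)
  init <- initialize_run(pure)
  expect_true(all(vapply(init$target_params, `[[`, numeric(1), "v") == 2))
  expect_true(all(vapply(init$target_params, `[[`, numeric(1), "eps") == 0.3))
})

test_that("mixed-ensemble draws have the uniform-distribution moments", {
  cfg <- std_cfg()
  set.seed(77)
  draws <- replicate(2000, {
    init <- initialize_run(cfg)
    c(mean(vapply(init$target_params, `[[`, numeric(1), "v")),
      mean(vapply(init$target_params, `[[`, numeric(1), "eps")))
  })
  expect_equal(mean(draws[1, ]), 3.0, tolerance = 0.05 / 3)  # E[U(0,6)]
  expect_equal(mean(draws[2, ]), 0.5, tolerance = 0.01)      # E[U(0,1)]
})

test_that("contact detection uses the touching-disk criterion inclusively", {
  expect_identical(detect_contacts(c(0, 0), rbind(c(20, 0)), 10, 10, 1000), 1L)
  expect_length(detect_contacts(c(0, 0), rbind(c(20.1, 0)), 10, 10, 1000), 0)
  # wrap-around contact and simultaneous double contact
  hits <- detect_contacts(c(1, 500), rbind(c(995, 500), c(15, 500), c(400, 400)),
                          10, 10, 1000)
  expect_identical(hits, c(1L, 2L))
  expect_length(detect_contacts(c(0, 0), NULL, 10, 10, 1000), 0)
})

test_that("compiled and reference engines produce identical runs", {
  for (preset in c("bls", "tgs", "sgs", "cgs")) {
    cfg <- std_cfg(strategy = strategy_preset(preset))
    for (seed in c(2, 17)) {
      a <- run_simulation(cfg, seed = seed, engine = "cpp")
      b <- run_simulation(cfg, seed = seed, engine = "r")
      expect_identical(a$Q, b$Q)
      expect_equal(a$immune_trajectory$x_unwrapped,
                   b$immune_trajectory$x_unwrapped, tolerance = 1e-9)
      expect_equal(a$immune_trajectory$mode, b$immune_trajectory$mode)
      expect_equal(a$contact_events$step, b$contact_events$step)
      expect_equal(a$target_x, b$target_x, tolerance = 1e-9)
    }
  }
})

test_that("re-running with the same seed reproduces the run exactly", {
  cfg <- std_cfg(strategy = strategy_preset("sgs"))
  a <- run_simulation(cfg, seed = 99)
  b <- run_simulation(cfg, seed = 99)
  expect_identical(a$Q, b$Q)
  expect_identical(a$immune_trajectory, b$immune_trajectory)
})

test_that("eliminated targets are removed and accounted consistently", {
  cfg <- std_cfg(strategy = strategy_preset("sgs"))
  for (seed in 1:10) {
    res <- run_simulation(cfg, seed = seed)
    expect_identical(nrow(res$contact_events), res$Q)  # contacts == kills
    expect_identical(sum(!res$alive[nrow(res$alive), ]), res$Q)
    expect_true(res$Q >= 0 && res$Q <= cfg$N_tar)
    # once eliminated, a target's position is no longer recorded
    for (i in seq_len(nrow(res$contact_events))) {
      tgt <- res$contact_events$target[i]
      stp <- res$contact_events$step[i]
      expect_true(all(is.na(res$target_x[(stp + 1):nrow(res$target_x), tgt])))
    }
  }
})

test_that("a blind searcher's trajectory is independent of the field", {
  # with c_A1 = c_R1 = 0 every decision is field-blind, so changing the
  # attractant decay (hence the kernel) must not change the trajectory
  cfg1 <- std_cfg(strategy = strategy_preset("bls"))
  cfg2 <- std_cfg(strategy = strategy_preset("bls"), k = 0.06)
  a <- run_simulation(cfg1, seed = 31)
  b <- run_simulation(cfg2, seed = 31)
  expect_equal(a$immune_trajectory$x_unwrapped, b$immune_trajectory$x_unwrapped)
  expect_equal(a$immune_trajectory$mode, b$immune_trajectory$mode)
})

test_that("degenerate scenarios behave as dictated by geometry", {
  # nothing moves: no contacts can ever occur
  still <- strategy_params(0, 0, 0, 0, -5, 0, 0)
  cfg <- std_cfg(strategy = still,
                 targets = target_ensemble("pure", v_tar = 0, eps_tar = 0))
  expect_identical(run_simulation(cfg, seed = 4, record = FALSE)$Q, 0L)

  # empty system is a valid run
  cfg0 <- std_cfg(N_tar = 0)
  res0 <- run_simulation(cfg0, seed = 4)
  expect_identical(res0$Q, 0L)
  expect_identical(nrow(res0$contact_events), 0L)

  # static pure(0,0) targets never move over the whole run
  cfgS <- std_cfg(targets = target_ensemble("pure", v_tar = 0, eps_tar = 0))
  resS <- run_simulation(cfgS, seed = 8)
  expect_true(all(apply(resS$target_x, 2, function(col)
    length(unique(col[!is.na(col)])) == 1)))
})

test_that("a ballistic blind searcher reaches a target placed dead ahead", {
  # 30 um ahead means 10 um to cover at Rayleigh-mean speed 6: contact
  # after about 2 steps in most seeds
  cfg <- std_cfg(
    strategy = strategy_preset("bls"),
    targets = target_ensemble("static", positions = rbind(c(530, 500))),
    immune_start = list(position = c(500, 500), heading = 0))
  first_contact <- vapply(1:50, function(s) {
    res <- run_simulation(cfg, seed = s)
    if (res$Q == 1) res$contact_events$step[1] else NA_integer_
  }, integer(1))
  expect_gt(mean(!is.na(first_contact)), 0.9)
  expect_lte(median(first_contact, na.rm = TRUE), 4)
})

test_that("trajectory CSV export is tidy and complete", {
  cfg <- std_cfg(N_tar = 3, strategy = strategy_preset("sgs"))
  res <- run_simulation(cfg, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(res, path)
  tab <- read.csv(path)
  expect_setequal(names(tab), c("run_id", "step", "agent_id", "role", "x", "y",
                                "x_unwrapped", "y_unwrapped", "mode", "alive"))
  expect_identical(nrow(tab), 101L * 4L)  # immune + 3 targets, steps 0..100
  expect_setequal(unique(tab$role), c("immune", "target"))
})
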