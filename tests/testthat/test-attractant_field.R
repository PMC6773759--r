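# The stationary kernel solves the modified Bessel equation of order zero,
# so K0(r/L_dif)/K0(r_tar/L_dif) is an independent closed-form oracle.

test_that("shooting solution matches the Bessel K0 closed form", {
  K <- std_kernel()
  expect_equal(K$L_dif, 100)
  r <- seq(10, 500, length.out = 400)
  oracle <- besselK(r / K$L_dif, 0) / besselK(K$r_tar / K$L_dif, 0)
  expect_lt(max(abs(kernel_value(K, r) - oracle) / oracle), 1e-4)
  # single-point interpolation contract away from the grid nodes
  expect_lt(abs(kernel_value(K, 200) -
                  besselK(2, 0) / besselK(0.1, 0)) /
              (besselK(2, 0) / besselK(0.1, 0)), 1e-3)
})

test_that("kernel satisfies its boundary, monotonicity and tail invariants", {
  K <- std_kernel()
  expect_identical(K$f_values[1], 1)
  expect_true(all(diff(K$f_values) < 0))
  expect_lt(K$f_values[length(K$f_values)], 1e-6)
  expect_gte(K$f_values[length(K$f_values)], 0)
  # exponential tail: log f affine in r with slope within 10% of -1/L_dif
  # (fitted between 4.5 and 8 diffusion lengths, past the algebraic
  # near-field correction and short of the truncation radius)
  r <- seq(4.5 * K$L_dif, 8 * K$L_dif, by = 5)
  slope <- coef(lm(log(kernel_value(K, r)) ~ r))[[2]]
  expect_lt(abs(slope - (-1 / K$L_dif)), 0.1 / K$L_dif)
})

test_that("larger diffusion lengths give pointwise larger profiles", {
  K50 <- solve_kernel(D = 6000, k = 6000 / 50^2, r_tar = 10)
  K100 <- std_kernel()
  K150 <- solve_kernel(D = 6000, k = 6000 / 150^2, r_tar = 10)
  r <- seq(15, 490, by = 5)
  expect_true(all(kernel_value(K50, r) < kernel_value(K100, r)))
  expect_true(all(kernel_value(K100, r) < kernel_value(K150, r)))
})

test_that("solver rejects invalid physical parameters", {
  expect_error(solve_kernel(D = -1, k = 0.6, r_tar = 10), "positive")
  expect_error(solve_kernel(D = 6000, k = 0, r_tar = 10), "positive")
  expect_error(solve_kernel(D = 6000, k = 0.6, r_tar = 10, r_max = 500),
               "r_max")
  expect_error(solve_kernel(D = 6000, k = 0.6, r_tar = 10, n_grid = 100),
               "n_grid")
})

test_that("kernel_value clamps below r_tar and truncates beyond r_max", {
  K <- std_kernel()
  expect_equal(kernel_value(K, K$r_tar), 1)
  expect_equal(kernel_value(K, 3), 1)  # inside the emitter body: clamped
  expect_identical(kernel_value(K, K$r_max + 1), 0)
  expect_identical(kernel_value(K, 1e6), 0)
})

test_that("minimum-image distance respects the torus geometry", {
  expect_equal(min_image_distance(c(0, 0), c(999, 0), 1000), 1)
  expect_equal(min_image_distance(c(5, 7), c(5, 7), 1000), 0)
  expect_equal(min_image_distance(c(0, 0), c(500, 500), 1000), 500 * sqrt(2))
  # never exceeds half the diagonal, symmetric, translation invariant
  set.seed(11)
  for (i in 1:50) {
    a <- runif(2) * 1000
    b <- runif(2) * 1000
    d <- min_image_distance(a, b, 1000)
    expect_lte(d, 1000 / sqrt(2) + 1e-9)
    expect_equal(d, min_image_distance(b, a, 1000))
    shift <- runif(2, -3000, 3000)
    expect_equal(min_image_distance(a + shift, b + shift, 1000), d,
                 tolerance = 1e-9)
  }
})

test_that("field superposition is additive and torus-symmetric", {
  K <- std_kernel()
  expect_equal(field_at(field_context(NULL, K, 1000), c(1, 2)), 0)

  p <- c(100, 100)
  one <- field_context(rbind(p + c(10, 0)), K, 1000)
  expect_equal(field_at(one, p), 1)  # one emitter at distance r_tar

  set.seed(21)
  pos <- cbind(runif(6) * 1000, runif(6) * 1000)
  ctx_all <- field_context(pos, K, 1000)
  total <- sum(vapply(seq_len(6), function(i)
    field_at(field_context(pos[i, , drop = FALSE], K, 1000), p), numeric(1)))
  expect_equal(field_at(ctx_all, p), total, tolerance = 1e-12)

  # two identical emitters at a common distance double the density
  two <- field_context(rbind(p + c(60, 0), p + c(0, 60)), K, 1000)
  expect_equal(field_at(two, p), 2 * kernel_value(K, 60), tolerance = 1e-12)

  # global translation modulo L_sys leaves the field unchanged
  shift <- c(431.7, -212.9)
  ctx_shift <- field_context(sweep(pos, 2, -shift), K, 1000)  # pos + shift
  expect_equal(field_at(ctx_shift, p + shift), field_at(ctx_all, p),
               tolerance = 1e-9)
})

test_that("kernel CSV round trip preserves the profile and metadata", {
  K <- std_kernel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel_csv(K, path)
  K2 <- read_kernel_csv(path)
  expect_equal(K2$r_grid, K$r_grid)
  expect_equal(K2$f_values, K$f_values)
  expect_equal(K2$L_dif, K$L_dif)
  expect_equal(K2$D, K$D)
  expect_equal(kernel_value(K2, 123.4), kernel_value(K, 123.4))
})
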