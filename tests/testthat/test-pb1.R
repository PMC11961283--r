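boys <- pb1_reference_params("boys")
girls <- pb1_reference_params("girls")

test_that("PB1 curve satisfies its closed-form identities at the reference estimates", {
  ## h(c) = hc: the denominator equals 2 at t = c
  expect_equal(pb1_height(boys$c, boys), 162.24, tolerance = 1e-8)
  expect_equal(pb1_height(girls$c, girls), 138.70, tolerance = 1e-8)
  ## large-age limit is the adult height
  expect_equal(pb1_height(100, boys), 174.60, tolerance = 0.01)
  expect_equal(pb1_height(100, girls), 162.2, tolerance = 0.01)
  expect_equal(pb1_height(1e6, boys), 174.60, tolerance = 1e-6)
  ## independently computed value of the closed form at age 12
  direct <- function(t, p) p$h1 - 2 * (p$h1 - p$hc) /
    (exp(p$s0 * (t - p$c)) + exp(p$s1 * (t - p$c)))
  expect_equal(pb1_height(12, boys), direct(12, boys), tolerance = 1e-12)
  expect_equal(pb1_height(12, boys), 140.42, tolerance = 0.01)
})

test_that("PB1 curve is strictly increasing and overflow-safe", {
  g <- seq(7, 20, by = 0.01)
  for (p in list(boys, girls)) {
    h <- pb1_height(g, p)
    expect_true(all(diff(h) > 0))
    ## far above the spurt the dominant-exponential form avoids overflow
    expect_true(all(is.finite(pb1_height(c(50, 1e4), p))))
    expect_true(all(is.finite(pb1_velocity(c(-50, 50, 1e4), p))))
  }
})

test_that("analytic velocity matches the closed form at c and finite differences on a grid", {
  for (p in list(boys, girls)) {
    expect_equal(pb1_velocity(p$c, p), (p$h1 - p$hc) * (p$s0 + p$s1) / 2,
                 tolerance = 1e-9)
    g <- seq(8, 20, by = 0.1)
    h <- 1e-5
    vfd <- (pb1_height(g + h, p) - pb1_height(g - h, p)) / (2 * h)
    expect_lt(max(abs(pb1_velocity(g, p) - vfd)), 1e-6)
  }
  expect_equal(pb1_velocity(boys$c, boys), 5.414, tolerance = 1e-3)
  expect_lt(pb1_velocity(boys$c + 30, boys), 1e-3)
})

test_that("peak finder agrees with a brute-force grid search", {
  for (p in list(boys, girls)) {
    pk <- pb1_peak(p)
    grid <- seq(7, 20, by = 1e-4)
    v <- pb1_velocity(grid, p)
    i <- which.max(v)
    if (i > 1 && i < length(grid)) {
      expect_equal(pk$aphv, grid[i], tolerance = 2e-4)
      expect_equal(pk$phv, v[i], tolerance = 1e-6)
      expect_false(pk$boundary_flag)
    } else {
      expect_true(pk$boundary_flag)
    }
    expect_gte(pk$phv, pb1_velocity(p$c, p) - 1e-9)
    expect_gt(pk$phv, 0)
    expect_true(pk$aphv > 7 && pk$aphv < 20)
  }
})

test_that("equal rate constants degenerate to pure exponential approach", {
  ## with s0 = s1 = s the curve reduces to h1 - (h1 - hc) exp(-s (t - c)):
  ## velocity is monotone decreasing, so the maximum sits on the boundary
  p <- pb1_params(h1 = 175, hc = 160, s0 = 0.5, s1 = 0.5 + 1e-9, c = 13)
  g <- seq(7, 20, 0.1)
  expect_equal(pb1_height(g, p), 175 - 15 * exp(-0.5 * (g - 13)), tolerance = 1e-6)
  expect_warning(pk <- pb1_peak(p), "boundary")
  expect_true(pk$boundary_flag)
  expect_equal(pk$aphv, 7)
})

test_that("parameter constructor enforces the invariants", {
  expect_error(pb1_params(160, 170, 0.1, 0.8, 13), "h1 > hc")
  expect_error(pb1_params(175, 160, 0.8, 0.1, 13), "s1 > s0")
  expect_error(pb1_params(175, 160, 0.1, 0.8, 22), "midpuberty")
})

test_that("noiseless dense data are recovered to high accuracy", {
  set.seed(2)
  t <- rep(seq(8, 20, by = 0.25), 3)
  y <- pb1_height(t, boys)
  suppressWarnings(f <- fit_pb1(t, y))   # SEs may be unavailable at ~zero noise
  est <- unlist(unclass(f$params))
  tru <- unlist(unclass(boys))
  expect_true(all(abs(est - tru) / tru < 1e-4))
  expect_lt(f$residual_sd, 1e-3)
})

test_that("correlation matrix is a proper correlation matrix", {
  set.seed(3)
  t <- rep(c(8, 12, 15, 19), each = 100) + runif(400, -0.4, 0.4)
  y <- pb1_height(t, girls) + rnorm(400, 0, 3)
  f <- fit_pb1(t, y)
  co <- pb1_param_correlations(f)
  expect_equal(diag(co), rep(1, 5), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(co, t(co), tolerance = 1e-12)
  expect_true(all(abs(co) <= 1 + 1e-8))
})

test_that("degenerate zero-growth data raise a singular-information error", {
  set.seed(4)
  t <- rep(c(8, 12, 15, 19), each = 20)
  y <- rep(150, length(t))
  expect_error(fit_pb1(t, y), "no growth signal")
})

test_that("fits refuse too little data", {
  expect_error(fit_pb1(c(8, 9, 10), c(120, 125, 130)), "at least 25")
  expect_error(fit_pb1(seq(8, 9, length.out = 30), seq(120, 125, length.out = 30)),
               "8 years")
})
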