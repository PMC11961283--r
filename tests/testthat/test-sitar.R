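test_that("the age transform follows its definition", {
  expect_equal(sitar_transform(10, 0, 0), 10)
  expect_equal(sitar_transform(10, 1, log(2)), 18)
  expect_equal(sitar_transform(10, 1, -log(2)), 4.5)
  ## invertible: back-transform recovers the age
  t <- seq(-5, 5, by = 0.5)
  ts <- sitar_transform(t, 0.7, 0.12)
  expect_equal(ts * exp(-0.12) + 0.7, t, tolerance = 1e-12)
})

test_that("predictions respond to subject effects as the model prescribes", {
  f <- sitar_fit_small()
  g <- seq(9, 18, by = 0.5)
  base <- sitar_predict(f, g)
  ## size adds verticaly
  expect_equal(sitar_predict(f, g, alpha = 5), base + 5, tolerance = 1e-12)
  ## shape invariance round-trip: predictions at shifted/scaled ages map back
  beta <- 0.8; gamma <- 0.1
  x0 <- f$curve$xoffset
  g_star <- (g - x0 - beta) * exp(gamma) + x0
  expect_equal(sitar_predict(f, g, beta = beta, gamma = gamma),
               sitar_predict(f, g_star), tolerance = 1e-9)
})

test_that("velocity obeys the chain rule and matches finite differences", {
  f <- sitar_fit_small()
  g <- seq(9.5, 18, by = 0.25)
  h <- 1e-5
  vfd <- (sitar_predict(f, g + h) - sitar_predict(f, g - h)) / (2 * h)
  expect_lt(max(abs(sitar_velocity(f, g) - vfd)), 1e-5)
  ## gamma scales velocity at the corresponding transformed age
  gamma <- log(2)
  x0 <- f$curve$xoffset
  g_star <- (g - x0) * exp(gamma) + x0
  expect_equal(sitar_velocity(f, g, gamma = gamma),
               2 * sitar_velocity(f, g_star), tolerance = 1e-9)
})

test_that("velocity integrates back to the height increment", {
  f <- sitar_fit_small()
  inc <- stats::integrate(function(t) sitar_velocity(f, t), 8, 19,
                          rel.tol = 1e-9, subdivisions = 500L)$value
  expect_equal(inc, sitar_predict(f, 19) - sitar_predict(f, 8), tolerance = 0.05)
})

test_that("peak finder recovers a constructed analytic maximum", {
  ## spline with a known interior velocity peak, built from a smooth target
  g0 <- seq(7, 20, by = 0.02)
  target <- 130 + 40 * pnorm(g0, mean = 12.3, sd = 1.6)
  cv <- spurtr:::fit_spline_curve(g0, target, df = 6)
  f <- structure(list(curve = cv), class = "sitar_fit")
  pk <- sitar_peak(f)
  gg <- seq(7, 20, by = 1e-4)
  vv <- eval_curve(cv, gg, deriv = 1)
  expect_equal(pk$aphv, gg[which.max(vv)], tolerance = 0.01)
  expect_equal(pk$phv, max(vv), tolerance = 1e-4)
  expect_false(pk$boundary_flag)
})

test_that("a monotone-decreasing velocity is boundary-flagged", {
  g0 <- seq(7, 20, by = 0.02)
  cv <- spurtr:::fit_spline_curve(g0, 170 - 120 * exp(-0.25 * (g0 - 7)), df = 4)
  f <- structure(list(curve = cv), class = "sitar_fit")
  pk <- sitar_peak(f)
  expect_true(pk$boundary_flag)
  expect_equal(pk$aphv, 7)
})

test_that("simulated truth is recovered at moderate size", {
  sim <- small_sim()
  f <- sitar_fit_small()
  tr <- sim$truth$config$truth$boy
  expect_lt(abs(f$re_sd["size"] - tr$re_sd["size"]) / tr$re_sd["size"], 0.35)
  expect_lt(abs(f$residual_sd - tr$residual_sd) / tr$residual_sd, 0.2)
  pk <- sitar_peak(f)
  expect_lt(abs(pk$aphv - sim$truth$peaks$boy["aphv"]), 1.0)
  expect_lt(abs(pk$phv - sim$truth$peaks$boy["phv"]), 0.8)
})

test_that("noise-free cohorts reproduce the median curve closely", {
  cfg <- default_config(n_subjects = 100L)
  for (sx in c("boy", "girl")) {
    cfg$truth[[sx]]$residual_sd <- 1e-3
    cfg$truth[[sx]]$re_sd <- c(size = 1e-3, timing = 1e-3, intensity = 1e-4)
  }
  sim <- simulate_cohort(cfg, seed = 3)
  d <- sex_subset(sim$cohort, "boy")
  f <- fit_sitar(d, df = 5, multistart = FALSE)
  g <- seq(8.5, 19, by = 0.5)
  tru <- eval_curve(sim$truth$curves$boy, g)
  expect_lt(max(abs(sitar_predict(f, g) - tru)), 0.25)
})

test_that("identical subjects shrink the random-effect SDs toward zero", {
  cfg <- default_config(n_subjects = 60L)
  for (sx in c("boy", "girl")) {
    cfg$truth[[sx]]$re_sd <- c(size = 1e-4, timing = 1e-4, intensity = 1e-5)
    cfg$truth[[sx]]$residual_sd <- 0.5
  }
  sim <- simulate_cohort(cfg, seed = 8)
  f <- fit_sitar(sex_subset(sim$cohort, "girl"), df = 3, multistart = FALSE)
  expect_lt(unname(f$re_sd["size"]), 0.3)
  expect_lt(unname(f$re_sd["timing"]), 0.3)
})

test_that("df selection returns a BIC table and respects single candidates", {
  sim <- small_sim()
  d <- sex_subset(sim$cohort, "girl")
  sel <- select_df(d, candidates = 2:3)
  expect_s3_class(sel$table, "data.frame")
  expect_equal(sel$table$df, 2:3)
  expect_true(sel$best %in% 2:3)
  expect_equal(sel$table$bic[sel$table$converged],
               with(sel$table[sel$table$converged, ],
                    -2 * loglik + n_params * log(nrow(d))))
  one <- select_df(d, candidates = 3L)
  expect_equal(one$best, 3L)
})

test_that("fits refuse inadequate data and oversized df", {
  sim <- small_sim()
  d <- sex_subset(sim$cohort, "boy")
  expect_error(fit_sitar(d[1:20, ]), "at least 20 subjects")
  expect_error(fit_sitar(d, df = 14), "too large")
})

test_that("fit serialization writes valid JSON and effect tables", {
  f <- sitar_fit_small()
  tmp <- tempfile(fileext = ".json")
  write_sitar_fit(f, tmp)
  js <- jsonlite::read_json(tmp)
  expect_equal(js$model, "SITAR")
  expect_equal(length(js$curve$coef), f$df)
  expect_equal(js$re_sd$size, unname(f$re_sd["size"]), tolerance = 1e-9)
  tmp2 <- tempfile(fileext = ".csv")
  write_sitar_ranef(f, tmp2)
  re <- utils::read.csv(tmp2)
  expect_equal(names(re), c("subject_id", "alpha", "beta", "gamma"))
  expect_equal(nrow(re), f$n_subjects)
  ct <- sitar_curve_table(f, ages = seq(9, 18, 0.5))
  expect_equal(names(ct), c("age", "height", "velocity"))
})
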