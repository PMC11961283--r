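## a linear random-intercept model posed as an NLME problem: the balanced
## one-way layout has closed-form ML estimates, which serve as the oracle
balanced_oneway <- function(m = 12L, n = 5L, mu = 10, sd_b = 2, sd_e = 1, seed = 9L) {
  set.seed(seed)
  bi <- rnorm(m, 0, sd_b)
  id <- rep(seq_len(m), each = n)
  y <- mu + bi[id] + rnorm(m * n, 0, sd_e)
  x <- rep(0, m * n)
  fn <- function(phi, x) {
    out <- phi[, "mu"]
    attr(out, "gradient") <- matrix(1, length(out), 1, dimnames = list(NULL, "mu"))
    out
  }
  list(prob = nlme_problem(y, x, id, fn, par_names = "mu", random = "mu",
                           fixed = list(mu = TRUE)),
       y = y, id = id, m = m, n = n)
}

oneway_ml_closed_form <- function(y, id, m, n) {
  ybar_i <- tapply(y, id, mean)
  ybar <- mean(y)
  ssw <- sum((y - ybar_i[id])^2)
  ssb <- n * sum((ybar_i - ybar)^2)
  sigma2 <- ssw / (m * (n - 1))
  lambda <- ssb / m                       # ML, divisor m (not m - 1)
  sb2 <- max((lambda - sigma2) / n, 0)
  ll <- -0.5 * (m * n * log(2 * pi) + m * (n - 1) * log(sigma2) +
                  m * log(sigma2 + n * sb2) + ssw / sigma2 +
                  ssb / (sigma2 + n * sb2))
  list(mu = ybar, sigma2 = sigma2, sb2 = sb2, loglik = ll)
}

test_that("linear mixed model special case matches the closed-form ML solution", {
  bw <- balanced_oneway()
  cf <- oneway_ml_closed_form(bw$y, bw$id, bw$m, bw$n)
  fit <- fit_nlme(bw$prob, start = list(beta = mean(bw$y), re_sd = 2, sigma = 1))
  expect_equal(unname(fit$beta), cf$mu, tolerance = 1e-6)
  expect_equal(fit$sigma^2, cf$sigma2, tolerance = 1e-4)
  expect_equal(unname(diag(fit$D)), cf$sb2, tolerance = 1e-3)
  expect_equal(fit$loglik, cf$loglik, tolerance = 1e-6)
})

test_that("quadrature oracle matches the closed-form marginal likelihood", {
  bw <- balanced_oneway(m = 6L, n = 4L)
  cf <- oneway_ml_closed_form(bw$y, bw$id, bw$m, bw$n)
  ## at the closed-form ML parameters the quadrature must reproduce the loglik
  ql <- marginal_loglik_quadrature(bw$prob, beta = cf$mu,
                                   D = matrix(max(cf$sb2, 1e-8), 1, 1),
                                   sigma = sqrt(cf$sigma2))
  expect_equal(ql, cf$loglik, tolerance = 1e-6)
})

test_that("quadrature collapses to the iid likelihood when variance is zero", {
  bw <- balanced_oneway(m = 4L, n = 3L, sd_b = 0.5)
  mu <- mean(bw$y); sig <- 1.3
  ql <- marginal_loglik_quadrature(bw$prob, beta = mu,
                                   D = matrix(1e-12, 1, 1), sigma = sig)
  expect_equal(ql, sum(dnorm(bw$y, mu, sig, log = TRUE)), tolerance = 1e-4)
})

test_that("quadrature guard refuses oversized instances", {
  bw <- balanced_oneway(m = 12L, n = 3L)
  expect_error(marginal_loglik_quadrature(bw$prob, 1, matrix(1, 1, 1), 1),
               "restricted")
})

test_that("Gauss-Hermite rule integrates low-order moments exactly", {
  gh <- gauss_hermite(15)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4, tolerance = 1e-9)
})

test_that("BIC follows its definition and penalizes parameters monotonically", {
  expect_equal(bic(-100, 3, 20), 200 + 3 * log(20))
  expect_equal(bic(-100, 0, 20), 200)
  expect_gt(bic(-50, 5, 100), bic(-50, 4, 100))
})

test_that("Wald contrasts reproduce single-parameter estimates and degenerate p-values", {
  fit <- list(beta = c(a = 2, b = -1),
              beta_vcov = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2))
  w <- wald_contrast(fit, c(1, 0))
  expect_equal(w$estimate, 2)
  expect_equal(w$se, 0.2)
  expect_equal(w$p_value, 2 * pnorm(-10))
  ## contrast estimate of zero gives p = 1
  fit0 <- list(beta = c(a = 1, b = 1), beta_vcov = diag(c(0.1, 0.1)))
  expect_equal(wald_contrast(fit0, c(1, -1))$p_value, 1)
  expect_error(wald_contrast(fit, c(1, 0, 0)), "length")
  fitS <- list(beta = c(a = 1, b = 1), beta_vcov = matrix(1, 2, 2))
  expect_error(wald_contrast(fitS, c(1, 0)), "singular")
})

test_that("near-noiseless generator data are recovered essentially exactly", {
  ## residual noise exactly zero makes Gaussian ML ill-posed (the likelihood
  ## is unbounded as sigma -> 0), so the generator oracle uses a residual SD
  ## far below every other scale in the problem
  set.seed(13)
  m <- 30L
  bi <- rnorm(m, 0, 3)
  id <- rep(seq_len(m), each = 4)
  x <- rep(c(0, 1, 2, 3), m)
  y <- 5 + 2 * x + bi[id] + rnorm(m * 4, 0, 0.01)
  fn <- function(phi, x) {
    out <- phi[, "a"] + phi[, "s"] * x
    attr(out, "gradient") <- cbind(s = x, a = 1)
    out
  }
  prob <- nlme_problem(y, x, id, fn, par_names = c("s", "a"), random = "a",
                       fixed = list(s = TRUE, a = TRUE))
  fit <- fit_nlme(prob, start = list(beta = c(1, 1), re_sd = 2, sigma = 1))
  ## the fixed intercept converges to the realized mean of the drawn effects
  expect_equal(unname(fit$beta), c(2, 5 + mean(bi)), tolerance = 2e-3)
  expect_lt(fit$sigma, 0.05)
  expect_equal(unname(fit$re_sd), sqrt(mean((bi - mean(bi))^2)), tolerance = 0.01)
})

test_that("a single subject pins the random-effect variance with a warning", {
  y <- c(1.2, 1.9, 3.1, 4.2)
  x <- 0:3
  fn <- function(phi, x) {
    out <- phi[, "a"] + phi[, "s"] * x
    attr(out, "gradient") <- cbind(s = x, a = 1)
    out
  }
  prob <- nlme_problem(y, x, rep(1, 4), fn, par_names = c("s", "a"),
                       random = "a", fixed = list(s = TRUE, a = TRUE))
  expect_warning(fit <- fit_nlme(prob, start = list(beta = c(1, 1), sigma = 0.5)),
                 "one subject")
  expect_lt(fit$re_sd, 1e-2)
})

test_that("refitting from the solution stays at the solution", {
  bw <- balanced_oneway(m = 10L, n = 4L)
  fit <- fit_nlme(bw$prob, start = list(beta = mean(bw$y), re_sd = 2, sigma = 1))
  fit2 <- fit_nlme(bw$prob, start = list(beta = fit$beta, theta = fit$theta,
                                         sigma = fit$sigma))
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("the independent linear mixed-model implementation agrees", {
  skip_if_not_installed("nlme")
  bw <- balanced_oneway(m = 15L, n = 6L, seed = 17L)
  fit <- fit_nlme(bw$prob, start = list(beta = mean(bw$y), re_sd = 2, sigma = 1))
  d <- data.frame(y = bw$y, id = factor(bw$id))
  lf <- nlme::lme(y ~ 1, random = ~ 1 | id, data = d, method = "ML")
  expect_equal(unname(fit$beta), unname(nlme::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  expect_equal(fit$sigma, lf$sigma, tolerance = 1e-3)
})
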