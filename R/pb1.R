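#' Preece-Baines model 1 parameters
#'
#' The five PB1 coefficients: `h1` adult height (cm), `hc` height at
#' midpuberty age `c` (cm), `s0` and `s1` the prepubertal and pubertal rate
#' constants (1/year), and `c` the midpuberty age (years). The height curve is
#' \deqn{h(t) = h_1 - \frac{2 (h_1 - h_c)}{e^{s_0 (t - c)} + e^{s_1 (t - c)}}}
#' so that \eqn{h(c) = h_c} and \eqn{h(t) \to h_1} as \eqn{t \to \infty}.
#'
#' Note on units: the rate constants appear inside exponentials of
#' (years), so their units are 1/year even though growth-study tables often
#' label them "cm/year".
#'
#' @param h1 adult height, cm; must exceed `hc`.
#' @param hc height at midpuberty, cm; positive.
#' @param s0 prepubertal rate constant, 1/year; `0 < s0 < s1`.
#' @param s1 pubertal rate constant, 1/year.
#' @param c midpuberty age, years, in (7, 20) for this age window.
#' @return an object of class `pb1_params`.
#' @examples
#' p <- pb1_params(h1 = 174.60, hc = 162.24, s0 = 0.096, s1 = 0.78, c = 16.02)
#' pb1_height(16.02, p)   # == hc
#' @export
pb1_params <- function(h1, hc, s0, s1, c) {
  stopifnot(is.finite(h1), is.finite(hc), is.finite(s0), is.finite(s1), is.finite(c))
  if (!(h1 > hc && hc > 0)) stop("need h1 > hc > 0", call. = FALSE)
  if (!(s1 > s0 && s0 > 0)) stop("need s1 > s0 > 0", call. = FALSE)
  if (!(c > 7 && c < 20)) stop("midpuberty age c must lie in (7, 20)", call. = FALSE)
  structure(list(h1 = h1, hc = hc, s0 = s0, s1 = s1, c = c), class = "pb1_params")
}

#' @export
print.pb1_params <- function(x, ...) {
  cat(sprintf("PB1 parameters: h1 = %.2f cm, hc = %.2f cm, s0 = %.4g /yr, s1 = %.4g /yr, c = %.2f yr\n",
              x$h1, x$hc, x$s0, x$s1, x$c))
  invisible(x)
}

#' Reference PB1 coefficients for the Young Lives Ethiopia older cohort
#'
#' Published sex-specific PB1 fixed effects for Ethiopian children and
#' adolescents followed over four survey rounds (ages 7-20). Used as
#' simulation-truth defaults and in worked examples.
#'
#' @param sex `"boys"` or `"girls"`.
#' @return a [pb1_params()] object.
#' @export
pb1_reference_params <- function(sex = c("boys", "girls")) {
  sex <- match.arg(sex)
  if (sex == "boys")
    pb1_params(h1 = 174.60, hc = 162.24, s0 = 0.096, s1 = 0.78, c = 16.02)
  else
    pb1_params(h1 = 162.2, hc = 138.70, s0 = 0.04, s1 = 0.47, c = 11.54)
}

#' PB1 height curve
#'
#' Overflow-safe evaluation of the PB1 distance curve; for large `|t - c|` the
#' dominant exponential is factored out so the curve approaches `h1` without
#' intermediate overflow.
#'
#' @param t age(s), years.
#' @param p a [pb1_params()] object.
#' @return height(s), cm.
#' @export
pb1_height <- function(t, p) {
  stopifnot(inherits(p, "pb1_params"))
  d <- t - p$c
  a <- p$s0 * d
  b <- p$s1 * d
  m <- pmax(a, b)
  ## 2(h1-hc) / (e^a + e^b) = 2(h1-hc) e^{-m} / (e^{a-m} + e^{b-m})
  p$h1 - 2 * (p$h1 - p$hc) * exp(-m) / (exp(a - m) + exp(b - m))
}

#' PB1 growth velocity
#'
#' Analytic first derivative of [pb1_height()]; positive for all ages and
#' decaying to zero far from midpuberty. At `t = c` it equals
#' `(h1 - hc) (s0 + s1) / 2`.
#'
#' @inheritParams pb1_height
#' @return velocity, cm/year.
#' @export
pb1_velocity <- function(t, p) {
  stopifnot(inherits(p, "pb1_params"))
  d <- t - p$c
  a <- p$s0 * d
  b <- p$s1 * d
  m <- pmax(a, b)
  ea <- exp(a - m)
  eb <- exp(b - m)
  2 * (p$h1 - p$hc) * exp(-m) * (p$s0 * ea + p$s1 * eb) / (ea + eb)^2
}

#' Age and magnitude of peak height velocity under PB1
#'
#' Locates the maximum of [pb1_velocity()] on an age interval by a dense grid
#' search refined with golden-section search to 1e-4 years. In PB1 the
#' velocity peak lies near, but in general not exactly at, the midpuberty age
#' `c`; both are of interest and `c` is available from the parameters.
#'
#' @inheritParams pb1_height
#' @param interval search interval in years.
#' @return a `peak_estimate`: list with `aphv` (years), `phv` (cm/year) and
#'   `boundary_flag` (`TRUE` when the maximum sits on the interval edge,
#'   with a warning).
#' @export
pb1_peak <- function(p, interval = c(7, 20)) {
  stopifnot(inherits(p, "pb1_params"))
  grid <- seq(interval[1], interval[2], by = 0.01)
  v <- pb1_velocity(grid, p)
  i <- which.max(v)
  if (i == 1L || i == length(grid)) {
    warning("velocity maximum lies on the search boundary")
    return(peak_estimate(grid[i], v[i], boundary_flag = TRUE))
  }
  opt <- stats::optimize(function(t) -pb1_velocity(t, p),
                         lower = grid[i - 1L], upper = grid[i + 1L], tol = 1e-5)
  peak_estimate(opt$minimum, -opt$objective, boundary_flag = FALSE)
}

#' @rdname pb1_peak
#' @param aphv age at peak height velocity, years.
#' @param phv peak height velocity, cm/year.
#' @param boundary_flag whether the maximum was found on the search boundary.
#' @export
peak_estimate <- function(aphv, phv, boundary_flag = FALSE) {
  structure(list(aphv = as.numeric(aphv), phv = as.numeric(phv),
                 boundary_flag = isTRUE(boundary_flag)),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("APHV = %.2f years, PHV = %.2f cm/year%s\n", x$aphv, x$phv,
              if (x$boundary_flag) " (boundary!)" else ""))
  invisible(x)
}

## negative profile (sigma profiled out) log-likelihood up to constants:
## n/2 log(SSE); working scale th = (h1, hc, log s0, log s1, c)
pb1_nll_work <- function(th, t, y) {
  h1 <- th[1]; hc <- th[2]; s0 <- exp(th[3]); s1 <- exp(th[4]); cc <- th[5]
  if (!is.finite(h1) || !is.finite(hc) || h1 <= hc) return(1e10)
  d <- t - cc
  a <- s0 * d; b <- s1 * d; m <- pmax(a, b)
  mu <- h1 - 2 * (h1 - hc) * exp(-m) / (exp(a - m) + exp(b - m))
  sse <- sum((y - mu)^2)
  if (!is.finite(sse)) return(1e10)
  ## tiny floor keeps the profile objective bounded on noise-free data
  0.5 * length(y) * log((sse + 1e-10 * length(y)) / length(y))
}

## full gaussian negative loglik on the natural scale incl. log sigma,
## used for the observed-information standard errors
pb1_nll_full <- function(par, t, y) {
  p <- list(h1 = par[1], hc = par[2], s0 = par[3], s1 = par[4], c = par[5])
  sig <- exp(par[6])
  d <- t - p$c
  a <- p$s0 * d; b <- p$s1 * d; m <- pmax(a, b)
  mu <- p$h1 - 2 * (p$h1 - p$hc) * exp(-m) / (exp(a - m) + exp(b - m))
  -sum(stats::dnorm(y, mu, sig, log = TRUE))
}

pb1_auto_start <- function(t, y) {
  h1 <- max(y) + 2
  o <- order(t)
  ts <- t[o]; ys <- y[o]
  med_age <- stats::median(ts)
  hc <- stats::median(ys[abs(ts - med_age) <= 2])
  ## crude pooled velocity: finite differences of binned means
  br <- seq(min(ts), max(ts), length.out = 9)
  mids <- (br[-1] + br[-length(br)]) / 2
  bm <- tapply(ys, cut(ts, br, include.lowest = TRUE), mean)
  vel <- diff(bm) / diff(mids)
  cc <- mids[which.max(vel)] + 0.5
  cc <- min(max(cc, 8.5), 18.5)
  list(h1 = h1, hc = hc, s0 = 0.1, s1 = 1.0, c = as.numeric(cc))
}

#' Fit the PB1 model by maximum likelihood
#'
#' Population-average PB1 fit: Gaussian maximum likelihood on the pooled
#' observations of one group (e.g. one sex), with homoscedastic residuals.
#' The optimizer is quasi-Newton (BFGS) on a log-reparameterization of
#' `(s0, s1)` to enforce positivity, with up to five jittered restarts.
#' Standard errors come from the inverse observed information of the full
#' likelihood (including the residual-scale parameter) at the optimum.
#'
#' @param age ages, years.
#' @param height heights, cm.
#' @param start a [pb1_params()] object or `"auto"` for data-driven starts
#'   (`h1` = max height + 2 cm, `hc` = median height near the median age, `c`
#'   at the crude pooled-velocity maximum, `s0 = 0.1`, `s1 = 1`).
#' @param max_restarts jittered restarts after a failed or non-converged
#'   attempt.
#' @return an object of class `pb1_fit`: `params` ([pb1_params()]),
#'   `std_errors`, `corr` (5x5 correlation matrix of the estimates), `loglik`,
#'   `n_obs`, `residual_sd`, and `trace` (per-attempt convergence summary).
#' @export
fit_pb1 <- function(age, height, start = "auto", max_restarts = 5L) {
  stopifnot(length(age) == length(height), all(is.finite(age)), all(is.finite(height)))
  if (length(age) < 25L || diff(range(age)) < 8)
    stop("need at least 25 observations spanning at least 8 years of age", call. = FALSE)
  if (diff(range(height)) < 1)
    stop("singular information matrix; heights carry no growth signal", call. = FALSE)
  st <- if (identical(start, "auto")) pb1_auto_start(age, height) else {
    stopifnot(inherits(start, "pb1_params")); unclass(start)
  }
  th0 <- c(st$h1, st$hc, log(st$s0), log(st$s1), st$c)
  ## the working surface has degenerate corners (rates collapsing to zero);
  ## a small systematic start battery plus jittered restarts avoids them
  starts <- list(th0,
                 th0 + c(0, 0, 0, log(0.4), 0),
                 th0 + c(0, -4, log(0.4), log(0.6), -1.5),
                 th0 + c(0, 3, 0, 0, 1.5))
  trace <- character(0)
  best <- NULL
  for (k in seq_len(length(starts) + max_restarts)) {
    thk <- if (k <= length(starts)) starts[[k]]
    else th0 + stats::rnorm(5, 0, c(2, 3, 0.25, 0.25, 0.8))
    o <- tryCatch(
      stats::optim(thk, pb1_nll_work, t = age, y = height,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o)) { trace <- c(trace, sprintf("attempt %d: error", k)); next }
    trace <- c(trace, sprintf("attempt %d: code %d, objective %.6f", k,
                              o$convergence, o$value))
    ## keep the lowest objective regardless of status; polished below
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
    ## two independent starts agreeing on a converged, non-degenerate
    ## optimum is enough
    if (k == 2L && !is.null(best) && best$convergence == 0) {
      vals <- suppressWarnings(as.numeric(sub(".*objective ", "", trace)))
      pk <- list2pb1(best$par)
      plausible <- pb1_height(20, pk) - pb1_height(7, pk) > 5 &&
        pk$c > 7.5 && pk$c < 19.5
      if (plausible && sum(abs(vals - best$value) < 1e-6) >= 2) break
    }
    if (!is.null(best) && best$convergence == 0 && k >= length(starts)) break
  }
  if (is.null(best))
    stop(paste(c("PB1 fit failed:", trace), collapse = "\n  "), call. = FALSE)
  for (polish in 1:3) {
    if (best$convergence == 0) break
    o <- tryCatch(stats::optim(best$par, pb1_nll_work, t = age, y = height,
                               method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o) || o$value > best$value + 1e-8) break
    best <- o
    trace <- c(trace, sprintf("polish: code %d, objective %.6f", o$convergence, o$value))
  }
  if (best$convergence != 0)
    stop(paste(c("PB1 fit did not converge:", trace), collapse = "\n  "), call. = FALSE)
  th <- best$par
  n <- length(age)
  pars <- list2pb1(th)
  mu_res <- height - pb1_height(age, pars)
  sse <- sum(mu_res^2)
  sigma <- sqrt(sse / n)
  if (pb1_height(20, pars) - pb1_height(7, pars) < 1) {
    stop("singular information matrix; the fitted curve is flat (no growth signal)",
         call. = FALSE)
  }
  pn <- c("h1", "hc", "s0", "s1", "c")
  se <- stats::setNames(rep(NA_real_, 5), pn)
  corr <- diag(5)
  dimnames(corr) <- list(pn, pn)
  V <- NULL
  if (sigma > 1e-6) {
    par_nat <- c(th[1], th[2], exp(th[3]), exp(th[4]), th[5], log(sigma))
    H <- stats::optimHess(par_nat, pb1_nll_full, t = age, y = height)
    ## condition assessed on the scale-free (correlation-form) information,
    ## since the raw parameters live on wildly different scales
    dH <- sqrt(abs(diag(H)))
    ok <- all(dH > 0) &&
      is.finite(kap <- kappa(H / tcrossprod(dH), exact = TRUE)) && kap < 1e12
    if (ok) {
      V <- tryCatch(solve(H)[1:5, 1:5, drop = FALSE], error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        se <- stats::setNames(sqrt(diag(V)), pn)
        corr <- V / tcrossprod(se)
        dimnames(corr) <- dimnames(V) <- list(pn, pn)
      } else V <- NULL
    }
    if (is.null(V)) {
      worst <- pn[which.min(dH[1:5])]
      warning(sprintf("information matrix is singular at the optimum (parameter '%s' ill-determined); standard errors unavailable",
                      worst))
    }
  } else {
    warning("residual variation is essentially zero; standard errors unavailable")
  }
  ll <- sum(stats::dnorm(height, height - mu_res, max(sigma, 1e-12), log = TRUE))
  structure(list(params = pars, std_errors = se, corr = corr,
                 vcov = V, loglik = ll, n_obs = n, n_params = 6L,
                 residual_sd = sigma, trace = trace),
            class = "pb1_fit")
}

list2pb1 <- function(th) {
  ## the curve is symmetric under swapping (s0, s1); store in canonical order
  s <- sort(exp(th[3:4]))
  if (s[2] <= s[1]) s[2] <- s[1] * (1 + 1e-9)
  pb1_params(h1 = th[1], hc = th[2], s0 = s[1], s1 = s[2],
             c = min(max(th[5], 7 + 1e-6), 20 - 1e-6))
}

#' Correlation matrix of PB1 parameter estimates
#'
#' Rescales the estimate covariance to a correlation matrix,
#' `corr = D^-1 Sigma D^-1` with `D` the diagonal square roots.
#'
#' @param fit a `pb1_fit`.
#' @return 5x5 correlation matrix (unit diagonal).
#' @export
pb1_param_correlations <- function(fit) {
  stopifnot(inherits(fit, "pb1_fit"))
  fit$corr
}

#' @export
print.pb1_fit <- function(x, ...) {
  cat("PB1 maximum-likelihood fit (", x$n_obs, " observations)\n", sep = "")
  est <- unlist(unclass(x$params))
  tab <- cbind(estimate = est, std.error = x$std_errors)
  print(round(tab, 4))
  cat(sprintf("residual SD %.2f cm, logLik %.2f\n", x$residual_sd, x$loglik))
  invisible(x)
}

#' Serialize a PB1 fit to JSON
#'
#' @param fit a `pb1_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pb1_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pb1_fit"))
  jsonlite::write_json(list(
    model = "PB1",
    params = unclass(fit$params),
    std_errors = as.list(fit$std_errors),
    corr = fit$corr,
    loglik = fit$loglik, n_obs = fit$n_obs, n_params = fit$n_params,
    residual_sd = fit$residual_sd, trace = fit$trace
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export PB1 distance and velocity curves as a table
#'
#' @param p a [pb1_params()] object.
#' @param ages evaluation grid, years.
#' @return data.frame with columns `age`, `height`, `velocity`.
#' @export
pb1_curve_table <- function(p, ages = seq(7, 20, by = 0.1)) {
  data.frame(age = ages, height = pb1_height(ages, p),
             velocity = pb1_velocity(ages, p))
}
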