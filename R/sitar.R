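#' SITAR age transformation
#'
#' The shape-invariant transform of (centred) age by a subject's timing and
#' intensity effects: `t* = (t - beta) * exp(gamma)`. Ages here are offsets
#' from the curve's age origin (`xoffset`, usually the mean observation age),
#' so that intensity stretches the age axis about the middle of the data
#' rather than about birth. Positive `gamma` means faster maturation (the
#' subject's age axis is compressed relative to the population).
#'
#' @param t centred age(s), years.
#' @param beta timing effect, years (positive = later).
#' @param gamma intensity effect, log-units (positive = faster).
#' @return transformed centred age(s), years.
#' @examples
#' sitar_transform(10, beta = 1, gamma = log(2))  # 18
#' @export
sitar_transform <- function(t, beta, gamma) {
  (t - beta) * exp(gamma)
}

## model function for the engine: par_names = s1..sk, a, b, c.
## gradient is exact; hess_random carries the analytic second derivatives
## with respect to the random effects (a, b, c) for the Laplace refinement:
##   d2y/db2 = e^{2c} s''      d2y/dbdc = -e^c s' - e^c xs s''
##   d2y/dc2 = xs s' + xs^2 s''   (xs = (x - b) e^c)
make_sitar_fn <- function(knots, boundary, k) {
  scols <- paste0("s", seq_len(k))
  pre <- ns_basis_pre(knots, boundary)
  function(phi, x) {
    eg <- exp(phi[, "c"])
    xs <- (x - phi[, "b"]) * eg
    ba <- ns_basis_all(xs, knots, boundary, pre = pre)
    B <- ba$B0
    Dv <- ba$B1
    D2 <- ba$B2
    S <- phi[, scols, drop = FALSE]
    v <- rowSums(Dv * S)
    w <- rowSums(D2 * S)
    out <- phi[, "a"] + rowSums(B * S)
    grad <- cbind(B, 1, -eg * v, xs * v)
    colnames(grad) <- c(scols, "a", "b", "c")
    attr(out, "gradient") <- grad
    zero <- numeric(length(out))
    hbb <- eg^2 * w
    hbc <- -eg * v - eg * xs * w
    hcc <- xs * v + xs^2 * w
    ## batch layout over random = (a, b, c): column (i-1)*3 + j for (i, j)
    attr(out, "hess_random") <- cbind(zero, zero, zero,
                                      zero, hbb, hbc,
                                      zero, hbc, hcc)
    out
  }
}

## equally spaced interior knots. Quantile placement, the usual default for
## dense designs, concentrates knots inside the narrow measurement-round
## bands of a sparse design; that family admits sharply curved mean curves
## whose linearized likelihood is grossly overstated, and model selection
## then chases artifacts. An even grid keeps curvature honest between rounds.
place_knots <- function(x, df, boundary) {
  seq(boundary[1], boundary[2], length.out = df + 1L)[2:df]
}

#' Fit the SITAR shape-invariant growth model
#'
#' Fits the model
#' \deqn{y_{ij} = \alpha_i + s\{(t_{ij} - x_0 - \beta_i) e^{\gamma_i}\} + e_{ij}}
#' where `s` is a natural cubic spline mean curve, `x0` the mean observation
#' age, and `(alpha_i, beta_i, gamma_i)` are per-subject size (cm), timing
#' (years) and intensity (log-units) random effects with an unstructured
#' trivariate normal distribution, estimated by [fit_nlme()]. The fixed size
#' is absorbed into the spline intercept; fixed timing and intensity are zero
#' for a single-group fit and can be estimated as group offsets through
#' `size_by` / `timing_by` / `intensity_by`.
#'
#' Interior knots are equally spaced over the observed age range, with
#' boundary knots padded `boundary_pad` years beyond it (quantile placement
#' concentrates knots inside the narrow measurement-round bands of sparse
#' designs and admits pathologically curved mean curves; an even grid keeps
#' curvature honest between rounds, and the padding keeps the natural-spline
#' zero-curvature constraint clear of the data edges).
#'
#' Estimation runs the Lindstrom-Bates alternation and then maximizes the
#' exact Laplace objective (see [laplace_refine()]); reported log-likelihoods
#' are Laplace values.
#'
#' @param data data.frame with columns `subject_id`, `age`, `height` (a
#'   [as_cohort_table()] works as-is).
#' @param df spline degrees of freedom (number of basis coefficients;
#'   `df - 1` interior knots).
#' @param size_by,timing_by,intensity_by optional factors (one value per row
#'   of `data`) whose non-reference levels get fixed offsets on size, timing
#'   or intensity.
#' @param chain warm-start chain: anchor at a stiff df = 3 fit (which cannot
#'   trade curve wiggle against the variance components), then refit at the
#'   target df with spline coefficients, variance parameters and modes
#'   carried over (default TRUE). Sparse clustered designs leave flexible
#'   splines badly multimodal; cold starts at high df often land in wiggly
#'   local optima.
#' @param laplace refine the final fit under the exact Laplace objective
#'   (default TRUE). The first-order objective can badly overstate the
#'   likelihood of strongly curved mean curves and lose the pubertal spurt;
#'   the refinement is run from two starts - the chain solution and a
#'   PB1-shaped curve projected onto the spline basis (which always carries a
#'   spurt) - and the better optimum is kept.
#' @param boundary_pad years added beyond the observed age range before
#'   placing the boundary knots (default 0.8). The natural-spline constraint
#'   (zero curvature at the boundary) otherwise acts exactly where the data
#'   stop; padding moves it clear of the measurement-round edges so a spurt
#'   near the first or last round is not flattened, and covers the span of
#'   timing-shifted transformed ages.
#' @param multistart also try a PB1-shaped alternative start at the final
#'   stage and keep the better optimum (default TRUE).
#' @param start_from optional previous `sitar_fit` on comparable data; the fit
#'   is warm-started from it (its median curve projected onto the new basis,
#'   variance parameters carried over) instead of running the full chain.
#' @param start optional list passed to [fit_nlme()] (overrides the chain's
#'   starts at the final stage).
#' @param control engine control list, see [fit_nlme()].
#' @return an object of class `sitar_fit`: `curve` (a [spline_curve()] for the
#'   population median), `re_sd` (size cm, timing years, intensity log-units),
#'   `re_corr`, `residual_sd`, `loglik`, `n_params`, `ranef` (per-subject
#'   predicted effects), `fixed_offsets`, and the underlying `engine` fit.
#' @export
fit_sitar <- function(data, df = 5L, size_by = NULL, timing_by = NULL,
                      intensity_by = NULL, chain = TRUE, laplace = TRUE,
                      boundary_pad = 0.8, multistart = TRUE,
                      start_from = NULL, start = NULL, control = list()) {
  dfs <- if (is.null(start_from) && chain && df > 3L) c(3L, df) else df
  fits <- sitar_chain(data, dfs = dfs,
                      size_by = size_by, timing_by = timing_by,
                      intensity_by = intensity_by, start = start,
                      control = control, keep_all = FALSE, laplace = laplace,
                      boundary_pad = boundary_pad, multistart = multistart,
                      prev0 = start_from)
  fits[[length(fits)]]
}

## fit a sequence of df values, each warm-started from the previous
sitar_chain <- function(data, dfs, size_by = NULL, timing_by = NULL,
                        intensity_by = NULL, start = NULL, control = list(),
                        keep_all = TRUE, laplace = TRUE, boundary_pad = 0.8,
                        multistart = TRUE, prev0 = NULL) {
  stopifnot(all(c("subject_id", "age", "height") %in% names(data)))
  age <- as.numeric(data$age)
  y <- as.numeric(data$height)
  id <- factor(data$subject_id)
  nobs <- table(id)
  if (sum(nobs >= 3L) < 20L)
    stop("need at least 20 subjects with at least 3 observations each", call. = FALSE)
  if (any(dfs < 2L)) stop("df must be at least 2", call. = FALSE)
  xoffset <- mean(age)
  x <- age - xoffset
  boundary <- range(x) + c(-boundary_pad, boundary_pad)
  if ((max(dfs) - 1L) > max(1, floor(diff(range(x)))))
    stop("df too large for the observed age span", call. = FALSE)
  si <- as.integer(id)

  make_problem <- function(df, knots) {
    k <- df
    scols <- paste0("s", seq_len(k))
    fixed <- stats::setNames(rep(list(TRUE), k), scols)
    fixed$a <- if (is.null(size_by)) TRUE else
      stats::model.matrix(~f, data.frame(f = factor(size_by)))
    if (!is.null(timing_by))
      fixed$b <- stats::model.matrix(~f, data.frame(f = factor(timing_by)))[, -1, drop = FALSE]
    if (!is.null(intensity_by))
      fixed$c <- stats::model.matrix(~f, data.frame(f = factor(intensity_by)))[, -1, drop = FALSE]
    fn <- make_sitar_fn(knots, boundary, k)
    nlme_problem(y, x, id, fn, par_names = c(scols, "a", "b", "c"),
                 random = c("a", "b", "c"), fixed = fixed)
  }

  ## project a previous stage's (or any) curve onto a new basis for warm starts
  project_curve <- function(prob, knots, k, n_off, heights_fn, ef = NULL) {
    gx <- seq(boundary[1], boundary[2], length.out = 200)
    Bg <- natural_spline_basis(gx, knots, boundary)
    co <- stats::lm.fit(cbind(1, Bg), heights_fn(gx))$coefficients
    beta <- c(co[-1], co[1], rep(0, n_off))
    if (!is.null(ef) && n_off > 0) {
      prev_off <- grep("\\.f", names(ef$beta))
      if (length(prev_off) == n_off) beta[k + 1L + seq_len(n_off)] <- ef$beta[prev_off]
    }
    beta
  }

  stage <- function(df, prev, final) {
    k <- df
    knots <- place_knots(x, df, boundary)
    prob <- make_problem(df, knots)
    n_off <- length(beta_names(prob)) - k - 1L
    coarse <- list(iter.max = 60L, rel.tol = 1e-7)
    ## a stiff (df <= 3) spline fit is a reliable anchor: it cannot trade
    ## curve wiggle against the variance components. Above df 3 the cold
    ## likelihood is multimodal, so warm-start from the previous stage.
    warm <- !is.null(prev) && (df > 3L || !is.null(prev0))
    if (!warm) {
      ## stiff base fit by the Lindstrom-Bates engine, then refine
      B0 <- natural_spline_basis(x, knots, boundary)
      ls0 <- stats::lm.fit(cbind(1, B0), y)
      co <- ls0$coefficients
      resid_by_subj <- tapply(ls0$residuals, id, mean)
      st <- list(beta = c(co[-1], co[1], rep(0, n_off)),
                 re_sd = c(max(stats::sd(resid_by_subj), 1), 1, 0.1),
                 sigma = max(stats::sd(ls0$residuals) / 2, 0.5))
      if (final && !is.null(start)) st <- utils::modifyList(st, start)
      efit <- fit_nlme(prob, st, control)
      if (laplace) efit <- laplace_refine(efit, control = coarse)
    } else {
      ## warm-start from the previous stage under the Laplace objective:
      ## project its median curve, carry variance parameters and modes
      ef <- prev$engine
      beta0 <- project_curve(prob, knots, k, n_off,
                             function(gx) suppressWarnings(
                               sitar_predict(prev, gx + xoffset)), ef)
      b0 <- if (is.matrix(ef$b) && identical(rownames(ef$b), levels(id)))
        ef$b else NULL
      st0 <- as_nlme_state(prob, beta0, ef$theta, ef$sigma, b0)
      if (final && !is.null(start)) {
        if (!is.null(start$beta)) st0$beta[] <- start$beta
        if (!is.null(start$theta)) st0$theta <- start$theta
        if (!is.null(start$sigma)) st0$sigma <- start$sigma
      }
      if (laplace) {
        efit <- laplace_refine(st0, control = coarse)
      } else {
        efit <- fit_nlme(prob, list(beta = st0$beta, theta = st0$theta,
                                    sigma = st0$sigma), control)
      }
    }
    if (laplace && final) {
      cand <- list(efit)
      ## alternative start: PB1-shaped mean curve (always carries a spurt)
      pb <- if (multistart) tryCatch(fit_pb1(age, y), error = function(e) NULL) else NULL
      if (!is.null(pb)) {
        beta_b <- efit$beta
        beta_b[seq_len(k + 1L)] <- project_curve(
          prob, knots, k, 0L, function(gx) pb1_height(gx + xoffset, pb$params))
        ## neutral variance starts (pubertal-growth magnitudes: ~1.25 y
        ## timing spread, ~15% intensity spread), so this candidate is not
        ## tied to wherever the chain drifted
        sd_a0 <- max(efit$re_sd[1], 2)
        th_b <- L_to_theta(diag(c(sd_a0, 1.25, 0.15) / efit$sigma))
        stb <- as_nlme_state(prob, beta_b, th_b, efit$sigma, efit$b)
        cand[[2]] <- tryCatch(laplace_refine(stb, control = coarse),
                              error = function(e) NULL)
      }
      lls <- vapply(cand, function(f) if (is.null(f)) -Inf else f$loglik, 0)
      best <- cand[[which.max(lls)]]
      efit <- laplace_refine(best, control = list(iter.max = 100L, rel.tol = 1e-8))
    }
    package_sitar_fit(efit, df, knots, boundary, xoffset)
  }
  out <- list()
  prev <- prev0
  for (j in seq_along(dfs)) {
    f <- tryCatch(stage(dfs[j], prev, final = j == length(dfs)),
                  error = function(e) e)
    if (!inherits(f, "error")) prev <- f
    if (keep_all || j == length(dfs)) out[[as.character(dfs[j])]] <- f
  }
  last <- out[[length(out)]]
  if (inherits(last, "error") && !keep_all) stop(last)
  out
}

package_sitar_fit <- function(efit, df, knots, boundary, xoffset) {
  scols <- paste0("s", seq_len(df))
  a_coefs <- efit$beta[grep("^a", names(efit$beta))]
  curve <- spline_curve(knots, boundary, intercept = a_coefs[1],
                        coef = efit$beta[scols], xoffset = xoffset)
  ranef <- data.frame(subject_id = rownames(efit$b),
                      alpha = efit$b[, "a"], beta = efit$b[, "b"],
                      gamma = efit$b[, "c"], row.names = NULL)
  re_sd <- stats::setNames(efit$re_sd, c("size", "timing", "intensity"))
  re_corr <- efit$re_corr
  dimnames(re_corr) <- list(c("size", "timing", "intensity"),
                            c("size", "timing", "intensity"))
  offs <- efit$beta[setdiff(names(efit$beta), c(scols, names(a_coefs)[1]))]
  structure(list(curve = curve, re_sd = re_sd, re_corr = re_corr,
                 residual_sd = efit$sigma, loglik = efit$loglik,
                 n_params = efit$n_params, n_obs = efit$n_obs,
                 n_subjects = efit$n_subjects,
                 fixed_offsets = offs, ranef = ranef, df = df,
                 engine = efit),
            class = "sitar_fit")
}

ncol2 <- function(f) if (isTRUE(f)) 1L else ncol(f)

#' @export
print.sitar_fit <- function(x, ...) {
  cat(sprintf("SITAR fit: %d obs, %d subjects, df = %d, logLik %.2f\n",
              x$n_obs, x$n_subjects, x$df, x$loglik))
  cat("Random-effect SDs: size", round(x$re_sd[1], 2), "cm, timing",
      round(x$re_sd[2], 2), "y, intensity", round(x$re_sd[3], 3), "\n")
  cat("Residual SD:", round(x$residual_sd, 2), "cm\n")
  pk <- sitar_peak(x)
  cat(sprintf("Population peak: APHV %.2f y, PHV %.2f cm/y\n", pk$aphv, pk$phv))
  invisible(x)
}

#' Predict heights from a SITAR fit
#'
#' With zero effects this is the population median curve; with a subject's
#' `(alpha, beta, gamma)` it is that subject's shifted and stretched curve.
#'
#' @param fit a `sitar_fit`.
#' @param age ages, years (observed scale).
#' @param alpha,beta,gamma subject effects (scalars), default zero.
#' @return heights, cm. Ages more than half a year outside the fitted range
#'   trigger an extrapolation warning.
#' @export
sitar_predict <- function(fit, age, alpha = 0, beta = 0, gamma = 0) {
  stopifnot(inherits(fit, "sitar_fit"))
  cv <- fit$curve
  x <- age - cv$xoffset
  xs <- sitar_transform(x, beta, gamma)
  if (any(xs < cv$boundary[1] - 0.5 | xs > cv$boundary[2] + 0.5))
    warning("extrapolating the mean curve beyond the fitted age range")
  B <- natural_spline_basis(xs, cv$knots, cv$boundary)
  alpha + cv$intercept + drop(B %*% cv$coef)
}

#' Growth velocity from a SITAR fit
#'
#' By the chain rule, `dy/dt = exp(gamma) * s'(t*)`; with zero effects this is
#' the population velocity `s'(t)`.
#'
#' @inheritParams sitar_predict
#' @return velocities, cm/year.
#' @export
sitar_velocity <- function(fit, age, alpha = 0, beta = 0, gamma = 0) {
  stopifnot(inherits(fit, "sitar_fit"))
  cv <- fit$curve
  x <- age - cv$xoffset
  xs <- sitar_transform(x, beta, gamma)
  Dv <- natural_spline_basis(xs, cv$knots, cv$boundary, deriv = 1)
  exp(gamma) * drop(Dv %*% cv$coef)
}

#' Age and magnitude of peak height velocity from a SITAR fit
#'
#' Grid search of the population velocity curve with quadratic interpolation
#' refinement around the grid maximum.
#'
#' @param fit a `sitar_fit`.
#' @param interval age search interval, years.
#' @param step grid step, years.
#' @return a [peak_estimate()]; `boundary_flag` is set when the maximum lies
#'   on the interval edge (e.g. a monotone velocity curve).
#' @export
sitar_peak <- function(fit, interval = c(7, 20), step = 0.01) {
  stopifnot(inherits(fit, "sitar_fit"))
  grid <- seq(interval[1], interval[2], by = step)
  v <- sitar_velocity(fit, grid)
  i <- which.max(v)
  if (i == 1L || i == length(grid))
    return(peak_estimate(grid[i], v[i], boundary_flag = TRUE))
  ## parabola through the three points around the maximum
  num <- v[i - 1L] - v[i + 1L]
  den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  dt <- if (abs(den) > 0) 0.5 * step * num / den else 0
  dt <- min(max(dt, -step), step)
  aphv <- grid[i] + dt
  peak_estimate(aphv, sitar_velocity(fit, aphv), boundary_flag = FALSE)
}

#' Choose the spline df by BIC
#'
#' Fits SITAR at each candidate df and returns the per-candidate BIC table and
#' the BIC-minimizing df. Candidates that fail to converge are skipped with a
#' warning.
#'
#' @param data as in [fit_sitar()].
#' @param candidates integer vector of df values to try.
#' @param ... passed to [fit_sitar()].
#' @return list with `table` (df, loglik, n_params, bic, converged) and
#'   `best` (the selected df); the fit at the selected df is in `fit`.
#' @export
select_df <- function(data, candidates = 2:5, ...) {
  dfs <- seq(2L, max(candidates))
  all_fits <- sitar_chain(data, dfs = dfs, keep_all = TRUE, ...)
  rows <- list()
  fits <- list()
  for (df in sort(unique(candidates))) {
    f <- all_fits[[as.character(df)]]
    if (is.null(f) || inherits(f, "error")) {
      if (!is.null(f)) warning("df = ", df, " failed: ", conditionMessage(f))
      rows[[length(rows) + 1L]] <- data.frame(df = df, loglik = NA_real_,
                                              n_params = NA_integer_,
                                              bic = NA_real_, converged = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(df = df, loglik = f$loglik,
                                              n_params = f$n_params,
                                              bic = bic(f$loglik, f$n_params, f$n_obs),
                                              converged = TRUE)
      fits[[as.character(df)]] <- f
    }
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$converged)) stop("all candidate df values failed", call. = FALSE)
  ok <- tab[tab$converged, ]
  best <- ok$df[which.min(ok$bic)]
  list(table = tab, best = best, fit = fits[[as.character(best)]])
}

#' Serialize a SITAR fit to JSON
#'
#' @param fit a `sitar_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sitar_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sitar_fit"))
  jsonlite::write_json(list(
    model = "SITAR",
    curve = unclass(fit$curve),
    fixed_offsets = as.list(fit$fixed_offsets),
    re_sd = as.list(fit$re_sd),
    re_corr = fit$re_corr,
    residual_sd = fit$residual_sd,
    loglik = fit$loglik, n_params = fit$n_params, n_obs = fit$n_obs
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export SITAR per-subject effects
#'
#' @param fit a `sitar_fit`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sitar_ranef <- function(fit, path) {
  utils::write.csv(fit$ranef, path, row.names = FALSE)
  invisible(path)
}

#' Export SITAR distance and velocity curves as a table
#'
#' @param fit a `sitar_fit`.
#' @param ages evaluation grid, years.
#' @return data.frame with columns `age`, `height`, `velocity`.
#' @export
sitar_curve_table <- function(fit, ages = seq(7, 20, by = 0.1)) {
  data.frame(age = ages,
             height = suppressWarnings(sitar_predict(fit, ages)),
             velocity = suppressWarnings(sitar_velocity(fit, ages)))
}
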