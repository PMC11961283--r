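#' Region-by-sex composition of the Young Lives Ethiopia older cohort
#'
#' Subject counts by region and sex for the 891-subject analysis sample of
#' the Young Lives Ethiopia older cohort (four survey rounds, 2002-2013).
#' Used for descriptive-summary checks and as the default composition of the
#' synthetic cohort.
#'
#' @return 2 x 5 integer matrix, rows `boy`/`girl`, columns the five regions.
#' @export
young_lives_composition <- function() {
  m <- rbind(boy  = c(60, 98, 99, 118, 97),
             girl = c(64, 86, 87, 92, 90))
  colnames(m) <- region_levels()
  m
}

#' @rdname young_lives_composition
#' @export
region_levels <- function() c("AddisAbaba", "Amhara", "Oromia", "SNNPRS", "Tigrai")

#' Construct a simulation-truth median curve
#'
#' Builds a monotone natural cubic spline height curve whose velocity peaks at
#' a requested age and magnitude and whose height at the upper age bound
#' matches a requested near-adult height. A PB1 curve is used as the smooth
#' skeleton: its `(hc, s1, c)` are calibrated numerically so that, after
#' least-squares projection onto the spline basis, the spline's own velocity
#' peak lands on the targets (the projection smooths the peak slightly, so the
#' skeleton targets are adjusted iteratively).
#'
#' @param aphv target age at peak height velocity, years.
#' @param phv target peak height velocity, cm/year.
#' @param adult_height target height at `age_range[2]`, cm.
#' @param df spline degrees of freedom for the truth curve.
#' @param age_range ages over which the curve is defined, years.
#' @return a [spline_curve()] with attributes `aphv`, `phv` recording the
#'   realized peak.
#' @export
build_truth_curve <- function(aphv, phv, adult_height, df = 5L,
                              age_range = c(7, 20)) {
  grid <- seq(age_range[1], age_range[2], by = 0.05)
  xoff <- mean(grid)
  ## PB1 velocity is U-shaped: the prepubertal term can rival the spurt, so
  ## calibrate on the interior (pubertal) maximum and keep early-childhood
  ## velocity clearly below the spurt
  skeleton <- function(targ_a, targ_v) {
    mkp <- function(par)
      tryCatch(pb1_params(adult_height + 1.5, par[1], exp(par[2]), exp(par[3]),
                          par[4]),
               error = function(e) NULL)
    obj <- function(par) {
      p <- mkp(par)
      if (is.null(p) || p$c <= 7.5 || p$c >= 19.5) return(1e6)
      pk <- suppressWarnings(pb1_peak(p, interval = c(max(age_range[1], targ_a - 2.5),
                                                      min(age_range[2], targ_a + 2.5))))
      vchild <- pb1_velocity(age_range[1] + 0.5, p)
      (pk$aphv - targ_a)^2 + (pk$phv - targ_v)^2 +
        100 * max(0, vchild - 0.85 * targ_v)^2 +
        10 * pk$boundary_flag
    }
    start <- c(adult_height - 14, log(0.07), log(0.9), targ_a + 0.5)
    op <- stats::nlminb(start, obj)
    mkp(op$par)
  }
  spline_peak <- function(cv) {
    g <- seq(aphv - 3, min(aphv + 3, age_range[2] - 0.1), by = 0.01)
    v <- eval_curve(cv, g, deriv = 1)
    i <- which.max(v)
    c(g[i], v[i])
  }
  ta <- aphv; tv <- phv
  cv <- NULL
  for (iter in 1:6) {
    p <- skeleton(ta, tv)
    h <- pb1_height(grid, p)
    cv <- fit_spline_curve(grid, h, df = df, xoffset = xoff)
    pk <- spline_peak(cv)
    if (abs(pk[1] - aphv) < 5e-3 && abs(pk[2] - phv) < 5e-3) break
    ta <- ta + (aphv - pk[1])
    tv <- tv * (phv / pk[2])
  }
  ## pin the near-adult height exactly at the upper bound
  cv$intercept <- cv$intercept + (adult_height - eval_curve(cv, age_range[2]))
  pk <- spline_peak(cv)
  attr(cv, "aphv") <- pk[1]
  attr(cv, "phv") <- pk[2]
  cv
}

#' Default simulation configuration
#'
#' The study conditions emulated by the generator: 891 subjects (472 boys,
#' 419 girls) in the five-region composition of [young_lives_composition()],
#' four measurement rounds at target ages 8, 12, 15 and 19 years with +/- 0.4
#' year uniform jitter, SITAR truth with per-sex size/timing/intensity SDs of
#' 5.15/1.28/0.12 (boys) and 5.50/1.29/0.17 (girls), residual SDs 3.63 and
#' 2.82 cm, and median curves built by [build_truth_curve()] so that the
#' boys' velocity peak is (13.15 y, 5.57 cm/y) at near-adult height 174.6 cm
#' and the girls' is (10.49 y, 6.34 cm/y) at 162.2 cm.
#'
#' @param n_subjects total cohort size.
#' @param missingness per-round probability that a round-2..4 measurement is
#'   missing (round 1 is never lost).
#' @return an object of class `sim_config`.
#' @export
default_config <- function(n_subjects = 891L, missingness = 0) {
  comp <- young_lives_composition()
  structure(list(
    n_subjects = as.integer(n_subjects),
    boys_fraction = sum(comp["boy", ]) / sum(comp),
    region_levels = region_levels(),
    region_sex_props = comp / sum(comp),
    round_ages = c(8, 12, 15, 19),
    age_jitter = 0.4,
    truth_model = "SITAR",
    truth = list(
      boy = list(aphv = 13.15, phv = 5.57, adult_height = 174.6,
                 re_sd = c(size = 5.15, timing = 1.28, intensity = 0.12),
                 re_corr = diag(3), residual_sd = 3.63),
      girl = list(aphv = 10.49, phv = 6.34, adult_height = 162.2,
                  re_sd = c(size = 5.50, timing = 1.29, intensity = 0.17),
                  re_corr = diag(3), residual_sd = 2.82)),
    truth_df = 5L,
    region_size_offset = stats::setNames(rep(0, 5), region_levels()),
    region_timing_offset = stats::setNames(rep(0, 5), region_levels()),
    missingness = missingness
  ), class = "sim_config")
}

#' PB1-truth simulation configuration
#'
#' Study conditions for fixed-effects recovery experiments: heights generated
#' from the sex-specific reference PB1 curves plus independent Gaussian
#' measurement noise at the four-round schedule, with no subject-level random
#' effects.
#'
#' @param n_subjects total cohort size.
#' @param residual_sd measurement noise SD, cm.
#' @return a `sim_config` with `truth_model = "PB1"`.
#' @export
pb1_config <- function(n_subjects = 891L, residual_sd = 3) {
  cfg <- default_config(n_subjects = n_subjects)
  cfg$truth_model <- "PB1"
  for (sx in c("boy", "girl")) {
    cfg$truth[[sx]]$pb1 <- pb1_reference_params(if (sx == "boy") "boys" else "girls")
    cfg$truth[[sx]]$re_sd <- c(size = 0, timing = 0, intensity = 0)
    cfg$truth[[sx]]$residual_sd <- residual_sd
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-cohort configuration:", x$n_subjects, "subjects,",
      sprintf("%.0f%% boys", 100 * x$boys_fraction), "\n")
  cat("  rounds at ages", paste(x$round_ages, collapse = ", "),
      sprintf("(+/- %.1f y)", x$age_jitter), "\n")
  cat("  truth:", x$truth_model, "- boys peak",
      sprintf("(%.2f y, %.2f cm/y)", x$truth$boy$aphv, x$truth$boy$phv),
      "girls peak",
      sprintf("(%.2f y, %.2f cm/y)", x$truth$girl$aphv, x$truth$girl$phv), "\n")
  invisible(x)
}

## largest-remainder allocation of n subjects to cells with given proportions
allocate_counts <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  base
}

#' Simulate a sparse four-round growth cohort
#'
#' Draws per-subject size/timing/intensity effects from the configured
#' trivariate normal, evaluates the sex-specific truth curve at jittered round
#' ages (transformed through [sitar_transform()] about the curve's age
#' origin), adds Gaussian measurement noise, rounds ages to 0.1 years and
#' heights to 0.1 cm as in the survey protocol, and applies missingness.
#' Fully reproducible from `seed`.
#'
#' @param config a [default_config()]-style `sim_config`.
#' @param seed integer seed; every source of randomness in the generator flows
#'   from it.
#' @return list with `cohort` (a [as_cohort_table()]) and `truth` (a
#'   `truth_record`: config echo, per-subject true effects, per-sex truth
#'   curves with their realized peaks).
#' @export
simulate_cohort <- function(config = default_config(), seed) {
  stopifnot(inherits(config, "sim_config"), !missing(seed))
  set.seed(seed)
  n <- config$n_subjects
  cells <- allocate_counts(n, as.numeric(config$region_sex_props))
  dim(cells) <- dim(config$region_sex_props)
  dimnames(cells) <- dimnames(config$region_sex_props)
  sex <- rep(rep(rownames(cells), ncol(cells)), as.integer(cells))
  region <- rep(rep(colnames(cells), each = nrow(cells)), as.integer(cells))
  ids <- sprintf("S%04d", seq_len(n))
  curves <- if (identical(config$truth_model, "PB1"))
    lapply(config$truth, function(tr) tr$pb1)
  else
    lapply(config$truth, function(tr)
      build_truth_curve(tr$aphv, tr$phv, tr$adult_height, df = config$truth_df))
  eff <- matrix(0, n, 3, dimnames = list(ids, c("alpha", "beta", "gamma")))
  for (sx in names(config$truth)) {
    sel <- sex == sx
    tr <- config$truth[[sx]]
    D <- diag(tr$re_sd) %*% tr$re_corr %*% diag(tr$re_sd)
    eff[sel, ] <- MASS::mvrnorm(sum(sel), mu = rep(0, 3), Sigma = D)
  }
  eff[, "alpha"] <- eff[, "alpha"] + config$region_size_offset[region]
  eff[, "beta"] <- eff[, "beta"] + config$region_timing_offset[region]
  nr <- length(config$round_ages)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ages <- round(config$round_ages +
                    stats::runif(nr, -config$age_jitter, config$age_jitter), 1)
    cv <- curves[[sex[i]]]
    mu <- if (inherits(cv, "pb1_params")) {
      eff[i, "alpha"] + pb1_height(ages, cv)
    } else {
      xs <- sitar_transform(ages - cv$xoffset, eff[i, "beta"], eff[i, "gamma"])
      eff[i, "alpha"] + cv$intercept +
        drop(natural_spline_basis(xs, cv$knots, cv$boundary) %*% cv$coef)
    }
    ht <- round(mu + stats::rnorm(nr, 0, config$truth[[sex[i]]]$residual_sd), 1)
    keep <- c(TRUE, stats::runif(nr - 1) >= config$missingness)
    rows[[i]] <- data.frame(subject_id = ids[i], sex = sex[i],
                            region = region[i], round = seq_len(nr),
                            age = ages, height = ht)[keep, ]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cohort <- as_cohort_table(tab, metadata = list(source = "simulate_cohort",
                                                 seed = seed))
  truth <- structure(list(config = config, seed = seed,
                          effects = data.frame(subject_id = ids, sex = sex,
                                               region = region,
                                               alpha = eff[, "alpha"],
                                               beta = eff[, "beta"],
                                               gamma = eff[, "gamma"],
                                               row.names = NULL),
                          curves = curves,
                          peaks = lapply(curves, function(cv) {
                            if (inherits(cv, "pb1_params")) {
                              pk <- suppressWarnings(pb1_peak(cv))
                              c(aphv = pk$aphv, phv = pk$phv)
                            } else c(aphv = attr(cv, "aphv"), phv = attr(cv, "phv"))
                          })),
                     class = "truth_record")
  list(cohort = cohort, truth = truth)
}

#' Serialize a truth record to JSON
#'
#' @param truth a `truth_record` from [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(list(
    seed = truth$seed,
    config = truth$config[setdiff(names(truth$config), "truth")],
    truth = truth$config$truth,
    peaks = truth$peaks,
    curves = lapply(truth$curves, unclass),
    effects = truth$effects
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' SITAR parameter-recovery suite over multiple seeds
#'
#' Simulates cohorts at the given configuration for each seed, fits SITAR per
#' sex, and stacks the [recovery_report()] rows. After the first seed, fits
#' are warm-started from the previous seed's solution (the truth is the same;
#' only the noise differs), which speeds the suite up substantially without
#' changing what is estimated.
#'
#' @param config a `sim_config`.
#' @param seeds integer vector of simulation seeds.
#' @param df SITAR spline df.
#' @param warm warm-start successive seeds (default TRUE).
#' @return data.frame of recovery rows with `seed` and `sex` columns.
#' @export
recovery_suite <- function(config = default_config(), seeds = 1:10, df = 5L,
                           warm = TRUE) {
  prev <- list(boy = NULL, girl = NULL)
  out <- list()
  for (s in seeds) {
    sim <- simulate_cohort(config, seed = s)
    for (sx in c("boy", "girl")) {
      d <- sim$cohort[sim$cohort$sex == sx, , drop = FALSE]
      class(d) <- class(sim$cohort)
      f <- if (is.null(prev[[sx]]) || !warm) fit_sitar(d, df = df)
      else fit_sitar(d, df = df, start_from = prev[[sx]], multistart = FALSE)
      prev[[sx]] <- f
      rep <- recovery_report(sim$truth, f, sx)
      rep$seed <- s
      rep$sex <- sx
      out[[paste(s, sx)]] <- rep
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PB1 fixed-effects recovery suite
#'
#' Repeatedly simulates cohorts from the PB1 truth ([pb1_config()]), fits the
#' population-average PB1 model, and records for each replicate whether every
#' fixed effect lies within `k_se` standard errors of its generating value.
#'
#' @param n_reps number of replicates.
#' @param config a `sim_config` with `truth_model = "PB1"`.
#' @param seed base seed; replicate r uses `seed * 1000 + r`.
#' @param k_se the coverage multiple (default 3).
#' @return data.frame with one row per replicate x parameter: `rep`, `sex`,
#'   `parameter`, `truth`, `estimate`, `se`, `covered`.
#' @export
pb1_recovery_suite <- function(n_reps = 50L, config = pb1_config(n_subjects = 400L),
                               seed = 1L, k_se = 3) {
  out <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_cohort(config, seed = seed * 1000L + r)
    for (sx in c("boy", "girl")) {
      d <- sim$cohort[sim$cohort$sex == sx, , drop = FALSE]
      tru <- unlist(unclass(config$truth[[sx]]$pb1))
      f <- tryCatch(fit_pb1(d$age, d$height), error = function(e) NULL)
      if (is.null(f)) {
        out[[paste(r, sx)]] <- data.frame(rep = r, sex = sx,
                                          parameter = names(tru), truth = tru,
                                          estimate = NA_real_, se = NA_real_,
                                          covered = FALSE, row.names = NULL)
        next
      }
      est <- unlist(unclass(f$params))
      out[[paste(r, sx)]] <- data.frame(
        rep = r, sex = sx, parameter = names(tru), truth = tru,
        estimate = est[names(tru)], se = f$std_errors[names(tru)],
        covered = abs(est[names(tru)] - tru) <= k_se * f$std_errors[names(tru)],
        row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parameter-recovery report
#'
#' Compares a fit against the generating truth, one row per scalar quantity:
#' variance components and curve-level peak quantities for a SITAR fit; only
#' the curve-level (APHV, PHV) rows for a cross-family PB1 fit, labelled as
#' such rather than erroring (cross-family fits are a legitimate experiment).
#'
#' @param truth a `truth_record`.
#' @param fit a `sitar_fit` or `pb1_fit`.
#' @param sex which sex's truth the fit corresponds to (`"boy"`/`"girl"`).
#' @return data.frame with columns `parameter`, `truth`, `estimate`, `bias`,
#'   `rel_bias`, `ci_covers` (NA where no standard error is available).
#' @export
recovery_report <- function(truth, fit, sex = c("boy", "girl")) {
  stopifnot(inherits(truth, "truth_record"))
  sex <- match.arg(sex)
  tr <- truth$config$truth[[sex]]
  pk_true <- truth$peaks[[sex]]
  row <- function(parameter, tru, est, se = NA_real_) {
    data.frame(parameter = parameter, truth = tru, estimate = est,
               bias = est - tru,
               rel_bias = if (tru != 0) (est - tru) / tru else NA_real_,
               ci_covers = if (is.finite(se)) abs(est - tru) <= 1.96 * se else NA)
  }
  if (inherits(fit, "sitar_fit")) {
    pk <- sitar_peak(fit)
    out <- rbind(
      row("sd_size", tr$re_sd["size"], unname(fit$re_sd["size"])),
      row("sd_timing", tr$re_sd["timing"], unname(fit$re_sd["timing"])),
      row("sd_intensity", tr$re_sd["intensity"], unname(fit$re_sd["intensity"])),
      row("residual_sd", tr$residual_sd, fit$residual_sd),
      row("aphv", unname(pk_true["aphv"]), pk$aphv),
      row("phv", unname(pk_true["phv"]), pk$phv))
  } else if (inherits(fit, "pb1_fit") && identical(truth$config$truth_model, "PB1")) {
    est <- unlist(unclass(fit$params))
    tru <- unlist(unclass(tr$pb1))
    out <- rbind(
      do.call(rbind, lapply(names(est), function(p)
        row(p, tru[[p]], est[[p]], fit$std_errors[[p]]))),
      row("residual_sd", tr$residual_sd, fit$residual_sd))
  } else if (inherits(fit, "pb1_fit")) {
    pk <- suppressWarnings(pb1_peak(fit$params))
    out <- rbind(
      row("aphv [PB1 cross-family]", unname(pk_true["aphv"]), pk$aphv),
      row("phv [PB1 cross-family]", unname(pk_true["phv"]), pk$phv))
  } else stop("unsupported fit class", call. = FALSE)
  rownames(out) <- NULL
  out
}
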