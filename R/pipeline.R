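#' Compare SITAR and PB1 fits by BIC, per sex
#'
#' Fits the SITAR mixed-effects model and the population-average PB1 model to
#' each sex and tabulates log-likelihood, parameter count and BIC. A model
#' failing for one sex is reported as a failed row and the comparison proceeds
#' as long as at least one model succeeds for that sex.
#'
#' @param table a `cohort_table`.
#' @param df SITAR spline df.
#' @param ... passed to [fit_sitar()].
#' @return list with `table` (sex, model, loglik, n_params, bic, converged,
#'   winner) and `fits` (named list of the successful fits).
#' @export
run_compare <- function(table, df = 5L, ...) {
  stopifnot(inherits(table, "cohort_table"))
  rows <- list()
  fits <- list()
  for (sx in c("boy", "girl")) {
    d <- table[table$sex == sx, , drop = FALSE]
    class(d) <- class(table)
    if (!nrow(d)) next
    sf <- tryCatch(fit_sitar(d, df = df, ...), error = function(e) e)
    pf <- tryCatch(fit_pb1(d$age, d$height), error = function(e) e)
    mk <- function(model, f) {
      if (inherits(f, "error"))
        data.frame(sex = sx, model = model, loglik = NA_real_,
                   n_params = NA_integer_, bic = NA_real_, converged = FALSE)
      else
        data.frame(sex = sx, model = model, loglik = f$loglik,
                   n_params = f$n_params,
                   bic = bic(f$loglik, f$n_params, f$n_obs), converged = TRUE)
    }
    r <- rbind(mk("SITAR", sf), mk("PB1", pf))
    if (!any(r$converged))
      stop("both models failed for sex '", sx, "'", call. = FALSE)
    r$winner <- FALSE
    r$winner[which.min(replace(r$bic, !r$converged, Inf))] <- TRUE
    rows[[sx]] <- r
    if (!inherits(sf, "error")) fits[[paste0("sitar_", sx)]] <- sf
    if (!inherits(pf, "error")) fits[[paste0("pb1_", sx)]] <- pf
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)), fits = fits)
}

#' Regional growth analysis
#'
#' Per-region-by-sex SITAR fits for the peak-velocity table (strata too small
#' to fit are skipped with a warning), plus, per sex, a joint SITAR fit with
#' fixed region offsets on size and Wald contrasts of each region against the
#' reference region.
#'
#' @param table a `cohort_table`.
#' @param reference reference region for the contrasts.
#' @param df SITAR spline df.
#' @param holm also report Holm-adjusted p-values (the raw p-values stay the
#'   default reporting).
#' @param ... passed to [fit_sitar()].
#' @return list with `peaks` (region, sex, n_subjects, aphv, phv,
#'   boundary_flag), `contrasts` (sex, region, estimate, se, z, p_value, and
#'   `p_holm` if requested), and `joint_fits`.
#' @export
run_regional <- function(table, reference = "AddisAbaba", df = 5L,
                         holm = FALSE, ...) {
  stopifnot(inherits(table, "cohort_table"))
  if (!reference %in% table$region)
    stop("configuration error: reference region '", reference,
         "' absent from the data", call. = FALSE)
  peaks <- list()
  for (sx in unique(table$sex)) for (rg in unique(table$region)) {
    d <- table[table$sex == sx & table$region == rg, , drop = FALSE]
    class(d) <- class(table)
    ns <- length(unique(d$subject_id))
    f <- tryCatch(fit_sitar(d, df = df, ...), error = function(e) e)
    if (inherits(f, "error")) {
      warning("stratum ", rg, " x ", sx, " skipped: ", conditionMessage(f))
      next
    }
    pk <- sitar_peak(f)
    peaks[[paste(sx, rg)]] <- data.frame(region = rg, sex = sx, n_subjects = ns,
                                         aphv = pk$aphv, phv = pk$phv,
                                         boundary_flag = pk$boundary_flag)
  }
  contrasts <- list()
  joint <- list()
  for (sx in unique(table$sex)) {
    d <- table[table$sex == sx, , drop = FALSE]
    class(d) <- class(table)
    reg <- factor(d$region, levels = c(reference,
                                       setdiff(sort(unique(d$region)), reference)))
    jf <- tryCatch(fit_sitar(d, df = df, size_by = reg, ...),
                   error = function(e) e)
    if (inherits(jf, "error")) {
      warning("joint regional fit failed for sex '", sx, "': ",
              conditionMessage(jf))
      next
    }
    joint[[sx]] <- jf
    en <- names(jf$engine$beta)
    off_idx <- grep("^a\\.f", en)
    res <- lapply(off_idx, function(j) {
      cvec <- as.numeric(seq_along(en) == j)
      wc <- wald_contrast(jf$engine, cvec)
      data.frame(sex = sx, region = sub("^a\\.f", "", en[j]),
                 estimate = wc$estimate, se = wc$se, z = wc$z,
                 p_value = wc$p_value)
    })
    contrasts[[sx]] <- do.call(rbind, res)
  }
  contrasts <- if (length(contrasts))
    do.call(rbind, c(contrasts, make.row.names = FALSE)) else NULL
  if (holm && !is.null(contrasts))
    contrasts$p_holm <- stats::p.adjust(contrasts$p_value, method = "holm")
  peaks <- if (length(peaks))
    do.call(rbind, c(peaks, make.row.names = FALSE)) else NULL
  list(peaks = peaks, contrasts = contrasts, joint_fits = joint)
}

#' Write the analysis report tables
#'
#' Writes the five report tables as CSV plus a short human-readable summary:
#' cohort composition, model comparison, SITAR variance components, PB1 fixed
#' effects with estimate correlations, and the regional peaks/contrasts.
#' Deterministic given its inputs; tables for missing fits are omitted and
#' noted in the summary.
#'
#' @param report a list as produced by [run_all()] (fields `summary`,
#'   `compare`, `regional`, and optionally `metadata`).
#' @param out_dir output directory, created if needed.
#' @return character vector of the files written, invisibly.
#' @export
run_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  lines <- c("Growth analysis report", "======================")
  if (!is.null(report$metadata))
    lines <- c(lines, paste0(names(report$metadata), ": ",
                             unlist(lapply(report$metadata, paste, collapse = " "))))
  if (!is.null(report$summary)) {
    cs <- report$summary
    put(data.frame(sex = rep(rownames(cs$counts), ncol(cs$counts)),
                   region = rep(colnames(cs$counts), each = nrow(cs$counts)),
                   n = as.integer(cs$counts),
                   within_region_pct = as.numeric(cs$within_region_pct)),
        "cohort_summary.csv")
    lines <- c(lines, sprintf("Cohort: %d subjects (%d boys, %d girls)",
                              cs$total, cs$sex_totals["boy"], cs$sex_totals["girl"]))
  }
  if (!is.null(report$compare)) {
    put(report$compare$table, "model_comparison.csv")
    w <- report$compare$table
    for (sx in unique(w$sex))
      lines <- c(lines, sprintf("Best fit (%s): %s by BIC", sx,
                                w$model[w$sex == sx & w$winner]))
    sit <- report$compare$fits[grep("^sitar_", names(report$compare$fits))]
    if (length(sit)) {
      vc <- do.call(rbind, lapply(names(sit), function(nm) {
        f <- sit[[nm]]
        data.frame(sex = sub("^sitar_", "", nm),
                   size_sd = f$re_sd["size"], timing_sd = f$re_sd["timing"],
                   intensity_sd = f$re_sd["intensity"],
                   residual_sd = f$residual_sd, row.names = NULL)
      }))
      put(vc, "sitar_variance_components.csv")
      pk <- do.call(rbind, lapply(names(sit), function(nm) {
        p <- sitar_peak(sit[[nm]])
        data.frame(sex = sub("^sitar_", "", nm), aphv = p$aphv, phv = p$phv,
                   row.names = NULL)
      }))
      put(pk, "sitar_peaks.csv")
      if (nrow(pk) == 2) {
        dA <- pk$aphv[pk$sex == "boy"] - pk$aphv[pk$sex == "girl"]
        lines <- c(lines, sprintf("APHV sex difference (boys - girls): %.2f years", dA))
      }
    }
    pbf <- report$compare$fits[grep("^pb1_", names(report$compare$fits))]
    if (length(pbf)) {
      fe <- do.call(rbind, lapply(names(pbf), function(nm) {
        f <- pbf[[nm]]
        est <- unlist(unclass(f$params))
        data.frame(sex = sub("^pb1_", "", nm), parameter = names(est),
                   estimate = est, std_error = as.numeric(f$std_errors),
                   row.names = NULL)
      }))
      put(fe, "pb1_fixed_effects.csv")
      co <- do.call(rbind, lapply(names(pbf), function(nm) {
        m <- pbf[[nm]]$corr
        data.frame(sex = sub("^pb1_", "", nm),
                   row = rep(rownames(m), ncol(m)),
                   col = rep(colnames(m), each = nrow(m)),
                   corr = as.numeric(m), row.names = NULL)
      }))
      put(co, "pb1_correlations.csv")
    } else lines <- c(lines, "PB1 fits unavailable; PB1 tables omitted")
  }
  if (!is.null(report$regional)) {
    if (!is.null(report$regional$peaks)) put(report$regional$peaks, "regional_peaks.csv")
    if (!is.null(report$regional$contrasts)) {
      put(report$regional$contrasts, "regional_contrasts.csv")
      sig <- report$regional$contrasts
      sig <- sig[sig$p_value < 0.05, , drop = FALSE]
      lines <- c(lines, sprintf("Regions differing from reference at 0.05: %d of %d contrasts",
                                nrow(sig), nrow(report$regional$contrasts)))
    }
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  files <- c(files, file.path(out_dir, "summary.txt"))
  invisible(files)
}

#' Run the whole analysis pipeline
#'
#' Simulates (or takes) a cohort, applies the inclusion rules, fits SITAR and
#' PB1 per sex, compares them by BIC, runs the regional analysis, and
#' optionally writes the report tables. Headless and reproducible from one
#' configuration and one seed.
#'
#' @param config a [default_config()] `sim_config` (ignored when `table` is
#'   supplied).
#' @param seed integer seed for the simulation.
#' @param table optional `cohort_table` to analyse instead of simulating.
#' @param out_dir optional report directory; when given, [run_report()] runs.
#' @param df SITAR spline df.
#' @param inclusion apply [compute_haz()] + [apply_inclusion()] first.
#' @param regional run the regional analysis.
#' @return list (`AnalysisReport`): `summary`, `compare`, `regional`,
#'   `exclusions`, `metadata`.
#' @export
run_all <- function(config = default_config(), seed = 1L, table = NULL,
                    out_dir = NULL, df = 5L, inclusion = TRUE,
                    regional = TRUE) {
  truth <- NULL
  if (is.null(table)) {
    sim <- simulate_cohort(config, seed = seed)
    table <- sim$cohort
    truth <- sim$truth
  }
  excl <- NULL
  if (inclusion) {
    tz <- compute_haz(table)
    res <- apply_inclusion(tz)
    table <- res$table
    excl <- res$report
  }
  out <- list(
    summary = cohort_summary(table),
    compare = run_compare(table, df = df),
    regional = if (regional) run_regional(table, df = df) else NULL,
    exclusions = excl,
    truth = truth,
    metadata = list(seed = seed, n_records = nrow(table),
                    n_subjects = length(unique(table$subject_id))))
  if (!is.null(out_dir)) run_report(out, out_dir)
  out
}
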