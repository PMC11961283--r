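#' Validate and construct a cohort table
#'
#' The universal input currency: one height measurement per subject-round in
#' long format. Validation enforces the sanity bounds (ages 7-20.5 years,
#' heights 80-220 cm), integer rounds 1-4, uniqueness of (subject, round),
#' and that age increases with round within a subject. Offending rows are
#' reported by row number.
#'
#' @param df data.frame with columns `subject_id`, `sex` (`boy`/`girl`),
#'   `region`, `round`, `age`, `height`, and optionally `chronic_condition`
#'   (logical, default `FALSE`).
#' @param metadata free-form provenance list stored as an attribute.
#' @return the validated data.frame with class `cohort_table`.
#' @export
as_cohort_table <- function(df, metadata = list()) {
  req <- c("subject_id", "sex", "region", "round", "age", "height")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("configuration error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)
  df$subject_id <- as.character(df$subject_id)
  df$sex <- as.character(df$sex)
  df$region <- as.character(df$region)
  df$round <- suppressWarnings(as.integer(df$round))
  df$age <- suppressWarnings(as.numeric(df$age))
  df$height <- suppressWarnings(as.numeric(df$height))
  if (is.null(df$chronic_condition)) df$chronic_condition <- FALSE
  df$chronic_condition <- as.logical(df$chronic_condition)
  bad <- which(
    is.na(df$age) | is.na(df$height) | is.na(df$round) |
      df$age < 7 | df$age > 20.5 | df$height < 80 | df$height > 220 |
      df$round < 1L | df$round > 4L |
      !df$sex %in% c("boy", "girl") |
      !df$region %in% region_levels() |
      is.na(df$chronic_condition))
  if (length(bad))
    stop("validation error: invalid rows: ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) sprintf(" (and %d more)", length(bad) - 20),
         call. = FALSE)
  key <- paste(df$subject_id, df$round)
  if (anyDuplicated(key))
    stop("validation error: duplicate (subject_id, round) rows: ",
         paste(utils::head(which(duplicated(key)), 20), collapse = ", "),
         call. = FALSE)
  ord <- order(df$subject_id, df$round)
  dfo <- df[ord, ]
  inc <- unlist(tapply(dfo$age, dfo$subject_id,
                       function(a) if (length(a) > 1) diff(a) <= 0 else logical(0)),
                use.names = FALSE)
  if (any(inc))
    stop("validation error: age must increase with round within a subject",
         call. = FALSE)
  nrec <- table(df$subject_id)
  if (any(nrec > 4L))
    stop("validation error: subjects with more than 4 records", call. = FALSE)
  structure(df, class = c("cohort_table", "data.frame"),
            metadata = metadata)
}

#' Read a cohort table from CSV
#'
#' UTF-8, comma-separated, header required. Arbitrary headers are supported
#' through `dialect`, a named character vector mapping the canonical column
#' names to the file's headers.
#'
#' @param path CSV file.
#' @param dialect named character vector; names are the canonical columns
#'   (`subject_id`, `sex`, `region`, `round`, `age`, `height`, optionally
#'   `chronic_condition`), values the file's column headers. Defaults to the
#'   identity mapping.
#' @param metadata provenance list.
#' @return a [as_cohort_table()].
#' @export
read_cohort <- function(path, dialect = NULL, metadata = list(file = path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(dialect)) {
    dialect <- stats::setNames(
      intersect(c("subject_id", "sex", "region", "round", "age", "height",
                  "chronic_condition"), names(raw)),
      intersect(c("subject_id", "sex", "region", "round", "age", "height",
                  "chronic_condition"), names(raw)))
  }
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss))
    stop("configuration error: file lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- stats::setNames(raw[, unname(dialect), drop = FALSE], names(dialect))
  as_cohort_table(df, metadata = metadata)
}

#' Write a cohort table to CSV
#'
#' @param table a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Height-for-age reference chart
#'
#' A grid of (sex, age) to (mean height, SD) with linear interpolation in age,
#' used for height-for-age z-scores.
#'
#' @param df data.frame with columns `sex`, `age`, `mean`, `sd`.
#' @return object of class `reference_chart`.
#' @export
reference_chart <- function(df) {
  stopifnot(all(c("sex", "age", "mean", "sd") %in% names(df)))
  if (any(df$sd <= 0)) stop("reference chart SD must be positive", call. = FALSE)
  structure(df[order(df$sex, df$age), ], class = c("reference_chart", "data.frame"))
}

#' @rdname reference_chart
#' @param path CSV with columns `sex`, `age_years`, `mean_cm`, `sd_cm`.
#' @export
read_reference_chart <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_years", "mean_cm", "sd_cm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("configuration error: reference chart lacks: ",
         paste(miss, collapse = ", "), call. = FALSE)
  reference_chart(data.frame(sex = raw$sex, age = raw$age_years,
                             mean = raw$mean_cm, sd = raw$sd_cm))
}

#' Cohort-internal empirical reference
#'
#' Builds a height-for-age reference from the cohort itself: per sex, ages are
#' binned to the nearest year and the bin mean and SD form the chart grid,
#' extended flat by half a year at either end so every observed age is
#' covered. Used as the default reference when no external chart is supplied.
#'
#' @param table a `cohort_table`.
#' @return a [reference_chart()].
#' @export
empirical_reference <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  out <- list()
  for (sx in unique(table$sex)) {
    d <- table[table$sex == sx, ]
    bin <- round(d$age)
    mu <- tapply(d$height, bin, mean)
    sd_ <- tapply(d$height, bin, stats::sd)
    n <- tapply(d$height, bin, length)
    ## bins too small for their own SD borrow the pooled within-bin SD
    pooled <- stats::sd(d$height - mu[as.character(bin)])
    if (!is.finite(pooled) || pooled <= 0) pooled <- max(stats::sd(d$height), 1)
    bad_sd <- !(n >= 2 & is.finite(sd_) & sd_ > 0)
    sd_[bad_sd] <- pooled
    grid <- data.frame(sex = sx, age = as.numeric(names(mu)),
                       mean = as.numeric(mu), sd = as.numeric(sd_))
    lo <- grid[1, ]; lo$age <- min(d$age) - 0.01
    hi <- grid[nrow(grid), ]; hi$age <- max(d$age) + 0.01
    out[[sx]] <- rbind(lo, grid, hi)
  }
  reference_chart(do.call(rbind, out))
}

#' Height-for-age z-scores
#'
#' Annotates the table with `z = (height - mean(sex, age)) / sd(sex, age)`,
#' with the reference mean and SD linearly interpolated in age.
#'
#' @param table a `cohort_table`.
#' @param ref a [reference_chart()]; default is the cohort-internal
#'   [empirical_reference()].
#' @return the table with a `z` column added.
#' @export
compute_haz <- function(table, ref = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (is.null(ref)) ref <- empirical_reference(table)
  stopifnot(inherits(ref, "reference_chart"))
  z <- rep(NA_real_, nrow(table))
  for (sx in unique(table$sex)) {
    sel <- table$sex == sx
    g <- ref[ref$sex == sx, ]
    if (!nrow(g)) stop("reference chart lacks sex '", sx, "'", call. = FALSE)
    a <- table$age[sel]
    out_of_range <- a < min(g$age) | a > max(g$age)
    if (any(out_of_range)) {
      rec <- which(sel)[which(out_of_range)[1]]
      stop(sprintf("age %.1f of subject %s (row %d) outside the reference grid [%.1f, %.1f]",
                   table$age[rec], table$subject_id[rec], rec,
                   min(g$age), max(g$age)), call. = FALSE)
    }
    mu <- stats::approx(g$age, g$mean, xout = a)$y
    sd_ <- stats::approx(g$age, g$sd, xout = a)$y
    z[sel] <- (table$height[sel] - mu) / sd_
  }
  table$z <- z
  table
}

#' Apply the inclusion rules
#'
#' A subject is excluded entirely (all rounds dropped) when any of their
#' rounds violates a rule: height-for-age z below `z_min`, or a chronic
#' condition flag when `require_no_chronic`. Subjects (not single
#' observations) are the unit of inclusion. Idempotent.
#'
#' @param table a `cohort_table`; must carry a `z` column (see
#'   [compute_haz()]) unless `z_min` is `NULL`.
#' @param z_min z-score threshold (default -2); `NULL` disables the screen.
#' @param require_no_chronic drop subjects with any chronic-condition flag.
#' @return list with `table` (filtered `cohort_table`) and `report`
#'   (data.frame `subject_id`, `reason`; empty when nothing is excluded).
#' @export
apply_inclusion <- function(table, z_min = -2, require_no_chronic = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  drop_ids <- character(0)
  reasons <- character(0)
  if (!is.null(z_min)) {
    if (is.null(table$z))
      stop("z column required; run compute_haz() first", call. = FALSE)
    low <- unique(table$subject_id[table$z < z_min])
    drop_ids <- c(drop_ids, low)
    reasons <- c(reasons, rep("low_haz", length(low)))
  }
  if (require_no_chronic) {
    chr <- unique(table$subject_id[table$chronic_condition])
    new <- setdiff(chr, drop_ids)
    drop_ids <- c(drop_ids, new)
    reasons <- c(reasons, rep("chronic_condition", length(new)))
  }
  keep <- !(table$subject_id %in% drop_ids)
  out <- table[keep, , drop = FALSE]
  attr(out, "metadata") <- attr(table, "metadata")
  class(out) <- class(table)
  list(table = out,
       report = data.frame(subject_id = drop_ids, reason = reasons,
                           stringsAsFactors = FALSE))
}

#' @rdname apply_inclusion
#' @param report the exclusion report.
#' @param path CSV path.
#' @export
write_exclusion_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Cohort composition summary
#'
#' Subject counts by region and sex with the two percentage conventions of a
#' cohort-description table: the within-region sex share and each region's
#' share of the total, both rounded to one decimal.
#'
#' @param table a `cohort_table`.
#' @return object of class `cohort_summary`: `counts` (sex x region),
#'   `sex_totals`, `region_totals`, `total`, `within_region_pct`,
#'   `region_share_pct`, `sex_pct`.
#' @export
cohort_summary <- function(table) {
  stopifnot(inherits(table, "cohort_table"), nrow(table) > 0)
  subj <- unique(as.data.frame(table)[, c("subject_id", "sex", "region")])
  counts <- table(factor(subj$sex, levels = c("boy", "girl")),
                  factor(subj$region, levels = region_levels()))
  counts <- unclass(counts)[, colSums(counts) > 0 | TRUE, drop = FALSE]
  total <- sum(counts)
  region_totals <- colSums(counts)
  sex_totals <- rowSums(counts)
  wr <- sweep(counts, 2, pmax(region_totals, 1), "/") * 100
  structure(list(counts = counts,
                 sex_totals = sex_totals,
                 region_totals = region_totals,
                 total = total,
                 within_region_pct = round(wr, 1),
                 region_share_pct = round(region_totals / total * 100, 1),
                 sex_pct = round(sex_totals / total * 100, 0)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort composition (", x$total, " subjects)\n", sep = "")
  tab <- rbind(x$counts, total = x$region_totals)
  print(tab)
  cat("Within-region sex share (%):\n")
  print(x$within_region_pct)
  cat("Region share of total (%):\n")
  print(x$region_share_pct)
  cat("Sex split (%):", paste(names(x$sex_pct), x$sex_pct, collapse = ", "), "\n")
  invisible(x)
}

#' Skeleton cohort from a composition matrix
#'
#' Expands a sex-by-region count matrix into a minimal one-record-per-subject
#' cohort table (round 1 placeholders), convenient for descriptive-summary
#' arithmetic on published composition tables.
#'
#' @param counts 2 x k matrix, rows `boy`/`girl`.
#' @return a [as_cohort_table()].
#' @export
cohort_from_counts <- function(counts) {
  sex <- rep(rep(rownames(counts), ncol(counts)), as.integer(counts))
  region <- rep(rep(colnames(counts), each = nrow(counts)), as.integer(counts))
  n <- length(sex)
  as_cohort_table(data.frame(
    subject_id = sprintf("C%04d", seq_len(n)), sex = sex, region = region,
    round = 1L, age = 8.0, height = 125.0),
    metadata = list(source = "cohort_from_counts"))
}
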