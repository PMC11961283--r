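test_that("CSV round-trip reproduces a table field-for-field", {
  tab <- as_cohort_table(toy_cohort_df())
  tmp <- tempfile(fileext = ".csv")
  write_cohort(tab, tmp)
  back <- read_cohort(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(length(unique(back$subject_id)), 2L)
  expect_equal(nrow(back), 8L)
})

test_that("column mapping supports arbitrary headers and reports missing columns", {
  df <- toy_cohort_df()
  names(df) <- c("id", "SEX", "reg", "visit", "age_y", "ht_cm")
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  tab <- read_cohort(tmp, dialect = c(subject_id = "id", sex = "SEX",
                                      region = "reg", round = "visit",
                                      age = "age_y", height = "ht_cm"))
  expect_s3_class(tab, "cohort_table")
  expect_error(read_cohort(tmp, dialect = c(subject_id = "id", sex = "SEX",
                                            region = "reg", round = "visit",
                                            age = "age_y", height = "missing_col")),
               "configuration error")
  expect_error(read_cohort(tmp), "configuration error")
})

test_that("validation rejects bad rows with row numbers", {
  df <- toy_cohort_df()
  df$height[3] <- 500            # out of bounds
  expect_error(as_cohort_table(df), "invalid rows: 3")
  df2 <- toy_cohort_df()
  df2$round[2] <- 1L             # duplicate (subject, round)
  expect_error(as_cohort_table(df2), "duplicate")
  df3 <- toy_cohort_df()
  df3$age[2] <- 7.5              # age not increasing with round
  expect_error(as_cohort_table(df3), "age must increase")
  df4 <- toy_cohort_df()
  df4$height <- as.character(df4$height)
  df4$height[5] <- "tall"
  expect_error(as_cohort_table(df4), "invalid rows: 5")
})

test_that("height-for-age z-scores follow the chart arithmetic", {
  chart <- reference_chart(data.frame(
    sex = "boy", age = c(7, 10, 13, 16, 20),
    mean = c(120, 135, 150, 163, 172), sd = c(5, 6, 7, 7, 7)))
  df <- data.frame(subject_id = "A", sex = "boy", region = "Amhara",
                   round = 1:3, age = c(10.0, 11.5, 13.0),
                   height = c(135, 131, 136))
  tab <- compute_haz(as_cohort_table(df), chart)
  ## exactly at the age-10 mean
  expect_equal(tab$z[1], 0, tolerance = 1e-12)
  ## mean interpolates to 142.5, sd to 6.5 at age 11.5; height 131 = mean - a bit
  expect_equal(tab$z[2], (131 - 142.5) / 6.5, tolerance = 1e-12)
  ## mean - 2 sd maps to exactly -2
  tab2 <- compute_haz(as_cohort_table(transform(df, height = c(135, 142.5 - 2 * 6.5, 136))),
                      chart)
  expect_equal(tab2$z[2], -2, tolerance = 1e-12)
  ## generic arithmetic: mean 140, sd 6, height 131
  chart3 <- reference_chart(data.frame(sex = "boy", age = c(7, 20),
                                       mean = c(140, 140), sd = c(6, 6)))
  tab3 <- compute_haz(as_cohort_table(df), chart3)
  expect_equal(tab3$z[tab3$height == 131], -1.5, tolerance = 1e-12)
})

test_that("records outside the reference grid raise a named error", {
  chart <- reference_chart(data.frame(sex = c("boy", "boy"), age = c(9, 12),
                                      mean = c(130, 145), sd = c(6, 6)))
  tab <- as_cohort_table(toy_cohort_df())
  expect_error(compute_haz(tab, chart), "outside the reference grid")
})

test_that("inclusion drops whole subjects and is idempotent", {
  df <- toy_cohort_df()
  tab <- compute_haz(as_cohort_table(df))
  ## no violations: unchanged, empty report
  res <- apply_inclusion(tab)
  expect_equal(nrow(res$table), nrow(tab))
  expect_equal(nrow(res$report), 0L)
  ## one low-z round removes all four of that subject's rows
  tab2 <- tab
  tab2$z[2] <- -2.5
  res2 <- apply_inclusion(tab2)
  expect_equal(sort(unique(res2$table$subject_id)), "B")
  expect_equal(nrow(res2$table), 4L)
  expect_equal(res2$report$reason, "low_haz")
  ## idempotence
  res3 <- apply_inclusion(res2$table)
  expect_equal(as.data.frame(res3$table), as.data.frame(res2$table))
  expect_equal(nrow(res3$report), 0L)
  ## z_min NULL leaves only the chronic rule
  tab3 <- tab2
  tab3$chronic_condition[6] <- TRUE
  res4 <- apply_inclusion(tab3, z_min = NULL)
  expect_equal(sort(unique(res4$table$subject_id)), "A")
  expect_equal(res4$report$reason, "chronic_condition")
})

test_that("summary reproduces the published composition arithmetic", {
  tab <- cohort_from_counts(young_lives_composition())
  cs <- cohort_summary(tab)
  expect_equal(cs$total, 891L)
  expect_equal(unname(cs$sex_pct), c(53, 47))
  expect_equal(unname(cs$region_share_pct["AddisAbaba"]), 13.9)
  expect_equal(unname(cs$within_region_pct["boy", "AddisAbaba"]), 48.4)
  expect_equal(unname(cs$within_region_pct["girl", "SNNPRS"]), 43.8)
  ## percentages are internally consistent after rounding
  expect_true(all(abs(colSums(cs$within_region_pct) - 100) <= 0.1))
  expect_lte(abs(sum(cs$region_share_pct) - 100), 0.2)
})

test_that("single-subject summary puts 100% in its cell", {
  df <- toy_cohort_df()[1:4, ]
  cs <- cohort_summary(as_cohort_table(df))
  expect_equal(cs$total, 1L)
  expect_equal(unname(cs$within_region_pct["boy", "AddisAbaba"]), 100)
})

test_that("an external reference chart round-trips through its CSV dialect", {
  chart <- data.frame(sex = rep(c("boy", "girl"), each = 3),
                      age_years = rep(c(8, 13, 19), 2),
                      mean_cm = c(126, 152, 172, 125, 150, 160),
                      sd_cm = rep(5.5, 6))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(chart, tmp, row.names = FALSE)
  rc <- read_reference_chart(tmp)
  expect_s3_class(rc, "reference_chart")
  expect_equal(nrow(rc), 6L)
  expect_error(read_reference_chart({
    tmp2 <- tempfile(fileext = ".csv")
    utils::write.csv(chart[, -4], tmp2, row.names = FALSE)
    tmp2
  }), "configuration error")
})
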