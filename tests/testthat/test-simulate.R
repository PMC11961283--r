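test_that("default configuration encodes the emulated study design", {
  cfg <- default_config()
  expect_equal(cfg$n_subjects, 891L)
  expect_equal(cfg$boys_fraction, 472 / 891)
  expect_equal(sum(cfg$region_sex_props), 1)
  counts <- round(891 * colSums(cfg$region_sex_props))
  expect_equal(unname(counts), c(124, 184, 186, 210, 187))
  ## two calls give identical configurations
  expect_identical(default_config(), default_config())
})

test_that("truth curves hit their configured peaks and adult heights", {
  cfg <- default_config()
  for (sx in c("boy", "girl")) {
    tr <- cfg$truth[[sx]]
    cv <- build_truth_curve(tr$aphv, tr$phv, tr$adult_height)
    expect_equal(unname(attr(cv, "aphv")), tr$aphv, tolerance = 0.02)
    expect_equal(unname(attr(cv, "phv")), tr$phv, tolerance = 0.02)
    expect_equal(eval_curve(cv, 20), tr$adult_height, tolerance = 1e-6)
    ## monotone distance curve: velocity positive everywhere in range
    v <- eval_curve(cv, seq(7, 20, by = 0.05), deriv = 1)
    expect_true(all(v > 0))
    ## the configured peak is the global maximum over the whole range
    expect_equal(max(v), tr$phv, tolerance = 0.03)
  }
})

test_that("simulation is reproducible and respects the design", {
  cfg <- default_config()
  s1 <- simulate_cohort(cfg, seed = 42)
  s2 <- simulate_cohort(cfg, seed = 42)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth$effects, s2$truth$effects)
  ## byte-identical CSV export
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(s1$cohort, f1); write_cohort(s2$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## n x 4 records without missingness, composition at the configured cells
  expect_equal(nrow(s1$cohort), 891L * 4L)
  cs <- cohort_summary(s1$cohort)
  expect_equal(unname(cs$counts), unname(young_lives_composition()))
  ## observed ages inside the round schedule bounds
  for (r in 1:4) {
    a <- s1$cohort$age[s1$cohort$round == r]
    expect_true(all(abs(a - cfg$round_ages[r]) <= cfg$age_jitter + 0.051))
  }
  ## within a subject age increases with round
  expect_true(all(tapply(s1$cohort$age, s1$cohort$subject_id,
                         function(a) all(diff(a) > 0))))
})

test_that("missingness removes later rounds but never round 1", {
  cfg <- default_config(n_subjects = 300L, missingness = 0.3)
  sim <- simulate_cohort(cfg, seed = 7)
  expect_lt(nrow(sim$cohort), 1200L)
  r1 <- table(sim$cohort$round)
  expect_equal(unname(r1["1"]), 300L)
  expect_lt(unname(r1["3"]), 300L)
})

test_that("simulated size effects match the configured spread at large n", {
  cfg <- default_config(n_subjects = 10000L)
  sim <- simulate_cohort(cfg, seed = 99)
  eff <- sim$truth$effects
  for (sx in c("boy", "girl")) {
    sd_cfg <- cfg$truth[[sx]]$re_sd["size"]
    expect_lt(abs(sd(eff$alpha[eff$sex == sx]) - sd_cfg) / sd_cfg, 0.02)
  }
})

test_that("region offsets shift the configured groups", {
  cfg <- default_config(n_subjects = 2000L)
  cfg$region_size_offset["Amhara"] <- -4
  sim <- simulate_cohort(cfg, seed = 5)
  eff <- sim$truth$effects
  expect_equal(mean(eff$alpha[eff$region == "Amhara"]) -
                 mean(eff$alpha[eff$region == "Oromia"]), -4, tolerance = 0.6)
})

test_that("PB1-truth cohorts carry no subject heterogeneity", {
  cfg <- pb1_config(n_subjects = 200L)
  sim <- simulate_cohort(cfg, seed = 3)
  expect_true(all(sim$truth$effects$alpha == 0))
  d <- sim$cohort[sim$cohort$sex == "boy", ]
  mu <- pb1_height(d$age, pb1_reference_params("boys"))
  expect_lt(abs(sd(d$height - mu) - 3), 0.35)
})

test_that("recovery reports label perfect and cross-family fits correctly", {
  sim <- small_sim()
  f <- fit_sitar(sex_subset(sim$cohort, "boy"), df = 4)
  rep <- recovery_report(sim$truth, f, "boy")
  expect_true(all(c("sd_size", "sd_timing", "sd_intensity", "residual_sd",
                    "aphv", "phv") %in% rep$parameter))
  expect_equal(rep$bias, rep$estimate - rep$truth)
  ## cross-family: PB1 fit on SITAR truth gives curve-level rows only
  d <- sex_subset(sim$cohort, "boy")
  pf <- fit_pb1(d$age, d$height)
  repx <- recovery_report(sim$truth, pf, "boy")
  expect_equal(nrow(repx), 2L)
  expect_match(repx$parameter, "cross-family")
})

test_that("truth records serialize to JSON", {
  sim <- small_sim()
  tmp <- tempfile(fileext = ".json")
  write_truth_record(sim$truth, tmp)
  js <- jsonlite::read_json(tmp)
  expect_equal(js$seed, 5L)
  expect_length(js$effects, nrow(sim$truth$effects))
})
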