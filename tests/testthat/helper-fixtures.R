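## cached fixtures shared across test files (built once per test run)
.fixture_env <- new.env()

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

small_sim <- function(n = 160L, seed = 5L) {
  cached(sprintf("sim_%d_%d", n, seed),
         simulate_cohort(default_config(n_subjects = n), seed = seed))
}

sex_subset <- function(cohort, sx) {
  d <- cohort[cohort$sex == sx, , drop = FALSE]
  class(d) <- class(cohort)
  d
}

sitar_fit_small <- function() {
  cached("sitar_fit_small", {
    sim <- small_sim()
    fit_sitar(sex_subset(sim$cohort, "boy"), df = 4)
  })
}

## a tiny hand-made valid cohort table
toy_cohort_df <- function() {
  data.frame(
    subject_id = rep(c("A", "B"), each = 4),
    sex = rep(c("boy", "girl"), each = 4),
    region = rep(c("AddisAbaba", "Oromia"), each = 4),
    round = rep(1:4, 2),
    age = c(8.1, 12.0, 15.2, 19.0, 7.9, 11.8, 15.1, 18.9),
    height = c(126.0, 148.2, 164.0, 172.5, 124.1, 146.0, 157.2, 159.9))
}
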