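test_that("complete input returns M identical copies", {
  d <- make_harmonized(30, "validation_survey", seed = 1)
  d[fusemi:::.exposure_vars] <- lapply(d[fusemi:::.exposure_vars],
    function(x) factor(ifelse(is.na(x), "negative", as.character(x)),
                       levels = fusemi_levels$tristate))
  out <- chained_impute(d, fast_impute_config(M = 3, seed = 2))
  expect_length(out, 3)
  for (cd in out) expect_identical(cd$data, d)
  expect_equal(vapply(out, function(cd) cd$m, integer(1)), 1:3)
})

test_that("observed cells are never modified by imputation", {
  cfg <- small_sim_config(seed = 3)
  sys <- simulate_systems(cfg)
  stacked <- stack_sources(sys$control_survey, sys$validation_survey)
  out <- suppressWarnings(chained_impute(stacked,
                                         fast_impute_config(M = 2, seed = 4)))
  for (cd in out) {
    for (v in c(fusemi:::.exposure_vars, fusemi:::.demographic_vars)) {
      obs <- !is.na(stacked[[v]])
      expect_identical(cd$data[[v]][obs], stacked[[v]][obs])
      expect_false(anyNA(cd$data[[v]]))
    }
  }
})

test_that("a near-certain conditional cell imputes positive almost always", {
  # one missing binary cell whose fitted conditional probability is ~1
  set.seed(5)
  n <- 400
  tri <- function(x) factor(x, levels = fusemi_levels$tristate)
  d <- make_harmonized(n, "validation_survey", seed = 6)
  # blood perfectly predicted by self (by construction), one cell masked
  d$self_cannabis <- tri(sample(c("positive", "negative"), n, TRUE))
  d$blood_cannabis <- d$self_cannabis
  d$self_alcohol <- tri("negative")
  d$blood_alcohol <- tri("negative")
  d$oral_cannabis <- tri("negative")
  d$oral_alcohol <- tri("negative")
  d$blood_cannabis[1] <- NA
  d$self_cannabis[1] <- tri("positive")
  hits <- 0
  for (r in 1:200) {
    out <- chained_impute(d, fast_impute_config(M = 1, seed = r, iters = 2))
    hits <- hits + (as.character(out[[1]]$data$blood_cannabis[1]) ==
                      "positive")
  }
  expect_gte(hits / 200, 0.95)
})

test_that("masked values are recovered at the pre-masking prevalence", {
  cfg <- small_sim_config(seed = 7, population_size = 60000)
  cfg$design$validation_sample_size <- 6000
  cfg$missingness_rates$validation <- c()
  sys <- simulate_systems(cfg)
  v <- sys$validation_survey
  pre <- mean(v$blood_cannabis == "positive")
  set.seed(8)
  mask <- runif(nrow(v)) < 0.30             # MCAR mask
  v$blood_cannabis[mask] <- NA
  out <- suppressWarnings(chained_impute(
    v, imputation_config(n_imputations = 4, n_iterations = 5,
                         learner = "logistic", seed = 9)))
  imp_prev <- mean(vapply(out, function(cd)
    mean(cd$data$blood_cannabis == "positive"), numeric(1)))
  se <- sqrt(pre * (1 - pre) / sum(mask))
  expect_lt(abs(imp_prev - pre), 3 * se)
})

test_that("proper imputation produces strictly positive between-imputation variance", {
  cfg <- small_sim_config(seed = 10)
  sys <- simulate_systems(cfg)
  stacked <- stack_sources(sys$control_survey, sys$validation_survey)
  out <- suppressWarnings(chained_impute(
    stacked, imputation_config(n_imputations = 4, n_iterations = 3,
                               learner = "logistic", proper = TRUE,
                               seed = 11)))
  prev <- vapply(out, function(cd) {
    ctrl <- cd$data[cd$data$source == "control_survey", ]
    mean(ctrl$blood_cannabis == "positive")
  }, numeric(1))
  expect_gt(var(prev), 0)
})

test_that("registry imputation completes blood tests and education, leaves structural columns", {
  cfg <- small_sim_config(seed = 12, population_size = 40000)
  sys <- simulate_systems(cfg)
  out <- suppressWarnings(impute_case_registry(sys$case_registry,
                                               fast_impute_config(M = 2,
                                                                  seed = 13)))
  expect_length(out, 2)
  expect_equal(vapply(out, function(cd) cd$m, integer(1)), 1:2)
  for (cd in out) {
    expect_false(anyNA(cd$data$education))
    expect_false(anyNA(cd$data$blood_cannabis))
    expect_false(anyNA(cd$data$blood_alcohol))
    # never measured by this system: left missing and logged
    expect_true(all(is.na(cd$data$self_cannabis)))
    expect_true(any(grepl("structurally missing", cd$log)))
  }
  # no missing values: M identical copies
  complete_reg <- out[[1]]$data
  again <- impute_case_registry(complete_reg, fast_impute_config(M = 2,
                                                                 seed = 14))
  expect_identical(again[[1]]$data, complete_reg)
})

test_that("masked education is recovered at the pre-masking distribution", {
  cfg <- small_sim_config(seed = 15, population_size = 100000)
  cfg$missingness_rates$registry <- c()
  sys <- simulate_systems(cfg)
  reg <- sys$case_registry
  pre <- prop.table(table(reg$education))
  set.seed(16)
  mask <- runif(nrow(reg)) < 0.40
  reg$education[mask] <- NA
  out <- suppressWarnings(impute_case_registry(
    reg, imputation_config(n_imputations = 4, n_iterations = 4,
                           learner = "logistic", seed = 17)))
  post <- Reduce(`+`, lapply(out, function(cd)
    prop.table(table(cd$data$education)))) / 4
  se <- sqrt(pre * (1 - pre) / sum(mask))
  expect_true(all(abs(post - pre) < 3 * se + 0.02))
})

test_that("pairing excludes validation rows and preserves provenance", {
  cfg <- small_sim_config(seed = 18)
  sys <- simulate_systems(cfg)
  stacked <- stack_sources(sys$control_survey, sys$validation_survey)
  fus <- suppressWarnings(chained_impute(stacked,
                                         fast_impute_config(M = 2, seed = 19)))
  reg <- suppressWarnings(impute_case_registry(
    sys$case_registry, fast_impute_config(M = 2, seed = 20)))
  out <- pair_and_stack(fus, reg)
  expect_length(out, 2)
  n_ctrl <- nrow(sys$control_survey)
  n_reg <- nrow(sys$case_registry)
  for (m in 1:2) {
    expect_equal(nrow(out[[m]]$data), n_ctrl + n_reg)
    expect_false(any(out[[m]]$data$source == "validation_survey"))
    expect_equal(out[[m]]$m, m)
  }
  expect_error(pair_and_stack(fus, reg[1]), "unequal")
})

test_that("chained imputation is deterministic given the config seed", {
  cfg <- small_sim_config(seed = 21)
  sys <- simulate_systems(cfg)
  stacked <- stack_sources(sys$control_survey, sys$validation_survey)
  a <- suppressWarnings(chained_impute(stacked, fast_impute_config(M = 2,
                                                                   seed = 22)))
  b <- suppressWarnings(chained_impute(stacked, fast_impute_config(M = 2,
                                                                   seed = 22)))
  expect_identical(lapply(a, `[[`, "data"), lapply(b, `[[`, "data"))
})

test_that("imputed biomarker prevalence corrects the self-report direction", {
  # alcohol self-report grossly over-reports (specificity 0.47): the
  # imputed biomarker prevalence must fall far below the self-report rate
  cfg <- small_sim_config(seed = 25, population_size = 40000,
                          control_n = 3000, validation_n = 3000)
  sys <- simulate_systems(cfg)
  stacked <- stack_sources(sys$control_survey, sys$validation_survey)
  out <- suppressWarnings(chained_impute(stacked,
                                         fast_impute_config(M = 2, seed = 26)))
  ctrl <- out[[1]]$data[out[[1]]$data$source == "control_survey", ]
  self_rate <- mean(ctrl$self_alcohol == "positive")
  imp_rate <- mean(ctrl$blood_alcohol == "positive")
  expect_lt(imp_rate, self_rate / 3)
})
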