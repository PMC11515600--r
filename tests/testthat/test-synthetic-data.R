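test_that("generator is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 42)
  a <- simulate_systems(cfg)
  b <- simulate_systems(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$control_survey, b$control_survey)
  expect_identical(a$validation_raw, b$validation_raw)
  expect_identical(a$case_registry, b$case_registry)
})

test_that("null cannabis effect yields a null adjusted association", {
  cfg <- small_sim_config(seed = 51, population_size = 150000)
  cfg$outcome_log_odds[["cannabis_test:positive"]] <- 0
  truth <- generate_population(cfg)
  # the adjusted coefficient is null; the crude one is confounded by the
  # demographic gradients shared with alcohol use
  g <- stats::glm(case ~ age_group + sex + race + education +
                    blood_alcohol + blood_cannabis,
                  data = truth, family = binomial())
  expect_lt(abs(coef(g)[["blood_cannabis"]]),
            3 * sqrt(diag(vcov(g))[["blood_cannabis"]]))
})

test_that("a hugely negative intercept produces zero cases", {
  cfg <- small_sim_config(seed = 52, population_size = 5000)
  cfg$outcome_log_odds[["intercept"]] <- -40
  truth <- generate_population(cfg)
  expect_equal(sum(truth$case), 0)
  reg <- draw_case_sample(truth, cfg, seed = 1)
  expect_equal(nrow(reg), 0)
  h <- add_registry_design_variables(harmonize_registry(reg))
  expect_equal(nrow(h), 0)
})

test_that("logistic fit on the fully observed truth recovers the cannabis log-OR", {
  cfg <- small_sim_config(seed = 53, population_size = 200000)
  truth <- generate_population(cfg)
  g <- stats::glm(case ~ age_group + sex + race + education +
                    blood_alcohol + blood_cannabis,
                  data = truth, family = binomial())
  est <- coef(g)[["blood_cannabis"]]
  se <- sqrt(diag(vcov(g)))[["blood_cannabis"]]
  expect_lt(abs(est - log(3.5)), 3 * se)
})

test_that("unknown model terms are refused by name", {
  expect_error(sim_config(outcome_log_odds = c(intercept = 0,
                                               "smoking:yes" = 1)),
               "smoking:yes")
  cfg <- small_sim_config()
  expect_error(
    misclassification_profile(offsets = list(
      cannabis_sensitivity = c("zodiac:aries" = 1))),
    "zodiac:aries")
  expect_error(misclassification_profile(offsets = list(bogus = c(a = 1))),
               "bogus")
})

test_that("misclassification hits configured sensitivity and specificity", {
  cfg <- small_sim_config(seed = 54, population_size = 100000)
  truth <- generate_population(cfg)
  prof <- misclassification_profile(
    cannabis = c(sensitivity = 0.62, specificity = 0.94),
    alcohol = c(sensitivity = 0.88, specificity = 0.47),
    offsets = list())
  t2 <- apply_misclassification(truth, prof, seed = 7)
  for (ex in c("cannabis", "alcohol")) {
    tv <- t2[[paste0("blood_", ex)]]
    sv <- t2[[paste0("self_", ex)]]
    sens_target <- prof[[ex]][["sensitivity"]]
    spec_target <- prof[[ex]][["specificity"]]
    sens <- mean(sv[tv == 1] == 1)
    spec <- mean(sv[tv == 0] == 0)
    expect_lt(abs(sens - sens_target),
              3 * sqrt(sens_target * (1 - sens_target) / sum(tv == 1)))
    expect_lt(abs(spec - spec_target),
              3 * sqrt(spec_target * (1 - spec_target) / sum(tv == 0)))
  }
  # perfect accuracy reproduces the truth exactly
  perfect <- misclassification_profile(
    cannabis = c(sensitivity = 1 - 1e-12, specificity = 1 - 1e-12),
    alcohol = c(sensitivity = 1 - 1e-12, specificity = 1 - 1e-12),
    offsets = list())
  t3 <- apply_misclassification(truth, perfect, seed = 8)
  expect_equal(t3$self_cannabis, t3$blood_cannabis)
  # determinism
  t4 <- apply_misclassification(truth, prof, seed = 7)
  expect_identical(t2$self_cannabis, t4$self_cannabis)
  # absent covariate level refused
  bad <- misclassification_profile(offsets = list(
    cannabis_sensitivity = c("race:Black" = -0.3)))
  tr2 <- truth[, setdiff(names(truth), "race")]
  expect_error(apply_misclassification(tr2, bad, seed = 1), "absent")
})

test_that("subgroup accuracy is homogeneous under a non-differential profile", {
  cfg <- small_sim_config(seed = 60, population_size = 80000)
  cfg$misclassification_profile <- misclassification_profile(offsets = list())
  cfg$missingness_rates <- list(validation = c(), registry = c())
  cfg$design$validation_sample_size <- 20000
  sys <- simulate_systems(cfg)
  cs <- confusion_summary(sys$validation_survey, "self_cannabis",
                          "blood_cannabis", by = "race")
  sub <- cs[cs$subgroup != "overall" & (cs$tp + cs$fn) > 50, ]
  se <- sqrt(0.62 * 0.38 / (sub$tp + sub$fn))
  expect_true(all(abs(sub$sensitivity - 0.62) < 3.5 * se))
})

test_that("equal-probability control sample satisfies the Horvitz-Thompson identity", {
  cfg <- small_sim_config(seed = 55, population_size = 20000)
  cfg$design$psus_sampled <- cfg$design$psus_per_stratum  # take all PSUs
  truth <- generate_population(cfg)
  smp <- draw_survey_sample(truth, cfg$design, seed = 3)
  expect_equal(length(unique(smp$weight)), 1)
  n_pop <- sum(truth$case == 0)
  expect_lt(abs(sum(smp$weight) - n_pop) / n_pop, 0.1)
  # all biomarker fields are structurally missing in this source
  for (v in c("blood_cannabis", "blood_alcohol", "oral_cannabis",
              "oral_alcohol"))
    expect_true(all(is.na(smp[[v]])))
  # demographics fully observed
  expect_false(anyNA(smp[, c("age_group", "sex", "race", "education")]))
})

test_that("weighted self-report prevalence estimates the population prevalence", {
  cfg <- small_sim_config(seed = 56, population_size = 50000,
                          control_n = 5000)
  truth <- generate_population(cfg)
  smp <- draw_survey_sample(truth, cfg$design, seed = 4)
  est <- weighted.mean(smp$self_cannabis == "positive", smp$weight)
  pop <- mean(truth$self_cannabis[truth$case == 0])
  se <- sqrt(est * (1 - est) / nrow(smp))
  # 3 design-based SEs, with a clustering allowance
  expect_lt(abs(est - pop), 3 * 2 * se)
})

test_that("validation missingness matches configured MAR rates", {
  cfg <- small_sim_config(seed = 57, population_size = 60000)
  cfg$design$validation_sample_size <- 10000
  cfg$missingness_rates$validation <- c(blood_cannabis = 0.30)
  truth <- generate_population(cfg)
  raw <- draw_validation_sample(truth, cfg, seed = 5)
  obs_frac <- mean(!is.na(raw$thc_blood))
  n <- nrow(raw)
  expect_lt(abs(obs_frac - 0.70), 3 * sqrt(0.3 * 0.7 / n))
  # zero rates give a complete table
  cfg$missingness_rates$validation <- c()
  raw0 <- draw_validation_sample(truth, cfg, seed = 5)
  expect_false(anyNA(raw0))
})

test_that("zero covariate shift leaves driver margins at population margins", {
  cfg <- small_sim_config(seed = 58, population_size = 60000)
  cfg$driver_shift <- c(intercept = 0)
  truth <- generate_population(cfg)
  drv <- truth[truth$driver == 1, ]
  for (m in c("sex", "race")) {
    p_all <- prop.table(table(truth[[m]]))
    p_drv <- prop.table(table(drv[[m]]))
    se <- sqrt(p_all * (1 - p_all) / nrow(drv))
    expect_true(all(abs(p_drv - p_all) < 4 * se))
  }
})

test_that("registry education missingness matches the configured rate", {
  cfg <- small_sim_config(seed = 59, population_size = 150000)
  truth <- generate_population(cfg)
  raw <- draw_case_sample(truth, cfg, seed = 6)
  miss_frac <- mean(is.na(raw$education))
  expect_lt(abs(miss_frac - 0.43), 3 * sqrt(0.43 * 0.57 / nrow(raw)))
  # zero missingness gives complete biomarkers
  cfg$missingness_rates$registry <- c()
  raw0 <- draw_case_sample(truth, cfg, seed = 6)
  expect_false(anyNA(raw0$thc_blood))
  expect_false(anyNA(raw0$bac_blood))
})

test_that("every sampled record links back to a population row", {
  cfg <- small_sim_config(seed = 61)
  sys <- simulate_systems(cfg)
  for (nm in c("control_survey", "validation_survey", "case_registry"))
    expect_true(all(sys[[nm]]$person_id %in% sys$truth$person_id))
  # case indicator consistent with the linked truth
  linked <- sys$truth[match(sys$case_registry$person_id,
                            sys$truth$person_id), ]
  expect_true(all(linked$case == 1))
})
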