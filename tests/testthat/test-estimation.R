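test_that("saturated weighted 2x2 fit matches the closed form", {
  d <- data.frame(
    case = c(1, 0, 1, 0),
    blood_cannabis = factor(c("positive", "positive", "negative",
                              "negative"), levels = fusemi_levels$tristate),
    weight = c(30, 70, 10, 90),
    stratum_id = "s", psu_id = c("a", "b", "c", "d"))
  f <- fit_weighted_logistic(d, model_spec(terms = "blood_cannabis"))
  expect_equal(unname(f$coefficients["(Intercept)"]), log(10 / 90),
               tolerance = 1e-6)
  expect_equal(unname(f$coefficients["blood_cannabis:positive"]),
               log((30 / 70) / (10 / 90)), tolerance = 1e-6)
})

test_that("unit weights reduce to the ordinary logistic MLE", {
  set.seed(12)
  n <- 400
  d <- data.frame(
    case = rbinom(n, 1, 0.4),
    sex = factor(sample(fusemi_levels$sex, n, TRUE),
                 levels = fusemi_levels$sex),
    race = factor(sample(fusemi_levels$race, n, TRUE),
                  levels = fusemi_levels$race),
    weight = 1, stratum_id = "s1", psu_id = as.character(seq_len(n)))
  sp <- model_spec(terms = c("sex", "race"))
  f <- fit_weighted_logistic(d, sp)
  g <- stats::glm(case ~ I(sex == "male") + I(race == "Black") +
                    I(race == "Hispanic") + I(race == "Others"),
                  data = d, family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-8)
})

test_that("weight rescaling leaves coefficients unchanged", {
  d <- make_harmonized(60, "control_survey", seed = 9)
  d$case <- rbinom(60, 1, 0.3)
  d$blood_cannabis <- factor(sample(c("negative", "positive"), 60, TRUE),
                             levels = fusemi_levels$tristate)
  sp <- model_spec(terms = c("sex", "blood_cannabis"))
  f1 <- fit_weighted_logistic(d, sp)
  d2 <- d
  d2$weight <- d$weight * 13
  f2 <- fit_weighted_logistic(d2, sp)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("exactly balanced exposure yields a zero slope", {
  d <- data.frame(
    case = rep(c(1, 0, 1, 0), 25),
    blood_cannabis = factor(rep(c("positive", "positive", "negative",
                                  "negative"), 25),
                            levels = fusemi_levels$tristate),
    weight = 1, stratum_id = "s",
    psu_id = as.character(1:100))
  f <- fit_weighted_logistic(d, model_spec(terms = "blood_cannabis"))
  expect_equal(unname(f$coefficients["blood_cannabis:positive"]), 0,
               tolerance = 1e-8)
})

test_that("iid design variance matches the textbook sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(3)
  n <- 500
  d <- data.frame(
    case = rbinom(n, 1, 0.3),
    blood_cannabis = factor(sample(c("negative", "positive"), n, TRUE),
                            levels = fusemi_levels$tristate),
    sex = factor(sample(fusemi_levels$sex, n, TRUE),
                 levels = fusemi_levels$sex),
    weight = 1, stratum_id = "s1", psu_id = as.character(seq_len(n)))
  sp <- model_spec(terms = c("blood_cannabis", "sex"))
  f <- fit_weighted_logistic(d, sp)
  v <- design_based_variance(d, sp, f)
  g <- stats::glm(case ~ I(blood_cannabis == "positive") + I(sex == "male"),
                  data = d, family = binomial())
  vref <- sandwich::vcovHC(g, type = "HC0") * n / (n - 1)
  expect_lt(max(abs(unname(v) - unname(vref))), 1e-8)
})

test_that("design variance: identical PSU score totals give a zero meat", {
  # two PSUs per stratum with mirrored rows => equal weighted score totals
  base <- data.frame(
    case = c(1, 0), blood_cannabis = factor(c("positive", "negative"),
                                            levels = fusemi_levels$tristate),
    weight = 1)
  d <- rbind(base, base)
  d$stratum_id <- "s1"
  d$psu_id <- c("p1", "p1", "p2", "p2")
  sp <- model_spec(terms = "blood_cannabis")
  f <- suppressWarnings(fit_weighted_logistic(d, sp))
  v <- design_based_variance(d, sp, f)
  expect_lt(max(abs(v)), 1e-12)
})

test_that("design variance is invariant to doubling all weights", {
  cfg <- small_sim_config(seed = 6)
  sys <- simulate_systems(cfg)
  d <- sys$control_survey
  d$case <- rbinom(nrow(d), 1, 0.2)
  sp <- model_spec(terms = c("sex", "race"))
  f1 <- fit_weighted_logistic(d, sp)
  v1 <- design_based_variance(d, sp, f1)
  d2 <- d
  d2$weight <- 2 * d$weight
  f2 <- fit_weighted_logistic(d2, sp)
  v2 <- design_based_variance(d2, sp, f2)
  expect_equal(v1, v2, tolerance = 1e-7)
})

test_that("a single-PSU stratum is refused by name", {
  d <- make_harmonized(10, "control_survey", seed = 7)
  d$case <- rbinom(10, 1, 0.5)
  d$stratum_id[1] <- "C:lonely"
  d$psu_id[1] <- "C:lonely:p1"
  sp <- model_spec(terms = "sex")
  f <- suppressWarnings(fit_weighted_logistic(d, sp))
  expect_error(design_based_variance(d, sp, f), "C:lonely")
})

test_that("zero-variance terms are dropped with a warning and separation is flagged", {
  d <- make_harmonized(40, "control_survey", seed = 8)
  d$case <- rbinom(40, 1, 0.4)
  d$blood_cannabis <- factor("negative", levels = fusemi_levels$tristate)
  sp <- model_spec(terms = c("sex", "blood_cannabis"))
  expect_warning(f <- fit_weighted_logistic(d, sp), "zero-variance")
  expect_false("blood_cannabis:positive" %in% names(f$coefficients))

  # perfectly separated exposure
  d2 <- data.frame(
    case = rep(c(1, 0), each = 20),
    blood_cannabis = factor(rep(c("positive", "negative"), each = 20),
                            levels = fusemi_levels$tristate),
    weight = 1, stratum_id = "s", psu_id = as.character(1:40))
  expect_warning(f2 <- fit_weighted_logistic(
    d2, model_spec(terms = "blood_cannabis")), "separation")
  expect_false(f2$converged)
})

test_that("model 3 on complete data reduces to a direct design-based fit", {
  cfg <- small_sim_config(seed = 13)
  sys <- simulate_systems(cfg)
  inputs <- sys[c("control_survey", "validation_survey", "case_registry")]
  # complete cases at this scale can leave a sparse race level near
  # separation; both routes must agree regardless
  rep3 <- suppressWarnings(run_model(3, inputs))
  d <- stack_sources(inputs$validation_survey, inputs$case_registry)
  cc <- stats::complete.cases(d[, model_spec()$terms])
  f <- suppressWarnings(fit_weighted_logistic(d[cc, ], model_spec()))
  expect_equal(rep3$estimate, unname(f$coefficients), tolerance = 1e-10)
  expect_equal(attr(rep3, "n"), sum(cc))
  # OR/CI duality holds exactly
  expect_equal(rep3$or, exp(rep3$estimate))
  expect_equal(rep3$or_low, exp(rep3$ci_low))
  expect_equal(rep3$or_high, exp(rep3$ci_high))
})

test_that("MI (model 4) analyses at least as many rows as listwise deletion (model 3)", {
  cfg <- small_sim_config(seed = 14)
  sys <- simulate_systems(cfg)
  inputs <- sys[c("control_survey", "validation_survey", "case_registry")]
  rep3 <- run_model(3, inputs)
  rep4 <- suppressWarnings(run_model(4, inputs,
                                     impute_config = fast_impute_config(M = 2,
                                                                        seed = 2)))
  expect_gte(attr(rep4, "n"), attr(rep3, "n"))
  expect_equal(attr(rep4, "method"), "Rubin")
})

test_that("transportability diagnostic is exactly zero on identical inputs", {
  cfg <- small_sim_config(seed = 15)
  sys <- simulate_systems(cfg)
  d <- sys$control_survey
  out <- check_transportability(d, d)
  expect_true(all(out$difference == 0))
  expect_true(all(out$z == 0 | is.nan(out$z)))
})

test_that("transportability holds between sources sharing one conditional model", {
  cfg <- sim_config(
    population_size = 60000,
    design = list(n_strata = 8, psus_per_stratum = 8, psus_sampled = 4,
                  control_sample_size = 8000,
                  validation_sample_size = 8000, case_fraction = 1),
    missingness_rates = list(validation = c(), registry = c()),
    seed = 16)
  sys <- simulate_systems(cfg)
  out <- check_transportability(sys$control_survey, sys$validation_survey)
  # both self-report models derive from one population model: differences
  # stay within 3 joint SEs for (almost) all coefficients
  expect_lt(mean(out$z > 3), 0.1)
})
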