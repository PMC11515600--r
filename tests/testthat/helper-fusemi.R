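# Shared fixture builders.  Everything is generated in code; no files.

# A small harmonized table built by hand (n rows, deterministic content).
make_harmonized <- function(n = 8, source = "control_survey",
                            seed = 11) {
  set.seed(seed)
  lev <- fusemi_levels
  d <- data.frame(
    person_id = seq_len(n),
    source = factor(rep(source, n), levels = lev$source),
    case = as.integer(source == "case_registry"),
    age_group = factor(sample(lev$age_group, n, TRUE),
                       levels = lev$age_group),
    sex = factor(sample(lev$sex, n, TRUE), levels = lev$sex),
    race = factor(sample(lev$race, n, TRUE), levels = lev$race),
    education = factor(sample(lev$education, n, TRUE),
                       levels = lev$education),
    self_cannabis = factor(sample(lev$tristate, n, TRUE),
                           levels = lev$tristate),
    self_alcohol = factor(sample(lev$tristate, n, TRUE),
                          levels = lev$tristate),
    blood_cannabis = factor(sample(lev$tristate, n, TRUE),
                            levels = lev$tristate),
    blood_alcohol = factor(sample(lev$tristate, n, TRUE),
                           levels = lev$tristate),
    oral_cannabis = factor(sample(lev$tristate, n, TRUE),
                           levels = lev$tristate),
    oral_alcohol = factor(sample(lev$tristate, n, TRUE),
                          levels = lev$tristate),
    stratum_id = if (source == "case_registry") NA_character_ else
      paste0("C:s", rep_len(1:2, n)),
    psu_id = if (source == "case_registry") NA_character_ else
      paste0("C:s", rep_len(1:2, n), ":p", rep_len(1:4, n)),
    weight = if (source == "case_registry") NA_real_ else 2)
  d
}

# A compact simulation: small population, small samples, fast to run.
small_sim_config <- function(seed = 1, population_size = 20000,
                             control_n = 1500, validation_n = 1500) {
  sim_config(
    population_size = population_size,
    design = list(n_strata = 6, psus_per_stratum = 6, psus_sampled = 3,
                  control_sample_size = control_n,
                  validation_sample_size = validation_n,
                  case_fraction = 1),
    seed = seed)
}

fast_impute_config <- function(M = 2, seed = 1, iters = 3) {
  imputation_config(n_imputations = M, n_iterations = iters,
                    learner = "logistic", seed = seed)
}
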