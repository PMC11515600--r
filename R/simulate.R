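#' Misclassification profile of self-report against the biomarker
#'
#' Sensitivity and specificity of self-reported use relative to the blood
#' test, per exposure, with optional additive-on-logit subgroup offsets
#' keyed as `"covariate:level"` (e.g. `"race:Black"`).  With all offsets
#' zero the profile is non-differential.  Defaults are the overall rows of
#' the validation-survey accuracy table (cannabis: sensitivity 0.62,
#' specificity 0.94; alcohol: sensitivity 0.88, specificity 0.47) with a
#' lower sensitivity for the Black race group for both substances, the
#' dominant differential pattern in that table.
#'
#' @param cannabis,alcohol named numeric vectors with elements
#'   `sensitivity` and `specificity`, each in (0, 1).
#' @param offsets named list; allowed elements are
#'   `cannabis_sensitivity`, `cannabis_specificity`, `alcohol_sensitivity`,
#'   `alcohol_specificity`, each a named numeric vector of logit offsets
#'   keyed by `"covariate:level"`.
#' @return an object of class `misclassification_profile`.
#' @export
misclassification_profile <- function(
    cannabis = c(sensitivity = 0.62, specificity = 0.94),
    alcohol  = c(sensitivity = 0.88, specificity = 0.47),
    offsets = list(
      cannabis_sensitivity = c("race:Black" = -0.25),
      alcohol_sensitivity  = c("race:Black" = -1.10)
    )) {
  for (v in list(cannabis, alcohol)) {
    stopifnot(all(c("sensitivity", "specificity") %in% names(v)),
              all(v > 0 & v < 1))
  }
  allowed <- c("cannabis_sensitivity", "cannabis_specificity",
               "alcohol_sensitivity", "alcohol_specificity")
  bad <- setdiff(names(offsets), allowed)
  if (length(bad)) stop("unknown offset slots: ", paste(bad, collapse = ", "))
  for (off in offsets) .check_term_names(names(off), demographics_only = TRUE)
  structure(list(cannabis = cannabis, alcohol = alcohol, offsets = offsets),
            class = "misclassification_profile")
}

# Validate "var:level" coefficient names against the schema level sets.
.check_term_names <- function(terms, demographics_only = FALSE) {
  vars <- fusemi_levels[.demographic_vars]
  if (!demographics_only)
    vars <- c(vars, list(alcohol_test = "positive", cannabis_test = "positive"))
  for (tm in terms) {
    if (tm == "intercept") next
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% names(vars)) ||
        !(parts[2] %in% vars[[parts[1]]]))
      stop("unknown model term '", tm, "'; terms are 'intercept' or ",
           "'<variable>:<level>' over the harmonized schema", call. = FALSE)
  }
  invisible(TRUE)
}

# Linear predictor for "var:level" coefficient vectors.  alcohol_test /
# cannabis_test refer to the true blood positivity columns.
.linpred <- function(df, coefs) {
  .check_term_names(names(coefs))
  if (any(!is.finite(coefs))) stop("non-finite coefficient in model terms")
  eta <- rep(if ("intercept" %in% names(coefs)) coefs[["intercept"]] else 0,
             nrow(df))
  for (tm in setdiff(names(coefs), "intercept")) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    col <- switch(parts[1],
                  alcohol_test = "blood_alcohol",
                  cannabis_test = "blood_cannabis",
                  parts[1])
    val <- df[[col]]
    ind <- if (is.numeric(val)) val else as.numeric(as.character(val) == parts[2])
    eta <- eta + coefs[[tm]] * ind
  }
  eta
}

#' Simulation configuration for the three-system generator
#'
#' Bundles the generating quantities of the synthetic study: demographic
#' margins of the general population, logistic models for true biomarker
#' positivity and for the outcome, the misclassification profile of
#' self-report, the driver (validation-subpopulation) selection model,
#' missing-at-random rates per source and variable, and the two-stage
#' survey design geometry.  Defaults emulate the published study
#' conditions: general-population demographic margins and per-source
#' missingness follow the descriptive table of the three systems, outcome
#' log-odds ratios follow the fused-analysis model, and self-report
#' accuracy follows the validation-survey accuracy table.
#'
#' @param population_size number of persons in the synthetic population.
#' @param demographics named list of probability vectors for `age_group`,
#'   `sex`, `race`, `education` (each normalized internally).
#' @param outcome_log_odds named coefficients (`intercept`,
#'   `"var:level"`) of the case-generating logistic model; exposure terms
#'   are `alcohol_test:positive` and `cannabis_test:positive` on true blood
#'   positivity.
#' @param exposure_models list with elements `cannabis` and `alcohol`:
#'   named coefficients of the logistic models for latent recent use given
#'   demographics.
#' @param concordance named vector: probability that the blood and oral
#'   indicators of one latent use agree, per exposure.
#' @param misclassification_profile a [misclassification_profile()].
#' @param design list: `n_strata`, `psus_per_stratum` (population frame),
#'   `psus_sampled` (per stratum, each survey), `control_sample_size`,
#'   `validation_sample_size`, `case_fraction` (fraction of cases entering
#'   the registry).
#' @param missingness_rates list with named rate vectors `validation` and
#'   `registry`; names are schema variables, values marginal MAR rates.
#' @param mar_coefficients named logit offsets (`"var:level"`) making
#'   missingness depend on observed demographics; the intercept of each
#'   missingness model is solved so the marginal rate matches the
#'   configured rate exactly in expectation.
#' @param driver_shift named coefficients of the logistic driver-selection
#'   model (covariate shift of the validation subpopulation).
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(
    population_size = 50000,
    demographics = list(
      age_group = c("16-20" = 0.088, "21-34" = 0.240, "35-49" = 0.247,
                    "50-64" = 0.247, "65+" = 0.178),
      sex       = c(male = 0.482, female = 0.518),
      race      = c(White = 0.655, Black = 0.118, Hispanic = 0.152,
                    Others = 0.075),
      education = c("less than HS" = 0.129, "HS graduate" = 0.286,
                    "some college" = 0.261, "college/some graduate" = 0.323)
    ),
    outcome_log_odds = c(
      intercept = -6.04,
      "age_group:16-20" = log(1.41), "age_group:21-34" = log(1.76),
      "age_group:50-64" = log(1.37), "age_group:65+" = log(0.71),
      "sex:male" = log(2.94),
      "race:Black" = log(5.25), "race:Hispanic" = log(0.73),
      "race:Others" = log(1.59),
      "education:less than HS" = log(1.67),
      "education:some college" = log(0.32),
      "education:college/some graduate" = log(0.19),
      "alcohol_test:positive" = log(18.53),
      "cannabis_test:positive" = log(3.50)
    ),
    exposure_models = list(
      cannabis = c(
        intercept = -2.73,
        "age_group:16-20" = 0.8, "age_group:21-34" = 0.6,
        "age_group:50-64" = -0.6, "age_group:65+" = -1.8,
        "sex:male" = 0.5, "race:Black" = 0.4, "race:Hispanic" = -0.2,
        "race:Others" = -0.1, "education:less than HS" = 0.3,
        "education:college/some graduate" = -0.5),
      alcohol = c(
        intercept = -3.96,
        "age_group:16-20" = 0.3, "age_group:21-34" = 0.5,
        "age_group:50-64" = -0.3, "age_group:65+" = -0.8,
        "sex:male" = 0.6, "race:Black" = 0.1, "race:Hispanic" = 0.1,
        "race:Others" = -0.1, "education:less than HS" = 0.2,
        "education:college/some graduate" = -0.2)
    ),
    concordance = c(cannabis = 0.95, alcohol = 0.95),
    misclassification_profile = fusemi::misclassification_profile(),
    design = list(n_strata = 10, psus_per_stratum = 8, psus_sampled = 4,
                  control_sample_size = 5000, validation_sample_size = 5000,
                  case_fraction = 1),
    missingness_rates = list(
      validation = c(age_group = 0.19, sex = 0.03, race = 0.20,
                     education = 0.19, self_cannabis = 0.32,
                     self_alcohol = 0.42, blood_cannabis = 0.55,
                     blood_alcohol = 0.55, oral_cannabis = 0.26,
                     oral_alcohol = 0.26),
      registry = c(education = 0.43, blood_cannabis = 0.65,
                   blood_alcohol = 0.44)
    ),
    mar_coefficients = c("sex:male" = 0.25, "age_group:16-20" = 0.25),
    driver_shift = c(
      intercept = -0.70,
      "age_group:16-20" = 0.30, "age_group:21-34" = 0.70,
      "age_group:50-64" = -0.25, "age_group:65+" = -0.90,
      "sex:male" = 0.40, "race:Black" = 0.80, "race:Hispanic" = -0.10,
      "race:Others" = 0.20, "education:less than HS" = -0.60,
      "education:some college" = 0.35,
      "education:college/some graduate" = 0.25),
    seed = 1L) {
  stopifnot(population_size >= 1)
  for (m in names(demographics)) {
    p <- demographics[[m]]
    stopifnot(all(p >= 0), sum(p) > 0,
              setequal(names(p), fusemi_levels[[m]]))
    demographics[[m]] <- p / sum(p)
  }
  .check_term_names(names(outcome_log_odds))
  for (em in exposure_models) .check_term_names(names(em),
                                                demographics_only = TRUE)
  .check_term_names(names(driver_shift), demographics_only = TRUE)
  .check_term_names(names(mar_coefficients), demographics_only = TRUE)
  stopifnot(inherits(misclassification_profile, "misclassification_profile"),
            all(unlist(missingness_rates) >= 0),
            all(unlist(missingness_rates) <= 1),
            all(concordance >= 0.5), all(concordance <= 1))
  structure(list(
    population_size = as.integer(population_size),
    demographics = demographics,
    outcome_log_odds = outcome_log_odds,
    exposure_models = exposure_models,
    concordance = concordance,
    misclassification_profile = misclassification_profile,
    design = design,
    missingness_rates = missingness_rates,
    mar_coefficients = mar_coefficients,
    driver_shift = driver_shift,
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate the synthetic population with latent truth
#'
#' Draws demographics from the configured categorical margins, assigns
#' persons to strata and primary sampling units, generates latent recent
#' use per exposure from the configured logistic models, derives blood and
#' oral biomarker indicators as two noisy measurements of the latent use
#' (agreement set by `concordance`), draws the case indicator from the
#' outcome model on true blood positivity, and draws the driver indicator
#' from the covariate-shift model.  Self-report columns are filled by
#' [apply_misclassification()].
#'
#' @param config a [sim_config()].
#' @return a `data.frame` (the population truth table) with one row per
#'   person: demographics, `blood_*`/`oral_*` 0/1 truth, `self_*` 0/1
#'   report, `case`, `driver`, `stratum`, `psu`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 101))
  n <- config$population_size
  pop <- data.frame(person_id = seq_len(n))
  for (m in .demographic_vars) {
    pop[[m]] <- factor(.rcat(n, config$demographics[[m]]),
                       levels = fusemi_levels[[m]])
  }
  # two-stage frame: persons uniformly over strata x PSUs
  pop$stratum <- sample.int(config$design$n_strata, n, replace = TRUE)
  pop$psu <- sample.int(config$design$psus_per_stratum, n, replace = TRUE)

  for (ex in c("cannabis", "alcohol")) {
    p_use <- stats::plogis(.linpred(pop, config$exposure_models[[ex]]))
    latent <- stats::rbinom(n, 1, p_use)
    # blood indicates the latent recent use exactly; oral is a second,
    # noisy indicator: positive agreement = concordance, false-positive
    # rate scaled to the person's use propensity so the oral marginal sits
    # just below the blood marginal
    conc <- config$concordance[[ex]]
    fp <- pmin((1 - conc) * p_use / (1 - p_use), 0.5)
    pop[[paste0("blood_", ex)]] <- latent
    u <- stats::runif(n)
    pop[[paste0("oral_", ex)]] <- ifelse(latent == 1L,
                                         as.integer(u < conc),
                                         as.integer(u < fp))
  }
  pop$case <- stats::rbinom(n, 1, stats::plogis(
    .linpred(pop, config$outcome_log_odds)))
  pop$driver <- stats::rbinom(n, 1, stats::plogis(
    .linpred(pop, config$driver_shift)))
  apply_misclassification(pop, config$misclassification_profile,
                          seed = .derive_seed(config$seed, 102))
}

#' Generate self-report from biomarker truth through an accuracy profile
#'
#' Fills the `self_cannabis` and `self_alcohol` 0/1 columns: for each
#' person, P(report positive | blood positive) is the subgroup sensitivity
#' and P(report negative | blood negative) the subgroup specificity, with
#' subgroup values obtained by adding the profile's logit offsets to the
#' baseline logit.
#'
#' @param truth population truth table with `blood_cannabis` and
#'   `blood_alcohol` 0/1 columns.
#' @param profile a [misclassification_profile()].
#' @param seed integer seed.
#' @return `truth` with `self_cannabis` and `self_alcohol` filled.
#' @export
apply_misclassification <- function(truth, profile, seed = 1L) {
  stopifnot(inherits(profile, "misclassification_profile"),
            all(c("blood_cannabis", "blood_alcohol") %in% names(truth)))
  set.seed(seed)
  n <- nrow(truth)
  subgroup_logit <- function(base, off_name) {
    eta <- rep(stats::qlogis(base), n)
    off <- profile$offsets[[off_name]]
    if (!is.null(off)) {
      for (tm in names(off)) {
        parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
        if (!parts[1] %in% names(truth))
          stop("offset references absent covariate: ", tm)
        if (!parts[2] %in% levels(factor(truth[[parts[1]]])) &&
            !parts[2] %in% fusemi_levels[[parts[1]]])
          stop("offset references absent covariate level: ", tm)
        eta <- eta + off[[tm]] * (as.character(truth[[parts[1]]]) == parts[2])
      }
    }
    stats::plogis(eta)
  }
  for (ex in c("cannabis", "alcohol")) {
    sens <- subgroup_logit(profile[[ex]][["sensitivity"]],
                           paste0(ex, "_sensitivity"))
    spec <- subgroup_logit(profile[[ex]][["specificity"]],
                           paste0(ex, "_specificity"))
    pos <- truth[[paste0("blood_", ex)]] == 1
    p_report <- ifelse(pos, sens, 1 - spec)
    truth[[paste0("self_", ex)]] <- as.integer(stats::runif(n) < p_report)
  }
  truth
}

# Two-stage sample core shared by the two surveys: SRS of PSUs within each
# stratum, then a within-PSU sampling fraction solved to hit the target
# size in expectation.  Weight = inverse inclusion probability.
.two_stage_sample <- function(frame, design, target_n, prefix) {
  n_sel <- design$psus_sampled
  n_psu <- design$psus_per_stratum
  if (n_psu < 1 || n_sel < 1) stop("design must sample at least one PSU")
  if (n_sel > n_psu) stop("cannot sample more PSUs than the stratum holds")
  keep <- logical(nrow(frame))
  for (h in seq_len(design$n_strata)) {
    in_h <- frame$stratum == h
    if (!any(in_h)) stop("stratum ", h, " has zero PSUs in the frame")
    sel <- sample.int(n_psu, n_sel)
    keep <- keep | (in_h & frame$psu %in% sel)
  }
  cand <- which(keep)
  # expected candidates = N * n_sel/n_psu; f2 from the realized count
  f2 <- min(1, target_n / length(cand))
  take <- cand[stats::runif(length(cand)) < f2]
  out <- frame[take, , drop = FALSE]
  out$stratum_id <- sprintf("%s:s%02d", prefix, out$stratum)
  out$psu_id <- sprintf("%s:s%02d:p%02d", prefix, out$stratum, out$psu)
  out$weight <- 1 / ((n_sel / n_psu) * f2)
  out
}

# Expand a 0/1 indicator into a tri-state factor.
.bin_to_tristate <- function(x) {
  .tristate_factor(ifelse(is.na(x), NA, ifelse(x == 1, "positive", "negative")))
}

# MAR missingness: marginal rate `rate`, logit offsets from
# mar_coefficients evaluated on the (observed) demographics.
.mar_mask <- function(df, rate, mar_coefficients) {
  if (rate <= 0) return(rep(FALSE, nrow(df)))
  off <- rep(0, nrow(df))
  for (tm in names(mar_coefficients)) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    off <- off + mar_coefficients[[tm]] *
      (as.character(df[[parts[1]]]) == parts[2])
  }
  a <- .mar_intercept(rate, off)
  stats::runif(nrow(df)) < stats::plogis(a + off)
}

#' Draw the control survey (self-report only, complex design)
#'
#' Two-stage sample from the outcome-free population: PSUs sampled within
#' strata, persons within PSUs, weights equal to inverse inclusion
#' probabilities.  Demographics and self-report are fully observed; all
#' biomarker columns are structurally missing — this source never measures
#' them.
#'
#' @param truth population truth table from [generate_population()].
#' @param design design geometry list (see [sim_config()]).
#' @param seed integer seed.
#' @return harmonized `data.frame` with `source == "control_survey"`.
#' @export
draw_survey_sample <- function(truth, design, seed = 1L) {
  set.seed(seed)
  smp <- .two_stage_sample(truth[truth$case == 0, , drop = FALSE], design,
                           design$control_sample_size, "C")
  out <- data.frame(
    person_id = smp$person_id,
    source = factor("control_survey", levels = fusemi_levels$source),
    case = 0L)
  for (m in .demographic_vars) out[[m]] <- smp[[m]]
  out$self_cannabis <- .bin_to_tristate(smp$self_cannabis)
  out$self_alcohol <- .bin_to_tristate(smp$self_alcohol)
  for (v in c("blood_cannabis", "blood_alcohol", "oral_cannabis",
              "oral_alcohol"))
    out[[v]] <- .tristate_factor(rep(NA_character_, nrow(smp)))
  out$stratum_id <- smp$stratum_id
  out$psu_id <- smp$psu_id
  out$weight <- smp$weight
  rownames(out) <- NULL
  out
}

#' Draw the validation survey in its raw dialect
#'
#' Two-stage sample from the outcome-free *driver* subpopulation.  Both
#' self-report and biomarkers are measured, but emitted in the validation
#' dialect — cannabis recency category, weekly alcohol-frequency category,
#' blood alcohol in g/dL, oral alcohol in mg/dL, binary THC tests, and age
#' in years — and then subjected to MAR missingness at the configured
#' rates.  Pass the result through [harmonize_validation()].
#'
#' @param truth population truth table.
#' @param config a [sim_config()] (design, missingness, MAR coefficients).
#' @param seed integer seed.
#' @return raw validation `data.frame`.
#' @export
draw_validation_sample <- function(truth, config, seed = 1L) {
  set.seed(seed)
  pool <- truth[truth$driver == 1 & truth$case == 0, , drop = FALSE]
  smp <- .two_stage_sample(pool, config$design,
                           config$design$validation_sample_size, "V")
  n <- nrow(smp)
  raw <- data.frame(person_id = smp$person_id)
  raw$age_years <- .age_years_from_group(smp$age_group)
  raw$sex <- as.character(smp$sex)
  raw$race <- as.character(smp$race)
  raw$education <- as.character(smp$education)
  # raw self-report dialect, consistent with the binary report
  lv <- fusemi_levels$recency
  raw$cannabis_recency <- ifelse(
    smp$self_cannabis == 1, sample(lv[1:3], n, replace = TRUE,
                                   prob = c(0.25, 0.25, 0.5)),
    sample(lv[4:5], n, replace = TRUE, prob = c(0.3, 0.7)))
  fq <- fusemi_levels$weekly_freq
  raw$alcohol_weekly_freq <- ifelse(
    smp$self_alcohol == 1, sample(fq[-1], n, replace = TRUE,
                                  prob = c(0.4, 0.25, 0.18, 0.12, 0.05)),
    "0")
  # concentrations consistent with the binary biomarker truth
  raw$bac_blood <- ifelse(smp$blood_alcohol == 1,
                          0.01 + stats::rexp(n, 1 / 0.06),
                          stats::runif(n, 0, 0.0099))
  raw$alcohol_oral <- ifelse(smp$oral_alcohol == 1,
                             10 + stats::rexp(n, 1 / 40),
                             stats::runif(n, 0, 9.9))
  raw$thc_blood <- smp$blood_cannabis
  raw$thc_oral <- smp$oral_cannabis
  raw$stratum_id <- smp$stratum_id
  raw$psu_id <- smp$psu_id
  raw$weight <- smp$weight

  rate <- config$missingness_rates$validation
  mar_cols <- c(age_group = "age_years", sex = "sex", race = "race",
                education = "education", self_cannabis = "cannabis_recency",
                self_alcohol = "alcohol_weekly_freq",
                blood_alcohol = "bac_blood", blood_cannabis = "thc_blood",
                oral_alcohol = "alcohol_oral", oral_cannabis = "thc_oral")
  for (v in names(rate)) {
    col <- mar_cols[[v]]
    mask <- .mar_mask(smp, rate[[v]], config$mar_coefficients)
    raw[[col]][mask] <- NA
  }
  rownames(raw) <- NULL
  raw
}

.age_years_from_group <- function(g) {
  lo <- c("16-20" = 16, "21-34" = 21, "35-49" = 35, "50-64" = 50, "65+" = 65)
  hi <- c("16-20" = 20, "21-34" = 34, "35-49" = 49, "50-64" = 64, "65+" = 90)
  g <- as.character(g)
  floor(stats::runif(length(g), lo[g], hi[g] + 1))
}

#' Draw the case registry in its raw dialect
#'
#' Takes all (or a configured fraction of) case rows.  Blood biomarkers and
#' education are observed subject to MAR missingness; oral tests and
#' self-report are structurally absent (never collected by this system);
#' there are no design variables.  Pass the result through
#' [harmonize_registry()] and [add_registry_design_variables()].
#'
#' @param truth population truth table.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return raw registry `data.frame` (possibly with zero rows).
#' @export
draw_case_sample <- function(truth, config, seed = 1L) {
  set.seed(seed)
  cases <- truth[truth$case == 1, , drop = FALSE]
  frac <- config$design$case_fraction
  if (frac < 1 && nrow(cases) > 0)
    cases <- cases[stats::runif(nrow(cases)) < frac, , drop = FALSE]
  n <- nrow(cases)
  raw <- data.frame(person_id = integer(0), age_years = numeric(0),
                    sex = character(0), race = character(0),
                    education = character(0), bac_blood = numeric(0),
                    thc_blood = integer(0))
  if (n > 0) {
    raw <- data.frame(
      person_id = cases$person_id,
      age_years = .age_years_from_group(cases$age_group),
      sex = as.character(cases$sex),
      race = as.character(cases$race),
      education = as.character(cases$education),
      bac_blood = ifelse(cases$blood_alcohol == 1,
                         0.01 + stats::rexp(n, 1 / 0.08),
                         stats::runif(n, 0, 0.0099)),
      thc_blood = cases$blood_cannabis)
    rate <- config$missingness_rates$registry
    mar_cols <- c(education = "education", blood_alcohol = "bac_blood",
                  blood_cannabis = "thc_blood")
    for (v in names(rate)) {
      mask <- .mar_mask(cases, rate[[v]], config$mar_coefficients)
      raw[[mar_cols[[v]]]][mask] <- NA
    }
  }
  rownames(raw) <- NULL
  raw
}

#' Simulate the three harmonized data systems with known truth
#'
#' Convenience wrapper running [generate_population()] and the three
#' sampling operations, returning both the raw-dialect tables and their
#' harmonized forms (the registry already augmented with pseudo-design
#' variables).
#'
#' @param config a [sim_config()].
#' @return list with `truth`, `control_survey`, `validation_raw`,
#'   `validation_survey`, `registry_raw`, `case_registry`, and the
#'   resolved `config`.
#' @export
simulate_systems <- function(config = sim_config()) {
  truth <- generate_population(config)
  control <- draw_survey_sample(truth, config$design,
                                seed = .derive_seed(config$seed, 201))
  validation_raw <- draw_validation_sample(truth, config,
                                           seed = .derive_seed(config$seed, 202))
  registry_raw <- draw_case_sample(truth, config,
                                   seed = .derive_seed(config$seed, 203))
  validation <- harmonize_validation(validation_raw)
  registry <- add_registry_design_variables(
    harmonize_registry(registry_raw),
    survey_strata = unique(c(control$stratum_id, validation$stratum_id)))
  list(truth = truth, control_survey = control,
       validation_raw = validation_raw, validation_survey = validation,
       registry_raw = registry_raw, case_registry = registry,
       config = config)
}
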