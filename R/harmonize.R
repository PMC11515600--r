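#' Harmonize cannabis recency categories to past-month use
#'
#' Recency of last cannabis use reported in the validation survey is
#' collapsed to the binary past-month definition used by the control
#' survey: use in the past 24 h, past 2 days or past month is positive;
#' over a month or beyond a year/never is negative; missing stays missing.
#'
#' @param category character/factor over the recency categories, `NA`
#'   allowed.
#' @return tri-state factor (`positive`/`negative`, `NA` = missing).
#' @export
harmonize_cannabis_recency <- function(category) {
  x <- as.character(category)
  known <- x %in% fusemi_levels$recency
  if (any(!known & !is.na(x)))
    stop("unknown cannabis recency label: '",
         x[which(!known & !is.na(x))[1]], "'", call. = FALSE)
  pos <- c("past 24 h", "past 2 days", "past month")
  .tristate_factor(ifelse(is.na(x), NA,
                          ifelse(x %in% pos, "positive", "negative")))
}

#' Harmonize weekly alcohol-frequency categories to past-month use
#'
#' Any non-zero weekly drinking frequency is positive; zero is negative;
#' missing stays missing.
#'
#' @param category character/factor over the weekly-frequency categories
#'   (`"0"`, `"1-2"`, `"3-4"`, `"5-7"`, `"8-14"`, `">14"`), `NA` allowed.
#' @return tri-state factor.
#' @export
harmonize_alcohol_frequency <- function(category) {
  x <- as.character(category)
  known <- x %in% fusemi_levels$weekly_freq
  if (any(!known & !is.na(x)))
    stop("unknown alcohol frequency label: '",
         x[which(!known & !is.na(x))[1]], "'", call. = FALSE)
  .tristate_factor(ifelse(is.na(x), NA,
                          ifelse(x == "0", "negative", "positive")))
}

#' Dichotomize an alcohol concentration
#'
#' Blood alcohol concentration of 0.01 g/dL or greater is positive; an
#' oral-fluid concentration of 10 mg/dL or greater is positive.  Both
#' thresholds are inclusive.  Missing passes through.
#'
#' @param concentration non-negative numeric, `NA` allowed.
#' @param matrix `"blood_gdl"` or `"oral_mgdl"`.
#' @return tri-state factor.
#' @export
alcohol_test_positive <- function(concentration, matrix = c("blood_gdl",
                                                            "oral_mgdl")) {
  matrix <- match.arg(matrix)
  if (any(concentration < 0, na.rm = TRUE))
    stop("negative concentration", call. = FALSE)
  thr <- if (matrix == "blood_gdl") 0.01 else 10
  .tristate_factor(ifelse(is.na(concentration), NA,
                          ifelse(concentration >= thr, "positive",
                                 "negative")))
}

#' Harmonize age to the five study age groups
#'
#' Continuous ages are binned with inclusive lower bounds (21 maps to
#' `21-34`); values already matching the category labels pass through.
#' Ages below the study floor of 16 are an error.
#'
#' @param raw numeric ages in years, or characters matching the age-group
#'   labels; `NA` allowed.
#' @return factor over the age groups.
#' @export
harmonize_age <- function(raw) {
  if (is.character(raw) || is.factor(raw)) {
    x <- as.character(raw)
    bad <- !(x %in% fusemi_levels$age_group) & !is.na(x)
    if (any(bad)) {
      num <- suppressWarnings(as.numeric(x))
      if (all(!is.na(num[!is.na(x)]))) return(harmonize_age(num))
      stop("unknown age category: '", x[which(bad)[1]], "'", call. = FALSE)
    }
    return(factor(x, levels = fusemi_levels$age_group))
  }
  if (any(raw < 16, na.rm = TRUE))
    stop("age below the study floor of 16", call. = FALSE)
  cut(raw, breaks = c(16, 21, 35, 50, 65, Inf), right = FALSE,
      labels = fusemi_levels$age_group)
}

#' Harmonize a raw validation-survey table into the unified schema
#'
#' Applies the recency, frequency, concentration and age maps, carries the
#' THC tests through as tri-state factors, and keeps design variables.
#'
#' @param raw a raw validation table as produced by
#'   [draw_validation_sample()] (columns `age_years`, `sex`, `race`,
#'   `education`, `cannabis_recency`, `alcohol_weekly_freq`, `bac_blood`,
#'   `alcohol_oral`, `thc_blood`, `thc_oral`, `stratum_id`, `psu_id`,
#'   `weight`).
#' @return harmonized `data.frame` with `source == "validation_survey"`.
#' @export
harmonize_validation <- function(raw) {
  out <- data.frame(
    person_id = raw$person_id,
    source = factor("validation_survey", levels = fusemi_levels$source),
    case = 0L,
    age_group = harmonize_age(raw$age_years),
    sex = factor(raw$sex, levels = fusemi_levels$sex),
    race = factor(raw$race, levels = fusemi_levels$race),
    education = factor(raw$education, levels = fusemi_levels$education),
    self_cannabis = harmonize_cannabis_recency(raw$cannabis_recency),
    self_alcohol = harmonize_alcohol_frequency(raw$alcohol_weekly_freq),
    blood_cannabis = .bin_to_tristate(raw$thc_blood),
    blood_alcohol = alcohol_test_positive(raw$bac_blood, "blood_gdl"),
    oral_cannabis = .bin_to_tristate(raw$thc_oral),
    oral_alcohol = alcohol_test_positive(raw$alcohol_oral, "oral_mgdl"),
    stratum_id = raw$stratum_id,
    psu_id = raw$psu_id,
    weight = raw$weight)
  rownames(out) <- NULL
  out
}

#' Harmonize a raw case-registry table into the unified schema
#'
#' Maps age, demographics and the blood tests; oral tests and self-report
#' are structurally missing for this source, and design variables are left
#' empty until [add_registry_design_variables()] is applied.
#'
#' @param raw a raw registry table as produced by [draw_case_sample()].
#' @return harmonized `data.frame` with `source == "case_registry"`.
#' @export
harmonize_registry <- function(raw) {
  n <- nrow(raw)
  out <- data.frame(
    person_id = raw$person_id,
    source = factor(rep("case_registry", n), levels = fusemi_levels$source),
    case = rep(1L, n),
    age_group = harmonize_age(raw$age_years),
    sex = factor(raw$sex, levels = fusemi_levels$sex),
    race = factor(raw$race, levels = fusemi_levels$race),
    education = factor(raw$education, levels = fusemi_levels$education),
    self_cannabis = .tristate_factor(rep(NA_character_, n)),
    self_alcohol = .tristate_factor(rep(NA_character_, n)),
    blood_cannabis = .bin_to_tristate(raw$thc_blood),
    blood_alcohol = alcohol_test_positive(raw$bac_blood, "blood_gdl"),
    oral_cannabis = .tristate_factor(rep(NA_character_, n)),
    oral_alcohol = .tristate_factor(rep(NA_character_, n)),
    stratum_id = rep(NA_character_, n),
    psu_id = rep(NA_character_, n),
    weight = rep(NA_real_, n))
  rownames(out) <- NULL
  out
}

#' Augment the case registry with pseudo-design variables
#'
#' So that registry rows can enter the survey-weighted analysis alongside
#' the control survey: each observation gets a unique primary-sampling-unit
#' label, all observations share one new stratum label absent from every
#' survey stratum, and every weight is set to 1.
#'
#' @param records harmonized registry table (design fields empty).
#' @param survey_strata character vector of stratum labels already in use
#'   by the surveys; the new label must not collide with them.
#' @param stratum_label label to assign (default `"R:registry"`).
#' @return the registry with `stratum_id`, `psu_id`, `weight` filled.
#' @export
add_registry_design_variables <- function(records,
                                          survey_strata = character(0),
                                          stratum_label = "R:registry") {
  stopifnot(all(as.character(records$source) == "case_registry"))
  if (stratum_label %in% survey_strata)
    stop("registry stratum label '", stratum_label,
         "' collides with an existing survey stratum", call. = FALSE)
  n <- nrow(records)
  records$stratum_id <- rep(stratum_label, n)
  records$psu_id <- sprintf("R:psu%06d", seq_len(n))
  records$weight <- rep(1, n)
  records
}

#' Stack harmonized tables row-wise
#'
#' Row-wise concatenation with strict schema alignment: all inputs must
#' share an identical column set with compatible types; the `source`
#' column preserves provenance.
#'
#' @param ... harmonized `data.frame`s.
#' @return one stacked `data.frame`.
#' @export
stack_sources <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) &&
      !is.data.frame(tables[[1]])) tables <- tables[[1]]
  stopifnot(length(tables) >= 1)
  ref <- names(tables[[1]])
  for (i in seq_along(tables)) {
    miss <- setdiff(ref, names(tables[[i]]))
    extra <- setdiff(names(tables[[i]]), ref)
    if (length(miss) || length(extra))
      stop("schema mismatch in table ", i,
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
           call. = FALSE)
    for (cn in ref) {
      a <- tables[[1]][[cn]]; b <- tables[[i]][[cn]]
      if (is.numeric(a) != is.numeric(b))
        stop("schema mismatch in table ", i, ": column '", cn,
             "' has conflicting type", call. = FALSE)
    }
  }
  out <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
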