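#' @name schema
#' @title The harmonized record schema
#'
#' @description
#' Every data system is mapped into one tabular schema before analysis.  A
#' harmonized table is an ordinary `data.frame` with the columns below;
#' categorical columns are factors over fixed level sets and missingness is
#' encoded as `NA` (the "missing" state of the tri-state exposure coding).
#'
#' \describe{
#'   \item{person_id}{integer, row id in the generating population (truth
#'     linkage; arbitrary for externally supplied data).}
#'   \item{source}{factor: `control_survey`, `validation_survey`,
#'     `case_registry`.}
#'   \item{case}{0/1 outcome; 1 only for `case_registry` rows.}
#'   \item{age_group}{factor: `16-20`, `21-34`, `35-49`, `50-64`, `65+`.}
#'   \item{sex}{factor: `male`, `female`.}
#'   \item{race}{factor: `White`, `Black`, `Hispanic`, `Others`.}
#'   \item{education}{factor: `less than HS`, `HS graduate`, `some college`,
#'     `college/some graduate`.}
#'   \item{self_cannabis, self_alcohol, blood_cannabis, blood_alcohol,
#'     oral_cannabis, oral_alcohol}{tri-state exposure factors with levels
#'     `negative`, `positive` and `NA` for missing.}
#'   \item{stratum_id, psu_id}{design labels (character), namespaced by
#'     source so labels can never collide across systems.}
#'   \item{weight}{positive sampling weight (inverse inclusion
#'     probability).}
#' }
NULL

# Canonical level sets ------------------------------------------------------

#' @rdname schema
#' @format `fusemi_levels` is a named list of the canonical level sets;
#'   `fusemi_ref_levels` names the analysis reference level per variable.
#' @export
fusemi_levels <- list(
  source     = c("control_survey", "validation_survey", "case_registry"),
  age_group  = c("16-20", "21-34", "35-49", "50-64", "65+"),
  sex        = c("male", "female"),
  race       = c("White", "Black", "Hispanic", "Others"),
  education  = c("less than HS", "HS graduate", "some college",
                 "college/some graduate"),
  tristate   = c("negative", "positive"),
  recency    = c("past 24 h", "past 2 days", "past month", "over a month",
                 "beyond a year/never"),
  weekly_freq = c("0", "1-2", "3-4", "5-7", "8-14", ">14")
)

# Analysis-model reference levels: the factor level listed first is the
# reference in model matrices (35-49, female, White, HS graduate, negative).
#' @rdname schema
#' @export
fusemi_ref_levels <- c(
  age_group = "35-49", sex = "female", race = "White",
  education = "HS graduate", tristate = "negative"
)

.demographic_vars <- c("age_group", "sex", "race", "education")
.exposure_vars <- c("self_cannabis", "self_alcohol",
                    "blood_cannabis", "blood_alcohol",
                    "oral_cannabis", "oral_alcohol")
.design_vars <- c("stratum_id", "psu_id", "weight")
.schema_cols <- c("person_id", "source", "case", .demographic_vars,
                  .exposure_vars, .design_vars)

.tristate_factor <- function(x) {
  factor(as.character(x), levels = fusemi_levels$tristate)
}

# Factor with the analysis reference level first.
.ref_factor <- function(x, var) {
  lev <- fusemi_levels[[if (var %in% .exposure_vars) "tristate" else var]]
  ref <- fusemi_ref_levels[[if (var %in% .exposure_vars) "tristate" else var]]
  stats::relevel(factor(as.character(x), levels = lev), ref = ref)
}

#' Validate a table against the harmonized schema
#'
#' Checks the column set, factor level sets, tri-state encodings, weight
#' positivity and the per-source design-variable rules: survey rows must
#' carry positive weights and design labels; a case registry is accepted
#' either pre-augmentation (no design variables filled in) or
#' post-augmentation (unique PSU per row, a single stratum, and weight
#' exactly 1 on every row).
#'
#' @param x a data.frame, or a path to a CSV file in the harmonized schema.
#' @param source_rule one of `"auto"`, `"control_survey"`,
#'   `"validation_survey"`, `"case_registry"`: which per-source design rules
#'   to enforce.  `"auto"` applies each row's own `source`.
#' @return a list with elements `ok` (logical) and `violations` (character
#'   vector, empty when `ok`).
#' @export
validate_schema <- function(x, source_rule = "auto") {
  if (is.character(x) && length(x) == 1L) x <- utils::read.csv(x)
  v <- character(0)
  missing_cols <- setdiff(.schema_cols, names(x))
  extra <- setdiff(names(x), .schema_cols)
  if (length(missing_cols))
    v <- c(v, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (length(extra))
    v <- c(v, paste("unknown columns:", paste(extra, collapse = ", ")))
  if (length(v)) return(list(ok = FALSE, violations = v))

  chk_levels <- function(var, lev) {
    bad <- setdiff(unique(as.character(x[[var]])), c(lev, NA))
    if (length(bad)) {
      rows <- which(as.character(x[[var]]) %in% bad)[1]
      sprintf("%s: unknown level '%s' (first at row %d)", var, bad[1], rows)
    } else character(0)
  }
  for (var in c("source", .demographic_vars))
    v <- c(v, chk_levels(var, fusemi_levels[[var]]))
  for (var in .exposure_vars)
    v <- c(v, chk_levels(var, fusemi_levels$tristate))
  if (any(!x$case %in% c(0, 1)))
    v <- c(v, "case: values outside {0,1}")
  src <- as.character(x$source)
  if (!any(is.na(x$case)) && !all((x$case == 1) == (src == "case_registry")))
    v <- c(v, "case=1 must hold exactly for case_registry rows")

  rule <- if (source_rule == "auto") src else rep(source_rule, nrow(x))
  surv <- rule %in% c("control_survey", "validation_survey")
  if (any(surv)) {
    w <- x$weight[surv]
    if (any(is.na(w)) || any(w <= 0))
      v <- c(v, "survey rows: weights must be present and > 0")
    if (any(is.na(x$stratum_id[surv])) || any(is.na(x$psu_id[surv])))
      v <- c(v, "survey rows: stratum_id/psu_id must be present")
  }
  reg <- rule == "case_registry"
  if (any(reg)) {
    w <- x$weight[reg]
    augmented <- !all(is.na(w))
    if (augmented) {
      if (!all(!is.na(w) & w == 1))
        v <- c(v, "case_registry rows: augmented weights must all equal 1")
      psu <- x$psu_id[reg]
      if (anyDuplicated(psu))
        v <- c(v, "case_registry rows: psu_id must be unique per row")
      if (length(unique(x$stratum_id[reg])) > 1)
        v <- c(v, "case_registry rows: a single stratum label is required")
      if (any(surv) && any(unique(x$stratum_id[reg]) %in% x$stratum_id[surv]))
        v <- c(v, "case_registry stratum label collides with a survey stratum")
    }
  }
  list(ok = length(v) == 0L, violations = v)
}
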