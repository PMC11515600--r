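#' Specification of the case-control analysis model
#'
#' Outcome is the case indicator; default terms are the demographic
#' covariates plus blood alcohol and blood cannabis positivity, with
#' reference levels 35-49, female, White, HS graduate, and negative for
#' both tests.  Coefficients are reported on the log-odds scale; the
#' report layer exponentiates to odds ratios.
#'
#' @param terms model terms (schema variables).
#' @param outcome outcome column (default `"case"`).
#' @param weight_var,stratum_var,psu_var design columns.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(terms = c("age_group", "sex", "race", "education",
                                 "blood_alcohol", "blood_cannabis"),
                       outcome = "case", weight_var = "weight",
                       stratum_var = "stratum_id", psu_var = "psu_id") {
  bad <- setdiff(terms, c(.demographic_vars, .exposure_vars))
  if (length(bad)) stop("terms outside schema: ", paste(bad, collapse = ", "))
  structure(list(terms = terms, outcome = outcome, weight_var = weight_var,
                 stratum_var = stratum_var, psu_var = psu_var),
            class = "model_spec")
}

# Model matrix with the analysis reference levels.
.spec_matrix <- function(data, spec) {
  blocks <- lapply(spec$terms, function(v) {
    vec <- data[[v]]
    if (any(is.na(vec)))
      stop("model term '", v, "' has missing values; complete data required",
           call. = FALSE)
    .dummy_block(vec, v)
  })
  x <- do.call(cbind, c(list(matrix(1, nrow(data), 1,
                                    dimnames = list(NULL, "(Intercept)"))),
                        blocks))
  x
}

#' Survey-weighted logistic regression (pseudo-MLE)
#'
#' Solves the weight-multiplied score equations of the logistic model by
#' iteratively reweighted least squares.  Zero-variance columns are
#' dropped with a warning; separation is flagged as non-convergence naming
#' the offending term (no silent penalization).
#'
#' @param data complete-data harmonized table.
#' @param spec a [model_spec()].
#' @return object of class `fit_result`: `coefficients` (named, log-odds
#'   scale), `n_used`, `converged`, `dropped`, plus internals used by
#'   [design_based_variance()].
#' @export
fit_weighted_logistic <- function(data, spec = model_spec()) {
  x <- .spec_matrix(data, spec)
  y <- data[[spec$outcome]]
  w <- data[[spec$weight_var]]
  if (any(is.na(w)) || any(w <= 0)) stop("weights must be positive")
  keep <- c(TRUE, apply(x[, -1, drop = FALSE], 2,
                        function(cc) stats::var(cc) > 0))
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    warning("zero-variance term(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  xk <- x[, keep, drop = FALSE]
  fit <- .irls_logistic(xk, y, w, maxit = 50L, tol = 1e-12)
  beta <- stats::setNames(fit$coefficients, colnames(xk))
  converged <- fit$converged && !fit$separated
  if (fit$separated) {
    worst <- colnames(xk)[which.max(abs(beta))]
    warning("possible separation; non-convergence flagged at term '",
            worst, "'", call. = FALSE)
  }
  structure(list(coefficients = beta, n_used = nrow(data),
                 converged = converged, dropped = dropped,
                 x = xk, y = y, w = w, spec = spec),
            class = "fit_result")
}

#' Taylor-linearization design-based covariance
#'
#' Sandwich estimator for the pseudo-MLE under a stratified multistage
#' design: weighted score contributions are totalled per primary sampling
#' unit, their between-PSU covariance within each stratum (around the
#' stratum mean, with the n_h/(n_h-1) factor) forms the meat, and the
#' inverse weighted information the bread.  Augmented registry rows — one
#' PSU each in a single stratum with unit weight — contribute
#' per-observation variation by construction.  A stratum with a single PSU
#' is an error naming the stratum.
#'
#' @param data the data the fit was computed on.
#' @param spec the [model_spec()].
#' @param fit the [fit_weighted_logistic()] result.
#' @return covariance matrix of the coefficients.
#' @export
design_based_variance <- function(data, spec, fit) {
  x <- fit$x
  y <- fit$y
  w <- fit$w
  p <- stats::plogis(drop(x %*% fit$coefficients))
  u <- x * (w * (y - p))                       # weighted score contributions
  a <- crossprod(x, x * (w * p * (1 - p)))     # weighted information
  strat <- as.character(data[[spec$stratum_var]])
  psu <- paste(strat, as.character(data[[spec$psu_var]]), sep = "\r")
  z <- rowsum(u, psu, reorder = FALSE)
  z_strat <- sub("\r.*$", "", rownames(z))
  g <- matrix(0, ncol(x), ncol(x))
  for (h in unique(z_strat)) {
    zh <- z[z_strat == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2)
      stop("stratum '", h, "' has a single PSU; design variance undefined",
           call. = FALSE)
    zc <- sweep(zh, 2, colMeans(zh))
    g <- g + crossprod(zc) * nh / (nh - 1)
  }
  ai <- solve(a)
  v <- ai %*% g %*% ai
  dimnames(v) <- list(names(fit$coefficients), names(fit$coefficients))
  v
}

# Fit + design variance on one completed dataset; returns NULL on
# non-convergence so callers can drop the replicate.
.fit_completed <- function(cd, spec, with_variance = TRUE) {
  fit <- withCallingHandlers(
    fit_weighted_logistic(cd$data, spec),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!fit$converged) return(NULL)
  out <- list(coefficients = fit$coefficients, n_used = fit$n_used)
  if (with_variance)
    out$variance <- diag(design_based_variance(cd$data, spec, fit))
  out
}

# Assemble a per-term report data.frame from pooled estimates.
.report_from_pooled <- function(pooled, method, B = NA, M = NA, n = NA) {
  out <- do.call(rbind, lapply(pooled, function(p)
    data.frame(term = p$term, estimate = p$point, se = sqrt(p$variance),
               df = p$df, ci_low = p$ci_low, ci_high = p$ci_high,
               or = exp(p$point), or_low = exp(p$ci_low),
               or_high = exp(p$ci_high),
               truncated = isTRUE(p$truncated))))
  rownames(out) <- NULL
  structure(out, method = method, B = B, M = M, n = n,
            class = c("model_report", "data.frame"))
}

#' Run one of the four case-control analysis models
#'
#' \describe{
#'   \item{model 1}{bootstrap-with-MI pipeline on the fused control +
#'     registry data ([bmi_pipeline()]); Satterthwaite-t intervals.}
#'   \item{model 2}{M fusion imputations without bootstrap, Rubin's rules
#'     with the design-based within-imputation variance.}
#'   \item{model 3}{validation + registry complete cases (listwise
#'     deletion on every model term), single design-based fit, normal
#'     intervals.}
#'   \item{model 4}{M imputations of the validation survey and of the
#'     registry (run separately, then paired and stacked), Rubin's
#'     rules.}
#' }
#'
#' @param model_id 1, 2, 3 or 4.
#' @param inputs list with harmonized `control_survey`,
#'   `validation_survey`, `case_registry` (registry already augmented).
#' @param impute_config an [imputation_config()]; its `n_imputations` is M
#'   for models 2 and 4 and the per-bootstrap M for model 1.
#' @param spec a [model_spec()].
#' @param B bootstrap replicates (model 1 only).
#' @param seed master seed (model 1 resampling).
#' @return a `model_report` data.frame (term, log-odds estimate, se, df,
#'   CI, OR and OR CI) with attributes `method`, `B`, `M`, `n`; model 1
#'   additionally carries the `grid` attribute ([bmi_pipeline()] output).
#' @export
run_model <- function(model_id, inputs, impute_config = imputation_config(),
                      spec = model_spec(), B = 200, seed = 1L) {
  stopifnot(model_id %in% 1:4)
  if (model_id == 1) {
    res <- bmi_pipeline(inputs, B = B, M = impute_config$n_imputations,
                        impute_config = impute_config, spec = spec,
                        seed = seed)
    rep <- .report_from_pooled(res$pooled, "BMI", B = B,
                               M = impute_config$n_imputations, n = res$n)
    attr(rep, "grid") <- res
    return(rep)
  }
  if (model_id == 2) {
    stacked <- stack_sources(inputs$control_survey, inputs$validation_survey)
    fus <- chained_impute(stacked, impute_config)
    reg <- impute_case_registry(inputs$case_registry, impute_config)
    completed <- pair_and_stack(fus, reg)
  } else if (model_id == 3) {
    d <- stack_sources(inputs$validation_survey, inputs$case_registry)
    cc <- stats::complete.cases(d[, spec$terms, drop = FALSE])
    d <- d[cc, , drop = FALSE]
    fit <- fit_weighted_logistic(d, spec)
    v <- design_based_variance(d, spec, fit)
    z <- stats::qnorm(0.975)
    est <- fit$coefficients
    se <- sqrt(diag(v))
    out <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), df = Inf,
                      ci_low = unname(est - z * se),
                      ci_high = unname(est + z * se),
                      or = exp(unname(est)),
                      or_low = exp(unname(est - z * se)),
                      or_high = exp(unname(est + z * se)),
                      truncated = FALSE)
    return(structure(out, method = "complete_case", B = NA,
                     M = NA, n = nrow(d),
                     class = c("model_report", "data.frame")))
  } else {
    # model 4: validation survey and registry are imputed separately —
    # every registry row is a case, so a pooled imputation model without
    # the (excluded) source indicator would shrink case exposures toward
    # the driver distribution
    val <- chained_impute(inputs$validation_survey, impute_config)
    reg <- impute_case_registry(inputs$case_registry, impute_config,
                                b_index = 0L)
    completed <- lapply(seq_along(val), function(m) {
      structure(list(data = stack_sources(val[[m]]$data, reg[[m]]$data),
                     b = 0L, m = m, learner = val[[m]]$learner,
                     seed = c(val[[m]]$seed, reg[[m]]$seed)),
                class = "completed_dataset")
    })
  }
  fits <- lapply(completed, .fit_completed, spec = spec)
  ok <- !vapply(fits, is.null, logical(1))
  if (!all(ok))
    warning(sum(!ok), " non-convergent imputation fit(s) dropped",
            call. = FALSE)
  fits <- fits[ok]
  if (length(fits) < 2) stop("fewer than 2 convergent imputation fits")
  terms <- names(fits[[1]]$coefficients)
  pooled <- lapply(terms, function(tm) {
    rubin_pool(vapply(fits, function(f) f$coefficients[[tm]], numeric(1)),
               vapply(fits, function(f) f$variance[[tm]], numeric(1)),
               term = tm)
  })
  .report_from_pooled(pooled, "Rubin", M = length(fits),
                      n = fits[[1]]$n_used)
}

#' Transportability diagnostic across the two surveys
#'
#' The fusion step assumes the conditional distribution of use given
#' demographics is shared between the control and validation populations.
#' As an observable proxy, this fits a weighted logistic regression of
#' each self-report variable on the demographics separately per source and
#' compares coefficients in units of the joint standard error.
#'
#' @param control_survey,validation_survey harmonized tables.
#' @param outcomes self-report variables to check.
#' @return data.frame: `outcome`, `term`, per-source estimates and SEs,
#'   `difference`, `z` (absolute standardized difference).
#' @export
check_transportability <- function(control_survey, validation_survey,
                                   outcomes = c("self_cannabis",
                                                "self_alcohol")) {
  out <- NULL
  for (ov in outcomes) {
    one <- function(d) {
      cc <- stats::complete.cases(d[, c(.demographic_vars, ov)])
      d <- d[cc, , drop = FALSE]
      d$.y <- as.integer(as.character(d[[ov]]) == "positive")
      sp <- model_spec(terms = .demographic_vars, outcome = ".y")
      fit <- fit_weighted_logistic(d, sp)
      v <- design_based_variance(d, sp, fit)
      list(est = fit$coefficients, se = sqrt(diag(v)))
    }
    a <- one(control_survey)
    b <- one(validation_survey)
    terms <- intersect(names(a$est), names(b$est))
    out <- rbind(out, data.frame(
      outcome = ov, term = terms,
      est_control = unname(a$est[terms]),
      est_validation = unname(b$est[terms]),
      se_control = unname(a$se[terms]), se_validation = unname(b$se[terms]),
      difference = unname(a$est[terms] - b$est[terms]),
      z = abs(unname(a$est[terms] - b$est[terms])) /
        sqrt(unname(a$se[terms])^2 + unname(b$se[terms])^2)))
  }
  rownames(out) <- NULL
  out
}

#' Naive case-control fit ignoring misclassification
#'
#' The comparison the fusion method replaces: self-reported use stands in
#' for the biomarker in the control survey while cases keep their blood
#' results, and the two are modelled as if they measured the same thing.
#' Used to quantify the misclassification bias on synthetic data.
#'
#' @param control_survey,case_registry harmonized tables (registry
#'   augmented, blood tests observed or completed).
#' @param spec a [model_spec()].
#' @return a `fit_result` plus design covariance in attribute `vcov`.
#' @export
naive_self_report_fit <- function(control_survey, case_registry,
                                  spec = model_spec()) {
  ctrl <- control_survey
  ctrl$blood_cannabis <- ctrl$self_cannabis
  ctrl$blood_alcohol <- ctrl$self_alcohol
  d <- stack_sources(ctrl, case_registry)
  cc <- stats::complete.cases(d[, spec$terms, drop = FALSE])
  d <- d[cc, , drop = FALSE]
  fit <- fit_weighted_logistic(d, spec)
  attr(fit, "vcov") <- design_based_variance(d, spec, fit)
  fit
}
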