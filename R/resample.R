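#' One stratified bootstrap replicate of the three data systems
#'
#' Surveys are resampled at the primary-sampling-unit level: within each
#' stratum holding n_h PSUs, n_h PSUs are drawn with replacement and all
#' their records included, with distinct replicate labels appended to
#' duplicated PSU ids.  The registry is resampled at the individual level
#' with replacement at its original size and its unique-PSU augmentation
#' is refreshed.  Duplicated PSUs keep their original weights by default
#' (the bootstrap targets total variability, not design-consistent
#' reweighting); `method = "rao_wu"` draws n_h - 1 PSUs and rescales
#' weights by n_h/(n_h - 1).
#'
#' @param control_survey,validation_survey,case_registry harmonized tables
#'   (registry augmented).
#' @param seed integer seed; fully determines the replicate.
#' @param method `"nh"` (default) or `"rao_wu"`.
#' @return list with the three resampled tables.
#' @export
stratified_bootstrap <- function(control_survey, validation_survey,
                                 case_registry, seed = 1L,
                                 method = c("nh", "rao_wu")) {
  method <- match.arg(method)
  set.seed(seed)
  resample_survey <- function(d) {
    pieces <- list()
    for (h in unique(d$stratum_id)) {
      dh <- d[d$stratum_id == h, , drop = FALSE]
      psus <- unique(dh$psu_id)
      nh <- length(psus)
      if (nh == 0) stop("stratum '", h, "' has zero PSUs", call. = FALSE)
      ndraw <- if (method == "rao_wu") max(nh - 1L, 1L) else nh
      drawn <- psus[sample.int(nh, ndraw, replace = TRUE)]
      for (k in seq_along(drawn)) {
        blk <- dh[dh$psu_id == drawn[k], , drop = FALSE]
        blk$psu_id <- paste0(blk$psu_id, "#", k)
        if (method == "rao_wu") blk$weight <- blk$weight * nh / ndraw
        pieces[[length(pieces) + 1L]] <- blk
      }
    }
    out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
  }
  reg <- case_registry
  if (nrow(reg) > 0) {
    reg <- reg[sample.int(nrow(reg), nrow(reg), replace = TRUE), ,
               drop = FALSE]
    reg$psu_id <- sprintf("R:psu%06d", seq_len(nrow(reg)))
    rownames(reg) <- NULL
  }
  list(control_survey = resample_survey(control_survey),
       validation_survey = resample_survey(validation_survey),
       case_registry = reg)
}

#' Pool a bootstrap-with-MI estimate grid (one term)
#'
#' One-way ANOVA pooling of the B x M grid of estimates from the
#' bootstrap-then-impute pipeline: the point estimate is the grand mean;
#' the between-bootstrap and within-bootstrap mean squares combine into a
#' variance estimate, and the 95% interval uses a t quantile with
#' Satterthwaite degrees of freedom.  A negative variance combination is
#' truncated at the Monte-Carlo floor MSW/(B*M) and flagged.
#'
#' @param theta B x M numeric matrix (rows = bootstrap replicates,
#'   columns = imputations).
#' @param term label carried into the result.
#' @param level confidence level.
#' @return a `pooled_estimate` list: `term`, `point`, `variance`, `df`,
#'   `ci_low`, `ci_high`, `method = "BMI"`, `msb`, `msw`, `truncated`.
#' @export
bmi_pool <- function(theta, term = "term", level = 0.95) {
  theta <- as.matrix(theta)
  B <- nrow(theta)
  M <- ncol(theta)
  if (B < 2 || M < 2) stop("BMI pooling requires B >= 2 and M >= 2")
  if (any(!is.finite(theta))) stop("incomplete estimate grid")
  gbar <- mean(theta)
  bbar <- rowMeans(theta)
  msb <- M * sum((bbar - gbar)^2) / (B - 1)
  msw <- sum((theta - bbar)^2) / (B * (M - 1))
  v <- ((1 + 1 / B) * msb - msw) / M
  floor_v <- msw / (B * M)
  truncated <- v <= floor_v
  if (truncated) v <- floor_v
  denom <- ((1 + 1 / B) * msb / M)^2 / (B - 1) +
    (msw / M)^2 / (B * (M - 1))
  df <- if (denom > 0) v^2 / denom else Inf
  half <- if (v > 0) stats::qt(1 - (1 - level) / 2, df) * sqrt(v) else 0
  structure(list(term = term, point = gbar, variance = v, df = df,
                 ci_low = gbar - half, ci_high = gbar + half,
                 method = "BMI", msb = msb, msw = msw,
                 truncated = truncated),
            class = "pooled_estimate")
}

#' Pool multiply imputed estimates by Rubin's rules
#'
#' Classical combination: point estimate is the mean over imputations,
#' total variance is the mean within-imputation variance plus (1 + 1/M)
#' times the between-imputation variance, and the interval uses a t
#' quantile with the standard MI degrees of freedom.  Zero
#' between-imputation variance yields an infinite-df (normal) interval,
#' flagged.
#'
#' @param theta length-M vector of estimates.
#' @param within length-M vector of within-imputation variances (>= 0).
#' @param term label carried into the result.
#' @param level confidence level.
#' @return a `pooled_estimate` list with `method = "Rubin"`, `wbar`,
#'   `bvar`, `zero_between` flag.
#' @export
rubin_pool <- function(theta, within, term = "term", level = 0.95) {
  M <- length(theta)
  if (M < 2) stop("Rubin pooling requires M >= 2")
  stopifnot(length(within) == M, all(within >= 0))
  point <- mean(theta)
  wbar <- mean(within)
  bvar <- stats::var(theta)
  total <- wbar + (1 + 1 / M) * bvar
  zero_between <- bvar == 0
  df <- if (zero_between) Inf else
    (M - 1) * (1 + wbar / ((1 + 1 / M) * bvar))^2
  q <- stats::qt(1 - (1 - level) / 2, df)
  half <- q * sqrt(total)
  structure(list(term = term, point = point, variance = total, df = df,
                 ci_low = point - half, ci_high = point + half,
                 method = "Rubin", wbar = wbar, bvar = bvar,
                 zero_between = zero_between, truncated = FALSE),
            class = "pooled_estimate")
}

#' The bootstrap-with-multiple-imputation pipeline
#'
#' For each bootstrap replicate b: resample the three systems by
#' [stratified_bootstrap()], run the fusion imputation (M imputations of
#' the stacked control + validation data) and the registry imputation,
#' pair and stack them, and fit the analysis model on each completed
#' integrative dataset.  The resulting B x M grid of coefficient vectors
#' is pooled per term by [bmi_pool()].  Replicate seeds derive
#' deterministically from the master seed, so the grid is reproducible
#' replicate-by-replicate.  Within-bootstrap imputations are run with
#' `proper = FALSE` regardless of the supplied config: the bootstrap
#' itself carries the imputation-model parameter uncertainty.
#'
#' Bootstrap replicates in which any imputation fit fails to converge (or
#' loses a model term to zero variance) are dropped with a count; more
#' than 5% dropped is an error.
#'
#' @param inputs list with harmonized `control_survey`,
#'   `validation_survey`, `case_registry`.
#' @param B number of bootstrap replicates (>= 2).
#' @param M imputations per replicate (>= 2).
#' @param impute_config an [imputation_config()].
#' @param spec a [model_spec()].
#' @param seed master seed.
#' @return list: `theta` (B_kept x M x terms array), `pooled` (list of
#'   `pooled_estimate` per term), `B`, `M`, `dropped` (replicates
#'   dropped), `n` (rows of one integrative dataset).
#' @export
bmi_pipeline <- function(inputs, B = 200, M = 2,
                         impute_config = imputation_config(),
                         spec = model_spec(), seed = 1L) {
  stopifnot(B >= 2, M >= 2)
  template <- NULL
  res <- vector("list", B)
  n_int <- NA_integer_
  for (b in seq_len(B)) {
    tri <- stratified_bootstrap(inputs$control_survey,
                                inputs$validation_survey,
                                inputs$case_registry,
                                seed = .derive_seed(seed, b, 0))
    cfg_b <- impute_config
    cfg_b$n_imputations <- as.integer(M)
    cfg_b$proper <- FALSE
    cfg_b$seed <- .derive_seed(seed, b, 1)
    fus <- chained_impute(stack_sources(tri$control_survey,
                                        tri$validation_survey),
                          cfg_b, b_index = b)
    reg <- impute_case_registry(tri$case_registry, cfg_b, b_index = b)
    completed <- pair_and_stack(fus, reg)
    if (is.na(n_int)) n_int <- nrow(completed[[1]]$data)
    fits <- lapply(completed, .fit_completed, spec = spec,
                   with_variance = FALSE)
    if (any(vapply(fits, is.null, logical(1)))) next
    if (is.null(template)) template <- names(fits[[1]]$coefficients)
    cm <- vapply(fits, function(f) {
      if (!setequal(names(f$coefficients), template))
        rep(NA_real_, length(template))
      else f$coefficients[template]
    }, numeric(length(template)))
    if (any(is.na(cm))) next
    res[[b]] <- t(cm)                                   # M x terms
  }
  kept <- !vapply(res, is.null, logical(1))
  dropped <- sum(!kept)
  if (dropped > 0.05 * B)
    stop(dropped, " of ", B, " bootstrap replicates dropped (> 5%)",
         call. = FALSE)
  if (dropped > 0)
    warning(dropped, " bootstrap replicate(s) dropped", call. = FALSE)
  theta <- array(NA_real_, dim = c(sum(kept), M, length(template)),
                 dimnames = list(NULL, NULL, template))
  for (i in seq_along(which(kept)))
    theta[i, , ] <- res[[which(kept)[i]]]
  pooled <- lapply(template, function(tm) bmi_pool(theta[, , tm], term = tm))
  names(pooled) <- template
  list(theta = theta, pooled = pooled, B = sum(kept), M = M,
       dropped = dropped, n = n_int)
}
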