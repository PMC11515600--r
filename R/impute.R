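#' Configuration for chained-equations multiple imputation
#'
#' @param n_imputations number of completed datasets M.
#' @param n_iterations chained-equation sweeps per imputation.  Imputed
#'   means typically stabilize within a few sweeps because every chain is
#'   initialized from observed within-source margins; the trace is kept in
#'   the `trace` attribute of each completed dataset.
#' @param learner conditional model for binary targets: `"logistic"`,
#'   `"penalized_logistic"` (lasso, penalty by 5-fold cross-validation
#'   inside each fit) or `"random_forest"`.  Multi-level categorical
#'   targets use the learner's multinomial analog (one-vs-rest with
#'   normalized probabilities for the regression learners; class
#'   probabilities for the forest).
#' @param predictor_set schema variables entering each conditional model.
#'   The default is all demographics plus the six exposure variables.  The
#'   source indicator is deliberately excluded: the biomarker is never
#'   observed for control-survey rows, so a source main effect is
#'   unidentified, and excluding it operationalizes the conditional-
#'   exchangeability assumption under which fusion is valid.  Survey
#'   weights are excluded by default (their scales are incomparable across
#'   sources); `include_weights = TRUE` adds within-source normalized
#'   log-weights for sensitivity analysis.
#' @param visit_sequence variable order; default ascending missingness
#'   fraction, ties broken by schema order.
#' @param proper if `TRUE`, each conditional model is fitted on a
#'   with-replacement resample of the observed rows so imputations carry
#'   imputation-model parameter uncertainty (a bootstrap analog of
#'   posterior draws, which penalized and forest learners lack).
#' @param include_weights see `predictor_set`.
#' @param seed integer seed.
#' @return an object of class `imputation_config`.
#' @export
imputation_config <- function(n_imputations = 20, n_iterations = 10,
                              learner = c("penalized_logistic", "logistic",
                                          "random_forest"),
                              predictor_set = NULL, visit_sequence = NULL,
                              proper = TRUE, include_weights = FALSE,
                              seed = 1L) {
  learner <- match.arg(learner)
  stopifnot(n_imputations >= 1, n_iterations >= 1)
  if (is.null(predictor_set))
    predictor_set <- c(.demographic_vars, .exposure_vars)
  bad <- setdiff(predictor_set, c(.demographic_vars, .exposure_vars))
  if (length(bad))
    stop("predictor_set outside schema: ", paste(bad, collapse = ", "))
  structure(list(n_imputations = as.integer(n_imputations),
                 n_iterations = as.integer(n_iterations),
                 learner = learner, predictor_set = predictor_set,
                 visit_sequence = visit_sequence, proper = proper,
                 include_weights = include_weights, seed = as.integer(seed)),
            class = "imputation_config")
}

# ---- learner abstraction --------------------------------------------------

.learner_fit <- function(learner, x, y, stabilize = "firth") {
  if (length(unique(y)) < 2L)
    return(list(kind = "prevalence", p = mean(y)))
  switch(learner,
    logistic = {
      # constant columns (a level unobserved in the fitting rows) would
      # make the information matrix singular; drop and refill with zeros
      keep <- c(TRUE, apply(x[, -1, drop = FALSE], 2,
                            function(cc) any(cc != cc[1])))
      fit <- if (stabilize == "firth")
        .irls_logistic(x[, keep, drop = FALSE], y, maxit = 6L,
                       tol = 1e-5, firth = TRUE)
      else
        .irls_logistic(x[, keep, drop = FALSE], y, maxit = 5L,
                       tol = 1e-5, ridge = 0.01)
      beta <- numeric(ncol(x))
      beta[keep] <- fit$coefficients
      list(kind = "logistic", beta = beta)
    },
    penalized_logistic = {
      xs <- x[, -1, drop = FALSE]                       # glmnet adds its own
      if (ncol(xs) < 2L) {
        fit <- .irls_logistic(x, y, maxit = 8L, tol = 1e-6, firth = TRUE)
        return(list(kind = "logistic", beta = fit$coefficients))
      }
      foldid <- rep_len(1:5, length(y))[order(stats::runif(length(y)))]
      cv <- glmnet::cv.glmnet(xs, y, family = "binomial", foldid = foldid,
                              nlambda = 50)
      list(kind = "glmnet", fit = cv$glmnet.fit, lambda = cv$lambda.min)
    },
    random_forest = {
      d <- data.frame(y = factor(y, levels = c(0, 1)),
                      x[, -1, drop = FALSE])
      rf <- ranger::ranger(y ~ ., data = d, probability = TRUE,
                           num.trees = 200, num.threads = 1,
                           seed = sample.int(1e6, 1), respect.unordered.factors = TRUE)
      list(kind = "ranger", fit = rf)
    })
}

.learner_prob <- function(obj, x) {
  switch(obj$kind,
    prevalence = rep(obj$p, nrow(x)),
    logistic = stats::plogis(drop(x %*% obj$beta)),
    glmnet = drop(stats::predict(obj$fit, newx = x[, -1, drop = FALSE],
                                 s = obj$lambda, type = "response")),
    ranger = {
      pr <- stats::predict(obj$fit, data = data.frame(x[, -1, drop = FALSE]),
                           num.threads = 1)$predictions
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(x))
    })
}

# ---- dummy-coded working matrix ------------------------------------------

# Columns for one variable at its current (filled) values: exposure
# tri-states give one positive-indicator column, demographics give K-1
# treatment dummies against the analysis reference level.
.dummy_block <- function(vec, var) {
  if (var %in% .exposure_vars) {
    m <- matrix(as.numeric(as.character(vec) == "positive"), ncol = 1)
    colnames(m) <- paste0(var, ":positive")
    return(m)
  }
  lev <- fusemi_levels[[var]]
  ref <- fusemi_ref_levels[[var]]
  keep <- setdiff(lev, ref)
  m <- vapply(keep, function(l) as.numeric(as.character(vec) == l),
              numeric(length(vec)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(vec))
  colnames(m) <- paste0(var, ":", keep)
  m
}

.build_working_matrix <- function(cur, vars) {
  blocks <- lapply(vars, function(v) .dummy_block(cur[[v]], v))
  x <- do.call(cbind, c(list(`(Intercept)` = matrix(1, nrow(cur), 1)), blocks))
  colnames(x)[1] <- "(Intercept)"
  col_of <- lapply(vars, function(v) grep(paste0("^", v, ":"), colnames(x)))
  names(col_of) <- vars
  list(x = x, col_of = col_of)
}

# ---- the chained-equations engine ----------------------------------------

# Core engine shared by chained_impute() and impute_case_registry().
# Imputes every predictor_set variable that has missingness AND at least
# one observed value; all-missing columns (structural for the source) are
# left missing and logged.
.cemi_once <- function(data, config, m_index, b_index, chain_seed) {
  set.seed(chain_seed)
  vars <- config$predictor_set
  miss <- lapply(vars, function(v) is.na(data[[v]]))
  names(miss) <- vars
  n_miss <- vapply(miss, sum, numeric(1))
  observed_any <- vapply(vars, function(v) any(!is.na(data[[v]])), logical(1))
  to_impute <- vars[n_miss > 0 & observed_any]
  log_lines <- character(0)
  skipped <- vars[n_miss > 0 & !observed_any]
  if (length(skipped))
    log_lines <- c(log_lines, paste0("structurally missing, not imputed: ",
                                     paste(skipped, collapse = ", ")))
  if (is.null(config$visit_sequence)) {
    ord <- order(n_miss[to_impute], match(to_impute, .schema_cols))
    visit <- to_impute[ord]
  } else {
    visit <- intersect(config$visit_sequence, to_impute)
    if (!setequal(visit, to_impute))
      stop("visit_sequence must cover exactly the variables with ",
           "(non-structural) missingness", call. = FALSE)
  }

  cur <- data
  # initialization: draws from observed within-source margins
  for (v in visit) {
    idx <- which(miss[[v]])
    src <- as.character(cur$source[idx])
    lev <- levels(cur[[v]])
    for (s in unique(src)) {
      rows <- idx[src == s]
      obs_s <- cur[[v]][!is.na(data[[v]]) & as.character(cur$source) == s]
      if (!length(obs_s)) obs_s <- cur[[v]][!is.na(data[[v]])]
      tab <- table(obs_s)
      p <- as.numeric(tab) / sum(tab)
      cur[[v]][rows] <- factor(.rcat(length(rows),
                                     stats::setNames(p, names(tab))),
                               levels = lev)
    }
  }
  # blood and oral indicators of one substance agree almost always, so the
  # pair forms a sticky two-site chain; independent marginal draws start
  # nearly all initial positives in the low-probability discordant states,
  # from which the chain mixes very slowly.  Start concordant instead:
  # where both members of a pair were missing, copy the blood draw.
  for (ex in c("cannabis", "alcohol")) {
    bv <- paste0("blood_", ex); ov <- paste0("oral_", ex)
    if (bv %in% visit && ov %in% visit) {
      both <- miss[[bv]] & miss[[ov]]
      cur[[ov]][both] <- cur[[bv]][both]
    }
  }

  # structurally missing columns would inject NA into every conditional
  # fit; they stay out of the predictor matrix
  pred_vars <- setdiff(vars, skipped)
  wm <- .build_working_matrix(cur, pred_vars)
  if (config$include_weights && !is.null(cur$weight)) {
    lw <- log(cur$weight)
    for (s in unique(as.character(cur$source))) {
      r <- as.character(cur$source) == s
      if (any(r) && !all(is.na(lw[r])))
        lw[r] <- (lw[r] - mean(lw[r], na.rm = TRUE))
    }
    lw[is.na(lw)] <- 0
    wm$x <- cbind(wm$x, log_weight = lw)
  }

  # Blood and oral tests of one substance agree almost always.  Visiting
  # them one at a time makes the pair a sticky two-site Gibbs chain whose
  # stationary marginal amplifies small conditional-model errors, so
  # where both members are under imputation the pair is drawn jointly as
  # one four-state block (blocked Gibbs); rows with only one member
  # missing fall back to the single-variable conditional.
  units <- list()
  consumed <- character(0)
  for (ex in c("cannabis", "alcohol")) {
    bv <- paste0("blood_", ex); ov <- paste0("oral_", ex)
    if (bv %in% visit && ov %in% visit) {
      units[[length(units) + 1L]] <- list(vars = c(bv, ov), type = "pair")
      consumed <- c(consumed, bv, ov)
    }
  }
  for (v in setdiff(visit, consumed))
    units[[length(units) + 1L]] <- list(vars = v, type = "single")
  # order units by the (minimum) missingness of their members
  ord <- order(vapply(units, function(u) min(n_miss[u$vars]), numeric(1)))
  units <- units[ord]

  draw_binary <- function(v, x_all, fit_rows, rows_target, iter) {
    pos_level <- if (v == "sex") "male" else "positive"
    y <- as.numeric(as.character(data[[v]][fit_rows]) == pos_level)
    obj <- .learner_fit(config$learner, x_all[fit_rows, , drop = FALSE],
                        y, stabilize = if (v %in% .exposure_vars)
                          "firth" else "ridge")
    if (obj$kind == "prevalence")
      log_lines <<- c(log_lines, paste0(
        "iteration ", iter, ", ", v, ": single observed class; ",
        "prevalence draw"))
    p <- .learner_prob(obj, x_all[rows_target, , drop = FALSE])
    # keep the chain ergodic: forest leaves and saturated fits may
    # return exact 0/1 probabilities
    p <- pmin(pmax(p, 5e-4), 1 - 5e-4)
    neg_level <- setdiff(levels(cur[[v]]), pos_level)[1]
    ifelse(stats::runif(length(rows_target)) < p, pos_level, neg_level)
  }
  draw_class <- function(x_fit, yobs, lev, x_new) {
    pmat <- matrix(0, nrow(x_new), length(lev),
                   dimnames = list(NULL, lev))
    for (l in lev) {
      obj <- .learner_fit(config$learner, x_fit, as.numeric(yobs == l),
                          stabilize = "ridge")
      pmat[, l] <- .learner_prob(obj, x_new)
    }
    pmat[!is.finite(pmat)] <- 0
    pmat <- pmax(pmat, 1e-8)
    .sample_levels(pmat, lev)
  }
  resample <- function(rows) {
    if (config$proper) rows[sample.int(length(rows), length(rows),
                                       replace = TRUE)] else rows
  }

  trace <- matrix(NA_real_, config$n_iterations, length(visit),
                  dimnames = list(NULL, visit))
  for (iter in seq_len(config$n_iterations)) {
    for (u in units) {
      if (u$type == "pair") {
        bv <- u$vars[1]; ov <- u$vars[2]
        keep_cols <- setdiff(seq_len(ncol(wm$x)),
                             c(wm$col_of[[bv]], wm$col_of[[ov]]))
        x_all <- wm$x[, keep_cols, drop = FALSE]
        both_miss <- which(miss[[bv]] & miss[[ov]])
        both_obs <- which(!miss[[bv]] & !miss[[ov]])
        if (length(both_miss) && length(both_obs) > 1L) {
          fr <- resample(both_obs)
          ystate <- paste(as.character(data[[bv]][fr]),
                          as.character(data[[ov]][fr]), sep = ".")
          lev <- c("negative.negative", "negative.positive",
                   "positive.negative", "positive.positive")
          drawn <- draw_class(x_all[fr, , drop = FALSE], ystate, lev,
                              x_all[both_miss, , drop = FALSE])
          parts <- strsplit(drawn, ".", fixed = TRUE)
          cur[[bv]][both_miss] <- factor(vapply(parts, `[`, "", 1L),
                                         levels = levels(cur[[bv]]))
          cur[[ov]][both_miss] <- factor(vapply(parts, `[`, "", 2L),
                                         levels = levels(cur[[ov]]))
        }
        # rows where exactly one member is missing: single-variable draw
        # with the observed partner as predictor
        for (v in u$vars) {
          partner <- setdiff(u$vars, v)
          only <- which(miss[[v]] & !miss[[partner]])
          if (!length(only)) next
          keep1 <- setdiff(seq_len(ncol(wm$x)), wm$col_of[[v]])
          x1 <- wm$x[, keep1, drop = FALSE]
          cur[[v]][only] <- factor(
            draw_binary(v, x1, resample(which(!miss[[v]])), only, iter),
            levels = levels(cur[[v]]))
        }
        for (v in u$vars) {
          wm$x[, wm$col_of[[v]]] <- .dummy_block(cur[[v]], v)
          trace[iter, v] <- mean(as.character(cur[[v]][miss[[v]]]) ==
                                   "positive")
        }
      } else {
        v <- u$vars
        rows_miss <- which(miss[[v]])
        keep_cols <- setdiff(seq_len(ncol(wm$x)), wm$col_of[[v]])
        x_all <- wm$x[, keep_cols, drop = FALSE]
        fit_rows <- resample(which(!miss[[v]]))
        if (v %in% .exposure_vars || v == "sex") {
          drawn <- draw_binary(v, x_all, fit_rows, rows_miss, iter)
          cur[[v]][rows_miss] <- factor(drawn, levels = levels(cur[[v]]))
          trace[iter, v] <- mean(drawn == if (v == "sex") "male" else
                                   "positive")
        } else {
          lev <- fusemi_levels[[v]]
          drawn <- draw_class(x_all[fit_rows, , drop = FALSE],
                              as.character(data[[v]][fit_rows]), lev,
                              x_all[rows_miss, , drop = FALSE])
          cur[[v]][rows_miss] <- factor(drawn, levels = levels(cur[[v]]))
          trace[iter, v] <- mean(drawn == lev[1])
        }
        wm$x[, wm$col_of[[v]]] <- .dummy_block(cur[[v]], v)
      }
    }
  }
  if (length(visit) && config$n_iterations >= 4) {
    half <- ceiling(config$n_iterations / 2)
    drift <- abs(trace[config$n_iterations, ] - trace[half, ])
    if (any(drift > 0.1, na.rm = TRUE))
      warning("imputed-mean trace not stabilized for: ",
              paste(visit[which(drift > 0.1)], collapse = ", "),
              call. = FALSE)
  }
  structure(list(data = cur, b = b_index, m = m_index,
                 learner = config$learner, seed = chain_seed,
                 trace = trace, log = log_lines),
            class = "completed_dataset")
}

#' Chained-equations multiple imputation of a stacked table
#'
#' The data-fusion step: given the stacked control + validation table (the
#' control survey's biomarker columns are wholly missing; the validation
#' survey has paired measurements with scattered missingness), run chained
#' equations — one conditional model per incomplete variable, cycling in
#' the visit sequence — and return M completed datasets.  Binary targets
#' are imputed by Bernoulli draws from the fitted conditional probability,
#' never by deterministic rounding; originally observed cells are never
#' modified.
#'
#' @param stacked_table harmonized stacked table ([stack_sources()]).
#' @param config an [imputation_config()].
#' @param b_index bootstrap replicate index recorded in the provenance
#'   (0 for non-bootstrap runs).
#' @return list of M `completed_dataset` objects (elements `data`, `b`,
#'   `m`, `learner`, `seed`, plus a per-sweep imputed-mean `trace` and a
#'   `log` of fallback events).
#' @export
chained_impute <- function(stacked_table, config, b_index = 0L) {
  stopifnot(inherits(config, "imputation_config"))
  lapply(seq_len(config$n_imputations), function(m) {
    .cemi_once(stacked_table, config, m_index = m, b_index = b_index,
               chain_seed = .derive_seed(config$seed, b_index, m))
  })
}

#' Multiply impute the case registry
#'
#' Runs the same chained-equations engine on the registry alone: blood
#' tests and education are imputed; columns the registry never measures
#' (self-report, oral tests) are left missing and logged.  Education is
#' imputed as a four-level categorical via the learner's multinomial
#' analog.
#'
#' @param registry_table harmonized (augmented) registry.
#' @param config an [imputation_config()]; the same `n_imputations` as the
#'   fusion step should be used so completions can be paired.
#' @param b_index bootstrap replicate index (0 outside the bootstrap).
#' @return list of M `completed_dataset` objects.
#' @export
impute_case_registry <- function(registry_table, config, b_index = 0L) {
  stopifnot(inherits(config, "imputation_config"))
  lapply(seq_len(config$n_imputations), function(m) {
    .cemi_once(registry_table, config, m_index = m, b_index = b_index,
               chain_seed = .derive_seed(config$seed, b_index, m, 7L))
  })
}

#' Pair fusion and registry imputations into integrative datasets
#'
#' Imputation m of the stacked control + validation data is paired with
#' imputation m of the registry (one-to-one, not a cross product).
#' Validation-survey rows are excluded: they take part in the imputation
#' but not in the post-imputation case-control analysis.
#'
#' @param control_imputations list of `completed_dataset` from
#'   [chained_impute()] (may still contain validation rows).
#' @param registry_imputations list of `completed_dataset` from
#'   [impute_case_registry()].
#' @return list of M integrative `completed_dataset` objects.
#' @export
pair_and_stack <- function(control_imputations, registry_imputations) {
  M <- length(control_imputations)
  if (length(registry_imputations) != M)
    stop("unequal numbers of imputations: ", M, " vs ",
         length(registry_imputations), call. = FALSE)
  lapply(seq_len(M), function(m) {
    ci <- control_imputations[[m]]
    ri <- registry_imputations[[m]]
    stopifnot(ci$m == m, ri$m == m)
    ctrl <- ci$data[as.character(ci$data$source) != "validation_survey", ,
                    drop = FALSE]
    structure(list(data = stack_sources(ctrl, ri$data), b = ci$b, m = m,
                   learner = ci$learner, seed = c(ci$seed, ri$seed)),
              class = "completed_dataset")
  })
}

#' Cross-validated selection of the binary imputation learner
#'
#' Compares candidate imputation models for a binary biomarker target by
#' stratified k-fold cross-validation on validation-survey rows with an
#' observed gold standard and complete predictors, reporting AUC,
#' sensitivity and specificity (at the 0.5 threshold) per learner and
#' returning the argmax-AUC learner (ties broken by candidate order).
#'
#' @param training_pairs harmonized rows with the gold-standard outcome
#'   observed; rows with incomplete predictors are dropped.
#' @param outcome_var tri-state gold-standard column
#'   (default `"blood_cannabis"`).
#' @param predictors predictor columns (default demographics + the two
#'   self-report variables).
#' @param candidates learners to compare.
#' @param n_folds folds (default 10); if some fold lacks an outcome class
#'   the data are refolded with fewer, larger folds, and an error is
#'   raised only when even 2 folds cannot hold both classes.
#' @param seed integer seed.
#' @return list with `chosen` (learner name) and `metrics` (data.frame
#'   with `learner`, `auc`, `sensitivity`, `specificity`).
#' @export
select_learner <- function(training_pairs, outcome_var = "blood_cannabis",
                           predictors = c(.demographic_vars, "self_cannabis",
                                          "self_alcohol"),
                           candidates = c("logistic", "penalized_logistic",
                                          "random_forest"),
                           n_folds = 10, seed = 1L) {
  set.seed(seed)
  keep <- !is.na(training_pairs[[outcome_var]])
  for (p in predictors) keep <- keep & !is.na(training_pairs[[p]])
  d <- training_pairs[keep, , drop = FALSE]
  y <- as.numeric(as.character(d[[outcome_var]]) == "positive")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot cross-validate", call. = FALSE)
  wm <- .build_working_matrix(d, predictors)
  x <- wm$x

  fold_ok <- FALSE
  k <- n_folds
  while (k >= 2 && !fold_ok) {
    folds <- integer(length(y))
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      folds[idx] <- rep_len(1:k, length(idx))[order(stats::runif(length(idx)))]
    }
    fold_ok <- all(vapply(1:k, function(f)
      length(unique(y[folds != f])) == 2L && sum(folds == f) > 0, logical(1)))
    if (!fold_ok) k <- k - 1L
  }
  if (!fold_ok)
    stop("could not build folds with both outcome classes", call. = FALSE)

  metrics <- data.frame(learner = candidates, auc = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_)
  for (i in seq_along(candidates)) {
    p_cv <- numeric(length(y))
    for (f in 1:k) {
      tr <- folds != f
      obj <- .learner_fit(candidates[i], x[tr, , drop = FALSE], y[tr])
      p_cv[!tr] <- .learner_prob(obj, x[!tr, , drop = FALSE])
    }
    pred <- as.numeric(p_cv >= 0.5)
    metrics$auc[i] <- .auc_rank(p_cv, y)
    metrics$sensitivity[i] <- if (sum(y == 1)) mean(pred[y == 1] == 1) else NA
    metrics$specificity[i] <- if (sum(y == 0)) mean(pred[y == 0] == 0) else NA
  }
  best <- which(metrics$auc == max(metrics$auc))[1]
  list(chosen = candidates[best], metrics = metrics, n_folds_used = k)
}
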