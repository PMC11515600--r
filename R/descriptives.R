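#' Frequency and percent table for one harmonized variable
#'
#' Emulates the descriptive-table convention of the study: percents are
#' computed among non-missing values (weighted by the survey weights in
#' `weighted_pct` mode), and the missing count is reported separately,
#' excluded from the percent base.
#'
#' @param records harmonized table (or any data.frame holding `variable`).
#' @param variable column name to tabulate.
#' @param mode `"unweighted_pct"` or `"weighted_pct"`.
#' @param digits decimals for the rounded `percent` column (full precision
#'   is kept in `percent_raw`).
#' @return `data.frame` with columns `level`, `frequency`, `percent`,
#'   `percent_raw`, `missing_count` (missing count repeated on each row for
#'   convenience).
#' @export
tabulate_variable <- function(records, variable,
                              mode = c("unweighted_pct", "weighted_pct"),
                              digits = 1) {
  mode <- match.arg(mode)
  if (!variable %in% names(records))
    stop("variable '", variable, "' not in table", call. = FALSE)
  x <- records[[variable]]
  lev <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
  obs <- !is.na(x)
  if (mode == "weighted_pct") {
    w <- records$weight
    if (is.null(w) || any(is.na(w[obs])) || any(w[obs] <= 0))
      stop("weighted_pct requires positive weights on all observed rows",
           call. = FALSE)
  } else {
    w <- rep(1, length(x))
  }
  freq <- vapply(lev, function(l) sum(obs & x == l), numeric(1))
  wsum <- vapply(lev, function(l) sum(w[obs & x == l]), numeric(1))
  pct <- if (sum(wsum) > 0) 100 * wsum / sum(wsum) else rep(NA_real_,
                                                            length(lev))
  data.frame(level = lev, frequency = as.integer(freq),
             percent = round(pct, digits), percent_raw = pct,
             missing_count = sum(!obs), row.names = NULL)
}

#' Sensitivity and specificity of self-report against the blood test
#'
#' Builds confusion summaries of a self-report variable against its
#' biomarker gold standard, overall and optionally within levels of a
#' covariate.  Following the accuracy-table convention of the study, rows
#' can be restricted to those with complete (self, blood) pairs for *both*
#' cannabis and alcohol (`both_pairs_complete = TRUE`); otherwise the
#' summary is pairwise-complete in the two supplied variables only.
#'
#' @param records harmonized table.
#' @param self_var,gold_var tri-state column names (e.g. `"self_cannabis"`,
#'   `"blood_cannabis"`).
#' @param by optional covariate name; one summary per level is added.
#' @param both_pairs_complete restrict to rows with complete self/blood
#'   pairs for both substances (default `TRUE`).
#' @return `data.frame` of confusion summaries: `subgroup`, `n_pairs`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity` (each `NA` when
#'   its denominator is empty).
#' @export
confusion_summary <- function(records, self_var, gold_var, by = NULL,
                              both_pairs_complete = TRUE) {
  for (v in c(self_var, gold_var))
    if (!v %in% names(records)) stop("no column '", v, "'", call. = FALSE)
  keep <- if (both_pairs_complete) {
    !is.na(records$self_cannabis) & !is.na(records$blood_cannabis) &
      !is.na(records$self_alcohol) & !is.na(records$blood_alcohol)
  } else {
    !is.na(records[[self_var]]) & !is.na(records[[gold_var]])
  }
  d <- records[keep, , drop = FALSE]
  one <- function(rows, label) {
    s <- as.character(d[[self_var]][rows]) == "positive"
    g <- as.character(d[[gold_var]][rows]) == "positive"
    tp <- sum(s & g); fn <- sum(!s & g)
    tn <- sum(!s & !g); fp <- sum(s & !g)
    data.frame(subgroup = label, n_pairs = length(s),
               tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  out <- one(seq_len(nrow(d)), "overall")
  if (!is.null(by)) {
    lev <- levels(factor(d[[by]]))
    for (l in lev)
      out <- rbind(out, one(which(as.character(d[[by]]) == l),
                            paste0(by, ":", l)))
  }
  rownames(out) <- NULL
  out
}
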