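## Shared machinery: fit an OLS model on complete cases of the involved
## columns and package coefficients, SEs, p-values, AIC (Gaussian likelihood,
## k = regressors + intercept + residual variance, i.e. stats::AIC on lm) and
## adjusted R^2 into a regression_result.
fit_ols <- function(table, formula, response, min_n = 10L) {
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    cfd_stop(sprintf("table lacks columns: %s", paste(missing_cols, collapse = ", ")),
             "argument_error")
  cc <- complete.cases(table[vars])
  dat <- table[cc, vars, drop = FALSE]
  if (nrow(dat) < min_n)
    cfd_stop(sprintf("only %d complete rows for %s (need >= %d)",
                     nrow(dat), deparse(formula), min_n), "insufficient_data")
  fit <- lm(formula, data = dat)
  if (anyNA(coef(fit)))
    cfd_stop(sprintf("singular design for %s: aliased terms %s",
                     deparse(formula),
                     paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
             "singular_design")
  sm <- suppressWarnings(summary(fit)) # noiseless designs fit essentially perfectly
  ct <- sm$coefficients
  terms <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      statistic = ct[, 3], p_value = ct[, 4],
                      row.names = NULL)
  structure(
    list(response = response, formula = formula, terms = terms,
         intercept = unname(coef(fit)[1L]), aic = AIC(fit),
         adj_r_squared = sm$adj.r.squared, n_used = nrow(dat),
         rows_used = which(cc), fit = fit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ %s  (n = %d, AIC = %.2f, adj R^2 = %.4f)\n",
              x$response, deparse(x$formula[[3]]), x$n_used, x$aic,
              x$adj_r_squared))
  print(x$terms, digits = 4)
  invisible(x)
}

## coefficient lookup helper used throughout tests and the pipeline
result_term <- function(result, term) {
  i <- match(term, result$terms$term)
  if (is.na(i)) cfd_stop(sprintf("no term '%s' in model", term), "argument_error")
  result$terms[i, ]
}

#' Age (+ optional age squared), sex and TBV model for one FD measure
#'
#' Fits `FD ~ age + sex + tbv` (or with an additional `age^2` term) by OLS on
#' the complete cases of the involved columns. Sex is coded female = 0,
#' male = 1, so a negative sex estimate means lower FD in males. Age enters
#' raw (uncentered), matching the convention of reporting age and age^2
#' estimates directly; the design-matrix condition number is recorded in the
#' result for quadratic fits.
#'
#' @param table Subject FD table with columns `age`, `sex` (0/1), `tbv`, and
#'   the `fd_*` measures.
#' @param response Name of the FD column to model, e.g. `"fd_lh"`.
#' @param include_quadratic Add an `I(age^2)` term?
#' @return A `regression_result`: coefficient table (`terms`), `intercept`,
#'   `aic`, `adj_r_squared`, `n_used`, `rows_used`, and the underlying `fit`.
#'   The downstream significance threshold for these ten models is
#'   `fd_alpha_levels()["fd_models"]` = .005.
#' @export
fit_fd_model <- function(table, response, include_quadratic = FALSE) {
  rhs <- if (include_quadratic) "age + I(age^2) + sex + tbv" else "age + sex + tbv"
  f <- stats::as.formula(paste(response, "~", rhs))
  res <- fit_ols(table, f, response)
  if (include_quadratic)
    res$condition_number <- kappa(stats::model.matrix(res$fit), exact = TRUE)
  res
}

#' Compare linear and quadratic age models by AIC
#'
#' The quadratic model is preferred iff its AIC is strictly lower (ties break
#' to the simpler linear model). `delta_aic = aic_linear - aic_quadratic` is
#' reported so callers can apply a materiality rule (differences below ~2 are
#' conventionally considered indistinguishable); no significance claim is
#' encoded here.
#'
#' @param linear,quadratic `regression_result`s fitted on identical rows and
#'   the same response.
#' @return A `model_comparison` list: `aic_linear`, `aic_quadratic`,
#'   `delta_aic`, `preferred`.
#' @export
compare_models_aic <- function(linear, quadratic) {
  if (!identical(linear$response, quadratic$response) ||
      !identical(linear$rows_used, quadratic$rows_used))
    cfd_stop("models were not fitted on identical rows and response",
             "comparability_error")
  structure(
    list(aic_linear = linear$aic, aic_quadratic = quadratic$aic,
         delta_aic = linear$aic - quadratic$aic,
         preferred = if (quadratic$aic < linear$aic) "quadratic" else "linear"),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> AIC linear %.2f vs quadratic %.2f (delta %.3f) -> %s\n",
              x$aic_linear, x$aic_quadratic, x$delta_aic, x$preferred))
  invisible(x)
}

#' Sex-stratified age models
#'
#' Splits the table by sex and fits `FD ~ age + tbv` in each stratum.
#'
#' @inheritParams fit_fd_model
#' @param min_n Minimum complete rows per stratum; a smaller stratum is
#'   returned as `NULL` and named in `flags`.
#' @return List with `female`, `male` (`regression_result` or `NULL`) and
#'   `flags` (character vector of skipped strata).
#' @export
fit_sex_stratified <- function(table, response, min_n = 10L) {
  f <- stats::as.formula(paste(response, "~ age + tbv"))
  one <- function(code) {
    sub <- table[!is.na(table$sex) & table$sex == code, , drop = FALSE]
    tryCatch(fit_ols(sub, f, response, min_n = min_n),
             corticalfd_insufficient_data = function(e) NULL)
  }
  female <- one(0); male <- one(1)
  flags <- c(if (is.null(female)) "female_stratum_too_small",
             if (is.null(male)) "male_stratum_too_small")
  list(female = female, male = male, flags = flags)
}

#' Age-by-sex interaction model
#'
#' Fits `FD ~ age + sex + age:sex + tbv`; the interaction p-value is the
#' quantity tested against the .005 threshold.
#'
#' @inheritParams fit_fd_model
#' @return A `regression_result`; the interaction row is named `age:sex`.
#' @export
fit_interaction_model <- function(table, response) {
  f <- stats::as.formula(paste(response, "~ age + sex + age:sex + tbv"))
  fit_ols(table, f, response)
}

#' Three-way age x sex x asymmetry models for one region pair
#'
#' For the given region pair, computes the per-subject asymmetry index and
#' fits, for each side's FD as response, an OLS model on age, sex, AI, all
#' two-way interactions and the three-way interaction (TBV is not included in
#' this model set; set `include_tbv = TRUE` to add it).
#'
#' @param table Subject FD table.
#' @param region One of `"hemisphere"`, `"frontal"`, `"temporal"`,
#'   `"parietal"`, `"occipital"`.
#' @param include_tbv Add TBV as an additional confounder (off by default).
#' @return List with `left` and `right` `regression_result`s (terms include
#'   `age:sex:ai`) and the `ai` vector used.
#' @export
fit_threeway_asymmetry_model <- function(table, region, include_tbv = FALSE) {
  pr <- REGION_PAIRS[[match.arg(region, names(REGION_PAIRS))]]
  tab <- table
  tab$ai <- asymmetry_index(tab[[pr[1]]], tab[[pr[2]]])
  rhs <- if (include_tbv) "age * sex * ai + tbv" else "age * sex * ai"
  one <- function(resp)
    fit_ols(tab, stats::as.formula(paste(resp, "~", rhs)), resp)
  list(left = one(pr[1]), right = one(pr[2]), ai = tab$ai)
}

#' Age and sex effects on an asymmetry measure
#'
#' Fits `AI ~ age + sex + tbv` for the given region pair. The downstream
#' significance threshold for these five models is
#' `fd_alpha_levels()["asymmetry"]` = .01.
#'
#' @inheritParams fit_threeway_asymmetry_model
#' @return A `regression_result` with response `ai_<region>`.
#' @export
fit_asymmetry_model <- function(table, region) {
  region <- match.arg(region, names(REGION_PAIRS))
  pr <- REGION_PAIRS[[region]]
  tab <- table
  resp <- paste0("ai_", region)
  tab[[resp]] <- asymmetry_index(tab[[pr[1]]], tab[[pr[2]]])
  fit_ols(tab, stats::as.formula(paste(resp, "~ age + sex + tbv")), resp)
}

#' Five-year age-subgroup regressions
#'
#' Bins subjects into half-open five-year age groups `[45,50), [50,55), ...`
#' with the final bin closed (`[75,80]`; a subject aged exactly 50 falls in
#' the 50-55 group), then fits `FD ~ age + sex + tbv` within each bin.
#'
#' @inheritParams fit_fd_model
#' @param bin_width Bin width in years.
#' @param age_min,age_max Bin range bounds.
#' @param min_n Minimum complete rows per bin; smaller bins are skipped and
#'   flagged.
#' @return List with `results` (named list of `regression_result` or `NULL`,
#'   one per bin), `bins` (data frame `bin`, `lower`, `upper`, `n`,
#'   `skipped`).
#' @export
age_subgroup_analysis <- function(table, response, bin_width = 5,
                                  age_min = 45, age_max = 80, min_n = 10L) {
  breaks <- seq(age_min, age_max, by = bin_width)
  if (length(breaks) < 2L) cfd_stop("age range spans no bin", "argument_error")
  lab <- paste0(head(breaks, -1), "-", tail(breaks, -1))
  grp <- cut(table$age, breaks = breaks, right = FALSE,
             include.lowest = TRUE, labels = lab)
  f <- stats::as.formula(paste(response, "~ age + sex + tbv"))
  results <- setNames(vector("list", length(lab)), lab)
  n_bin <- integer(length(lab)); skipped <- logical(length(lab))
  for (i in seq_along(lab)) {
    sub <- table[!is.na(grp) & grp == lab[i], , drop = FALSE]
    n_bin[i] <- nrow(sub)
    res <- tryCatch(fit_ols(sub, f, response, min_n = min_n),
                    corticalfd_insufficient_data = function(e) NULL,
                    corticalfd_singular_design = function(e) NULL)
    results[i] <- list(res) # keep NULL placeholders for skipped bins
    skipped[i] <- is.null(res)
  }
  list(results = results,
       bins = data.frame(bin = lab, lower = head(breaks, -1),
                         upper = tail(breaks, -1), n = n_bin,
                         skipped = skipped))
}

#' Paired t-test with asymmetry direction
#'
#' Classical paired-sample t-test of left vs right values; the direction is
#' leftward when the mean difference is positive, rightward otherwise.
#'
#' @param left,right Equal-length paired numeric vectors (pairs with missing
#'   values are dropped; at least 3 complete pairs required).
#' @return List `t`, `df`, `p`, `mean_diff`, `direction`.
#' @export
paired_t <- function(left, right) {
  if (length(left) != length(right))
    cfd_stop("left and right must have equal length", "argument_error")
  ok <- !is.na(left) & !is.na(right)
  d <- left[ok] - right[ok]
  if (length(d) < 3L) cfd_stop("need at least 3 complete pairs", "argument_error")
  ## constant differences (up to floating-point noise) make t explode
  if (sd(d) <= 1e-12 * max(abs(mean(d)), .Machine$double.xmin))
    cfd_stop("degenerate paired test: differences have zero variance",
             "degenerate_test")
  tt <- t.test(left[ok], right[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d),
       direction = if (mean(d) > 0) "leftward" else "rightward")
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom (used e.g. for female/male group comparisons of FD or TBV).
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 non-missing
#'   values.
#' @return List `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    cfd_stop("each group needs at least 2 values", "argument_error")
  if (sd(a) == 0 && sd(b) == 0) {
    ## identical-constant groups: define t = 0 if means equal, else degenerate
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    cfd_stop("degenerate test: both groups constant", "degenerate_test")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}
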