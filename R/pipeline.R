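#' Read a subject covariate/FD table from CSV
#'
#' Expects columns `id`, `age`, `sex` (strings `F`/`M`, mapped to 0/1;
#' anything else is an error), `tbv`, and optionally the ten `fd_*` columns.
#'
#' @param path CSV path.
#' @return Data frame with `sex` recoded to numeric 0 (female) / 1 (male).
#' @export
read_subject_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "tbv")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    cfd_stop(sprintf("%s lacks columns: %s", path, paste(miss, collapse = ", ")),
             "format_error")
  if (is.character(tab$sex)) {
    s <- toupper(trimws(tab$sex))
    bad <- !s %in% c("F", "M")
    if (any(bad))
      cfd_stop(sprintf("unknown sex codes: %s (want F or M)",
                       paste(unique(tab$sex[bad]), collapse = ", ")),
               "format_error")
    tab$sex <- ifelse(s == "M", 1, 0)
  } else if (!all(tab$sex %in% c(0, 1), na.rm = TRUE)) {
    cfd_stop("numeric sex column must be coded 0 (female) / 1 (male)",
             "format_error")
  }
  tab
}

## one tidy row per region x term, mirroring the layout of the result tables
tidy_result <- function(res, region, extra = list()) {
  out <- res$terms
  out$region <- region
  out$aic <- res$aic
  out$adj_r_squared <- res$adj_r_squared
  out$n_used <- res$n_used
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out[, c("region", setdiff(names(out), "region"))]
}

#' Run the full statistical battery on a subject FD table
#'
#' Applies, in order: per-measure extreme-outlier removal; for each of the
#' ten FD measures the linear and quadratic age models (with AIC comparison)
#' and the age-by-sex interaction model; sex-stratified age models; for each
#' of the five region pairs the paired t-test of direction, the three-way
#' age x sex x asymmetry models and the AI main-effects model; and the
#' five-year age-subgroup regressions.
#'
#' @param table Subject FD table (see [read_subject_table()] /
#'   [generate_cohort_table()]).
#' @param outlier_multiplier IQR multiplier for the outlier screen.
#' @param bin_width Age bin width in years for the subgroup analysis.
#' @return Named list of tidy data frames: `main_models`, `model_comparison`,
#'   `interaction_models`, `sex_stratified`, `paired_tests`, `threeway_models`,
#'   `asymmetry_models`, `age_subgroups`, `outlier_log`, plus `table`
#'   (the screened table).
#' @export
analyze_fd_cohort <- function(table, outlier_multiplier = 3, bin_width = 5) {
  scr <- remove_extreme_outliers(table, multiplier = outlier_multiplier)
  tab <- scr$table
  regions <- FD_REGIONS[FD_COLUMNS %in% names(tab)]

  main <- list(); cmp <- list(); inter <- list(); strat <- list(); subgrp <- list()
  for (rg in regions) {
    col <- paste0("fd_", rg)
    lin <- tryCatch(fit_fd_model(tab, col, include_quadratic = FALSE),
                    corticalfd_error = function(e) NULL)
    qd <- tryCatch(fit_fd_model(tab, col, include_quadratic = TRUE),
                   corticalfd_error = function(e) NULL)
    if (!is.null(lin)) main[[paste0(rg, "_lin")]] <- tidy_result(lin, rg, list(model = "linear"))
    if (!is.null(qd)) main[[paste0(rg, "_quad")]] <- tidy_result(qd, rg, list(model = "quadratic"))
    if (!is.null(lin) && !is.null(qd)) {
      mc <- compare_models_aic(lin, qd)
      cmp[[rg]] <- data.frame(region = rg, aic_linear = mc$aic_linear,
                              aic_quadratic = mc$aic_quadratic,
                              delta_aic = mc$delta_aic, preferred = mc$preferred)
    }
    it <- tryCatch(fit_interaction_model(tab, col),
                   corticalfd_error = function(e) NULL)
    if (!is.null(it)) inter[[rg]] <- tidy_result(it, rg)
    ss <- tryCatch(fit_sex_stratified(tab, col),
                   corticalfd_error = function(e) NULL)
    if (!is.null(ss)) {
      if (!is.null(ss$female))
        strat[[paste0(rg, "_f")]] <- tidy_result(ss$female, rg, list(stratum = "female"))
      if (!is.null(ss$male))
        strat[[paste0(rg, "_m")]] <- tidy_result(ss$male, rg, list(stratum = "male"))
    }
    sg <- tryCatch(age_subgroup_analysis(tab, col, bin_width = bin_width),
                   corticalfd_error = function(e) NULL)
    if (!is.null(sg)) {
      rows <- lapply(names(sg$results), function(bn) {
        r <- sg$results[[bn]]
        if (is.null(r)) return(NULL)
        a <- result_term(r, "age")
        data.frame(region = rg, bin = bn, b_o = r$intercept,
                   age_estimate = a$estimate, age_se = a$se,
                   age_p = a$p_value, n = r$n_used)
      })
      subgrp[[rg]] <- do.call(rbind, rows)
    }
  }

  pairs_present <- names(REGION_PAIRS)[vapply(REGION_PAIRS, function(pr)
    all(pr %in% names(tab)), logical(1))]
  pt <- list(); tw <- list(); am <- list()
  for (region in pairs_present) {
    pr <- REGION_PAIRS[[region]]
    res <- tryCatch(paired_t(tab[[pr[1]]], tab[[pr[2]]]),
                    corticalfd_error = function(e) NULL)
    if (!is.null(res))
      pt[[region]] <- data.frame(region = region, t = res$t, df = res$df,
                                 p = res$p, mean_diff = res$mean_diff,
                                 direction = res$direction)
    t3 <- tryCatch(fit_threeway_asymmetry_model(tab, region),
                   corticalfd_error = function(e) NULL)
    if (!is.null(t3))
      tw[[region]] <- rbind(tidy_result(t3$left, region, list(side = "left")),
                            tidy_result(t3$right, region, list(side = "right")))
    ai <- tryCatch(fit_asymmetry_model(tab, region),
                   corticalfd_error = function(e) NULL)
    if (!is.null(ai)) am[[region]] <- tidy_result(ai, region)
  }

  bind <- function(x) if (length(x)) do.call(rbind, c(x, make.row.names = FALSE)) else NULL
  list(main_models = bind(main), model_comparison = bind(cmp),
       interaction_models = bind(inter), sex_stratified = bind(strat),
       paired_tests = bind(pt), threeway_models = bind(tw),
       asymmetry_models = bind(am), age_subgroups = bind(subgrp),
       outlier_log = scr$log, table = tab)
}

#' Extract a subject FD table from volumes
#'
#' @param subjects Data frame with columns `id`, `age`, `sex`, `tbv` and
#'   either paths (`labels_path`, optional `ribbon_left_path`,
#'   `ribbon_right_path`) or, via `volumes`, in-memory volume sets.
#' @param volumes Optional named list (by subject id) of lists with elements
#'   `labels`, `ribbon_left`, `ribbon_right` (as from
#'   [generate_subject_volume()]). When absent, paths are read with
#'   [read_volume()].
#' @return Subject FD table with the ten `fd_*` columns appended; extraction
#'   failures leave NA and are collected in `attr(, "failures")`.
#' @export
extract_fd_table <- function(subjects, volumes = NULL) {
  out <- subjects[, c("id", "age", "sex", "tbv")]
  for (col in FD_COLUMNS) out[[col]] <- NA_real_
  failures <- character(0)
  for (i in seq_len(nrow(subjects))) {
    sid <- as.character(subjects$id[i])
    res <- tryCatch({
      vs <- if (!is.null(volumes)) volumes[[sid]] else list(
        labels = read_volume(subjects$labels_path[i], as = "labels"),
        ribbon_left = if ("ribbon_left_path" %in% names(subjects))
          read_volume(subjects$ribbon_left_path[i], as = "mask") else NULL,
        ribbon_right = if ("ribbon_right_path" %in% names(subjects))
          read_volume(subjects$ribbon_right_path[i], as = "mask") else NULL
      )
      subject_fd_table(vs$ribbon_left, vs$ribbon_right, vs$labels)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", sid, conditionMessage(res)))
    } else {
      out[i, FD_COLUMNS] <- res$values[FD_REGIONS]
    }
  }
  if (length(failures) > nrow(subjects) / 2)
    cfd_stop(sprintf("FD extraction failed for %d of %d subjects",
                     length(failures), nrow(subjects)), "pipeline_error")
  attr(out, "failures") <- failures
  out
}

#' Run the end-to-end pipeline
#'
#' Takes subject input (an FD table, a table CSV, a synthetic cohort config,
#' or volumes), screens outliers, runs the full model battery and writes tidy
#' result CSVs plus a machine-readable JSON manifest (with file checksums) to
#' `output_dir`. Deterministic for a fixed seed.
#'
#' @param table Subject FD table, or `NULL`.
#' @param table_csv Path to a subject table CSV, or `NULL`.
#' @param cohort A [cohort_config()] to simulate, or `NULL`.
#' @param subjects,volumes Volume input for [extract_fd_table()], or `NULL`.
#' @param output_dir Directory for outputs (created if needed); `NULL` skips
#'   writing.
#' @param outlier_multiplier,bin_width Passed to [analyze_fd_cohort()].
#' @return The [analyze_fd_cohort()] result list, with `manifest` appended
#'   when outputs were written.
#' @export
run_pipeline <- function(table = NULL, table_csv = NULL, cohort = NULL,
                         subjects = NULL, volumes = NULL,
                         output_dir = NULL, outlier_multiplier = 3,
                         bin_width = 5) {
  n_inputs <- sum(!is.null(table), !is.null(table_csv), !is.null(cohort),
                  !is.null(subjects))
  if (n_inputs != 1L)
    cfd_stop("supply exactly one of table, table_csv, cohort, subjects",
             "config_error")
  if (!is.null(table_csv)) table <- read_subject_table(table_csv)
  if (!is.null(cohort)) table <- generate_cohort_table(cohort)
  if (!is.null(subjects)) table <- extract_fd_table(subjects, volumes)
  if (nrow(table) == 0L) cfd_stop("empty subject table", "config_error")

  res <- analyze_fd_cohort(table, outlier_multiplier = outlier_multiplier,
                           bin_width = bin_width)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(main_models = "models_main.csv",
               model_comparison = "model_comparison.csv",
               interaction_models = "models_interaction.csv",
               sex_stratified = "models_sex_stratified.csv",
               paired_tests = "paired_tests.csv",
               threeway_models = "models_threeway.csv",
               asymmetry_models = "models_asymmetry.csv",
               age_subgroups = "age_subgroups.csv",
               outlier_log = "outlier_log.csv",
               table = "subject_fd_table.csv")
    written <- character(0)
    for (key in names(files)) {
      df <- res[[key]]
      if (is.null(df)) next
      p <- file.path(output_dir, files[[key]])
      write.csv(df, p, row.names = FALSE)
      written <- c(written, p)
    }
    manifest <- list(
      package = "corticalfd",
      version = as.character(utils::packageVersion("corticalfd")),
      n_subjects = nrow(table),
      outlier_multiplier = outlier_multiplier,
      bin_width = bin_width,
      files = lapply(written, function(p)
        list(name = basename(p), md5 = unname(tools::md5sum(p))))
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }
  res
}
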