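## Default per-region generative coefficients, at the magnitudes reported for
## a large middle-to-older-age cohort: intercepts and age/sex effects on the
## scale of adjusted-model estimates, quadratic age terms only where a
## nonlinear age effect is expected (bilateral frontal, right temporal),
## residual SDs at the scale of the observed per-region FD SDs, and a small
## positive TBV slope (FD correlates positively with brain volume).

#' Default generative coefficients for the ten FD measures
#'
#' Per-region intercepts, age / age-squared / sex / TBV effects and residual
#' SDs used by [cohort_config()] unless overridden.
#'
#' @return Data frame with one row per region.
#' @export
default_region_coefs <- function() {
  data.frame(
    region    = FD_REGIONS,
    b0        = c(2.38399, 2.37428, 2.34641, 2.35161, 2.32761,
                  2.29513, 2.30984, 2.31595, 2.24495, 2.25451),
    beta_age  = c(-2e-4, -1e-4, -3e-4, -3e-4, -2e-4,
                  -1e-4, -3e-4, -3e-4, -2e-4, -2e-4),
    beta_age2 = c(0, 0, 9.6e-6, 1.15e-5, 0, 7.29e-6, 0, 0, 0, 0),
    beta_sex  = c(-0.0014, -0.0004, 0.0005, -0.0003, 0.0012,
                  0.0017, -0.0060, -0.0041, 0.0020, 0.0038),
    beta_tbv  = rep(2e-8, 10),
    sigma     = c(0.0106, 0.0112, 0.0151, 0.0147, 0.0164,
                  0.0163, 0.0163, 0.0160, 0.0227, 0.0226)
  )
}

#' Configuration for a simulated FD cohort
#'
#' Describes the generative model for [generate_cohort_table()]: per subject,
#' age uniform over `age_range`, sex female (0) with probability
#' `sex_ratio_female`, TBV normal with sex-specific mean/SD (mm^3), and each
#' regional FD drawn as
#' `b0 + beta_age * age + beta_age2 * age^2 + beta_sex * sex + beta_tbv * tbv`
#' plus Gaussian noise. With probability `outlier_rate` a data point is
#' displaced by `outlier_magnitude` residual SDs (sign random) to emulate the
#' extreme outliers screened before analysis.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Length-2 age range in years.
#' @param sex_ratio_female Proportion of females.
#' @param tbv_mean,tbv_sd Named (`female`, `male`) TBV moments in mm^3.
#' @param coefs Data frame like [default_region_coefs()] (columns `region`,
#'   `b0`, `beta_age`, `beta_age2`, `beta_sex`, `beta_tbv`, `sigma`); may
#'   contain any subset of the ten regions.
#' @param outlier_rate Per-data-point probability of an injected extreme
#'   outlier (default 0.0052, about 0.5% of data points).
#' @param outlier_magnitude Outlier displacement in residual-SD units.
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 1000,
                          age_range = c(45, 79),
                          sex_ratio_female = 0.5246,
                          tbv_mean = c(female = 1051176, male = 1159948),
                          tbv_sd = c(female = 79038, male = 92742),
                          coefs = default_region_coefs(),
                          outlier_rate = 0.0052,
                          outlier_magnitude = 8,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, length(age_range) == 2, age_range[1] < age_range[2],
            sex_ratio_female >= 0, sex_ratio_female <= 1,
            all(coefs$sigma > 0), !anyDuplicated(coefs$region),
            all(coefs$region %in% FD_REGIONS),
            outlier_rate >= 0, outlier_rate < 1)
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         sex_ratio_female = sex_ratio_female, tbv_mean = tbv_mean,
         tbv_sd = tbv_sd, coefs = coefs, outlier_rate = outlier_rate,
         outlier_magnitude = outlier_magnitude, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a subject-level FD table with known ground truth
#'
#' Draws a cohort from the generative model in a [cohort_config()]. The
#' returned table carries the full generating parameter record in
#' `attr(, "truth")` so recovery tests can compare fitted coefficients with
#' the injected ones, plus an `attr(, "outliers")` log of injected extreme
#' points.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, `age`, `sex` (0 = female, 1 = male),
#'   `tbv`, and one `fd_<region>` column per configured region.
#' @export
#' @examples
#' tab <- generate_cohort_table(cohort_config(n_subjects = 50, seed = 7))
#' str(attr(tab, "truth")$coefs)
generate_cohort_table <- function(config) {
  if (!inherits(config, "cohort_config"))
    cfd_stop("config must be a cohort_config", "argument_error")
  set.seed(config$seed)
  n <- config$n_subjects
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, 1 - config$sex_ratio_female) # 1 = male
  tbv <- ifelse(sex == 1,
                rnorm(n, config$tbv_mean[["male"]], config$tbv_sd[["male"]]),
                rnorm(n, config$tbv_mean[["female"]], config$tbv_sd[["female"]]))
  tab <- data.frame(id = sprintf("S%05d", seq_len(n)), age = age,
                    sex = sex, tbv = tbv)
  outlog <- list()
  for (i in seq_len(nrow(config$coefs))) {
    co <- config$coefs[i, ]
    fd <- co$b0 + co$beta_age * age + co$beta_age2 * age^2 +
      co$beta_sex * sex + co$beta_tbv * tbv + rnorm(n, 0, co$sigma)
    if (config$outlier_rate > 0) {
      hit <- runif(n) < config$outlier_rate
      if (any(hit)) {
        shift <- sample(c(-1, 1), sum(hit), replace = TRUE) *
          config$outlier_magnitude * co$sigma
        fd[hit] <- fd[hit] + shift
        outlog[[co$region]] <- data.frame(subject = tab$id[hit],
                                          measure = paste0("fd_", co$region),
                                          shift = shift)
      }
    }
    tab[[paste0("fd_", co$region)]] <- fd
  }
  attr(tab, "truth") <- config[c("coefs", "age_range", "sex_ratio_female",
                                 "tbv_mean", "tbv_sd", "outlier_rate",
                                 "outlier_magnitude", "seed")]
  attr(tab, "outliers") <- if (length(outlog))
    do.call(rbind, c(outlog, make.row.names = FALSE))
  else data.frame(subject = character(0), measure = character(0),
                  shift = numeric(0))
  tab
}
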