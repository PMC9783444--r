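test_that("asymmetry index follows the normalized L-R formula", {
  expect_equal(asymmetry_index(2.4, 2.4), 0)
  expect_equal(asymmetry_index(2.43, 2.42), 2 * 0.01 / 4.85)
  expect_error(asymmetry_index(1, -1), class = "corticalfd_argument_error")

  set.seed(11)
  a <- runif(200, 1, 3); b <- runif(200, 1, 3); c <- runif(200, 0.1, 10)
  expect_equal(asymmetry_index(a, b), -asymmetry_index(b, a))
  expect_equal(asymmetry_index(c * a, c * b), asymmetry_index(a, b))
  expect_true(all(abs(asymmetry_index(a, b)) < 2))
})

test_that("extreme-outlier screening flags exactly the 3xIQR violations", {
  x <- c(1:10, 1000)
  tab <- data.frame(id = 1:11, fd_lh = x, fd_rh = rev(1:11) / 100 + 2)
  res <- remove_extreme_outliers(tab)
  ## type-7 quartiles of x: Q1 = 3.5, Q3 = 8.5, IQR = 5 -> bounds [-11.5, 23.5]
  expect_equal(res$log$subject, 11)
  expect_equal(res$log$measure, "fd_lh")
  expect_equal(res$log$value, 1000)
  expect_true(is.na(res$table$fd_lh[11]))
  ## only the offending data point is dropped, not the subject
  expect_false(is.na(res$table$fd_rh[11]))

  same <- data.frame(fd_lh = rep(2.4, 20))
  expect_equal(nrow(remove_extreme_outliers(same)$log), 0)
})

test_that("noiseless cohorts are recovered exactly by the matching models", {
  cfg <- one_region_config(200, seed = 21, b0 = 2.4, beta_age = -2e-4,
                           beta_age2 = 1e-5, beta_sex = -4e-3,
                           beta_tbv = 2e-8, sigma = 1e-12)
  tab <- generate_cohort_table(cfg)
  fit <- fit_fd_model(tab, "fd_lh", include_quadratic = TRUE)
  expect_equal(result_term(fit, "age")$estimate, -2e-4, tolerance = 1e-6)
  expect_equal(result_term(fit, "I(age^2)")$estimate, 1e-5, tolerance = 1e-6)
  expect_equal(result_term(fit, "sex")$estimate, -4e-3, tolerance = 1e-6)
  expect_equal(result_term(fit, "tbv")$estimate, 2e-8, tolerance = 1e-6)
  expect_equal(fit$intercept, 2.4, tolerance = 1e-6)
  expect_equal(fit$n_used, 200L)
})

test_that("the AIC convention matches the Gaussian likelihood identity", {
  tab <- generate_cohort_table(one_region_config(80, seed = 22,
                                                 beta_age = -3e-4))
  fit <- fit_fd_model(tab, "fd_lh")
  n <- fit$n_used
  rss <- sum(residuals(fit$fit)^2)
  k <- length(coef(fit$fit)) + 1 # regressors + intercept + residual variance
  aic_manual <- n * log(2 * pi * rss / n) + n + 2 * k
  expect_equal(fit$aic, aic_manual)
})

test_that("AIC comparison ties break to linear and enforces identical rows", {
  tab <- generate_cohort_table(one_region_config(150, seed = 23,
                                                 beta_age = -3e-4))
  lin <- fit_fd_model(tab, "fd_lh")
  expect_equal(compare_models_aic(lin, lin)$delta_aic, 0)
  expect_equal(compare_models_aic(lin, lin)$preferred, "linear")

  quad <- fit_fd_model(tab, "fd_lh", include_quadratic = TRUE)
  cmp <- compare_models_aic(lin, quad)
  expect_equal(cmp$delta_aic, cmp$aic_linear - cmp$aic_quadratic)
  ## a useless extra regressor can improve AIC by at most its 2-unit penalty
  expect_lte(cmp$delta_aic, 2)

  other <- fit_fd_model(tab[1:100, ], "fd_lh", include_quadratic = TRUE)
  expect_error(compare_models_aic(lin, other),
               class = "corticalfd_comparability_error")
})

test_that("shifting all FD values moves intercepts but no other estimate", {
  tab <- generate_cohort_table(one_region_config(300, seed = 24,
                                                 beta_age = -3e-4,
                                                 beta_sex = 2e-3))
  tab2 <- tab; tab2$fd_lh <- tab2$fd_lh + 0.5
  f1 <- fit_fd_model(tab, "fd_lh"); f2 <- fit_fd_model(tab2, "fd_lh")
  expect_equal(f2$intercept - f1$intercept, 0.5)
  for (term in c("age", "sex", "tbv"))
    expect_equal(result_term(f2, term)$estimate, result_term(f1, term)$estimate)
  q1 <- fit_fd_model(tab, "fd_lh", TRUE); q2 <- fit_fd_model(tab2, "fd_lh", TRUE)
  expect_equal(compare_models_aic(f1, q1)$delta_aic,
               compare_models_aic(f2, q2)$delta_aic)
})

test_that("sex-stratified fits split correctly and flag small strata", {
  ## distinct noiseless slopes per stratum are recovered exactly
  set.seed(25)
  n <- 120
  tab <- data.frame(id = 1:n, age = runif(n, 45, 79),
                    sex = rep(c(0, 1), n / 2), tbv = rnorm(n, 1.1e6, 9e4))
  tab$fd_lh <- with(tab, ifelse(sex == 0, 2.40 - 1e-4 * age, 2.45 - 3e-4 * age))
  res <- fit_sex_stratified(tab, "fd_lh")
  expect_equal(result_term(res$female, "age")$estimate, -1e-4, tolerance = 1e-8)
  expect_equal(result_term(res$male, "age")$estimate, -3e-4, tolerance = 1e-8)

  solo <- tab[tab$sex == 0, ]
  res1 <- fit_sex_stratified(solo, "fd_lh")
  expect_null(res1$male)
  expect_true("male_stratum_too_small" %in% res1$flags)
})

test_that("matched strata differ only by sampling noise", {
  cfg <- one_region_config(2000, seed = 26, beta_age = -2e-4, sigma = 0.015)
  tab <- generate_cohort_table(cfg)
  res <- fit_sex_stratified(tab, "fd_lh")
  af <- result_term(res$female, "age"); am <- result_term(res$male, "age")
  expect_lt(abs(af$estimate - am$estimate),
            4 * sqrt(af$se^2 + am$se^2))
})

test_that("interaction model recovers injected terms and rejects degenerate designs", {
  set.seed(27)
  n <- 100
  tab <- data.frame(age = runif(n, 45, 79), sex = rep(c(0, 1), n / 2),
                    tbv = rnorm(n, 1.1e6, 9e4))
  gamma <- 5e-5
  tab$fd_lh <- 2.4 - 2e-4 * tab$age + 1e-3 * tab$sex + gamma * tab$age * tab$sex
  fit <- fit_interaction_model(tab, "fd_lh")
  expect_equal(result_term(fit, "age:sex")$estimate, gamma, tolerance = 1e-8)

  solo <- tab[tab$sex == 1, ]
  expect_error(fit_interaction_model(solo, "fd_lh"),
               class = "corticalfd_singular_design")
})

test_that("three-way asymmetry models expose all interactions and fail on constant AI", {
  set.seed(28)
  n <- 200
  tab <- data.frame(age = runif(n, 45, 79), sex = rep(c(0, 1), n / 2),
                    tbv = rnorm(n, 1.1e6, 9e4))
  tab$fd_rh <- 2.42 + rnorm(n, 0, 0.01)
  tab$fd_lh <- tab$fd_rh * (1 + rnorm(n, 0, 0.002)) # varying asymmetry
  res <- fit_threeway_asymmetry_model(tab, "hemisphere")
  for (side in c("left", "right"))
    expect_true(all(c("age", "sex", "ai", "age:sex", "age:ai", "sex:ai",
                      "age:sex:ai") %in% res[[side]]$terms$term))
  expect_equal(res$ai, asymmetry_index(tab$fd_lh, tab$fd_rh))

  tab$fd_lh <- tab$fd_rh # AI identically zero
  expect_error(fit_threeway_asymmetry_model(tab, "hemisphere"),
               class = "corticalfd_singular_design")
})

test_that("asymmetry main-effects model recovers a noiseless construction", {
  set.seed(29)
  n <- 150
  tab <- data.frame(age = runif(n, 45, 79), sex = rep(c(0, 1), n / 2),
                    tbv = rnorm(n, 1.1e6, 9e4))
  ai <- 4e-3 - 2.5e-5 * tab$age - 4e-4 * tab$sex
  tab$fd_rh <- 2.42
  tab$fd_lh <- tab$fd_rh * (2 + ai) / (2 - ai) # inverts AI = 2(L-R)/(L+R)
  fit <- fit_asymmetry_model(tab, "hemisphere")
  expect_equal(result_term(fit, "age")$estimate, -2.5e-5, tolerance = 1e-6)
  expect_equal(result_term(fit, "sex")$estimate, -4e-4, tolerance = 1e-6)
})

test_that("asymmetry-model age slope is recovered in noisy simulation", {
  set.seed(30)
  n <- 2000
  tab <- data.frame(age = runif(n, 45, 79), sex = rbinom(n, 1, 0.5),
                    tbv = rnorm(n, 1.1e6, 9e4))
  ai <- 4e-3 - 2.5e-5 * tab$age + rnorm(n, 0, 0.003)
  tab$fd_rh <- 2.42
  tab$fd_lh <- tab$fd_rh * (2 + ai) / (2 - ai)
  fit <- fit_asymmetry_model(tab, "hemisphere")
  a <- result_term(fit, "age")
  expect_lt(abs(a$estimate - (-2.5e-5)), 2 * a$se)
})

test_that("age subgroups use half-open five-year bins with a closed last bin", {
  set.seed(31)
  n <- 700
  tab <- data.frame(age = runif(n, 45, 79), sex = rbinom(n, 1, 0.5),
                    tbv = rnorm(n, 1.1e6, 9e4))
  tab$fd_lh <- 2.4 - 2e-4 * tab$age + rnorm(n, 0, 0.01)
  ## force boundary subjects
  tab$age[1] <- 50; tab$age[2] <- 80; tab$age[3] <- 45
  res <- age_subgroup_analysis(tab, "fd_lh")
  expect_equal(res$bins$bin, c("45-50", "50-55", "55-60", "60-65",
                               "65-70", "70-75", "75-80"))
  expect_equal(nrow(res$bins), 7L)
  expect_false(any(res$bins$skipped))
  ## bin membership of the boundary ages
  grp <- cut(tab$age, seq(45, 80, 5), right = FALSE, include.lowest = TRUE,
             labels = res$bins$bin)
  expect_equal(as.character(grp[1]), "50-55")
  expect_equal(as.character(grp[2]), "75-80")
  expect_equal(as.character(grp[3]), "45-50")
  ## per-bin results report intercept and age effect
  expect_true(all(vapply(res$results, function(r)
    !is.null(r) && "age" %in% r$terms$term, logical(1))))
})

test_that("a bin with too few subjects is skipped and flagged", {
  set.seed(32)
  n <- 60
  tab <- data.frame(age = c(runif(n - 2, 50, 75), 77, 78),
                    sex = rbinom(n, 1, 0.5), tbv = rnorm(n, 1.1e6, 9e4))
  tab$fd_lh <- 2.4 + rnorm(n, 0, 0.01)
  res <- age_subgroup_analysis(tab, "fd_lh")
  expect_true(res$bins$skipped[res$bins$bin == "75-80"])
  expect_null(res$results[["75-80"]])
})

test_that("a steeper injected subgroup slope is detected as most negative", {
  hits <- 0L
  for (rep in 1:20) {
    set.seed(300 + rep)
    n <- 2100
    tab <- data.frame(age = runif(n, 45, 80), sex = rbinom(n, 1, 0.5),
                      tbv = rnorm(n, 1.1e6, 9e4))
    slope <- ifelse(tab$age >= 60 & tab$age < 65, -25e-4, -2e-4)
    tab$fd_lh <- 2.5 + slope * (tab$age - 60) + rnorm(n, 0, 0.01)
    res <- age_subgroup_analysis(tab, "fd_lh")
    est <- vapply(res$results, function(r) result_term(r, "age")$estimate,
                  numeric(1))
    if (names(which.min(est)) == "60-65") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("paired t-test matches the textbook formula and flags degeneracy", {
  L <- c(1, 2, 3); R <- c(2, 2, 5)
  res <- paired_t(L, R)
  d <- L - R # -1, 0, -2
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 2)
  expect_equal(res$direction, "rightward")

  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)),
               class = "corticalfd_degenerate_test")
  expect_error(paired_t(1:10 + 0.01, 1:10), # constant difference
               class = "corticalfd_degenerate_test")
  expect_error(paired_t(1:2, 1:2), class = "corticalfd_argument_error")
})

test_that("Welch t-test matches hand computation", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res$t, (mean(a) - mean(b)) / se)
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$df, df_hand)
  expect_equal(welch_t(c(1, 2, 4), c(1, 2, 4))$t, 0)
  expect_error(welch_t(1, c(1, 2)), class = "corticalfd_argument_error")
})

test_that("study-wide alpha thresholds are exposed as named constants", {
  a <- fd_alpha_levels()
  expect_equal(unname(a["fd_models"]), 0.005)
  expect_equal(unname(a["asymmetry"]), 0.01)
  expect_equal(unname(a["sex_stratified"]), 0.0025)
})
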