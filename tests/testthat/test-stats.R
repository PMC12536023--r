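test_that("pooled t from summaries equals the raw-data pooled t", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 9)
  out <- pooled_two_sample_t(mean(x), sd(x) / sqrt(3), 3,
                             mean(y), sd(y) / sqrt(3), 3)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(out$statistic), unname(ref$statistic))
  expect_equal(unname(out$parameter), 4)
  expect_equal(out$p.value, ref$p.value)

  same <- pooled_two_sample_t(5, 1, 10, 5, 2, 12)
  expect_equal(unname(same$statistic), 0)

  expect_error(pooled_two_sample_t(1, 0, 10, 2, 1, 10))
  expect_error(pooled_two_sample_t(1, 1, 1, 2, 1, 10))
})

test_that("descriptive group statistics reconstruct known summaries", {
  # chi-square for a 29 vs 22 sex split of 16/13 vs 14/8
  chi <- chi_square_2x2(matrix(c(16, 14, 13, 8), 2))
  expect_equal(unname(chi$statistic), 0.37, tolerance = 0.005)
  # SRS-style group contrast from mean/SE summaries
  srs <- pooled_two_sample_t(68.9, 3.0, 22, 47.9, 1.7, 29)
  expect_equal(unname(srs$statistic), 6.44, tolerance = 0.01)
  expect_equal(unname(srs$parameter), 49)
})

test_that("chi-square matches the 2x2 closed form, no correction", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rpois(4, 20) + 1, 2)
    n <- sum(m)
    closed <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m)) / prod(colSums(m))
    expect_equal(unname(chi_square_2x2(m)$statistic), closed)
  }
  prop <- matrix(c(10, 20, 5, 10), 2)  # proportional table
  expect_equal(unname(chi_square_2x2(prop)$statistic), 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("bonferroni gate uses strict inequality at 0.05/n", {
  expect_true(bonferroni_gate(0.005, 5))
  expect_false(bonferroni_gate(0.012, 5))
  expect_false(bonferroni_gate(0.05, 1))
  expect_equal(bonferroni_gate(c(0.001, 0.024, 0.025, 0.03), 2),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the mixed model recovers a noiseless fixed-effect structure", {
  d <- cohort_design(subject_sd = 0, residual_sd = 0, change_sd = 0,
                     baseline_coupling = 0,
                     failure_prob = c(TD = 0, ASD = 0))
  tab <- generate_cohort(d, seed = 11)$table
  m <- suppressWarnings(suppressMessages(
    fit_reactivity_lmm(tab, "temporal_right")))
  cf <- coef(m)
  expect_equal(cf[["diagnosisASD:conditionEO"]], -0.662, tolerance = 1e-6)
  expect_equal(cf[["conditionEO"]], 0.387, tolerance = 1e-6)
  expect_equal(cf[["diagnosisASD"]], 0.471, tolerance = 1e-6)
  expect_equal(cf[["age"]], 0.037, tolerance = 1e-6)
  expect_equal(cf[["sexmale"]], 0.3, tolerance = 1e-6)
})

test_that("model objects carry coherent inference columns", {
  tab <- generate_cohort(cohort_design(), seed = 21)$table
  m <- fit_reactivity_lmm(tab, "occipital_left")
  tt <- m$coefficients
  expect_true(all(tt$p >= 0 & tt$p <= 1))
  expect_true(all(tt$ci_lo <= tt$estimate & tt$estimate <= tt$ci_hi))
  expect_equal(tt$statistic, tt$estimate / tt$se)
  ci <- confint(m)
  expect_equal(unname(ci[, 1]), tt$ci_lo, tolerance = 1e-10)
  expect_output(print(m), "reactivity")
})

test_that("subgroup models recover group-specific condition effects", {
  # TD-only condition effect near +0.387 (mean over replicate cohorts)
  est_td <- sapply(1:30, function(s) {
    tab <- generate_cohort(cohort_design(baseline_coupling = 0),
                           seed = 300 + s)$table
    coef(fit_subgroup_lmm(tab, "temporal_right", "TD"))[["conditionEO"]]
  })
  expect_lt(abs(mean(est_td) - 0.387), 0.1)

  # ASD group with a null condition effect is centered on zero
  d0 <- cohort_design(beta_condition = 0, beta_interaction = 0,
                      baseline_coupling = 0)
  est_asd <- sapply(1:30, function(s) {
    tab <- generate_cohort(d0, seed = 600 + s)$table
    coef(fit_subgroup_lmm(tab, "temporal_right", "ASD"))[["conditionEO"]]
  })
  expect_lt(abs(mean(est_asd)), 0.1)

  # without an interaction, TD and ASD condition CIs overlap
  tab <- generate_cohort(cohort_design(beta_interaction = 0,
                                       baseline_coupling = 0),
                         seed = 77)$table
  td <- fit_subgroup_lmm(tab, "parietal_left", "TD")$coefficients
  asd <- fit_subgroup_lmm(tab, "parietal_left", "ASD")$coefficients
  td <- td[td$term == "conditionEO", ]
  asd <- asd[asd$term == "conditionEO", ]
  expect_true(td$ci_lo <= asd$ci_hi && asd$ci_lo <= td$ci_hi)
})

test_that("change-score regression matches closed forms", {
  # regression to the mean: equicorrelated same-variance conditions give a
  # baseline slope of corr - 1
  set.seed(13)
  n <- 500
  rho <- 0.6
  dr <- rnorm(n)
  eo <- rho * dr + sqrt(1 - rho^2) * rnorm(n)
  tab <- data.frame(
    subject = rep(sprintf("S%03d", 1:n), 2),
    diagnosis = rep(rep(c("TD", "ASD"), length.out = n), 2),
    condition = rep(c("DR", "EO"), each = n),
    region = "temporal_left",
    paf_hz = c(dr, eo) + 10,
    age_months = rep(round(runif(n, 60, 95)), 2),
    sex = rep(sample(c("female", "male"), n, replace = TRUE), 2),
    srs_total = rep(50, 2 * n))
  m <- change_score_regression(tab, "temporal_left")
  expect_lt(abs(coef(m)[["baseline_paf"]] - (rho - 1)), 0.06)

  # noise-free linear construction: exact recovery
  eo2 <- dr - 0.4 * (dr - mean(dr)) + 0.25
  tab$paf_hz <- c(dr, eo2) + 10
  m2 <- change_score_regression(tab, "temporal_left")
  expect_equal(coef(m2)[["baseline_paf"]], -0.4, tolerance = 1e-10)
})

test_that("injected baseline coupling is recovered across cohorts", {
  g <- sapply(1:40, function(s) {
    tab <- generate_cohort(cohort_design(), seed = 1000 + s)$table
    coef(change_score_regression(tab, "temporal_left"))[["baseline_paf"]]
  })
  expect_lt(abs(mean(g) + 0.624), 0.1)
})

test_that("OLS coefficients equal the closed-form solution on small data", {
  set.seed(4)
  d <- data.frame(y = rnorm(10), x1 = rnorm(10), x2 = rnorm(10))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  fit <- lm(y ~ x1 + x2, d)
  expect_equal(unname(coef(fit)), as.numeric(beta))
})

test_that("robust and classical SEs diverge only under heteroscedasticity", {
  # homoscedastic: HC1 and classical agree within 5% on average
  ratios <- replicate(60, {
    n <- 100
    x <- rnorm(n)
    y <- 1 + 0.5 * x + rnorm(n)
    fit <- lm(y ~ x)
    sqrt(diag(sandwich::vcovHC(fit, type = "HC1")))[2] /
      sqrt(diag(vcov(fit)))[2]
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)

  # variance growing with the predictor: robust SEs are larger
  set.seed(19)
  bigger <- replicate(30, {
    n <- 300
    x <- runif(n, 0.5, 3)
    y <- 1 + 0.5 * x + rnorm(n, sd = x^2)
    fit <- lm(y ~ x)
    sqrt(diag(sandwich::vcovHC(fit, type = "HC1")))[2] >
      sqrt(diag(vcov(fit)))[2]
  })
  expect_gt(mean(bigger), 0.9)
})

test_that("SRS association recovers an exact log-linear construction", {
  n <- 60
  set.seed(23)
  dr <- rnorm(n, 9, 0.5)
  eo <- dr + rnorm(n, 0.3, 0.4)
  age <- round(runif(n, 60, 95))
  sexm <- rep(0:1, length.out = n)
  srs <- exp(3.9 - 0.32 * (eo - dr) + 0.01 * (age - 74) + 0.2 * sexm)
  tab <- data.frame(
    subject = rep(sprintf("S%03d", 1:n), 2),
    diagnosis = "TD", condition = rep(c("DR", "EO"), each = n),
    region = "temporal_right", paf_hz = c(dr, eo),
    age_months = rep(age, 2),
    sex = rep(ifelse(sexm == 1, "male", "female"), 2),
    srs_total = rep(srs, 2))
  m <- suppressWarnings(srs_association(tab, "temporal_right"))
  expect_equal(coef(m)[["delta_paf"]], -0.32, tolerance = 1e-8)

  tab$srs_total[1] <- -2
  expect_error(srs_association(tab, "temporal_right"), "nonpositive")
})

test_that("SRS slope is centered on zero when reactivity is decoupled", {
  d <- cohort_design(srs_coupling = 0, srs_diagnosis = 0)
  est <- sapply(1:30, function(s) {
    tab <- generate_cohort(d, seed = 500 + s)$table
    coef(srs_association(tab, "temporal_right"))[["delta_paf"]]
  })
  expect_lt(abs(mean(est)), 0.08)
})

test_that("region fits are independent of other regions' rows", {
  tab <- generate_cohort(cohort_design(), seed = 31)$table
  full <- fit_reactivity_lmm(tab, "temporal_right")
  dropped <- fit_reactivity_lmm(tab[tab$region != "frontal_left", ],
                                "temporal_right")
  expect_equal(coef(full), coef(dropped))
  expect_equal(full$coefficients$se, dropped$coefficients$se)
})
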