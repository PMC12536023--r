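test_that("synthetic spectra match their generative model exactly", {
  # pure power law: collinear log-log points with the injected slope
  psd <- synth_psd(spectral_params(offset = 2, exponent = 1.5,
                                   peak_amplitude = 0),
                   freqs = seq(1, 55, by = 0.2))
  pts <- data.frame(lf = log10(psd$freqs), lp = log10(psd$power))
  cf <- coef(lm(lp ~ lf, pts))
  expect_equal(unname(cf[2]), -1.5, tolerance = 1e-12)
  expect_lt(max(abs(residuals(lm(lp ~ lf, pts)))), 1e-12)

  # peak argmax over the band sits at the grid point nearest the center
  psd2 <- synth_psd(spectral_params(offset = 2, exponent = 1.5,
                                    peak_center = 10, peak_amplitude = 0.4,
                                    peak_width = 1))
  flat_true <- psd2$power / 10^(2 - 1.5 * log10(psd2$freqs))
  band <- psd2$freqs >= 7 & psd2$freqs <= 13
  f_band <- psd2$freqs[band]
  expect_equal(f_band[which.max(flat_true[band])],
               f_band[which.min(abs(f_band - 10))])

  expect_error(synth_psd(spectral_params(), freqs = c(-1, 1, 2)),
               "positive")
})

test_that("generator truth closes with the estimator", {
  fit <- estimate_paf(synth_psd(spectral_params(peak_center = 10.2,
                                                peak_amplitude = 0.3,
                                                peak_width = 1.2)))
  expect_lt(abs(fit$paf - 10.2), 0.05)
})

test_that("time-series synthesis is seed-deterministic", {
  p <- spectral_params(noise_sd = 0.02)
  x1 <- synth_timeseries(p, seed = 42)
  x2 <- synth_timeseries(p, seed = 42)
  expect_identical(x1, x2)
  x3 <- synth_timeseries(p, seed = 43)
  expect_false(identical(x1, x3))
  expect_error(synth_timeseries(p, duration = 3), "too short")
})

test_that("welch spectra of shaped signals recover the injected shape", {
  # exponent recovery within 0.15
  x <- synth_timeseries(spectral_params(exponent = 1.5,
                                        peak_amplitude = 0.4), seed = 2)
  psd <- compute_psd(x, 500)
  ap <- fit_aperiodic_huber(log_log_points(psd))
  expect_lt(abs(ap$slope + 1.5), 0.15)

  # alpha-band maximum of the flattened spectrum lands within 0.3 Hz of mu
  for (s in 1:5) {
    mu <- 8 + s
    x <- synth_timeseries(spectral_params(peak_center = mu,
                                          peak_amplitude = 0.4), seed = s)
    fl <- flatten(psd <- compute_psd(x, 500),
                  fit_aperiodic_huber(log_log_points(psd)))
    band <- fl$freqs >= 7 & fl$freqs <= 13
    expect_lt(abs(fl$freqs[band][which.max(fl$ratio[band])] - mu), 0.3)
  }
})

test_that("peak-free signals are declared absent across seeds", {
  absent <- sapply(1:40, function(s) {
    x <- synth_timeseries(spectral_params(peak_amplitude = 0), seed = s)
    estimate_paf(compute_psd(x, 500))$status == "absent"
  })
  expect_gte(mean(absent), 0.95)
})

test_that("cohort generation is deterministic and correctly sized", {
  d <- cohort_design()
  c1 <- generate_cohort(d, seed = 7)
  c2 <- generate_cohort(d, seed = 7)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$spectra_params, c2$spectra_params)

  tab <- c1$table
  expect_equal(length(unique(tab$subject)), 51)
  expect_equal(sum(tab$condition == "DR" & tab$region == "temporal_right" &
                     tab$diagnosis == "TD"), 29)
  expect_equal(sum(tab$condition == "DR" & tab$region == "temporal_right" &
                     tab$diagnosis == "ASD"), 22)
  expect_equal(nrow(tab), 51 * 10 * 2)
  expect_true(all(tab$age_months >= 60 & tab$age_months <= 95))
  expect_true(all(tab$srs_total > 0))
  # failed cells carry no alpha peak in the spectral parameters
  failed <- is.na(tab$paf_hz)
  expect_true(all(c1$spectra_params$peak_amplitude[failed] == 0))
  expect_true(all(c1$spectra_params$peak_amplitude[!failed] > 0))
})

test_that("zero effects and zero noise give a flat cohort", {
  d <- cohort_design(beta_condition = 0, beta_diagnosis = 0,
                     beta_interaction = 0, beta_age = 0, beta_sex = 0,
                     subject_sd = 0, residual_sd = 0, change_sd = 0,
                     baseline_coupling = 0, failure_prob = c(TD = 0, ASD = 0))
  tab <- generate_cohort(d, seed = 1)$table
  expect_true(all(abs(tab$paf_hz - d$base_paf) < 1e-12))
})

test_that("design validation rejects bad inputs", {
  expect_error(cohort_design(n_td = 0))
  expect_error(cohort_design(failure_prob = c(TD = -0.1, ASD = 0.5)))
  expect_error(cohort_design(beta_condition = c(bogus_region = 1)))
})
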