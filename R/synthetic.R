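#' Spectral shape parameters for synthetic region-level spectra
#'
#' Parameterises the generative model of one region-level power spectrum:
#' a power-law aperiodic background plus an additive Gaussian alpha peak in
#' log10-power, `log10 P(f) = offset - exponent * log10 f +
#' peak_amplitude * exp(-(f - peak_center)^2 / (2 peak_width^2)) + noise`.
#' With `peak_amplitude = 0` the spectrum is a pure power law.
#'
#' @param offset log10-power intercept.
#' @param exponent Aperiodic slope magnitude (> 0 for physiological shapes).
#' @param peak_center Alpha peak center in Hz.
#' @param peak_amplitude Peak height in log10-power units (>= 0; 0 = none).
#' @param peak_width Peak standard deviation in Hz (> 0).
#' @param noise_sd Per-bin noise standard deviation in log10-power units.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(offset = 1.5, exponent = 1.2, peak_center = 10,
                            peak_amplitude = 0.35, peak_width = 1.2,
                            noise_sd = 0) {
  stopifnot(exponent > 0, peak_amplitude >= 0, peak_width > 0, noise_sd >= 0)
  structure(list(offset = offset, exponent = exponent,
                 peak_center = peak_center, peak_amplitude = peak_amplitude,
                 peak_width = peak_width, noise_sd = noise_sd),
            class = "spectral_params")
}

#' @export
print.spectral_params <- function(x, ...) {
  cat(sprintf(
    "Spectral params: offset %.2f, exponent %.2f, peak %s, noise sd %.3f\n",
    x$offset, x$exponent,
    if (x$peak_amplitude > 0)
      sprintf("%.2f @ %.2f Hz (width %.2f)", x$peak_amplitude,
              x$peak_center, x$peak_width)
    else "none", x$noise_sd))
  invisible(x)
}

# Noise-free model spectrum on a frequency grid (linear power units).
model_power <- function(params, freqs) {
  lp <- params$offset - params$exponent * log10(freqs)
  if (params$peak_amplitude > 0)
    lp <- lp + params$peak_amplitude *
      exp(-(freqs - params$peak_center)^2 / (2 * params$peak_width^2))
  10^lp
}

#' Synthesise a power spectrum
#'
#' Evaluates the generative spectral model on a frequency grid, optionally
#' adding independent Gaussian noise in log10-power space.
#'
#' @param params A [spectral_params()].
#' @param freqs Strictly increasing frequency grid in Hz, all positive.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A [paf_psd()].
#' @examples
#' psd <- synth_psd(spectral_params(peak_amplitude = 0))  # pure power law
#' @export
synth_psd <- function(params, freqs = seq(0.2, 55, by = 0.2), seed = NULL) {
  stopifnot(inherits(params, "spectral_params"))
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  lp <- log10(model_power(params, freqs))
  if (params$noise_sd > 0)
    lp <- lp + with_seed(seed, rnorm(length(freqs), 0, params$noise_sd))
  paf_psd(freqs, 10^lp)
}

#' Synthesise a time series with a target spectrum
#'
#' Generates a real-valued signal whose power spectral density matches the
#' generative spectral model, by inverse-FFT shaping: deterministic Fourier
#' amplitudes set from the target one-sided density with uniformly random
#' phases.  The full-length periodogram of the output equals the target
#' exactly; Welch estimates over sub-epochs recover it up to window leakage
#' and averaging noise.
#'
#' @param params A [spectral_params()].
#' @param fs Sampling rate in Hz (must be at least twice the highest
#'   frequency analysed downstream; 500 recommended).
#' @param duration Length in seconds (>= 50 to satisfy the minimum-epoch
#'   gate at the default spectral settings).
#' @param seed Optional integer seed.
#' @return Numeric vector of `fs * duration` samples.
#' @export
synth_timeseries <- function(params, fs = 500, duration = 120, seed = NULL) {
  stopifnot(inherits(params, "spectral_params"), fs > 0, duration > 0)
  n <- round(fs * duration)
  if (n < fs * 5)
    stop("duration too short for a single 5-s epoch")
  with_seed(seed, {
    n_half <- n %/% 2
    f <- (1:(n_half - 1)) * fs / n
    lp <- log10(model_power(params, f))
    if (params$noise_sd > 0) lp <- lp + rnorm(length(f), 0, params$noise_sd)
    # |X_k|^2 = P(f_k) * fs * n / 2 makes the one-sided periodogram equal P
    amp <- sqrt(10^lp * fs * n / 2)
    phase <- runif(length(f), 0, 2 * pi)
    X <- complex(modulus = amp, argument = phase)
    spec <- complex(real = numeric(n), imaginary = numeric(n))
    spec[2:n_half] <- X
    spec[n - (1:(n_half - 1)) + 1] <- Conj(X)
    Re(fft(spec, inverse = TRUE)) / n
  })
}

#' The ten macro-regions
#'
#' @return Character vector of the 10 lobe-by-hemisphere macro-region names.
#' @export
macro_regions <- function() {
  as.vector(outer(c("cingulate", "frontal", "occipital", "parietal",
                    "temporal"),
                  c("left", "right"), paste, sep = "_"))
}

# Region-wise default fixed effects for the cohort generator (Hz).  These
# are the study-scale condition (DR->EO), diagnosis (ASD-TD) and
# diagnosis-by-condition effects used as simulation truth.
default_region_effects <- function() {
  regions <- macro_regions()
  cond <- c(cingulate_left = 0.104, frontal_left = 0.009,
            occipital_left = 0.668, parietal_left = 0.101,
            temporal_left = 0.309,
            cingulate_right = 0.147, frontal_right = 0.109,
            occipital_right = 0.608, parietal_right = 0.063,
            temporal_right = 0.387)
  diag <- c(cingulate_left = 0.088, frontal_left = -0.037,
            occipital_left = -0.036, parietal_left = -0.100,
            temporal_left = 0.030,
            cingulate_right = 0.079, frontal_right = 0.053,
            occipital_right = -0.068, parietal_right = -0.062,
            temporal_right = 0.471)
  inter <- c(cingulate_left = -0.330, frontal_left = -0.031,
             occipital_left = -0.331, parietal_left = -0.094,
             temporal_left = -0.522,
             cingulate_right = -0.252, frontal_right = -0.178,
             occipital_right = -0.355, parietal_right = -0.074,
             temporal_right = -0.662)
  list(condition = cond[regions], diagnosis = diag[regions],
       interaction = inter[regions])
}

#' Design of a synthetic two-condition cohort
#'
#' Describes the cohort the generator emulates: 29 typically developing
#' (TD) and 22 autistic (ASD) children aged 60-95 months, each measured in
#' a dark-room (DR) and an eyes-open (EO) condition over 10 macro-regions.
#' True PAF per subject, region and condition follows a linear model with
#' region-specific condition, diagnosis and interaction effects, age and
#' sex effects, a shared subject-level random intercept, and a
#' baseline-dependent change component: the EO-DR change includes
#' `baseline_coupling * (DR - regional mean DR)`.  Social responsiveness
#' (SRS) raw totals are generated on the log scale, coupled to the true
#' right-temporal PAF change.  Peak detection failure is simulated by
#' flagging region-by-subject-by-condition cells at a group-specific rate;
#' flagged cells get no alpha peak (and a missing PAF).
#'
#' @param n_td,n_asd Group sizes.
#' @param age_range_months Inclusive age range in months.
#' @param prop_male Named probabilities of male sex per group.
#' @param base_paf Reference PAF (Hz) for a TD girl of average age, DR.
#' @param beta_condition,beta_diagnosis,beta_interaction Named numeric
#'   vectors over [macro_regions()] (Hz).
#' @param beta_age Hz per month of age (centered at `age_center`).
#' @param age_center Centering age in months.
#' @param beta_sex Hz added for male sex.
#' @param subject_sd SD of the subject random intercept (Hz).
#' @param residual_sd SD of the DR-condition residual (Hz).
#' @param change_sd SD of the change-score residual (Hz).
#' @param baseline_coupling Slope of the EO-DR change on the realized DR
#'   value (dimensionless).
#' @param srs_intercept,srs_diagnosis,srs_age,srs_sex,srs_coupling,srs_sd
#'   Log-scale SRS model: intercept, ASD shift, age and sex effects,
#'   effect per Hz of true right-temporal PAF change, and residual SD.
#' @param failure_prob Named per-group probability that a region cell fails
#'   peak detection.
#' @param spectra List of hyperparameters for the per-cell spectral shapes
#'   (means and SDs of offset, exponent, peak amplitude and width, plus the
#'   per-bin noise SD).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_td = 29, n_asd = 22,
                          age_range_months = c(60, 95),
                          prop_male = c(TD = 0.552, ASD = 0.636),
                          base_paf = 8.6,
                          beta_condition = NULL,
                          beta_diagnosis = NULL,
                          beta_interaction = NULL,
                          beta_age = 0.037, age_center = 74,
                          beta_sex = 0.3,
                          subject_sd = 0.3, residual_sd = 0.4,
                          change_sd = 0.35,
                          baseline_coupling = -0.624,
                          srs_intercept = 3.85, srs_diagnosis = 0.15,
                          srs_age = 0.017, srs_sex = 0.205,
                          srs_coupling = -0.324, srs_sd = 0.2,
                          failure_prob = c(TD = 0.05, ASD = 0.08),
                          spectra = list(offset_mean = 1.5, offset_sd = 0.2,
                                         exponent_mean = 1.2,
                                         exponent_sd = 0.15,
                                         amplitude_mean = 0.35,
                                         amplitude_sd = 0.08,
                                         width_mean = 1.2, width_sd = 0.2,
                                         noise_sd = 0.015)) {
  eff <- default_region_effects()
  expand <- function(x, default) {
    if (is.null(x)) return(default)
    if (length(x) == 1 && is.null(names(x)))
      return(setNames(rep(x, 10), macro_regions()))
    stopifnot(all(macro_regions() %in% names(x)))
    x[macro_regions()]
  }
  stopifnot(n_td >= 1, n_asd >= 1,
            length(age_range_months) == 2,
            age_range_months[2] >= age_range_months[1],
            all(failure_prob >= 0), all(failure_prob <= 1),
            all(c("TD", "ASD") %in% names(failure_prob)),
            all(prop_male >= 0), all(prop_male <= 1),
            subject_sd >= 0, residual_sd >= 0, change_sd >= 0, srs_sd >= 0)
  structure(list(n_td = n_td, n_asd = n_asd,
                 age_range_months = age_range_months,
                 prop_male = prop_male, base_paf = base_paf,
                 beta_condition = expand(beta_condition, eff$condition),
                 beta_diagnosis = expand(beta_diagnosis, eff$diagnosis),
                 beta_interaction = expand(beta_interaction, eff$interaction),
                 beta_age = beta_age, age_center = age_center,
                 beta_sex = beta_sex, subject_sd = subject_sd,
                 residual_sd = residual_sd, change_sd = change_sd,
                 baseline_coupling = baseline_coupling,
                 srs_intercept = srs_intercept,
                 srs_diagnosis = srs_diagnosis, srs_age = srs_age,
                 srs_sex = srs_sex, srs_coupling = srs_coupling,
                 srs_sd = srs_sd, failure_prob = failure_prob,
                 spectra = spectra),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("Cohort design: %d TD + %d ASD, age %d-%d months\n",
              x$n_td, x$n_asd, x$age_range_months[1], x$age_range_months[2]))
  cat(sprintf("  interaction (right temporal): %.3f Hz; baseline coupling %.3f\n",
              x$beta_interaction[["temporal_right"]], x$baseline_coupling))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_design()]: a long PAF table (subject
#' x macro-region x condition), per-cell spectral shape parameters from
#' which region spectra or time series can be synthesised, and a truth
#' record holding every injected coefficient for recovery tests.
#'
#' @param design A [cohort_design()].
#' @param seed Optional integer seed; with a seed the output is fully
#'   deterministic.
#' @return An object of class `paf_cohort`: list with
#'   \describe{
#'     \item{table}{data frame with columns `subject`, `diagnosis`
#'       (`TD`/`ASD`), `condition` (`DR`/`EO`), `hemisphere`, `lobe`,
#'       `region`, `paf_hz` (NA where peak detection failed),
#'       `age_months`, `sex` (`female`/`male`), `srs_total`.}
#'     \item{spectra_params}{data frame keyed like `table` with the
#'       generative spectral parameters of each cell (`peak_amplitude` is 0
#'       in failed cells).}
#'     \item{truth}{list of injected coefficients, subject intercepts and
#'       the underlying (pre-failure) PAF values.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_design(n_td = 4, n_asd = 3), seed = 1)
#' head(coh$table)
#' @export
generate_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    n <- design$n_td + design$n_asd
    subjects <- sprintf("S%03d", seq_len(n))
    diagnosis <- rep(c("TD", "ASD"), c(design$n_td, design$n_asd))
    sex <- ifelse(rbinom(n, 1, design$prop_male[diagnosis]) == 1,
                  "male", "female")
    age <- round(runif(n, design$age_range_months[1],
                       design$age_range_months[2]))
    u <- rnorm(n, 0, design$subject_sd)
    regions <- macro_regions()
    asd <- as.numeric(diagnosis == "ASD")
    male <- as.numeric(sex == "male")
    agec <- age - design$age_center

    dr <- eo <- matrix(NA_real_, n, length(regions),
                       dimnames = list(subjects, regions))
    for (r in regions) {
      dr[, r] <- design$base_paf +
        design$beta_diagnosis[[r]] * asd +
        design$beta_age * agec + design$beta_sex * male + u +
        rnorm(n, 0, design$residual_sd)
      delta <- design$beta_condition[[r]] +
        design$beta_interaction[[r]] * asd +
        design$baseline_coupling * (dr[, r] - mean(dr[, r])) +
        rnorm(n, 0, design$change_sd)
      eo[, r] <- dr[, r] + delta
    }

    delta_rt <- eo[, "temporal_right"] - dr[, "temporal_right"]
    log_srs <- design$srs_intercept + design$srs_diagnosis * asd +
      design$srs_coupling * delta_rt +
      design$srs_age * agec + design$srs_sex * male +
      rnorm(n, 0, design$srs_sd)
    srs <- round(exp(log_srs), 1)

    grid <- expand.grid(subject = subjects, region = regions,
                        condition = c("DR", "EO"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(grid$subject, subjects)
    true_paf <- ifelse(grid$condition == "DR",
                       dr[cbind(i, match(grid$region, regions))],
                       eo[cbind(i, match(grid$region, regions))])
    failed <- rbinom(nrow(grid), 1,
                     design$failure_prob[diagnosis[i]]) == 1

    hemi <- sub("^.*_", "", grid$region)
    lobe <- sub("_.*$", "", grid$region)
    tab <- data.frame(subject = grid$subject, diagnosis = diagnosis[i],
                      condition = grid$condition, hemisphere = hemi,
                      lobe = lobe, region = grid$region,
                      paf_hz = ifelse(failed, NA_real_, true_paf),
                      age_months = age[i], sex = sex[i],
                      srs_total = srs[i], stringsAsFactors = FALSE)
    ord <- order(tab$subject, tab$region, tab$condition)
    tab <- tab[ord, ]
    rownames(tab) <- NULL

    sp <- design$spectra
    m <- nrow(grid)
    spectra_params <- data.frame(
      subject = grid$subject, region = grid$region,
      condition = grid$condition,
      offset = rnorm(m, sp$offset_mean, sp$offset_sd),
      exponent = pmax(0.3, rnorm(m, sp$exponent_mean, sp$exponent_sd)),
      peak_center = true_paf,
      peak_amplitude = ifelse(failed, 0,
                              pmax(0.1, rnorm(m, sp$amplitude_mean,
                                              sp$amplitude_sd))),
      peak_width = pmax(0.5, rnorm(m, sp$width_mean, sp$width_sd)),
      noise_sd = sp$noise_sd, stringsAsFactors = FALSE)[ord, ]
    rownames(spectra_params) <- NULL

    structure(list(table = tab, spectra_params = spectra_params,
                   truth = list(design = design,
                                subject_intercepts = setNames(u, subjects),
                                true_dr = dr, true_eo = eo,
                                delta_right_temporal = setNames(delta_rt,
                                                                subjects),
                                failed = failed[ord])),
              class = "paf_cohort")
  })
}

#' @export
print.paf_cohort <- function(x, ...) {
  tab <- x$table
  cat(sprintf(
    "Synthetic cohort: %d subjects (%d TD, %d ASD), %d regions x 2 conditions; %d/%d cells missing\n",
    length(unique(tab$subject)),
    length(unique(tab$subject[tab$diagnosis == "TD"])),
    length(unique(tab$subject[tab$diagnosis == "ASD"])),
    length(unique(tab$region)), sum(is.na(tab$paf_hz)), nrow(tab)))
  invisible(x)
}
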