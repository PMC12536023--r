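---
title: "Peak alpha frequency estimation and condition reactivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak alpha frequency estimation and condition reactivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pafreact)
```

# The problem

The peak alpha frequency (PAF) — the frequency at which alpha-band
(7–13 Hz) cortical activity is strongest — is a developmental and
clinical marker in M/EEG research. Estimating it from a power spectrum is
complicated by the aperiodic 1/f background, which can shift or mask the
apparent peak, and by the fact that in clinical paediatric cohorts many
region-level spectra simply have no detectable alpha peak. This package
implements a complete PAF *reactivity* analysis: spectral estimation,
robust peak extraction, region aggregation with explicit validity rules,
and mixed-model statistics comparing a dark-room resting condition (DR)
with an eyes-open video-viewing condition (EO) in two diagnostic groups
(typically developing, TD, and autistic, ASD, children).

# Spectral estimation

Region-level recordings are segmented into 5-s epochs with 80% overlap;
each epoch is mean-removed, Hamming-tapered, and its one-sided
periodogram computed without zero-padding, so the bin spacing is exactly
`1/epoch_seconds` = 0.2 Hz. Periodograms are averaged (Welch's method)
with a window-power correction, so the density integrates to the signal
variance over `[0, fs/2]`. A recording must supply at least 10 epochs
(50 s of unique data at the defaults) to enter the analysis.

Two choices here were open:

* **Detrending.** Only the epoch mean is removed; this prevents a DC leak
  into the low bins without touching the low-frequency slope the 1/f fit
  needs.
* **Normalisation.** One-sided density (power/Hz). The PAF procedure is
  invariant to any positive rescaling of the spectrum (the log-log line
  absorbs it into the intercept), so this choice affects reported power
  only, never the PAF.

# The PAF estimator

For each spectrum:

1. **Log-log transform** over 1–55 Hz (base 10 throughout; the base
   cancels in the PAF).
2. **Robust 1/f fit**: `log10 P = b + m log10 f` by iteratively
   reweighted least squares with Huber weights at tuning constant
   M = 1.35. Residuals are standardised by 1.4826 × their median absolute
   deviation, re-estimated each iteration; convergence is declared when
   coefficients change by less than 1e-8 (at most 200 iterations, with an
   early exit when the residual scale collapses to zero, i.e. an exact
   fit). The fit uses *all* bins in 1–55 Hz including the alpha band:
   Huber downweighting is the mechanism that keeps the narrow-band peak
   from tilting the line, and the package tests verify that it does so
   strictly better than ordinary least squares whenever a peak is
   present.
3. **Flattening**: subtract the fitted line in log space and
   exponentiate, giving the ratio of observed to aperiodic power
   (1 everywhere for a pure power law).
4. **Gaussian peak fit** on the 7–13 Hz portion of the flattened
   spectrum: `ratio ≈ 1 + a·exp(−(f−c)²/2w²)` by bounded
   Levenberg–Marquardt least squares (`minpack.lm`). The baseline is
   fixed at 1 because flattening guarantees it; there is no free offset.
   Initialisation: centre at the in-band argmax, amplitude at
   `max(ratio) − 1`, width 1 Hz. Bounds: centre in 6–14 Hz, width
   0.2–6 Hz, amplitude ≥ 0. The centre bound is deliberately *wider*
   than the band so that a peak just outside 7–13 Hz is found where it
   is and then rejected by the band rule, rather than being dragged onto
   the boundary and accepted.

The fitted vertex is the PAF. A peak is **absent** when (a) fewer than 5
bins fall in the band, (b) the optimiser fails (as it does, correctly, on
an exactly flat input), (c) the fitted centre falls outside 7–13 Hz, or
(d) the amplitude does not exceed the detection floor below. Absence is a
value, not an error; each absence carries a reason code.

An overall R² is computed in log10-power space over 1–55 Hz between the
observed spectrum and the full model (aperiodic line plus, when a peak is
present, `log10(1 + a·exp(·))`). Fitting happens in log space, so the fit
quality is reported there; note this conflates periodic and aperiodic
misfit, and a mediocre R² does not by itself impugn the peak location.

## The detection floor

The band rule alone cannot separate true peaks from estimation noise: a
flattened Welch spectrum fluctuates around 1, and an unconstrained
least-squares fit will happily lock onto the largest noise excursion.
Measured on this package's own Welch path (116 overlapping 5-s epochs of
a 120-s recording), such spurious fits have amplitudes below ~0.035 ratio
units, while a modest physiological peak of 0.15 log10-power units
already produces a flattened amplitude of `10^0.15 − 1 ≈ 0.41`. The
default floor `min_amplitude = 0.1` sits between the two: an order of
magnitude above the noise fits, a quarter of the weakest peak of
interest. With the floor in place, peak-free 120-s signals are declared
absent in ≥ 95% of seeded replicates, while detection of injected peaks
degrades gracefully as the injected amplitude shrinks. Set
`min_amplitude = 0` to recover the pure band rule.

# Region aggregation

The 68 Desikan–Killiany parcels map onto 10 macro-regions (cingulate,
frontal, occipital, parietal, temporal × hemisphere); per hemisphere the
lobes hold 4, 11, 4, 5 and 10 parcels. The insula belongs to no classical
lobe; it is assigned to the adjacent temporal group, and the mapping is
shipped as a plain-text table (`inst/extdata/dk_macro_regions.tsv`) so
users can override that choice — the loader revalidates any override (68
unique parcels, 10 macro-regions, mirror-symmetric hemispheres).

Within a macro-region, the PAF is the arithmetic mean of the parcels with
*valid* (present, in-band) estimates; absent parcels are excluded rather
than imputed, and a macro-region with no valid parcel is missing. This
rule means aggregation can only rescue subjects, never lose them: the
macro-level completeness always dominates the parcel-level validity
proportion, which is reported as
`100 × n_present / (n_parcels × n_subjects)`.

# Statistical analysis

All models code TD, DR and female as reference levels; sex coding is a
convention, not a claim. Per macro-region:

* **Reactivity**: `paf ~ diagnosis * condition + age + sex +
  (1 | subject)`, fitted by maximum likelihood (`lme4`), with Wald z
  statistics — the convention of the software family these models are
  usually reported from. REML is available as an option. Missing cells
  are dropped (complete case within each model); singular or
  non-converged fits are flagged in the result object, never silently
  NA'd.
* **Bonferroni gates**: strict `p < 0.05/5 = 0.01` across the five
  region families (hemispheric pairs are correlated, so the correction
  counts families, not regions), and `p < 0.025` for the two within-group
  follow-ups, which refit `paf ~ condition + age + sex + (1 | subject)`
  per diagnostic group (each subgroup fit estimates its own residual
  variance).
* **Baseline dependence**: per region, OLS of the change score
  `ΔPAF = EO − DR` on baseline (DR) PAF, diagnosis, age and sex, with
  HC1 heteroscedasticity-robust standard errors and t statistics on the
  residual degrees of freedom; optionally with a diagnosis × baseline
  interaction. HC1 is the conventional default of that software family;
  under homoscedasticity it agrees with the classical covariance to a few
  percent, and the tests check both that agreement and the directional
  inflation under variance growing with the predictor. Note that a
  negative baseline slope arises from regression to the mean alone
  whenever the two conditions are noisy and equicorrelated (slope
  ≈ correlation − 1); the package tests pin this closed form down so the
  genuine coupling and the artefact are not confused.
* **Trait association**: OLS of `log(SRS)` on ΔPAF, age and sex (HC1
  SEs), in regions whose interaction survived the gate. The natural log
  is used; the base rescales coefficients by a constant and is recorded
  in the model metadata. Nonpositive raw SRS scores are an error, not a
  silent drop.

# The synthetic cohort generator

The generator is the package's study stand-in: 29 TD and 22 ASD children
aged 60–95 months, two conditions, 10 macro-regions. True PAF follows

```
DR  = base + β_diag·ASD + β_age·(age − 74) + β_sex·male + u_subj + ε_DR
ΔPAF = β_cond + β_int·ASD + γ·(DR − regional mean DR) + ε_Δ
EO  = DR + ΔPAF
```

with a shared subject intercept `u_subj` (SD 0.3 Hz — the within-subject
correlation of PAF across regions is not characterised empirically, so a
single shared intercept is exposed as a tunable rather than asserted),
condition residual SD 0.4 Hz and change residual SD 0.35 Hz. The default
region-wise effects are study-scale values: a right-temporal
diagnosis-by-condition interaction of −0.662 Hz, bilateral occipital
condition effects of ~0.6 Hz, age slope 0.037 Hz/month, and a baseline
coupling γ = −0.624. SRS totals are generated on the log scale,
coupled to the true right-temporal ΔPAF at −0.324 per Hz, with a direct
diagnosis shift of 0.15 chosen so that the *total* group difference
(direct plus reactivity-mediated) reproduces the descriptive group means
(≈ 48 vs 69).

Each cell also receives generative spectral parameters (offset, exponent,
peak amplitude/width) from which `synth_psd()` or `synth_timeseries()`
can materialise data for the estimation path. The per-bin log10 noise
default is 0.015, calibrated to the averaging noise of the package's own
Welch estimates at 116 epochs; peak-detection failure is simulated by
zeroing the peak amplitude of randomly chosen cells at group-specific
rates (TD 0.05, ASD 0.08 — chosen so macro-level completeness matches a
cohort in which nearly all participants contribute to every macro-region,
with slightly more loss in the ASD group).

Time series are synthesised by inverse-FFT spectral shaping with random
phases and deterministic amplitudes, so the full-length periodogram
equals the target spectrum exactly and only window leakage and averaging
noise separate the Welch estimate from it.

**What the generator does not emulate**: sensor-level physics and
artifacts, head models, source leakage between regions, non-Gaussian or
nonstationary dynamics, region-specific aperiodic exponents, multi-peak
alpha structure, and any dependence of detection failure on the signal
itself (failure is injected at random, not caused by low SNR). Passing
recovery tests therefore demonstrates that the estimator and the models
are correct *for data satisfying their own assumptions* — not that those
assumptions hold in recorded MEG.

## Recovery simulations

Two generator couplings are switched off in specific recovery
experiments, by design rather than convenience:

* Coefficient recovery for the interaction (and the null calibration)
  sets γ = 0, because a nonzero baseline coupling feeds the diagnosis
  main effect into the change score and shifts the *marginal* interaction
  away from the injected value — the experiment would otherwise measure a
  mixture, not the estimator's bias.
* SRS-slope recovery sets the direct diagnosis shift to 0, because the
  trait model (deliberately mirroring its reference analysis) omits
  diagnosis, and the direct shift would confound the marginal slope.

Problem sizes: recovery means use 200 replicate cohorts at study scale
(51 subjects), null calibration uses 500, and estimator–oracle agreement
uses 20 noisy spectra against a brute-force grid search at 0.01 Hz centre
resolution with the amplitude profiled in closed form. These sizes put
Monte-Carlo error comfortably below the tolerances being checked while
keeping the full suite in the tens of seconds.

# Worked example

```{r example, eval = FALSE}
psd <- synth_psd(spectral_params(peak_center = 10.2, peak_amplitude = 0.3,
                                 peak_width = 1.2))
fit <- estimate_paf(psd)
fit
plot(fit)

coh <- generate_cohort(cohort_design(), seed = 1)
m <- fit_reactivity_lmm(coh$table, "temporal_right")
m
bonferroni_gate(m$coefficients$p[6], 5)
```

# Known limitations

* The aperiodic model is a single power law; spectra with a "knee" (a
  bend in log-log space) are fit with whatever compromise line Huber
  weighting finds. No multi-peak decomposition is attempted: if the
  flattened band is multimodal, the single-Gaussian least-squares fit
  resolves it to one compromise vertex, which is precisely what makes the
  estimator well-defined for indistinct peaks, and precisely what makes
  it blind to split peaks.
* Wald z inference in the mixed models is asymptotic; at 51 subjects the
  null rejection rate of the interaction test measures slightly above
  nominal (~0.06 at α = 0.05 over 500 replicates), consistent with using
  z rather than a small-sample t and ML rather than REML.
* The detection floor trades sensitivity for specificity at a fixed
  recording length; much shorter recordings have noisier flattened
  spectra and would need a higher floor (or longer recordings).
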