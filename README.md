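# pafreact

Peak alpha frequency (PAF) estimation and condition-reactivity analysis
for region-level M/EEG power spectra.

The alpha rhythm's peak frequency is a marker of cortical maturation and
cognitive function, and how it *shifts* between recording conditions —
here a dark-room resting state (DR) versus eyes-open video viewing (EO) —
is of particular interest when comparing autistic (ASD) and typically
developing (TD) children. `pafreact` is for researchers who have
region-level spectra or time series (e.g. source-reconstructed MEG
parcels) and want the complete analysis chain with every rule explicit
and tested: Welch spectra, robust peak extraction, lobe-level
aggregation, and the mixed-model statistics, plus a synthetic cohort
generator that makes the whole pipeline verifiable without any recorded
data.

## The estimator

For a spectrum \(P(f)\), the aperiodic background is modelled as a power
law, linear in log-log space,

    log10 P(f) = b − χ · log10 f,

and fitted over 1–55 Hz by Huber robust regression (M = 1.35, IRLS with
MAD rescaling) so that the alpha bump is downweighted instead of tilting
the line. The spectrum is flattened by subtract-then-exponentiate, and
the 7–13 Hz band of the flattened ratio is fitted with a fixed-baseline
Gaussian,

    ratio(f) ≈ 1 + a · exp(−(f − μ)² / 2σ²).

The fitted vertex μ is the PAF. A peak is *absent* when the fitted centre
leaves the 7–13 Hz band or the amplitude fails a detection floor
(`min_amplitude = 0.1` ratio units; set 0 for the pure band rule).
Parcel estimates are averaged into 10 lobe-by-hemisphere macro-regions
over valid parcels only (missing if none), and reactivity is analysed
with

    paf ~ diagnosis * condition + age + sex + (1 | subject)

per region (ML, Wald z, Bonferroni gate p < 0.05/5), followed by
within-group condition models, baseline-dependent change regressions and
log-SRS trait associations with HC1 robust standard errors.

## Worked example

```r
library(pafreact)

psd <- synth_psd(spectral_params(peak_center = 10.2, peak_amplitude = 0.3,
                                 peak_width = 1.2))
fit <- estimate_paf(psd)
fit
#> Peak alpha frequency fit
#>   aperiodic: intercept 1.500, slope -1.200 (Huber M = 1.35)
#>   alpha peak: PAF = 10.200 Hz, amplitude 0.981, width 1.085 Hz
#>   fit R^2 (log10-power, 1-55 Hz): 1.000
```

The injected peak (10.2 Hz, 0.3 log10-power units ≙ flattened amplitude
10^0.3 − 1 ≈ 1.0) is recovered exactly on a noiseless spectrum, as is the
aperiodic slope −1.2. On a synthetic cohort the statistical battery
recovers the injected effects:

```r
coh <- generate_cohort(cohort_design(), seed = 1)
coh
#> Synthetic cohort: 51 subjects (29 TD, 22 ASD), 10 regions x 2 conditions; 66/1020 cells missing

fit_reactivity_lmm(coh$table, "temporal_right")
#> reactivity mixed model — region temporal_right (model-based SEs, z statistics)
#>                      term estimate    se statistic     p  ci_lo  ci_hi
#>               (Intercept)    6.985 0.524    13.341 0.000  5.958  8.011
#>              diagnosisASD    0.350 0.150     2.330 0.020  0.056  0.645
#>               conditionEO    0.447 0.101     4.424 0.000  0.249  0.644
#>                       age    0.025 0.007     3.677 0.000  0.012  0.038
#>                   sexmale    0.258 0.125     2.065 0.039  0.013  0.504
#>  diagnosisASD:conditionEO   -0.920 0.157    -5.847 0.000 -1.228 -0.612
```

The interaction row is this cohort draw's estimate of the injected
−0.662 Hz right-temporal diagnosis-by-condition effect (single-cohort
estimates scatter with SE ≈ 0.16–0.24; averaged over replicate cohorts
the estimator is unbiased to < 0.01 Hz — see the acceptance script). A
negative interaction means the EO-over-DR PAF increase seen in TD
children is absent (or reversed) in the ASD group.

`run_pipeline()` chains simulate → synthesise spectra → estimate →
aggregate → analyse into a run directory with a JSON manifest;
`inst/cli/pafreact-cli.R` exposes the same stages as shell subcommands.
See the methods vignette (`vignettes/paf-reactivity-methods.Rmd`) for the
model details, numerical choices and the generator's scope.

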