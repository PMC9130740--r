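# nbrlifespan

Event-related fMRI analysis of how the **negative BOLD response (NBR)**
changes across the adult lifespan — for researchers studying sensorimotor
deactivation, haemodynamic-response (HR) ageing, or the pitfalls of
fixed-kernel GLM analysis in ageing cohorts.

During a right-hand button press, contralateral sensorimotor cortex
(cSM1) activates (positive BOLD response, PBR) while ipsilateral
sensorimotor cortex (iSM1) and the default-mode posterior cingulate
deactivate (NBR). With age the iSM1 NBR grows shallower and peaks later.
A conventional GLM convolves event timings with the canonical
double-gamma HRF, so a late-peaking response is scored as weak even at
unchanged amplitude: apparent ageing effects mix true amplitude loss
with kernel misfit. This package implements the machinery to separate
the two:

* **Synthetic data**: a rapid audiovisual paradigm generator (2–26 s
  SOAs on a 2 s grid, 120 bimodal + 8 unimodal trials, 261 volumes at
  TR 1.97 s), lifespan HR trajectories (iSM1 amplitude −0.034 → −0.013
  fractional signal change and time-to-peak 10 → 18 s between the
  youngest and oldest age bins), AR(1)+drift noise, age-scaled motion
  traces, toy block atlas, NIfTI/TSV/CSV output.
* **First-level GLM**: per-condition regressors from a model
  `y = β₀ + A·(s ∗ h) + drift + ε`, mean ± contrasts, OLS with t→Z
  mapping, Gaussian smoothing, motion regressors.
* **FIR deconvolution**: shape-free HR estimation at TR resolution from
  pooled constant-amplitude event trains; peak magnitude and
  time-to-peak metrics; decile-mean HRs; unit-extremum normalization.
* **Re-analysis**: refit the GLM with normalized decile-mean data-driven
  kernels and compare percent-of-youngest-decile |Z| profiles against
  the canonical analysis (with an anti-circularity split-half option).
* **ROI & extent**: subject-specific 27-voxel cubic ROIs at response
  peaks, per-sign 5%-of-max spatial-extent proportions and PBR/NBR
  ratio, 18/19/18 tertile splits, framewise displacement.
* **Group statistics**: second-level mean + age-covariate maps, pairwise
  decile contrasts, one-way ANOVA, Welch post-hoc tests, Pearson
  correlations, age residualization, nested-regression incremental-F.

## Worked example

Simulate an oldest-decile subject, deconvolve its iSM1 HR, and compare
the canonical GLM with a data-driven refit:

```r
library(nbrlifespan)

schedule <- generate_paradigm(seed = 1)
schedule
#> <event_schedule: 128 trials over 514.2 s>
#>   SOA range 2.00-26.00 s, mean 4.03 s

spec <- subject_spec(age = 82.6, motion_seed = 1, noise_seed = 2)
tc <- synthesize_region_timecourse(spec, schedule, "iSM1")
hr <- deconvolve_hr(tc, schedule, tr = 1.97, window = 24)
hr_metrics(hr)
#> <hr_metrics: peak -0.01636 at 19.7 s>

canonical <- canonical_double_gamma(dt = 0.01)
fit_can <- fit_glm(tc, build_design_matrix(schedule, canonical, 1.97, 261))
fit_dd <- rerun_glm_with_hr(tc, schedule, normalize_hr(hr),
                            tr = 1.97, n_volumes = 261)
abs(fit_can$contrasts$nbr$z)   # canonical |Z| = 1.11
abs(fit_dd$contrasts$pbr$z)    # data-driven |Z| = 13.17
```

The injected response (amplitude −0.013, peaking near 18 s) is invisible
to the canonical kernel (|Z| ≈ 1.1) but strongly detected once the
subject's own deconvolved HR shapes the regressor (|Z| ≈ 13) — note that
with a negative-going kernel the positive contrast carries the NBR.

At cohort level, the canonical kernel manufactures a much steeper
apparent decline than the data-driven kernels:

```r
cohort <- simulate_cohort(n_per_decile = 5, seed = 3)
cmp <- lifespan_kernel_comparison(cohort, schedule)
cmp$summary[, c("decile", "pct_twenties_canonical",
                "pct_twenties_datadriven")]
#>       decile pct_twenties_canonical pct_twenties_datadriven
#>     Twenties                  100.0                   100.0
#>     Thirties                   60.3                   102.2
#>      Forties                   39.2                    96.9
#>      Fifties                   27.7                    86.8
#>      Sixties                   29.9                    74.3
#>    Seventies                   13.5                    68.4
#>     Eighties                   15.5                    60.6
```

A shell front end wrapping the same functions is installed at
`inst/cli/nbr-pipeline.R` with subcommands `simulate`, `first-level`,
`deconvolve`, `group` and `pipeline`.

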