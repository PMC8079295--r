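# shuttlebox

Analysis pipeline for **shuttle-box hypoxia-avoidance trials** with weakly
electric fish. A shuttle-box is a two-compartment choice chamber whose
dissolved oxygen (DO, % air saturation) is controlled per compartment; after
a normoxic baseline, DO on the fish's preferred side is stepped down
(70 → 50 → 30 → 25 → 20 → 15 → 10 %) while the refuge side stays normoxic.
The package turns per-second position logs and electric organ discharge
(EOD) recordings into the standard outputs of such an experiment:

* **Behavioural metrics** per 10-min interval: residence in the hypoxic
  compartment, shelter time, side changes, distance, velocity (BL/s).
* **The hypoxia-avoidance threshold** via broken-stick (segmented)
  regression with linear mixed models: two random-intercept LMMs
  `residence ~ DO + (1 | fish)` fitted above and below every admissible
  split of the DO levels, the split chosen by minimum summed RSS, and the
  threshold defined as the intersection of the two fixed-effect lines —
  the mixed-model generalisation of the classic two-segment P~crit~
  procedure. Satterthwaite t-tests and Nakagawa marginal/conditional R² are
  reported per segment.
* **EOD frequency tracking**: per-second spectral peak frequency
  (zero-padded FFT, 0.076 Hz resolution), baseline-normalised interval
  medians, the Q10 temperature prediction
  `100·(Q10^(ΔT/10) − 1)`, and a zero-intercept random-slope mixed model of
  frequency change vs time and hypoxia exposure.
* **Hypothesis tests**: one-sample Wilcoxon for baseline side preference,
  Friedman tests across intervals with Holm-corrected paired Wilcoxon
  post-hocs, and a repeated-measures ANOVA for repeatability.
* **A synthetic-trial generator** (cohort parameters, trajectories, EOD
  voltage traces) that emulates the study conditions — 16 fish, strong
  baseline side preference, one non-responder, threshold-triggered roaming
  with brief excursions into hypoxia, EOD base frequencies 807–1151 Hz,
  slight temperature drift — so the whole pipeline is testable without any
  recordings.

It is written tidyverse-style: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, and `autoplot()` for results.

## Worked example

```r
library(shuttlebox)

cfg <- sim_config(n_fish = 16, seed = 1)   # default 200-min protocol
res <- run_avoidance_pipeline(cfg)          # simulate -> metrics -> threshold
res$fit
#> <broken_stick_fit> split at 18.75 % air sat -> threshold 20.57 % air sat (total RSS 28941.46)
#> pre-threshold segment:
#> <lmm_fit> lmm | n = 176 obs, 16 fish | RSS = 16134.11 | R2m = 0.012, R2c = 0.050
#>          term estimate std_error    df statistic   p_value
#> 1 (Intercept) 95.52205   1.61294 116.4    59.222 9.240e-89
#> 2          do  0.04117   0.02808 160.0     1.467 1.445e-01
#> post-threshold segment:
#> <lmm_fit> lmm | n = 64 obs, 16 fish | RSS = 12807.34 | R2m = 0.459, R2c = 0.727
#>          term estimate std_error    df statistic   p_value
#> 1 (Intercept)  -53.230    10.664 61.84    -4.992 5.171e-06
#> 2          do    7.274     0.707 48.00    10.289 9.892e-14
```

The cohort was simulated with a population avoidance threshold of 22 % air
saturation (and one non-responder); the estimator reads it back at 20.6 %:
a flat pre-threshold segment (slope 0.041, p = 0.14 — DO has no effect on
residence above threshold) and a steep post-threshold segment (slope 7.3 per
% air saturation, p < 0.001) whose intersection is the threshold.
`autoplot(res$fit, data = res$residence)` draws the dose-response plot with
both regression lines and the threshold diamond.

Baseline side preference across the cohort is near-exclusive and clearly
non-random:

```r
behavior_report(res$summaries)$side_preference
#>   method                            statistic  p_value     n
#> 1 one-sample Wilcoxon signed-rank         136  0.00015    16
```

The Q10 temperature argument in one line: cooling of 0.15 °C at Q10 = 1.55
predicts an EOD frequency change of

```r
q10_predicted_change(1.55, -0.15)
#> [1] -0.6552264    # i.e. a drop of ~0.7 %
```

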